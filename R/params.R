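#' Base-case model parameters
#'
#' Returns the full base-case parameter set of the model: treatment efficacy
#' (relative risks vs. no treatment, with 95% intervals), cumulative
#' persistence curves, the alendronate adherence curve, age-banded hip and
#' clinical vertebral fracture incidence in the general female population,
#' risk modifiers (osteoporosis multipliers, prior-fracture multipliers,
#' post-hip-fracture mortality hazards), all costs in Japanese yen, utilities
#' and fracture disutility multipliers, economic settings, and the two
#' treatment strategies compared (3 years of annual zoledronic acid versus
#' 3 years of biannual denosumab followed by 3 years of weekly alendronate).
#'
#' The life table is deliberately left unset: attach one with
#' [load_life_table()], [make_synthetic_life_table()] or
#' [japan_like_life_table()] before running the engine.
#'
#' All monetary values are stored in yen; dollars are a display conversion at
#' the fixed rate in `econ$yen_per_usd`. Rates given per 100,000 persons are
#' stored as printed and divided at the point of use. Percentages are stored
#' as fractions.
#'
#' @return An object of class `osteo_config` (a validated nested list).
#' @export
#' @examples
#' cfg <- default_parameters()
#' cfg$efficacy$za$rr_vert  # 0.40
default_parameters <- function() {
  cfg <- list(
    start_age = 65L,
    horizon_age = 105L,
    n_trials = 100000L,
    seed = 1L,

    efficacy = list(
      za = list(
        rr_hip = 0.64, rr_hip_ci = c(0.47, 0.86),
        rr_vert = 0.40, rr_vert_ci = c(0.29, 0.55)
      ),
      deno = list(
        rr_hip = 0.56, rr_hip_ci = c(0.31, 0.94),
        rr_vert = 0.30, rr_vert_ci = c(0.21, 0.43)
      ),
      aln = list(
        rr_hip = 0.64, rr_hip_ci = c(0.45, 0.88),
        rr_vert = 0.50, rr_vert_ci = c(0.40, 0.64)
      )
    ),

    persistence = list(
      za = list(
        cumulative = c(1.00, 0.52, 0.36),
        ci_low = c(1.00, 0.40, 0.23), ci_high = c(1.00, 0.65, 0.50),
        permissive_gap_days = 90L
      ),
      deno = list(
        cumulative = c(0.81, 0.55, 0.37),
        ci_low = c(0.76, 0.48, 0.33), ci_high = c(0.85, 0.63, 0.43),
        permissive_gap_days = 60L
      ),
      aln = list(
        cumulative = c(0.55, 0.39, 0.28),
        ci_low = NULL, ci_high = NULL,  # varied as a +/-25% triangular multiplier
        permissive_gap_days = 30L
      )
    ),

    adherence = list(
      anchors = data.frame(year = c(1, 5), fraction = c(0.706, 0.609)),
      beyond_last_rule = "hold_last",
      triangular_pct = 0.13
    ),

    incidence = list(
      hip = data.frame(
        age_low  = c(65, 70, 75, 80, 85, 90, 95, 100),
        age_high = c(69, 74, 79, 84, 89, 94, 99, 105),
        rate = c(83.9, 158.1, 362.2, 851.1, 1580.2, 2466.0, 2961.7, 2471.0)
      ),
      vert = data.frame(
        age_low  = c(65, 70, 75, 80, 85, 90, 95, 100),
        age_high = c(69, 74, 79, 84, 89, 94, 99, 105),
        rate = c(156.7, 513.9, 1106.2, 2034.1, 2331.2, 3638.0, 4369.3, 3645.4)
      )
    ),

    risk = list(
      rr_osteo_hip = data.frame(
        age_low  = c(65, 70, 75, 80, 85),
        age_high = c(69, 74, 79, 84, 105),
        rr = c(2.39, 1.89, 1.57, 1.35, 1.25),
        ci_low  = c(2.16, 1.79, 1.52, 1.32, 1.22),
        ci_high = c(2.60, 1.99, 1.62, 1.38, 1.27)
      ),
      rr_osteo_vert = data.frame(
        age_low  = c(65, 70, 80),
        age_high = c(69, 79, 105),
        rr = c(2.47, 2.09, 1.86),
        ci_low  = c(2.10, 1.84, 1.68),
        ci_high = c(2.86, 2.34, 2.04)
      ),
      rr_prior_hip = 2.3,  rr_prior_hip_ci = c(1.5, 3.7),
      rr_prior_vert = 4.4, rr_prior_vert_ci = c(3.6, 5.4),
      rh_mort_hip_year1 = 2.87, rh_mort_hip_year1_ci = c(2.52, 3.27),
      rh_mort_hip_later = 1.73, rh_mort_hip_later_ci = c(1.56, 1.90),
      rh_mort_vert_year1 = 1.0,
      rh_mort_vert_later = 1.0,
      attributable_fraction_hip = 0.25,
      attributable_fraction_hip_range = c(0, 0.50),
      attributable_fraction_vert = 0
    ),

    costs = list(
      med_annual = c(za = 38000, deno = 58000, aln = 8700),
      rx_charge_aln = 1700,
      visit_first = c(za = 5500, deno = 3100, aln = 3600),
      visit_subsequent = c(za = 3900, deno = 1500, aln = 1900),
      blood_test = 2900,
      dxa = 4500,
      fx_hip = 1726000,
      fx_vert_first = 420000,
      fx_vert_subsequent = 842000,
      ltc_post_hip = 876000,
      ltc_post_vert = 213000
    ),

    utilities = list(
      base_by_age = data.frame(
        age_low  = c(65, 70, 75, 80, 85),
        age_high = c(69, 74, 79, 84, 105),
        utility = c(0.862, 0.810, 0.771, 0.769, 0.684)
      ),
      mult_hip_y1 = 0.776,    mult_hip_y1_ci = c(0.720, 0.844),
      mult_hip_later = 0.855, mult_hip_later_ci = c(0.800, 0.909),
      mult_vert_y1 = 0.724,   mult_vert_y1_ci = c(0.667, 0.779),
      mult_vert_later = 0.868, mult_vert_later_ci = c(0.827, 0.922),
      triangular_pct = 0.15
    ),

    econ = list(
      perspective = "healthcare_plus_ltc",
      discount_cost = 0.02,
      discount_qaly = 0.02,
      wtp = c(5e6, 1e7),
      yen_per_usd = 105
    ),

    scenario_flags = list(
      vert_excess_mortality = FALSE,
      reduced_deno_visits = FALSE,
      biosimilar_deno = FALSE,
      long_duration = FALSE,
      persistence_scenario = "base",
      deno_rebound = FALSE
    ),

    life_table = NULL
  )
  cfg$strategies <- list(
    za = list(name = "za",
              episodes = list(list(drug = "za", years = 3L, gap_before = 0L)),
              handoff_rule = "only_if_persistent_through_previous_episode"),
    da = list(name = "da",
              episodes = list(list(drug = "deno", years = 3L, gap_before = 0L),
                              list(drug = "aln", years = 3L, gap_before = 0L)),
              handoff_rule = "only_if_persistent_through_previous_episode")
  )
  class(cfg) <- "osteo_config"
  validate_config(cfg)
}

band_value <- function(bands, age, col) {
  i <- which(age >= bands$age_low & age <= bands$age_high)
  if (length(i) != 1L) {
    stop("age ", age, " not covered by a unique band", call. = FALSE)
  }
  bands[[col]][i]
}

check_bands <- function(bands, field, value_col, lo = 65, hi = 105) {
  if (any(bands[[value_col]] < 0)) {
    stop("range error in '", field, "': negative values", call. = FALSE)
  }
  o <- order(bands$age_low)
  bands <- bands[o, , drop = FALSE]
  if (bands$age_low[1] > lo || bands$age_high[nrow(bands)] < hi) {
    stop("validation error in '", field, "': bands must cover ages ",
         lo, "-", hi, call. = FALSE)
  }
  if (nrow(bands) > 1 &&
      any(bands$age_low[-1] != bands$age_high[-nrow(bands)] + 1)) {
    stop("validation error in '", field, "': bands must be contiguous",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a model configuration
#'
#' Checks every structural and range invariant of the configuration: relative
#' risks in (0, 1], persistence curves non-increasing in `[0, 1]`, adherence
#' fractions in (0, 1], contiguous age bands covering 65-105, non-negative
#' costs, utilities in (0, 1], discount rates in `[0, 0.10]`, and strategy
#' episode durations of at least one year. Throws an error naming the
#' offending field; returns the configuration invisibly when valid.
#'
#' @param cfg An `osteo_config` object (or a plain list with the same shape).
#' @return The validated configuration, invisibly.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("range error in '", field, "': ", msg, call. = FALSE)
  }
  if (!cfg$start_age %in% c(65L, 70L, 75L, 80L)) {
    fail("start_age", "must be one of 65, 70, 75, 80")
  }
  if (cfg$horizon_age != 105L) fail("horizon_age", "must be 105")
  if (cfg$n_trials < 1) fail("n_trials", "must be >= 1")

  for (drug in .DRUGS) {
    e <- cfg$efficacy[[drug]]
    for (site in c("hip", "vert")) {
      rr <- e[[paste0("rr_", site)]]
      ci <- e[[paste0("rr_", site, "_ci")]]
      if (!(rr > 0 && rr <= 1)) {
        fail(paste0("efficacy.", drug, ".rr_", site), "RR must be in (0, 1]")
      }
      if (!is.null(ci) && !(ci[1] <= rr && rr <= ci[2])) {
        fail(paste0("efficacy.", drug, ".rr_", site, "_ci"),
             "interval must bracket the base value")
      }
    }
    p <- cfg$persistence[[drug]]$cumulative
    if (length(p) < 1 || any(p < 0 | p > 1)) {
      fail(paste0("persistence.", drug, ".cumulative"),
           "values must lie in [0, 1]")
    }
    if (any(diff(p) > 1e-12)) {
      fail(paste0("persistence.", drug, ".cumulative"),
           "cumulative persistence must be non-increasing")
    }
  }
  a <- cfg$adherence$anchors
  if (any(a$fraction <= 0 | a$fraction > 1)) {
    fail("adherence.anchors", "fractions must be in (0, 1]")
  }
  if (any(diff(a$year) <= 0)) fail("adherence.anchors",
                                   "years must be strictly increasing")

  check_bands(cfg$incidence$hip, "incidence.hip", "rate")
  check_bands(cfg$incidence$vert, "incidence.vert", "rate")
  check_bands(cfg$risk$rr_osteo_hip, "risk.rr_osteo_hip", "rr")
  check_bands(cfg$risk$rr_osteo_vert, "risk.rr_osteo_vert", "rr")
  check_bands(cfg$utilities$base_by_age, "utilities.base_by_age", "utility")

  r <- cfg$risk
  for (f in c("rr_prior_hip", "rr_prior_vert", "rh_mort_hip_year1",
              "rh_mort_hip_later", "rh_mort_vert_year1", "rh_mort_vert_later")) {
    if (r[[f]] < 1) fail(paste0("risk.", f), "multiplier must be >= 1")
  }
  for (f in c("attributable_fraction_hip", "attributable_fraction_vert")) {
    if (r[[f]] < 0 || r[[f]] > 1) fail(paste0("risk.", f),
                                       "fraction must be in [0, 1]")
  }

  cvals <- unlist(cfg$costs)
  if (any(cvals < 0)) fail("costs", "all costs must be >= 0")

  u <- cfg$utilities
  if (any(u$base_by_age$utility <= 0 | u$base_by_age$utility > 1)) {
    fail("utilities.base_by_age", "utilities must be in (0, 1]")
  }
  for (f in c("mult_hip_y1", "mult_hip_later", "mult_vert_y1",
              "mult_vert_later")) {
    if (u[[f]] <= 0 || u[[f]] > 1) fail(paste0("utilities.", f),
                                        "multiplier must be in (0, 1]")
  }

  ec <- cfg$econ
  if (!ec$perspective %in% c("healthcare_plus_ltc", "healthcare_only")) {
    fail("econ.perspective", "unknown perspective")
  }
  if (ec$discount_cost < 0 || ec$discount_cost > 0.10 ||
      ec$discount_qaly < 0 || ec$discount_qaly > 0.10) {
    fail("econ.discount", "discount rates must be in [0, 0.10]")
  }
  if (any(ec$wtp <= 0)) fail("econ.wtp", "willingness-to-pay must be > 0")

  for (s in cfg$strategies) {
    for (ep in s$episodes) {
      if (!ep$drug %in% .DRUGS) fail("strategies", "unknown drug")
      if (ep$years < 1) fail("strategies", "planned_years must be >= 1")
    }
  }
  sf <- cfg$scenario_flags
  if (!sf$persistence_scenario %in% c("base", "s1", "s2", "s3")) {
    fail("scenario_flags.persistence_scenario", "must be base, s1, s2 or s3")
  }
  if (!is.null(cfg$life_table)) validate_life_table(cfg$life_table)
  invisible(cfg)
}

# ---- configuration text I/O --------------------------------------------------

band_like_fields <- c("anchors", "base_by_age")

config_to_list <- function(cfg) {
  strip <- function(x) {
    if (is.data.frame(x)) {
      as.list(x)
    } else if (is.list(x)) {
      x <- x[!vapply(x, is.null, logical(1))]
      lapply(x, strip)
    } else if (!is.null(names(x))) {
      as.list(x)  # named vectors must stay mappings through YAML
    } else {
      x
    }
  }
  out <- strip(unclass(cfg))
  out$life_table <- NULL  # attached separately, not part of the config text
  out
}

rebuild_config <- function(lst) {
  as_df <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  for (site in c("hip", "vert")) {
    lst$incidence[[site]] <- as_df(lst$incidence[[site]])
  }
  lst$risk$rr_osteo_hip <- as_df(lst$risk$rr_osteo_hip)
  lst$risk$rr_osteo_vert <- as_df(lst$risk$rr_osteo_vert)
  lst$utilities$base_by_age <- as_df(lst$utilities$base_by_age)
  lst$adherence$anchors <- as_df(lst$adherence$anchors)
  for (d in names(lst$persistence)) {
    for (f in c("ci_low", "ci_high")) {
      if (!is.null(lst$persistence[[d]][[f]]) &&
          length(lst$persistence[[d]][[f]]) == 0) {
        lst$persistence[[d]][[f]] <- NULL
      }
    }
  }
  cm <- lst$costs
  for (f in c("med_annual", "visit_first", "visit_subsequent")) {
    cm[[f]] <- unlist(cm[[f]])
  }
  lst$costs <- cm
  class(lst) <- "osteo_config"
  lst
}

#' Serialise a configuration to YAML text
#'
#' The attached life table (if any) is not serialised; life tables travel as
#' separate CSV files (see [load_life_table()]).
#'
#' @param cfg An `osteo_config`.
#' @return A single YAML string.
#' @export
serialize_config <- function(cfg) {
  yaml::as.yaml(config_to_list(cfg))
}

deep_merge <- function(base, override) {
  if (!is.list(base) || !is.list(override) || is.data.frame(base)) {
    return(override)
  }
  for (nm in names(override)) {
    base[[nm]] <- if (nm %in% names(base)) {
      deep_merge(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

#' Load a model configuration from YAML
#'
#' Reads a YAML document whose keys mirror the structure returned by
#' [default_parameters()]; any field not present falls back to the base-case
#' default. An empty document therefore yields the base case. The merged
#' configuration is validated before being returned.
#'
#' @param text A YAML string, or a path to a YAML file.
#' @return A validated `osteo_config`.
#' @export
#' @examples
#' cfg <- load_config("efficacy:\n  za:\n    rr_hip: 0.60\n")
#' cfg$efficacy$za$rr_hip
load_config <- function(text) {
  ov <- if (length(text) == 1 && file.exists(text)) {
    yaml::read_yaml(text)
  } else {
    yaml::yaml.load(paste(text, collapse = "\n"))
  }
  if (is.null(ov)) ov <- list()
  if (!is.list(ov)) stop("validation error: configuration must be a mapping",
                         call. = FALSE)
  base <- config_to_list(default_parameters())
  known <- names(base)
  unknown <- setdiff(names(ov), known)
  if (length(unknown)) {
    stop("validation error: unknown field(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- deep_merge(base, ov)
  cfg <- rebuild_config(merged)
  validate_config(cfg)
  cfg
}

# ---- life tables -------------------------------------------------------------

validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns age and qx", call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("range error in life table: death probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (max(lt$age) < 105) {
    stop("coverage error: life table must extend to age 105", call. = FALSE)
  }
  invisible(lt)
}

new_life_table <- function(age, qx, source = "unspecified") {
  lt <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  lt <- lt[order(lt$age), ]
  attr(lt, "source") <- source
  class(lt) <- c("life_table", "data.frame")
  validate_life_table(lt)
  lt
}

#' Load a female life table from delimited text
#'
#' Expects two columns, `age` and `qx` (annual death probability); a header
#' row is optional. Abridged tables listing only every fifth age are filled
#' in by linear interpolation of the log death probability, which keeps the
#' filled values positive and monotone between anchors. The table must extend
#' to age 105 (the model horizon).
#'
#' @param path Path to a CSV file, or a character vector of CSV lines.
#' @return A `life_table` data frame with one row per single year of age.
#' @export
#' @examples
#' lt <- load_life_table(c("age,qx", "65,0.004", "105,0.5"))
#' lt$qx[lt$age == 85]  # exp(mean(log(c(0.004, 0.5))))
load_life_table <- function(path) {
  raw <- if (length(path) == 1 && file.exists(path)) {
    readLines(path)
  } else {
    as.character(path)
  }
  raw <- raw[nzchar(trimws(raw))]
  has_header <- grepl("[A-Za-z]", raw[1])
  df <- read.csv(text = paste(raw, collapse = "\n"), header = has_header)
  if (!has_header) names(df) <- c("age", "qx")
  names(df) <- tolower(names(df))
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life table must have columns age and qx", call. = FALSE)
  }
  if (any(df$qx < 0 | df$qx > 1)) {
    stop("range error in life table: death probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(df$qx == 0)) {
    # log-interpolation needs positive anchors; a literal zero is treated as
    # a vanishingly small hazard
    df$qx[df$qx == 0] <- 1e-10
  }
  if (max(df$age) < 105) {
    stop("coverage error: life table must extend to age 105", call. = FALSE)
  }
  ages <- seq(min(df$age), max(df$age))
  lq <- approx(df$age, log(df$qx), xout = ages)$y
  new_life_table(ages, exp(lq), source = "loaded")
}

q_at <- function(life_table, age) {
  i <- match(age, life_table$age)
  if (anyNA(i)) {
    stop("age ", paste(age[is.na(i)], collapse = ", "),
         " not covered by the life table", call. = FALSE)
  }
  life_table$qx[i]
}

#' Attach a life table to a configuration
#'
#' @param cfg An `osteo_config`.
#' @param life_table A `life_table`, e.g. from [load_life_table()].
#' @return The configuration with the table attached, validated.
#' @export
attach_life_table <- function(cfg, life_table) {
  validate_life_table(life_table)
  if (min(life_table$age) > cfg$start_age) {
    stop("coverage error: life table starts above start_age", call. = FALSE)
  }
  cfg$life_table <- life_table
  cfg
}

#' Set or replace fields of a configuration by dotted path
#'
#' Used by the one-way sensitivity machinery: `set_param(cfg,
#' "efficacy.za.rr_vert", 0.55)` returns a revalidated copy. Vector values
#' replace vector fields wholesale.
#'
#' @param cfg An `osteo_config`.
#' @param path Dotted field path.
#' @param value Replacement value.
#' @param validate Revalidate afterwards (default `TRUE`).
#' @return The modified configuration.
#' @export
set_param <- function(cfg, path, value, validate = TRUE) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- cfg
  for (k in keys[-length(keys)]) {
    if (is.null(ref[[k]])) stop("unknown parameter '", path, "'", call. = FALSE)
    ref <- ref[[k]]
  }
  last <- keys[length(keys)]
  if (is.null(ref[[last]])) stop("unknown parameter '", path, "'", call. = FALSE)
  cfg[[keys]] <- value
  if (validate) validate_config(cfg)
  cfg
}

get_param <- function(cfg, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- cfg
  for (k in keys) {
    if (is.null(out[[k]])) stop("unknown parameter '", path, "'", call. = FALSE)
    out <- out[[k]]
  }
  out
}
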