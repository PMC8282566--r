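#' Fit a sampling distribution to a base value and range
#'
#' Triangular specifications use the base value as the mode with support
#' `[low, high]`. Beta and gamma specifications interpret `(low, high)` as a
#' 95% interval: the two shape parameters are solved numerically so that the
#' 2.5% and 97.5% quantiles reproduce the interval to within 1e-3 relative
#' error (an error is raised if the family cannot achieve it).
#'
#' @param spec List with `family` (`"beta"`, `"gamma"`, `"triangular"`),
#'   `base`, `low`, `high`.
#' @return A `psa_sampler`: the spec plus `qfun(u)` (quantile function) and
#'   `rfun(n)` (random draws).
#' @export
#' @examples
#' s <- fit_sampler(list(family = "beta", base = 0.40, low = 0.29,
#'                       high = 0.55))
#' s$qfun(0.025)  # ~0.29
fit_sampler <- function(spec) {
  family <- match.arg(spec$family, c("beta", "gamma", "triangular"))
  base <- spec$base
  low <- spec$low
  high <- spec$high
  if (!(low <= base && base <= high)) {
    stop("require low <= base <= high", call. = FALSE)
  }
  if (high - low < .Machine$double.eps) {
    qfun <- function(u) rep(base, length(u))
    return(structure(c(spec, list(qfun = qfun,
                                  rfun = function(n) rep(base, n),
                                  params = NULL)),
                     class = "psa_sampler"))
  }

  if (family == "triangular") {
    a <- low; b <- high; cm <- base
    fc <- (cm - a) / (b - a)
    qfun <- function(u) {
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (cm - a)),
             b - sqrt((1 - u) * (b - a) * (b - cm)))
    }
    return(structure(c(spec, list(qfun = qfun,
                                  rfun = function(n) qfun(runif(n)),
                                  params = c(a = a, b = b, c = cm))),
                     class = "psa_sampler"))
  }

  qdist <- if (family == "beta") qbeta else qgamma
  m <- (low + high) / 2
  s <- (high - low) / (2 * 1.959964)
  init <- if (family == "beta") {
    v <- s^2
    a0 <- max(m * (m * (1 - m) / v - 1), 0.1)
    b0 <- max((1 - m) * (m * (1 - m) / v - 1), 0.1)
    log(c(a0, b0))
  } else {
    log(c(max(m^2 / s^2, 1e-3), max(m / s^2, 1e-6)))
  }
  obj <- function(par) {
    p <- exp(par)
    ql <- qdist(0.025, p[1], p[2])
    qh <- qdist(0.975, p[1], p[2])
    ((ql - low) / low)^2 + ((qh - high) / high)^2
  }
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  p <- exp(fit$par)
  rel_err <- max(abs(qdist(0.025, p[1], p[2]) - low) / abs(low),
                 abs(qdist(0.975, p[1], p[2]) - high) / abs(high))
  if (rel_err > 1e-3) {
    stop("infeasible interval for ", family, " family (relative error ",
         signif(rel_err, 3), ")", call. = FALSE)
  }
  qfun <- function(u) qdist(u, p[1], p[2])
  structure(c(spec, list(qfun = qfun, rfun = function(n) qfun(runif(n)),
                         params = p)),
            class = "psa_sampler")
}

# samplers for every distribution-bearing parameter of the base case;
# built once and cached (quantile-matching is iterative)
.sampler_cache <- new.env(parent = emptyenv())

psa_samplers <- function(cfg) {
  key <- "base"
  if (!is.null(.sampler_cache[[key]])) return(.sampler_cache[[key]])
  beta_s <- function(base, ci) fit_sampler(list(family = "beta", base = base,
                                                low = ci[1], high = ci[2]))
  gamma_s <- function(base, ci) fit_sampler(list(family = "gamma", base = base,
                                                 low = ci[1], high = ci[2]))
  tri_pm <- function(pct) fit_sampler(list(family = "triangular", base = 1,
                                           low = 1 - pct, high = 1 + pct))
  e <- cfg$efficacy
  p <- cfg$persistence
  u <- cfg$utilities
  r <- cfg$risk
  s <- list(
    eff_za_hip = beta_s(e$za$rr_hip, e$za$rr_hip_ci),
    eff_za_vert = beta_s(e$za$rr_vert, e$za$rr_vert_ci),
    eff_deno_hip = beta_s(e$deno$rr_hip, e$deno$rr_hip_ci),
    eff_deno_vert = beta_s(e$deno$rr_vert, e$deno$rr_vert_ci),
    eff_aln_hip = beta_s(e$aln$rr_hip, e$aln$rr_hip_ci),
    eff_aln_vert = beta_s(e$aln$rr_vert, e$aln$rr_vert_ci),
    pers_za_y2 = beta_s(p$za$cumulative[2], c(p$za$ci_low[2], p$za$ci_high[2])),
    pers_za_y3 = beta_s(p$za$cumulative[3], c(p$za$ci_low[3], p$za$ci_high[3])),
    pers_deno_y1 = beta_s(p$deno$cumulative[1],
                          c(p$deno$ci_low[1], p$deno$ci_high[1])),
    pers_deno_y2 = beta_s(p$deno$cumulative[2],
                          c(p$deno$ci_low[2], p$deno$ci_high[2])),
    pers_deno_y3 = beta_s(p$deno$cumulative[3],
                          c(p$deno$ci_low[3], p$deno$ci_high[3])),
    pers_aln_mult = tri_pm(0.25),
    adherence_mult = tri_pm(cfg$adherence$triangular_pct),
    cost_hip_mult = tri_pm(0.50),
    cost_vert_mult = tri_pm(0.50),
    cost_ltc_mult = tri_pm(0.50),
    util_mult = tri_pm(u$triangular_pct),
    dis_hip_y1 = beta_s(u$mult_hip_y1, u$mult_hip_y1_ci),
    dis_hip_later = beta_s(u$mult_hip_later, u$mult_hip_later_ci),
    dis_vert_y1 = beta_s(u$mult_vert_y1, u$mult_vert_y1_ci),
    dis_vert_later = beta_s(u$mult_vert_later, u$mult_vert_later_ci),
    inc_hip_mult = tri_pm(0.10),
    inc_vert_mult = tri_pm(0.25),
    prior_hip = gamma_s(r$rr_prior_hip, r$rr_prior_hip_ci),
    prior_vert = gamma_s(r$rr_prior_vert, r$rr_prior_vert_ci),
    rh_hip_y1 = gamma_s(r$rh_mort_hip_year1, r$rh_mort_hip_year1_ci),
    rh_hip_later = gamma_s(r$rh_mort_hip_later, r$rh_mort_hip_later_ci),
    af_hip = fit_sampler(list(family = "triangular",
                              base = r$attributable_fraction_hip,
                              low = r$attributable_fraction_hip_range[1],
                              high = r$attributable_fraction_hip_range[2])),
    disc_cost = fit_sampler(list(family = "triangular", base = 0.02,
                                 low = 0, high = 0.04)),
    disc_qaly = fit_sampler(list(family = "triangular", base = 0.02,
                                 low = 0, high = 0.04))
  )
  for (band in seq_len(nrow(r$rr_osteo_hip))) {
    s[[paste0("osteo_hip_", band)]] <-
      gamma_s(r$rr_osteo_hip$rr[band],
              c(r$rr_osteo_hip$ci_low[band], r$rr_osteo_hip$ci_high[band]))
  }
  for (band in seq_len(nrow(r$rr_osteo_vert))) {
    s[[paste0("osteo_vert_", band)]] <-
      gamma_s(r$rr_osteo_vert$rr[band],
              c(r$rr_osteo_vert$ci_low[band], r$rr_osteo_vert$ci_high[band]))
  }
  .sampler_cache[[key]] <- s
  s
}

# apply one joint parameter draw (vector of uniform quantiles, one per
# sampler) to the base configuration. Persistence curves share a single
# quantile across their years so sampled curves stay monotone.
draw_psa_config <- function(cfg, samplers, u) {
  q <- function(nm, uu) unname(samplers[[nm]]$qfun(unname(uu)))
  cfg$efficacy$za$rr_hip <- q("eff_za_hip", u["eff_za_hip"])
  cfg$efficacy$za$rr_vert <- q("eff_za_vert", u["eff_za_vert"])
  cfg$efficacy$deno$rr_hip <- q("eff_deno_hip", u["eff_deno_hip"])
  cfg$efficacy$deno$rr_vert <- q("eff_deno_vert", u["eff_deno_vert"])
  cfg$efficacy$aln$rr_hip <- q("eff_aln_hip", u["eff_aln_hip"])
  cfg$efficacy$aln$rr_vert <- q("eff_aln_vert", u["eff_aln_vert"])

  uz <- u["pers_za_y2"]  # shared quantile within the curve
  za <- c(1, q("pers_za_y2", uz), q("pers_za_y3", uz))
  cfg$persistence$za$cumulative <- cummin(za)
  ud <- u["pers_deno_y1"]
  dn <- c(q("pers_deno_y1", ud), q("pers_deno_y2", ud), q("pers_deno_y3", ud))
  cfg$persistence$deno$cumulative <- cummin(dn)
  cfg$persistence$aln$cumulative <-
    pmin(1, cfg$persistence$aln$cumulative * q("pers_aln_mult",
                                               u["pers_aln_mult"]))

  cfg$adherence$anchors$fraction <-
    pmin(1, cfg$adherence$anchors$fraction * q("adherence_mult",
                                               u["adherence_mult"]))

  cfg$costs$fx_hip <- cfg$costs$fx_hip * q("cost_hip_mult", u["cost_hip_mult"])
  vm <- q("cost_vert_mult", u["cost_vert_mult"])
  cfg$costs$fx_vert_first <- cfg$costs$fx_vert_first * vm
  cfg$costs$fx_vert_subsequent <- cfg$costs$fx_vert_subsequent * vm
  lm <- q("cost_ltc_mult", u["cost_ltc_mult"])
  cfg$costs$ltc_post_hip <- cfg$costs$ltc_post_hip * lm
  cfg$costs$ltc_post_vert <- cfg$costs$ltc_post_vert * lm

  cfg$utilities$base_by_age$utility <-
    pmin(1, cfg$utilities$base_by_age$utility * q("util_mult", u["util_mult"]))
  cfg$utilities$mult_hip_y1 <- q("dis_hip_y1", u["dis_hip_y1"])
  cfg$utilities$mult_hip_later <- q("dis_hip_later", u["dis_hip_later"])
  cfg$utilities$mult_vert_y1 <- q("dis_vert_y1", u["dis_vert_y1"])
  cfg$utilities$mult_vert_later <- q("dis_vert_later", u["dis_vert_later"])

  cfg$incidence$hip$rate <- cfg$incidence$hip$rate *
    q("inc_hip_mult", u["inc_hip_mult"])
  cfg$incidence$vert$rate <- cfg$incidence$vert$rate *
    q("inc_vert_mult", u["inc_vert_mult"])

  for (band in seq_len(nrow(cfg$risk$rr_osteo_hip))) {
    nm <- paste0("osteo_hip_", band)
    cfg$risk$rr_osteo_hip$rr[band] <- q(nm, u[nm])
  }
  for (band in seq_len(nrow(cfg$risk$rr_osteo_vert))) {
    nm <- paste0("osteo_vert_", band)
    cfg$risk$rr_osteo_vert$rr[band] <- q(nm, u[nm])
  }
  cfg$risk$rr_prior_hip <- q("prior_hip", u["prior_hip"])
  cfg$risk$rr_prior_vert <- q("prior_vert", u["prior_vert"])
  cfg$risk$rh_mort_hip_year1 <- q("rh_hip_y1", u["rh_hip_y1"])
  cfg$risk$rh_mort_hip_later <- q("rh_hip_later", u["rh_hip_later"])
  cfg$risk$attributable_fraction_hip <- q("af_hip", u["af_hip"])
  cfg$econ$discount_cost <- q("disc_cost", u["disc_cost"])
  cfg$econ$discount_qaly <- q("disc_qaly", u["disc_qaly"])
  cfg
}

#' One-way deterministic sensitivity analysis for one parameter
#'
#' Reruns both arms with the parameter at its low and at its high bound,
#' everything else at base values, using the same seed throughout (common
#' random numbers), and classifies each comparison of zoledronic acid
#' against sequential denosumab/alendronate.
#'
#' @param config Base configuration (life table attached).
#' @param parameter_path Dotted path (or character vector of paths varied
#'   jointly, e.g. a persistence curve).
#' @param low,high Bound value(s); lists when several paths vary jointly.
#' @param seed Seed shared by all runs.
#' @param n_trials Trials per arm.
#' @return A `dsa_result` with `base`, `low` and `high` `ce_comparison`s.
#' @export
run_dsa <- function(config, parameter_path, low, high,
                    seed = config$seed, n_trials = config$n_trials) {
  set_many <- function(cfg, paths, values) {
    if (length(paths) == 1 && !is.list(values)) values <- list(values)
    for (i in seq_along(paths)) {
      cfg <- set_param(cfg, paths[i], values[[i]], validate = FALSE)
    }
    cfg
  }
  arm_pair <- function(cfg) {
    za <- run_arm(cfg, "za", n_trials, seed)
    da <- run_arm(cfg, "da", n_trials, seed)
    compare(za, da)
  }
  base_cmp <- arm_pair(config)
  low_cmp <- arm_pair(set_many(config, parameter_path, low))
  high_cmp <- arm_pair(set_many(config, parameter_path, high))
  structure(list(parameter = paste(parameter_path, collapse = "+"),
                 low = low, high = high,
                 base_comparison = base_cmp,
                 low_comparison = low_cmp,
                 high_comparison = high_cmp),
            class = "dsa_result")
}

#' The one-way sensitivity ranges of the base-case parameter table
#'
#' @param cfg Configuration supplying base values.
#' @return A list of entries with `name`, `path`, `low`, `high` suitable for
#'   [run_dsa()].
#' @export
dsa_default_ranges <- function(cfg = default_parameters()) {
  e <- cfg$efficacy
  p <- cfg$persistence
  entry <- function(name, path, low, high) list(name = name, path = path,
                                                low = low, high = high)
  list(
    entry("ZA efficacy, hip", "efficacy.za.rr_hip",
          e$za$rr_hip_ci[1], e$za$rr_hip_ci[2]),
    entry("ZA efficacy, vertebral", "efficacy.za.rr_vert",
          e$za$rr_vert_ci[1], e$za$rr_vert_ci[2]),
    entry("Denosumab efficacy, hip", "efficacy.deno.rr_hip",
          e$deno$rr_hip_ci[1], e$deno$rr_hip_ci[2]),
    entry("Denosumab efficacy, vertebral", "efficacy.deno.rr_vert",
          e$deno$rr_vert_ci[1], e$deno$rr_vert_ci[2]),
    entry("Alendronate efficacy, hip", "efficacy.aln.rr_hip",
          e$aln$rr_hip_ci[1], e$aln$rr_hip_ci[2]),
    entry("Alendronate efficacy, vertebral", "efficacy.aln.rr_vert",
          e$aln$rr_vert_ci[1], e$aln$rr_vert_ci[2]),
    entry("ZA persistence (years 2-3 jointly)", "persistence.za.cumulative",
          p$za$ci_low, p$za$ci_high),
    entry("Denosumab persistence (jointly)", "persistence.deno.cumulative",
          p$deno$ci_low, p$deno$ci_high),
    entry("Alendronate persistence (+/-25%)", "persistence.aln.cumulative",
          0.75 * p$aln$cumulative, pmin(1, 1.25 * p$aln$cumulative)),
    entry("Alendronate adherence (+/-13%)", "adherence.anchors.fraction",
          0.87 * cfg$adherence$anchors$fraction,
          pmin(1, 1.13 * cfg$adherence$anchors$fraction)),
    entry("Hip fracture cost (+/-50%)", "costs.fx_hip",
          0.5 * cfg$costs$fx_hip, 1.5 * cfg$costs$fx_hip),
    entry("Hip incidence (+/-50%)", "incidence.hip.rate",
          0.5 * cfg$incidence$hip$rate, 1.5 * cfg$incidence$hip$rate),
    entry("Vertebral incidence (+/-50%)", "incidence.vert.rate",
          0.5 * cfg$incidence$vert$rate, 1.5 * cfg$incidence$vert$rate)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Each simulation draws one value per distribution-bearing parameter
#' (persistence curves share a single quantile across years so every sampled
#' curve is monotone), reruns both arms with common random numbers, and
#' records the incremental cost and QALYs of zoledronic acid versus
#' sequential denosumab/alendronate. Cost-effectiveness acceptability is
#' evaluated at the configured willingness-to-pay thresholds from the same
#' set of increments.
#'
#' @param config Base configuration (life table attached).
#' @param n_sims Number of parameter draws.
#' @param n_trials Microsimulation trials per arm per draw.
#' @param seed Master seed; simulation `s` runs its arms with `seed + s`.
#' @param sample_params Set `FALSE` to keep every parameter at its base
#'   value (all distributions degenerate).
#' @return A `psa_result`: `deltas` data frame (yen, QALYs), the CEAC
#'   points, and the run sizes.
#' @export
run_psa <- function(config, n_sims, n_trials, seed = config$seed,
                    sample_params = TRUE) {
  if (n_sims < 1 || n_trials < 1) stop("n_sims and n_trials must be >= 1",
                                       call. = FALSE)
  samplers <- psa_samplers(default_parameters())
  n_par <- length(samplers)
  set.seed(as.integer(seed))
  U <- matrix(runif(n_sims * n_par), n_sims, n_par,
              dimnames = list(NULL, names(samplers)))
  dc <- dq <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    cfg_s <- if (sample_params) {
      draw_psa_config(config, samplers, U[s, ])
    } else {
      config
    }
    run_seed <- as.integer(seed) + s
    za <- run_arm(cfg_s, "za", n_trials, run_seed)
    da <- run_arm(cfg_s, "da", n_trials, run_seed)
    cmp <- compare(za, da)
    dc[s] <- cmp$delta_cost
    dq[s] <- cmp$delta_qaly
  }
  deltas <- data.frame(delta_cost = dc, delta_qaly = dq)
  structure(list(
    deltas = deltas,
    n_sims = n_sims,
    n_trials_per_sim = n_trials,
    ceac = lapply(config$econ$wtp, function(w) ceac(deltas, w))
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d simulations x %s trials\n", x$n_sims,
              format(x$n_trials_per_sim, big.mark = ",")))
  for (pt in x$ceac) {
    cat(sprintf("  P(cost-effective at %0.0f yen/QALY) = %0.3f\n",
                pt$wtp, pt$probability))
  }
  invisible(x)
}
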