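usd_round10 <- function(usd) round(usd / 10) * 10

verdict_label <- function(cmp) {
  switch(cmp$verdict,
    cost_saving = "cost-saving",
    dominated = "dominated",
    icer = sprintf("ICER %0.0f yen/QALY ($%0.0f/QALY)", cmp$icer_value,
                   cmp$icer_value / 105)
  )
}

resolve_run_config <- function(config, age, life_table) {
  cfg <- if (is.null(config)) {
    default_parameters()
  } else if (is.character(config)) {
    load_config(config)
  } else {
    config
  }
  if (!is.null(age)) cfg$start_age <- as.integer(age)
  lt <- if (is.null(life_table)) {
    japan_like_life_table()
  } else if (is.character(life_table)) {
    load_life_table(life_table)
  } else {
    life_table
  }
  cfg <- attach_life_table(cfg, lt)
  validate_config(cfg)
  cfg
}

write_manifest <- function(cfg, seed, out_dir) {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(serialize_config(cfg), tmp)
  digest <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    config_digest = digest,
    seed = seed,
    start_age = cfg$start_age,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(packageVersion("osteosim"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Run the base-case comparison and write result tables
#'
#' Runs both strategy arms at the requested starting age and writes a
#' per-arm cost/QALY table covering both payer perspectives (yen and
#' dollars, dollars rounded to the nearest 10, QALYs to three decimals) plus
#' the incremental comparison and a run manifest. Internal computation is
#' unrounded; rounding is presentation only.
#'
#' @param config `osteo_config`, a YAML path, or `NULL` for defaults.
#' @param age Starting age (65, 70, 75 or 80); `NULL` keeps the config's.
#' @param out_dir Output directory (created if missing).
#' @param n_trials,seed Run size and seed (default from config).
#' @param life_table A `life_table`, a CSV path, or `NULL` for the packaged
#'   Japan-like synthetic table.
#' @return Invisibly, a list with the arm results, comparisons and file
#'   paths.
#' @export
cmd_run <- function(config = NULL, age = NULL, out_dir = ".",
                    n_trials = NULL, seed = NULL, life_table = NULL) {
  cfg <- resolve_run_config(config, age, life_table)
  n <- n_trials %||% cfg$n_trials
  sd_ <- seed %||% cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  za <- run_arm(cfg, "za", n, sd_)
  da <- run_arm(cfg, "da", n, sd_)
  rows <- list()
  cmps <- list()
  for (persp in c("healthcare_plus_ltc", "healthcare_only")) {
    cmp <- compare(za, da, perspective = persp)
    cmps[[persp]] <- cmp
    for (arm in list(za, da)) {
      cost <- if (persp == "healthcare_only") arm$mean_cost_hc
              else arm$mean_cost_total
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = arm$strategy,
        start_age = cfg$start_age,
        perspective = persp,
        cost_yen = round(cost),
        cost_usd = usd_round10(cost / cfg$econ$yen_per_usd),
        qaly = round(arm$mean_qaly, 3),
        verdict = if (arm$strategy == "za") verdict_label(cmp)
                  else "comparator"
      )
    }
  }
  tab <- do.call(rbind, rows)
  csv_path <- file.path(out_dir, "base_case.csv")
  write.csv(tab, csv_path, row.names = FALSE)
  cmp_path <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(
    lapply(cmps, function(cmp) {
      list(perspective = cmp$perspective,
           delta_cost_yen = cmp$delta_cost,
           delta_qaly = cmp$delta_qaly,
           verdict = cmp$verdict,
           icer_yen_per_qaly = if (is.na(cmp$icer_value)) NULL
                               else cmp$icer_value)
    }),
    cmp_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- write_manifest(cfg, sd_, out_dir)
  invisible(list(za = za, da = da, comparisons = cmps, table = tab,
                 files = c(csv_path, cmp_path), manifest = manifest))
}

#' Run the no-intervention validation arm and write its summary
#'
#' @inheritParams cmd_run
#' @return Invisibly, the `arm_result` and output path.
#' @export
cmd_validate <- function(config = NULL, age = NULL, out_dir = ".",
                         n_trials = NULL, seed = NULL, life_table = NULL) {
  cfg <- resolve_run_config(config, age, life_table)
  n <- n_trials %||% cfg$n_trials
  sd_ <- seed %||% cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arm <- run_validation(cfg, n, sd_)
  out <- list(start_age = cfg$start_age,
              n_trials = n,
              p_any_hip = arm$p_any_hip,
              p_any_vert = arm$p_any_vert,
              p_dead_by_horizon = arm$p_dead_by_horizon)
  path <- file.path(out_dir, "validation.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_manifest(cfg, sd_, out_dir)
  invisible(list(result = arm, file = path))
}

#' Run the one-way sensitivity analyses and write a tornado table
#'
#' @inheritParams cmd_run
#' @param ranges Entries as from [dsa_default_ranges()].
#' @return Invisibly, the tornado data frame and output path.
#' @export
cmd_dsa <- function(config = NULL, age = NULL, out_dir = ".",
                    n_trials = NULL, seed = NULL, life_table = NULL,
                    ranges = dsa_default_ranges()) {
  cfg <- resolve_run_config(config, age, life_table)
  n <- n_trials %||% cfg$n_trials
  sd_ <- seed %||% cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(ranges, function(en) {
    res <- run_dsa(cfg, en$path, en$low, en$high, seed = sd_, n_trials = n)
    summarise <- function(cmp) {
      data.frame(delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
                 verdict = cmp$verdict,
                 icer = ifelse(is.na(cmp$icer_value), NA, cmp$icer_value))
    }
    cbind(data.frame(parameter = en$name),
          setNames(summarise(res$low_comparison),
                   paste0("low_", names(summarise(res$low_comparison)))),
          setNames(summarise(res$high_comparison),
                   paste0("high_", names(summarise(res$high_comparison)))))
  })
  tab <- do.call(rbind, rows)
  path <- file.path(out_dir, "tornado.csv")
  write.csv(tab, path, row.names = FALSE)
  write_manifest(cfg, sd_, out_dir)
  invisible(list(table = tab, file = path))
}

#' Run the probabilistic sensitivity analysis and write scatter and CEAC
#'
#' @inheritParams cmd_run
#' @param n_sims Parameter draws.
#' @param n_trials Trials per arm per draw.
#' @return Invisibly, the `psa_result` and output paths.
#' @export
cmd_psa <- function(config = NULL, age = NULL, out_dir = ".",
                    n_sims = 1000L, n_trials = NULL, seed = NULL,
                    life_table = NULL) {
  cfg <- resolve_run_config(config, age, life_table)
  n <- n_trials %||% cfg$n_trials
  sd_ <- seed %||% cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_psa(cfg, n_sims = n_sims, n_trials = n, seed = sd_)
  scatter_path <- file.path(out_dir, "psa_scatter.csv")
  write.csv(res$deltas, scatter_path, row.names = FALSE)
  ceac_tab <- do.call(rbind, lapply(res$ceac, function(pt) {
    data.frame(wtp_yen_per_qaly = pt$wtp, probability = pt$probability)
  }))
  ceac_path <- file.path(out_dir, "ceac.csv")
  write.csv(ceac_tab, ceac_path, row.names = FALSE)
  write_manifest(cfg, sd_, out_dir)
  invisible(list(result = res, files = c(scatter_path, ceac_path)))
}
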