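#' Generate a synthetic female life table
#'
#' A two-parameter Gompertz form: `q(a) = min(1, q65 * exp(growth *
#' (a - 65)))` for ages 65 through 105. The defaults produce a table on
#' which more than 99% of a cohort entering at 65 dies by age 105, matching
#' the qualitative behaviour of a contemporary high-longevity female
#' population, which is what the engine's validation checks need. It makes
#' no attempt to replicate any specific national table; use
#' [load_life_table()] (or [japan_like_life_table()]) for that.
#'
#' @param q65 Annual death probability at age 65 (in (0, 0.05)).
#' @param growth Per-year log-hazard slope (in (0, 0.2)).
#' @return A `life_table`.
#' @export
make_synthetic_life_table <- function(q65 = 0.005, growth = 0.12) {
  if (!(q65 > 0 && q65 < 0.05)) stop("q65 must be in (0, 0.05)",
                                     call. = FALSE)
  if (!(growth > 0 && growth < 0.2)) stop("growth must be in (0, 0.2)",
                                          call. = FALSE)
  ages <- 65:105
  new_life_table(ages, pmin(1, q65 * exp(growth * (ages - 65))),
                 source = "synthetic_gompertz")
}

#' Write a life table in the CSV dialect the loader reads
#'
#' @param life_table A `life_table`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  write.csv(data.frame(age = life_table$age, qx = life_table$qx),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A Japan-2018-like female abridged life table (synthetic reconstruction)
#'
#' Loads the abridged life table shipped with the package
#' (`extdata/jp_female_2018_like_synthetic_abridged.csv`). This is a
#' synthetic reconstruction, not the official table: annual death
#' probabilities at five-year ages were chosen to match the published
#' summary behaviour of 2018 Japanese female mortality (life expectancy at
#' 65 of about 24.5 years, over 99% of 65-year-olds dead by 105), with
#' intermediate ages filled by log-linear interpolation. Replace it with
#' the official table via [load_life_table()] where exact national
#' mortality is required.
#'
#' @return A `life_table` covering ages 65-105 by single year.
#' @export
japan_like_life_table <- function() {
  path <- system.file("extdata", "jp_female_2018_like_synthetic_abridged.csv",
                      package = "osteosim")
  lt <- load_life_table(path)
  attr(lt, "source") <- "synthetic_japan_2018_like"
  lt
}

#' Small, fast configuration for tests and examples
#'
#' Base-case parameters with the synthetic Gompertz life table attached, a
#' reduced trial count and a fixed seed, plus any overrides applied on top
#' (a named list merged into the configuration, as in [load_config()]).
#'
#' @param overrides Named list of configuration overrides (may be `NULL`).
#' @param n_trials Trials (default 2000).
#' @param seed Seed (default 42).
#' @return An `osteo_config` ready to run.
#' @export
make_toy_config <- function(overrides = NULL, n_trials = 2000L, seed = 42L) {
  cfg <- default_parameters()
  if (!is.null(overrides)) {
    merged <- deep_merge(config_to_list(cfg), overrides)
    cfg <- rebuild_config(merged)
  }
  cfg$n_trials <- as.integer(n_trials)
  cfg$seed <- as.integer(seed)
  cfg <- attach_life_table(cfg, make_synthetic_life_table())
  validate_config(cfg)
  cfg
}
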