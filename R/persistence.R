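#' Persistence rate at the sixth denosumab dose
#'
#' The cumulative persistence rate at the sixth biannual dose (end of year 3)
#' is derived by applying the observed dose-2-to-dose-4 ratio once more:
#' `p4 * (p4 / p2)`. With the meta-analytic rates of 81% at the second dose
#' and 55% at the fourth, this gives 0.3735, i.e. 37% after rounding.
#'
#' @param p2 Cumulative persistence at the second dose (end of year 1).
#' @param p4 Cumulative persistence at the fourth dose (end of year 2).
#' @return The derived cumulative persistence at the sixth dose.
#' @export
#' @examples
#' sixth_dose_rate(0.81, 0.55)  # 0.3735
sixth_dose_rate <- function(p2, p4) {
  if (p2 == 0) stop("undefined ratio: p2 must be positive", call. = FALSE)
  if (!(p4 <= p2 && p2 <= 1 && p4 > 0)) {
    stop("require 0 < p4 <= p2 <= 1", call. = FALSE)
  }
  p4 * (p4 / p2)
}

#' Extend a cumulative persistence curve beyond its last observed year
#'
#' Each added year multiplies the previous (unrounded) value by the last
#' observed year-on-year ratio `cumulative[last] / cumulative[last - 1]`.
#' Rounding happens only at display: the zoledronic acid curve (100, 52, 36)%
#' extends to 24.9, 17.3, 11.9% in years 4-6, which print as 25, 17 and 12%.
#'
#' @param cumulative Numeric vector of year-end cumulative persistence
#'   fractions (at least two entries).
#' @param horizon_years Target curve length (>= current length).
#' @return The extended cumulative persistence vector.
#' @export
extend_curve <- function(cumulative, horizon_years) {
  n <- length(cumulative)
  if (n < 2) stop("curve must have at least two entries", call. = FALSE)
  if (horizon_years < n) stop("horizon_years must be >= curve length",
                              call. = FALSE)
  if (cumulative[n - 1] == 0) {
    stop("cannot extend: penultimate persistence is zero", call. = FALSE)
  }
  r <- cumulative[n] / cumulative[n - 1]
  extra <- cumulative[n] * r^seq_len(horizon_years - n)
  c(cumulative, extra)
}

#' Distribution of the year of discontinuation within a treatment episode
#'
#' Differences the cumulative persistence curve: the probability of stopping
#' during year `k` is `cumulative[k - 1] - cumulative[k]` (with
#' `cumulative[0] = 1`), and the probability of completing the planned
#' duration is the final cumulative value. The result sums to one exactly.
#'
#' @param cumulative Cumulative persistence vector.
#' @return A list with `stop_in_year` (vector) and `complete` (scalar).
#' @export
#' @examples
#' stop_distribution(c(1.00, 0.52, 0.36))  # stop (0, 0.48, 0.16), complete 0.36
stop_distribution <- function(cumulative) {
  stop_in_year <- -diff(c(1, cumulative))
  list(stop_in_year = stop_in_year, complete = cumulative[length(cumulative)])
}

#' Adherence with oral alendronate in a given treatment year
#'
#' Linear interpolation between the anchor years (70.6% in year 1, 60.9% in
#' year 5 in the base case); beyond the last anchor the rate is held constant
#' (the year-5 rate applies from year 6 onward).
#'
#' @param year Treatment year (1-based).
#' @param curve Adherence curve (`anchors` data frame), e.g.
#'   `default_parameters()$adherence`.
#' @return Adherence fraction in `[0, 1]`.
#' @export
#' @examples
#' adherence_at(3, default_parameters()$adherence)  # 0.6575
adherence_at <- function(year, curve) {
  if (any(year < 1)) stop("year must be >= 1", call. = FALSE)
  a <- curve$anchors
  approx(a$year, a$fraction, xout = year, rule = 2)$y
}

#' Alternative persistence-curve assumptions
#'
#' Returns the persistence curve set (per drug) for the scenario analyses:
#' \describe{
#'   \item{base}{the base-case curves.}
#'   \item{s1}{denosumab at the upper 95% bound of the meta-analysis,
#'     (85, 63, 43)%.}
#'   \item{s2}{denosumab persistence from a small Japanese single-centre
#'     study: (94, 92, 87)% at starting ages 65-75, (83, 71, 59)% at 80.}
#'   \item{s3}{as s2, with zoledronic acid additionally raised by applying
#'     the meta-analytic ZA:denosumab ratio to the s2 denosumab curve:
#'     (100, 87, 85)% at ages 65-75, (100, 67, 57)% at 80.}
#' }
#'
#' @param scenario One of `"base"`, `"s1"`, `"s2"`, `"s3"`.
#' @param start_age Starting age (the Japanese study reported age-specific
#'   curves; 80 differs from 65-75).
#' @param cfg Configuration supplying the base curves.
#' @return Named list of cumulative persistence vectors (`za`, `deno`, `aln`).
#' @export
scenario_curves <- function(scenario, start_age,
                            cfg = default_parameters()) {
  base <- lapply(cfg$persistence, `[[`, "cumulative")
  old <- start_age >= 80
  switch(scenario,
    base = base,
    s1 = {
      base$deno <- c(0.85, 0.63, 0.43)
      base
    },
    s2 = {
      base$deno <- if (old) c(0.83, 0.71, 0.59) else c(0.94, 0.92, 0.87)
      base
    },
    s3 = {
      base$deno <- if (old) c(0.83, 0.71, 0.59) else c(0.94, 0.92, 0.87)
      base$za <- if (old) c(1.00, 0.67, 0.57) else c(1.00, 0.87, 0.85)
      base
    },
    stop("unknown persistence scenario '", scenario, "'", call. = FALSE)
  )
}
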