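#' Fresh fracture history at model entry
#'
#' @return A list of tracker variables: fracture counts, this-cycle event
#'   flags, and recency (`years_since_last_hip` / `_vert`, `NA` if never).
#' @export
new_fracture_history <- function() {
  list(hip_count = 0L, vert_count = 0L,
       hip_event_this_cycle = FALSE, vert_event_this_cycle = FALSE,
       years_since_last_hip = NA_integer_, years_since_last_vert = NA_integer_)
}

#' Per-cycle fracture probability
#'
#' The population incidence rate for the site and age (per 100,000 per
#' year), multiplied by the age-banded osteoporosis relative risk, the
#' same-site prior-fracture relative risk where applicable, and the current
#' treatment relative risk; truncated at 1. Hip fractures are capped at two
#' per lifetime: with two prior hip fractures the hip probability is zero.
#'
#' @param site `"hip"` or `"vert"`.
#' @param age Age in years.
#' @param history Fracture history (see [new_fracture_history()]).
#' @param rr_treatment Treatment relative risk this cycle.
#' @param cfg Configuration.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' h <- new_fracture_history()
#' fracture_probability("hip", 82, h, 1.0)  # 851.1e-5 * 1.35
fracture_probability <- function(site, age, history, rr_treatment,
                                 cfg = default_parameters()) {
  if (age < 65 || age > cfg$horizon_age) {
    stop("age ", age, " outside the incidence tables", call. = FALSE)
  }
  if (site == "hip" && history$hip_count >= 2L) return(0)
  rate <- band_value(cfg$incidence[[site]], age, "rate") / 1e5
  rr_osteo <- band_value(
    cfg$risk[[paste0("rr_osteo_", site)]], age, "rr")
  prior <- if (site == "hip") {
    if (history$hip_count >= 1L) cfg$risk$rr_prior_hip else 1
  } else {
    if (history$vert_count >= 1L) cfg$risk$rr_prior_vert else 1
  }
  min(1, rate * rr_osteo * prior * rr_treatment)
}

#' Per-cycle death probability, adjusted for fracture history
#'
#' The life-table annual death probability `q(age)` is inflated by
#' `1 + f * (RH - 1)`, where `RH` is the mortality hazard ratio after a
#' fracture (a higher value within the first year, a lower one lifelong
#' thereafter) and `f` the fraction of that excess mortality attributed to
#' the fracture itself (0.25 for hip; comorbidity explains the rest). In the
#' base case vertebral fractures carry no excess mortality; a scenario flag
#' gives them the hip values. The elevated first-year hazard applies in the
#' event cycle itself and a second hip fracture restarts the clock; when hip
#' and vertebral history are both applicable the larger excess applies.
#'
#' @param age Age in years.
#' @param history Fracture history; recency via `years_since_last_hip`
#'   (`0` = event this cycle) and `years_since_last_vert`.
#' @param life_table A `life_table`.
#' @param risk `cfg$risk` modifiers.
#' @return Probability in `[0, 1]`.
#' @export
death_probability <- function(age, history, life_table, risk) {
  q <- q_at(life_table, age)
  excess_for <- function(count, years_since, rh1, rh2, f) {
    if (count < 1L || is.na(years_since)) return(0)
    rh <- if (years_since < 1L) rh1 else rh2
    f * (rh - 1)
  }
  ex_hip <- excess_for(history$hip_count, history$years_since_last_hip,
                       risk$rh_mort_hip_year1, risk$rh_mort_hip_later,
                       risk$attributable_fraction_hip)
  ex_vert <- excess_for(history$vert_count, history$years_since_last_vert,
                        risk$rh_mort_vert_year1, risk$rh_mort_vert_later,
                        risk$attributable_fraction_vert)
  min(1, q * (1 + max(ex_hip, ex_vert)))
}
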