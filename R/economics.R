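#' Discount factor for a model cycle
#'
#' The first cycle is undiscounted; cycle `t` is discounted by
#' `(1 + rate)^-(t - 1)`. No half-cycle correction is applied.
#'
#' @param cycle_index 1-based cycle index.
#' @param rate Annual discount rate.
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle_index, rate) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1", call. = FALSE)
  (1 + rate)^-(cycle_index - 1)
}

visit_schedule <- function(drug, cfg) {
  reduced <- isTRUE(cfg$scenario_flags$reduced_deno_visits)
  switch(drug,
    za = list(visits = 2L, tests = 2L),
    deno = if (reduced) list(visits = 2L, tests = 2L)
           else list(visits = 4L, tests = 4L),
    aln = list(visits = 4L, tests = 2L),
    stop("unknown drug '", drug, "'", call. = FALSE)
  )
}

medication_cost <- function(drug, episode_year, cfg) {
  cm <- cfg$costs
  switch(drug,
    za = cm$med_annual[["za"]],
    deno = cm$med_annual[["deno"]] *
      (if (isTRUE(cfg$scenario_flags$biosimilar_deno)) 0.6 else 1),
    aln = cm$med_annual[["aln"]] * adherence_at(episode_year, cfg$adherence) +
      cm$rx_charge_aln,
    stop("unknown drug '", drug, "'", call. = FALSE)
  )
}

#' Treatment cost charged in one cycle
#'
#' Persistent years are charged the full annual medication cost (scaled by
#' adherence for alendronate, plus its prescription charge), the drug's
#' visit schedule (one first-visit fee then subsequent-visit fees in year 1
#' of an episode, all subsequent fees later) and its blood tests. The year
#' of discontinuation is charged half of every annual component (stop time
#' uniform within the year), with two floors taken directly from the fee
#' schedule: an alendronate year-1 stopper is charged one filled
#' prescription (a 3-month supply plus a quarter of the annual pharmacy
#' charge, one first visit, one blood test), and a denosumab year-1 stopper
#' the cost of a single dose (half the annual price, the first visit, and
#' the two peri-injection blood tests).
#'
#' The biosimilar scenario prices denosumab at 60% of the brand product;
#' the reduced-visit scenario gives denosumab two visits and two blood
#' tests per year.
#'
#' @param drug `"za"`, `"deno"` or `"aln"`.
#' @param episode_year Year within the treatment episode (1-based).
#' @param status `"persistent_full_year"` or `"stops_this_year"`.
#' @param cfg Configuration.
#' @return Cost in yen for the cycle.
#' @export
#' @examples
#' annual_treatment_cost("za", 1, "persistent_full_year")  # 53200
annual_treatment_cost <- function(drug, episode_year, status,
                                  cfg = default_parameters()) {
  if (!drug %in% .DRUGS) stop("unknown drug '", drug, "'", call. = FALSE)
  status <- match.arg(status, c("persistent_full_year", "stops_this_year"))
  cm <- cfg$costs
  vs <- visit_schedule(drug, cfg)
  visit_fees <- if (episode_year == 1) {
    cm$visit_first[[drug]] + (vs$visits - 1L) * cm$visit_subsequent[[drug]]
  } else {
    vs$visits * cm$visit_subsequent[[drug]]
  }
  full <- medication_cost(drug, episode_year, cfg) + visit_fees +
    vs$tests * cm$blood_test
  if (status == "persistent_full_year") return(full)
  if (drug == "aln" && episode_year == 1) {
    return(cm$med_annual[["aln"]] / 4 + cm$rx_charge_aln / 4 +
             cm$visit_first[["aln"]] + cm$blood_test)
  }
  if (drug == "deno" && episode_year == 1) {
    return(medication_cost("deno", 1, cfg) / 2 + cm$visit_first[["deno"]] +
             2 * cm$blood_test)
  }
  full / 2
}

#' Bone-density (DXA) scan cost due in a cycle
#'
#' Charged to every individual alive at the end of the third and the sixth
#' model year, in both arms.
#'
#' @param cycle_index 1-based cycle index.
#' @param cfg Configuration.
#' @return Cost in yen (0 except at cycles 3 and 6).
#' @export
dxa_cost_due <- function(cycle_index, cfg = default_parameters()) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1", call. = FALSE)
  ifelse(cycle_index %in% c(3L, 6L), cfg$costs$dxa, 0)
}

#' One-time medical cost of a fracture event
#'
#' @param site `"hip"` or `"vert"`.
#' @param prior_same_site_count Prior fractures at the same site.
#' @param cfg Configuration.
#' @return Cost in yen.
#' @export
fracture_event_cost <- function(site, prior_same_site_count,
                                cfg = default_parameters()) {
  cm <- cfg$costs
  switch(site,
    hip = cm$fx_hip,
    vert = if (prior_same_site_count >= 1) cm$fx_vert_subsequent
           else cm$fx_vert_first,
    stop("unknown site '", site, "'", call. = FALSE)
  )
}

#' Annual long-term care cost for the post-fracture states
#'
#' Under the combined healthcare and long-term care payer perspective, every
#' cycle lived in the post-hip-fracture state costs the annual post-hip
#' long-term care amount; the post-vertebral state (with no hip history)
#' costs the post-vertebral amount. The healthcare-only perspective carries
#' no long-term care costs.
#'
#' @param history A fracture history (list with `hip_count`, `vert_count`).
#' @param perspective `"healthcare_plus_ltc"` or `"healthcare_only"`.
#' @param cfg Configuration.
#' @return Cost in yen per year.
#' @export
annual_ltc_cost <- function(history, perspective,
                            cfg = default_parameters()) {
  if (perspective == "healthcare_only") return(0)
  if (history$hip_count >= 1) return(cfg$costs$ltc_post_hip)
  if (history$vert_count >= 1) return(cfg$costs$ltc_post_vert)
  0
}

#' Utility weight for one cycle
#'
#' Age-band base utility times a disutility multiplier: the event-year
#' multiplier of this cycle's fracture if one occurred (vertebral events use
#' the vertebral event multiplier even in post-hip individuals), otherwise
#' the post-state multiplier, with the post-hip state dominating the
#' post-vertebral state.
#'
#' @param age Age in the cycle.
#' @param history Fracture history list: `hip_count`, `vert_count`,
#'   `hip_event_this_cycle`, `vert_event_this_cycle`.
#' @param utilities `cfg$utilities`.
#' @return Utility weight in (0, 1].
#' @export
cycle_utility <- function(age, history, utilities) {
  base <- band_value(utilities$base_by_age, age, "utility")
  mult <- if (isTRUE(history$hip_event_this_cycle)) {
    utilities$mult_hip_y1
  } else if (isTRUE(history$vert_event_this_cycle)) {
    utilities$mult_vert_y1
  } else if (history$hip_count >= 1) {
    utilities$mult_hip_later
  } else if (history$vert_count >= 1) {
    utilities$mult_vert_later
  } else {
    1
  }
  base * mult
}

#' Compare two strategies' mean discounted costs and QALYs
#'
#' Classifies the intervention against the comparator: cost-saving when it
#' is cheaper and more effective, dominated when it is costlier and less
#' effective, otherwise an incremental cost-effectiveness ratio
#' (yen per QALY gained). A QALY tie with a cost difference is classified by
#' cost alone and flagged; two identical arms are indeterminate.
#'
#' @param intervention,comparator `arm_result` objects from [run_arm()]
#'   with the same start age and perspective.
#' @param perspective Which cost to compare (defaults to the arms' own).
#' @return A `ce_comparison` with `delta_cost` (yen), `delta_qaly`,
#'   `verdict` and, for ICER verdicts, `icer_value` (yen/QALY).
#' @export
compare <- function(intervention, comparator, perspective = NULL) {
  if (intervention$start_age != comparator$start_age) {
    stop("arms must share a start age", call. = FALSE)
  }
  persp <- perspective %||% intervention$perspective
  pick_cost <- function(arm) {
    if (persp == "healthcare_only") arm$mean_cost_hc else arm$mean_cost_total
  }
  dc <- pick_cost(intervention) - pick_cost(comparator)
  dq <- intervention$mean_qaly - comparator$mean_qaly
  qaly_tie <- FALSE
  if (dc == 0 && dq == 0) {
    stop("indeterminate comparison: identical arms", call. = FALSE)
  }
  if (dq == 0) {
    verdict <- if (dc < 0) "cost_saving" else "dominated"
    qaly_tie <- TRUE
    icer <- NA_real_
  } else if (dc < 0 && dq > 0) {
    verdict <- "cost_saving"
    icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    verdict <- "dominated"
    icer <- NA_real_
  } else {
    verdict <- "icer"
    icer <- dc / dq
  }
  structure(list(
    intervention = intervention$strategy,
    comparator = comparator$strategy,
    perspective = persp,
    delta_cost = dc,
    delta_qaly = dq,
    verdict = verdict,
    icer_value = icer,
    qaly_tie = qaly_tie
  ), class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (%s)\n", x$intervention, x$comparator, x$perspective))
  cat(sprintf("  delta cost: %0.0f yen   delta QALY: %0.4f\n",
              x$delta_cost, x$delta_qaly))
  cat("  verdict:", gsub("_", "-", x$verdict))
  if (x$verdict == "icer") cat(sprintf(" (%0.0f yen/QALY)", x$icer_value))
  cat("\n")
  invisible(x)
}

#' Probability of cost-effectiveness at a willingness-to-pay threshold
#'
#' The fraction of probabilistic-sensitivity draws with strictly positive
#' incremental net monetary benefit `wtp * dQALY - dCost`; an exact tie
#' counts as not cost-effective.
#'
#' @param psa_deltas Data frame (or list) with `delta_cost` and `delta_qaly`
#'   per simulation (yen and QALYs).
#' @param wtp Willingness-to-pay in yen per QALY.
#' @return A `ceac_point` list with `wtp` and `probability`.
#' @export
#' @examples
#' ceac(data.frame(delta_cost = c(-1, 10, 5),
#'                 delta_qaly = c(0.01, 0.001, -0.01)), 5000)$probability
ceac <- function(psa_deltas, wtp) {
  dc <- psa_deltas$delta_cost
  dq <- psa_deltas$delta_qaly
  if (length(dc) < 1) stop("need at least one simulation", call. = FALSE)
  nmb <- wtp * dq - dc
  structure(list(wtp = wtp, probability = mean(nmb > 0)),
            class = "ceac_point")
}

yen_to_usd <- function(yen, cfg) yen / cfg$econ$yen_per_usd

`%||%` <- function(a, b) if (is.null(a)) b else a
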