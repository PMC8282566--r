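apply_scenario_flags <- function(cfg) {
  if (isTRUE(cfg$scenario_flags$deno_rebound)) {
    stop("the post-denosumab rebound scenario has no quantified magnitude; ",
         "it cannot be simulated", call. = FALSE)
  }
  if (isTRUE(cfg$scenario_flags$vert_excess_mortality)) {
    cfg$risk$rh_mort_vert_year1 <- cfg$risk$rh_mort_hip_year1
    cfg$risk$rh_mort_vert_later <- cfg$risk$rh_mort_hip_later
    cfg$risk$attributable_fraction_vert <- cfg$risk$attributable_fraction_hip
  }
  cfg
}

cycle_constants <- function(cfg) {
  n_cycles <- cfg$horizon_age - cfg$start_age
  ages <- cfg$start_age + seq_len(n_cycles) - 1L
  bv <- function(bands, col) vapply(ages, band_value, numeric(1),
                                    bands = bands, col = col)
  r <- cfg$risk
  list(
    n_cycles = n_cycles,
    ages = ages,
    q = q_at(cfg$life_table, ages),
    ph_base = bv(cfg$incidence$hip, "rate") / 1e5 * bv(r$rr_osteo_hip, "rr"),
    pv_base = bv(cfg$incidence$vert, "rate") / 1e5 * bv(r$rr_osteo_vert, "rr"),
    base_util = bv(cfg$utilities$base_by_age, "utility"),
    dfc = discount_factor(seq_len(n_cycles), cfg$econ$discount_cost),
    dfq = discount_factor(seq_len(n_cycles), cfg$econ$discount_qaly),
    ex_hip_y1 = r$attributable_fraction_hip * (r$rh_mort_hip_year1 - 1),
    ex_hip_later = r$attributable_fraction_hip * (r$rh_mort_hip_later - 1),
    ex_vert_y1 = r$attributable_fraction_vert * (r$rh_mort_vert_year1 - 1),
    ex_vert_later = r$attributable_fraction_vert * (r$rh_mort_vert_later - 1),
    dxa = dxa_cost_due(seq_len(n_cycles), cfg),
    rr_prior_hip = r$rr_prior_hip,
    rr_prior_vert = r$rr_prior_vert,
    c_hip = cfg$costs$fx_hip,
    c_vert_first = cfg$costs$fx_vert_first,
    c_vert_sub = cfg$costs$fx_vert_subsequent,
    ltc_hip = cfg$costs$ltc_post_hip,
    ltc_vert = cfg$costs$ltc_post_vert,
    u_hip_y1 = cfg$utilities$mult_hip_y1,
    u_hip_later = cfg$utilities$mult_hip_later,
    u_vert_y1 = cfg$utilities$mult_vert_y1,
    u_vert_later = cfg$utilities$mult_vert_later
  )
}

check_run_config <- function(cfg) {
  if (is.null(cfg$life_table)) {
    stop("incomplete config: no life table attached", call. = FALSE)
  }
  validate_life_table(cfg$life_table)
  if (min(cfg$life_table$age) > cfg$start_age) {
    stop("coverage error: life table starts above start_age", call. = FALSE)
  }
  invisible(cfg)
}

new_arm_result <- function(strategy_name, cfg, n_trials, totals) {
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  persp <- cfg$econ$perspective
  cost_total <- totals$c_hc + totals$c_ltc
  cost_sel <- if (persp == "healthcare_only") totals$c_hc else cost_total
  structure(list(
    strategy = strategy_name,
    start_age = cfg$start_age,
    perspective = persp,
    n_trials = n_trials,
    mean_cost = mean(cost_sel),
    mean_cost_total = mean(cost_total),
    mean_cost_hc = mean(totals$c_hc),
    mean_cost_ltc = mean(totals$c_ltc),
    mean_qaly = mean(totals$qaly),
    mc_se_cost = se(cost_sel),
    mc_se_cost_total = se(cost_total),
    mc_se_cost_hc = se(totals$c_hc),
    mc_se_qaly = se(totals$qaly),
    p_any_hip = mean(totals$any_hip),
    p_any_vert = mean(totals$any_vert),
    p_dead_by_horizon = mean(totals$dead),
    mean_hip_fractures = mean(totals$n_hip),
    mean_vert_fractures = mean(totals$n_vert),
    mean_cost_usd = mean(cost_sel) / cfg$econ$yen_per_usd
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("strategy %s, start age %d, %s (n = %s)\n", x$strategy,
              x$start_age, x$perspective, format(x$n_trials, big.mark = ",")))
  cat(sprintf("  mean cost: %0.0f yen ($%0.0f)   mean QALYs: %0.3f\n",
              x$mean_cost, x$mean_cost_usd, x$mean_qaly))
  cat(sprintf("  P(any hip) %0.3f  P(any vert) %0.3f  P(dead by 105) %0.3f\n",
              x$p_any_hip, x$p_any_vert, x$p_dead_by_horizon))
  invisible(x)
}

#' Run one strategy arm of the microsimulation
#'
#' Simulates `n_trials` individual women in lockstep through yearly cycles
#' from the starting age to death or age 105. Within each cycle the fixed
#' order is: treatment-status update and cycle relative risk, at most one
#' fracture event (the hip draw first, the vertebral draw conditional on no
#' hip event), the death draw using the updated history, then cost and
#' utility accrual with discounting. Individuals dying in a cycle accrue the
#' fracture event cost but no utility and no long-term care cost for that
#' cycle.
#'
#' All uniform draws are pre-generated from `seed` in a fixed layout
#' (trajectory assignment, then hip/vertebral/death blocks per cycle), so a
#' rerun with the same seed is bit-identical and two arms run with the same
#' seed share their random numbers individual-by-individual (common random
#' numbers, which stabilises incremental results).
#'
#' @param config An `osteo_config` with a life table attached.
#' @param strategy One entry of `config$strategies`, the name of one
#'   (`"za"`, `"da"`), or `NULL` for no intervention.
#' @param n_trials Number of simulated individuals.
#' @param seed Integer seed.
#' @return An `arm_result`: mean discounted cost (yen, with healthcare-only
#'   and long-term-care components and a dollar conversion) and QALYs with
#'   Monte-Carlo standard errors, lifetime fracture probabilities and the
#'   probability of death by the horizon.
#' @export
run_arm <- function(config, strategy = NULL,
                    n_trials = config$n_trials, seed = config$seed) {
  cfg <- apply_scenario_flags(config)
  check_run_config(cfg)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (is.character(strategy)) strategy <- cfg$strategies[[strategy]]
  sname <- if (is.null(strategy)) "no_intervention" else strategy$name

  sched <- build_strategy_schedules(cfg, strategy)
  cc <- cycle_constants(cfg)
  # monitoring DXA scans belong to the treatment strategies (charged in both
  # arms); the no-intervention validation arm carries no monitoring costs
  if (is.null(strategy)) cc$dxa[] <- 0
  n_cycles <- cc$n_cycles
  N <- as.integer(n_trials)

  set.seed(as.integer(seed))
  u_type <- runif(N)
  u_hip <- matrix(runif(N * n_cycles), N, n_cycles)
  u_vert <- matrix(runif(N * n_cycles), N, n_cycles)
  u_death <- matrix(runif(N * n_cycles), N, n_cycles)

  cp <- cumsum(sched$prob)
  cp[length(cp)] <- 1
  type <- findInterval(u_type, cp, left.open = TRUE) + 1L

  alive <- rep(TRUE, N)
  hipc <- integer(N)
  vertc <- integer(N)
  c_hc <- numeric(N)
  c_ltc <- numeric(N)
  qaly <- numeric(N)

  for (t in seq_len(n_cycles)) {
    if (!any(alive)) break
    rr_h <- sched$rr_hip[, t][type]
    rr_v <- sched$rr_vert[, t][type]

    p_hip <- pmin(1, cc$ph_base[t] * ifelse(hipc > 0L, cc$rr_prior_hip, 1) *
                    rr_h)
    p_hip[hipc >= 2L] <- 0
    hip_ev <- alive & (u_hip[, t] < p_hip)

    p_vert <- pmin(1, cc$pv_base[t] * ifelse(vertc > 0L, cc$rr_prior_vert, 1) *
                     rr_v)
    vert_ev <- alive & !hip_ev & (u_vert[, t] < p_vert)

    ex_h <- ifelse(hip_ev, cc$ex_hip_y1, ifelse(hipc > 0L, cc$ex_hip_later, 0))
    ex_v <- ifelse(vert_ev, cc$ex_vert_y1,
                   ifelse(vertc > 0L, cc$ex_vert_later, 0))
    q_adj <- pmin(1, cc$q[t] * (1 + pmax(ex_h, ex_v)))
    died <- alive & (u_death[, t] < q_adj)
    surv <- alive & !died

    tx <- sched$cost[, t][type]
    fx <- ifelse(hip_ev, cc$c_hip, 0) +
      ifelse(vert_ev, ifelse(vertc > 0L, cc$c_vert_sub, cc$c_vert_first), 0)
    c_hc <- c_hc + cc$dfc[t] * alive * (tx + cc$dxa[t] + fx)

    # long-term care accrues by state; an event cycle averages the entry
    # and exit states (the fracture happens mid-cycle on average)
    ltc_pre <- ifelse(hipc > 0L, cc$ltc_hip,
                      ifelse(vertc > 0L, cc$ltc_vert, 0))
    ltc_post <- ifelse(hip_ev | hipc > 0L, cc$ltc_hip,
                       ifelse(vert_ev | vertc > 0L, cc$ltc_vert, 0))
    c_ltc <- c_ltc + cc$dfc[t] * surv * (ltc_pre + ltc_post) / 2

    umult <- ifelse(hip_ev, cc$u_hip_y1,
             ifelse(vert_ev, cc$u_vert_y1,
             ifelse(hipc > 0L, cc$u_hip_later,
             ifelse(vertc > 0L, cc$u_vert_later, 1))))
    qaly <- qaly + cc$dfq[t] * cc$base_util[t] * umult * surv

    hipc <- hipc + as.integer(hip_ev)
    vertc <- vertc + as.integer(vert_ev)
    alive <- surv
  }

  new_arm_result(sname, cfg, N, list(
    c_hc = c_hc, c_ltc = c_ltc, qaly = qaly,
    any_hip = hipc > 0L, any_vert = vertc > 0L, dead = !alive,
    n_hip = hipc, n_vert = vertc
  ))
}

#' Run the no-intervention validation arm
#'
#' Convenience wrapper for `run_arm(config, strategy = NULL, ...)`: reports
#' lifetime probabilities of at least one hip and one clinical vertebral
#' fracture and of death by age 105 in the absence of treatment.
#'
#' @inheritParams run_arm
#' @return An `arm_result`.
#' @export
run_validation <- function(config, n_trials = config$n_trials,
                           seed = config$seed) {
  run_arm(config, strategy = NULL, n_trials = n_trials, seed = seed)
}

#' Simulate a single individual (scalar reference path)
#'
#' A direct, unvectorised implementation of one woman's trajectory using the
#' scalar per-cycle operations ([fracture_probability()],
#' [death_probability()], [cycle_utility()] and the treatment-status
#' machine). It exists as an independently written path against which the
#' vectorised engine and the cohort oracle are checked; it draws from R's
#' current random stream.
#'
#' @param config An `osteo_config` with a life table attached.
#' @param strategy Strategy entry or `NULL`.
#' @return A list with discounted `cost_hc`, `cost_ltc`, `qaly` and event
#'   flags.
#' @export
simulate_individual <- function(config, strategy = NULL) {
  cfg <- apply_scenario_flags(config)
  check_run_config(cfg)
  if (is.character(strategy)) strategy <- cfg$strategies[[strategy]]
  n_cycles <- cfg$horizon_age - cfg$start_age

  # draw the discontinuation trajectory, then walk cycles
  sched <- build_strategy_schedules(cfg, strategy)
  cp <- cumsum(sched$prob)
  cp[length(cp)] <- 1
  k <- findInterval(runif(1), cp, left.open = TRUE) + 1L

  hist <- new_fracture_history()
  c_hc <- c_ltc <- qa <- 0
  alive <- TRUE
  for (t in seq_len(n_cycles)) {
    if (!alive) break
    age <- cfg$start_age + t - 1L
    hist$hip_event_this_cycle <- FALSE
    hist$vert_event_this_cycle <- FALSE

    p_hip <- fracture_probability("hip", age, hist, sched$rr_hip[k, t], cfg)
    if (runif(1) < p_hip) {
      hist$hip_event_this_cycle <- TRUE
    } else {
      p_vert <- fracture_probability("vert", age, hist, sched$rr_vert[k, t],
                                     cfg)
      if (runif(1) < p_vert) hist$vert_event_this_cycle <- TRUE
    }
    hist_after <- hist
    if (hist$hip_event_this_cycle) {
      hist_after$hip_count <- hist$hip_count + 1L
      hist_after$years_since_last_hip <- 0L
    }
    if (hist$vert_event_this_cycle) {
      hist_after$vert_count <- hist$vert_count + 1L
      hist_after$years_since_last_vert <- 0L
    }
    q_adj <- death_probability(age, hist_after, cfg$life_table, cfg$risk)
    died <- runif(1) < q_adj

    dfc <- discount_factor(t, cfg$econ$discount_cost)
    fx <- 0
    if (hist$hip_event_this_cycle) fx <- fracture_event_cost("hip",
                                                             hist$hip_count,
                                                             cfg)
    if (hist$vert_event_this_cycle) fx <- fracture_event_cost("vert",
                                                              hist$vert_count,
                                                              cfg)
    dxa <- if (is.null(strategy)) 0 else dxa_cost_due(t, cfg)
    c_hc <- c_hc + dfc * (sched$cost[k, t] + dxa + fx)
    if (!died) {
      c_ltc <- c_ltc + dfc *
        (annual_ltc_cost(hist, "healthcare_plus_ltc", cfg) +
           annual_ltc_cost(hist_after, "healthcare_plus_ltc", cfg)) / 2
      qa <- qa + discount_factor(t, cfg$econ$discount_qaly) *
        cycle_utility(age, hist_after, cfg$utilities)
    }

    hist <- hist_after
    if (!is.na(hist$years_since_last_hip)) {
      hist$years_since_last_hip <- hist$years_since_last_hip + 1L
    }
    if (!is.na(hist$years_since_last_vert)) {
      hist$years_since_last_vert <- hist$years_since_last_vert + 1L
    }
    alive <- !died
  }
  list(cost_hc = c_hc, cost_ltc = c_ltc, qaly = qa,
       any_hip = hist$hip_count > 0L, any_vert = hist$vert_count > 0L,
       dead = !alive)
}

#' Exact cohort expectation for no-treatment configurations
#'
#' A deterministic expanded-state Markov chain over (hip count 0-2,
#' vertebral history yes/no) that applies the identical within-cycle
#' ordering, cost, utility and discounting rules as the microsimulation,
#' computing expectations exactly by forward probability recursion -- no
#' sampling. It serves as the engine's correctness oracle: microsimulation
#' means must agree with it to within Monte-Carlo error.
#'
#' @param config A no-treatment `osteo_config` with a life table attached.
#' @return An `arm_result` with zero Monte-Carlo standard errors.
#' @export
cohort_oracle <- function(config) {
  arm_expectation(config, strategy = NULL)
}

#' Exact cohort expectation of an arm by trajectory mixing
#'
#' Because a treatment trajectory is fully determined by the per-episode
#' discontinuation draws, an arm's expectation is the stop-probability-
#' weighted mixture of expanded-state cohort chains, one per enumerated
#' trajectory. This computes arm means (costs, QALYs, event probabilities)
#' exactly, with no Monte-Carlo error, under the identical cycle rules as
#' [run_arm()]. The no-treatment case is the single-trajectory chain used
#' by [cohort_oracle()].
#'
#' @inheritParams run_arm
#' @return An `arm_result` with zero Monte-Carlo standard errors.
#' @export
arm_expectation <- function(config, strategy = NULL) {
  cfg <- apply_scenario_flags(config)
  check_run_config(cfg)
  if (is.character(strategy)) strategy <- cfg$strategies[[strategy]]
  sname <- if (is.null(strategy)) "no_intervention" else strategy$name
  sched <- build_strategy_schedules(cfg, strategy)
  cc <- cycle_constants(cfg)
  if (is.null(strategy)) cc$dxa[] <- 0
  K <- length(sched$prob)
  fields <- c("mean_cost_total", "mean_cost_hc", "mean_cost_ltc",
              "mean_qaly", "p_any_hip", "p_any_vert", "p_dead_by_horizon",
              "mean_hip_fractures", "mean_vert_fractures")
  acc <- setNames(numeric(length(fields)), fields)
  for (k in seq_len(K)) {
    ch <- cohort_chain(cfg, cc, sched$rr_hip[k, ], sched$rr_vert[k, ],
                       sched$cost[k, ])
    for (f in fields) acc[[f]] <- acc[[f]] + sched$prob[k] * ch[[f]]
  }
  persp <- cfg$econ$perspective
  cost_sel <- if (persp == "healthcare_only") acc[["mean_cost_hc"]]
              else acc[["mean_cost_total"]]
  structure(c(
    list(strategy = sname, start_age = cfg$start_age, perspective = persp,
         n_trials = Inf, mean_cost = cost_sel),
    as.list(acc),
    list(mc_se_cost = 0, mc_se_cost_total = 0, mc_se_cost_hc = 0,
         mc_se_qaly = 0,
         mean_cost_usd = cost_sel / cfg$econ$yen_per_usd)
  ), class = "arm_result")
}

cohort_chain <- function(cfg, cc, rr_hip_t, rr_vert_t, tx_cost_t) {
  # state space: hip count 0..2 x any-vert 0/1
  states <- expand.grid(h = 0:2, v = 0:1)
  n_s <- nrow(states)
  m <- numeric(n_s)
  m[states$h == 0 & states$v == 0] <- 1

  cost_hc <- cost_ltc <- qa <- 0
  p_any_hip <- p_any_vert <- 0
  exp_hip <- exp_vert <- 0

  for (t in seq_len(cc$n_cycles)) {
    new_m <- numeric(n_s)
    for (s in seq_len(n_s)) {
      if (m[s] <= 0) next
      h <- states$h[s]
      v <- states$v[s]
      ms <- m[s]

      ph <- if (h < 2) {
        min(1, cc$ph_base[t] * (if (h > 0) cc$rr_prior_hip else 1) *
              rr_hip_t[t])
      } else 0
      pv <- min(1, cc$pv_base[t] * (if (v > 0) cc$rr_prior_vert else 1) *
                  rr_vert_t[t])
      b_hip <- ph
      b_vert <- (1 - ph) * pv
      b_none <- (1 - ph) * (1 - pv)

      ex_later <- max(if (h > 0) cc$ex_hip_later else 0,
                      if (v > 0) cc$ex_vert_later else 0)
      q_hip <- min(1, cc$q[t] * (1 + max(cc$ex_hip_y1,
                                         if (v > 0) cc$ex_vert_later else 0)))
      q_vert <- min(1, cc$q[t] * (1 + max(cc$ex_vert_y1,
                                          if (h > 0) cc$ex_hip_later else 0)))
      q_none <- min(1, cc$q[t] * (1 + ex_later))

      dfc <- cc$dfc[t]
      dfq <- cc$dfq[t]
      fx_vert <- if (v > 0) cc$c_vert_sub else cc$c_vert_first
      cost_hc <- cost_hc + dfc * ms *
        (tx_cost_t[t] + cc$dxa[t] + b_hip * cc$c_hip + b_vert * fx_vert)

      ltc_s <- if (h > 0) cc$ltc_hip else if (v > 0) cc$ltc_vert else 0
      ltc_after_vert <- if (h > 0) cc$ltc_hip else cc$ltc_vert
      cost_ltc <- cost_ltc + dfc * ms *
        (b_hip * (1 - q_hip) * (ltc_s + cc$ltc_hip) / 2 +
           b_vert * (1 - q_vert) * (ltc_s + ltc_after_vert) / 2 +
           b_none * (1 - q_none) * ltc_s)

      post_mult <- if (h > 0) cc$u_hip_later else if (v > 0) cc$u_vert_later
                   else 1
      qa <- qa + dfq * ms * cc$base_util[t] *
        (b_hip * (1 - q_hip) * cc$u_hip_y1 +
           b_vert * (1 - q_vert) * cc$u_vert_y1 +
           b_none * (1 - q_none) * post_mult)

      if (h == 0) p_any_hip <- p_any_hip + ms * b_hip
      if (v == 0) p_any_vert <- p_any_vert + ms * b_vert
      exp_hip <- exp_hip + ms * b_hip
      exp_vert <- exp_vert + ms * b_vert

      i_hip <- which(states$h == h + 1 & states$v == v)
      i_vert <- which(states$h == h & states$v == 1)
      new_m[i_hip] <- new_m[i_hip] + ms * b_hip * (1 - q_hip)
      new_m[i_vert] <- new_m[i_vert] + ms * b_vert * (1 - q_vert)
      new_m[s] <- new_m[s] + ms * b_none * (1 - q_none)
    }
    m <- new_m
  }

  list(
    mean_cost_total = cost_hc + cost_ltc,
    mean_cost_hc = cost_hc,
    mean_cost_ltc = cost_ltc,
    mean_qaly = qa,
    p_any_hip = p_any_hip,
    p_any_vert = p_any_vert,
    p_dead_by_horizon = 1 - sum(m),
    mean_hip_fractures = exp_hip,
    mean_vert_fractures = exp_vert
  )
}
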