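#' On-treatment relative risk, scaled by adherence
#'
#' Effectiveness in the community is assumed linear in adherence:
#' `RR_eff = 1 - adherence * (1 - RR_trial)`. Injectables (zoledronic acid,
#' denosumab) have adherence 1 by construction -- anyone persistent with an
#' injection schedule has, by definition, received the doses.
#'
#' @param drug `"za"`, `"deno"` or `"aln"`.
#' @param site `"hip"` or `"vert"`.
#' @param adherence Adherence fraction in `[0, 1]`.
#' @param cfg Configuration supplying trial relative risks.
#' @return Effective relative risk in (0, 1].
#' @export
#' @examples
#' on_treatment_rr("aln", "hip", 0.706)  # 1 - 0.706 * 0.36 = 0.74584
on_treatment_rr <- function(drug, site, adherence,
                            cfg = default_parameters()) {
  if (!drug %in% .DRUGS) stop("unknown drug '", drug, "'", call. = FALSE)
  if (!site %in% c("hip", "vert")) stop("unknown site '", site, "'",
                                        call. = FALSE)
  if (adherence < 0 || adherence > 1) stop("adherence must be in [0, 1]",
                                           call. = FALSE)
  rr_trial <- cfg$efficacy[[drug]][[paste0("rr_", site)]]
  1 - adherence * (1 - rr_trial)
}

#' Residual (offset) relative risk after stopping treatment
#'
#' Bisphosphonates retain a residual effect that decays linearly back to no
#' effect over a period equal to the time treated:
#' `RR(t) = rr_at_stop + (1 - rr_at_stop) * min(t / years_on, 1)`.
#' Denosumab has no offset -- its effect is lost at the end of the cycle of
#' the final dose, so the relative risk is 1 for any time after stopping.
#'
#' @param drug Drug whose effect is wearing off.
#' @param site Fracture site (the formula is site-agnostic but the signature
#'   mirrors [on_treatment_rr()]).
#' @param years_on Completed years on the drug at stop.
#' @param years_since_stop Whole years since the offset clock started (> 0).
#' @param rr_at_stop Effective relative risk in the final treated year.
#' @return Relative risk in (0, 1].
#' @export
offset_rr <- function(drug, site, years_on, years_since_stop, rr_at_stop) {
  if (!drug %in% .DRUGS) stop("unknown drug '", drug, "'", call. = FALSE)
  if (years_since_stop <= 0) stop("years_since_stop must be > 0",
                                  call. = FALSE)
  if (years_on == 0) return(1.0)
  if (drug == "deno") return(1.0)
  rr_at_stop + (1 - rr_at_stop) * min(years_since_stop / years_on, 1)
}

# ---- treatment status machine ------------------------------------------------

#' Fresh treatment status at model entry
#'
#' Tracker variables for the treatment episode bookkeeping: which drug (if
#' any) is active, the year within the episode, whether and when treatment
#' stopped, and the residual-effect (offset) state.
#'
#' @return A `treatment_status` list.
#' @export
new_treatment_status <- function() {
  structure(list(
    phase = "pre",          # pre | on | stop_year | gap | offset | none
    current_drug = NA_character_,
    episode_index = 0L,
    episode_year = 0L,
    gap_remaining = 0L,
    started_alendronate = FALSE,
    off_drug = NA_character_,
    off_years_on = 0L,
    off_rr_hip = 1,
    off_rr_vert = 1,
    years_since_stop = 0L
  ), class = "treatment_status")
}

status_effective_rr <- function(status, drug, year, cfg) {
  adh <- if (drug == "aln") adherence_at(year, cfg$adherence) else 1
  c(hip = on_treatment_rr(drug, "hip", adh, cfg),
    vert = on_treatment_rr(drug, "vert", adh, cfg))
}

begin_offset <- function(status, drug, years_on, cfg) {
  status$off_drug <- drug
  status$off_years_on <- as.integer(years_on)
  if (years_on >= 1) {
    rr <- status_effective_rr(status, drug, years_on, cfg)
    status$off_rr_hip <- rr[["hip"]]
    status$off_rr_vert <- rr[["vert"]]
  } else {
    status$off_rr_hip <- 1
    status$off_rr_vert <- 1
  }
  status$years_since_stop <- 0L
  status
}

#' Advance the treatment status into the next model cycle
#'
#' Episode bookkeeping: moves an on-treatment individual one year forward,
#' marks the stop year when she discontinues (no fracture protection in that
#' year, per the end-of-cycle persistence rule), hands a denosumab completer
#' over to alendronate, inserts planned between-episode gap years (the
#' long-duration zoledronic acid scenario), and otherwise advances the
#' offset clock. Only individuals persistent through an entire episode
#' proceed to the next one; a stopper never restarts.
#'
#' @param status A `treatment_status`.
#' @param persisted_this_year Will she still be persistent at the end of the
#'   cycle being entered? (Ignored when not on treatment.)
#' @param strategy A resolved strategy (see [resolve_strategy()]).
#' @param cfg Configuration.
#' @return The updated `treatment_status`.
#' @export
advance_status <- function(status, persisted_this_year, strategy, cfg) {
  episodes <- strategy$episodes
  enter_episode <- function(status, idx) {
    ep <- episodes[[idx]]
    status$phase <- "on"
    status$current_drug <- ep$drug
    status$episode_index <- as.integer(idx)
    status$episode_year <- 1L
    if (ep$drug == "aln" && idx > 1) status$started_alendronate <- TRUE
    status
  }
  next_after_completion <- function(status, cfg) {
    idx <- status$episode_index
    ep <- episodes[[idx]]
    status <- begin_offset(status, ep$drug, ep$years, cfg)
    if (idx < length(episodes)) {
      gap <- episodes[[idx + 1]]$gap_before
      if (gap > 0) {
        status$phase <- "gap"
        status$gap_remaining <- as.integer(gap)
        status$current_drug <- NA_character_
        status$years_since_stop <- 1L
        status
      } else {
        enter_episode(status, idx + 1)
      }
    } else {
      status$phase <- "offset"
      status$current_drug <- NA_character_
      status$years_since_stop <- 1L
      status
    }
  }

  switch(status$phase,
    pre = {
      if (length(episodes) == 0) {
        status$phase <- "none"
        status
      } else {
        status <- enter_episode(status, 1L)
        if (!persisted_this_year) status$phase <- "stop_year"
        status
      }
    },
    on = {
      ep <- episodes[[status$episode_index]]
      if (status$episode_year < ep$years) {
        status$episode_year <- status$episode_year + 1L
        if (!persisted_this_year) status$phase <- "stop_year"
        status
      } else {
        # completed the episode while persistent
        status <- next_after_completion(status, cfg)
        if (status$phase == "on" && !persisted_this_year) {
          status$phase <- "stop_year"
        }
        status
      }
    },
    stop_year = {
      # the stop year has elapsed; offset runs from the completed full years
      status <- begin_offset(status, status$current_drug,
                             status$episode_year - 1L, cfg)
      status$phase <- "offset"
      status$current_drug <- NA_character_
      status$years_since_stop <- 1L
      status
    },
    gap = {
      status$gap_remaining <- status$gap_remaining - 1L
      status$years_since_stop <- status$years_since_stop + 1L
      if (status$gap_remaining == 0L) {
        status <- enter_episode(status, status$episode_index + 1L)
        if (!persisted_this_year) status$phase <- "stop_year"
        status$years_since_stop <- 0L
      }
      status
    },
    offset = {
      status$years_since_stop <- status$years_since_stop + 1L
      status
    },
    none = status
  )
}

#' Per-cycle treatment relative risk
#'
#' Dispatches over the treatment rules: on drug and persistent this year,
#' the adherence-scaled on-treatment relative risk applies; in the stop year
#' there is no protection (benefits accrue only to those persistent at the
#' end of the cycle); after stopping or between episodes the offset applies
#' (linear ramp for bisphosphonates, immediate loss for denosumab); never
#' treated means relative risk 1. In the sequential arm, alendronate is
#' reached only by completing denosumab -- denosumab stoppers never start it.
#'
#' The bisphosphonate ramp is a continuous linear return to baseline over a
#' period equal to the time treated; each post-treatment cycle uses the
#' ramp's mid-year value, so a 3-year completer retains partial protection
#' in post-years 1-3 and none from post-year 4 on.
#'
#' @param status A `treatment_status` (as evolved by [advance_status()]).
#' @param site `"hip"` or `"vert"`.
#' @param cfg Configuration.
#' @return Relative risk in (0, 1].
#' @export
cycle_rr <- function(status, site, cfg) {
  switch(status$phase,
    pre = 1.0,
    none = 1.0,
    stop_year = 1.0,
    on = {
      rr <- status_effective_rr(status, status$current_drug,
                                status$episode_year, cfg)
      rr[[site]]
    },
    gap = ,
    offset = {
      if (is.na(status$off_drug)) return(1.0)
      rr0 <- if (site == "hip") status$off_rr_hip else status$off_rr_vert
      # evaluate the continuous linear ramp at the middle of the cycle, so
      # the residual effect spans exactly years_on post-treatment years
      # (full return to baseline only after that)
      offset_rr(status$off_drug, site, status$off_years_on,
                status$years_since_stop - 0.5, rr0)
    }
  )
}

status_cycle_cost <- function(status, cfg) {
  if (status$phase == "on") {
    annual_treatment_cost(status$current_drug, status$episode_year,
                          "persistent_full_year", cfg)
  } else if (status$phase == "stop_year") {
    annual_treatment_cost(status$current_drug, status$episode_year,
                          "stops_this_year", cfg)
  } else {
    0
  }
}

# ---- strategy resolution and trajectory enumeration --------------------------

#' Resolve a strategy against the configuration's scenario flags
#'
#' Applies the persistence scenario (base/s1/s2/s3) and the long-duration
#' flag, and attaches to each episode its cumulative persistence curve:
#' the base 3-year curves; for long durations, zoledronic acid extended to
#' 6 years and denosumab to 10 years by chaining the last year-on-year
#' ratio, and alendronate extended to year 7 by the same rule and then held
#' flat (no dropout from year 8 onward). Under the long-duration flag the
#' zoledronic acid arm becomes 6 years on, 2 years off, 6 years on, and the
#' sequential arm 10 years of denosumab then 10 of alendronate.
#'
#' @param cfg Configuration.
#' @param strategy One entry of `cfg$strategies`.
#' @return The strategy with per-episode `curve` fields attached.
#' @export
resolve_strategy <- function(cfg, strategy) {
  curves <- scenario_curves(cfg$scenario_flags$persistence_scenario,
                            cfg$start_age, cfg)
  if (isTRUE(cfg$scenario_flags$long_duration)) {
    if (strategy$name == "za") {
      strategy$episodes <- list(
        list(drug = "za", years = 6L, gap_before = 0L),
        list(drug = "za", years = 6L, gap_before = 2L)
      )
    } else if (strategy$name == "da") {
      strategy$episodes <- list(
        list(drug = "deno", years = 10L, gap_before = 0L),
        list(drug = "aln", years = 10L, gap_before = 0L)
      )
    }
  }
  strategy$episodes <- lapply(strategy$episodes, function(ep) {
    base <- curves[[ep$drug]]
    cum <- if (ep$years <= length(base)) {
      base[seq_len(ep$years)]
    } else if (ep$drug == "aln") {
      ext <- extend_curve(base, min(ep$years, 7L))
      c(ext, rep(ext[length(ext)], max(0L, ep$years - 7L)))
    } else {
      extend_curve(base, ep$years)
    }
    ep$curve <- cum
    ep
  })
  strategy
}

#' Enumerate the treatment trajectories of a strategy
#'
#' A trajectory is one joint outcome of the per-episode discontinuation
#' draws: stopping during year `k` of some episode (later episodes are then
#' never entered, per the handoff rule) or completing every episode. Returns
#' each trajectory's probability (product of stop-distribution terms along
#' the path) and its per-episode stop years (`NA` = completed).
#'
#' @param strategy A resolved strategy.
#' @return A list of `list(prob, stops)` entries; probabilities sum to 1.
#' @export
enumerate_trajectories <- function(strategy) {
  episodes <- strategy$episodes
  out <- list()
  recurse <- function(idx, prob, stops) {
    if (idx > length(episodes)) {
      out[[length(out) + 1L]] <<- list(prob = prob, stops = stops)
      return(invisible())
    }
    sd <- stop_distribution(episodes[[idx]]$curve)
    for (k in seq_along(sd$stop_in_year)) {
      pk <- sd$stop_in_year[k]
      if (pk > 1e-12) {
        s <- stops
        s[idx] <- k
        out[[length(out) + 1L]] <<- list(prob = prob * pk, stops = s)
      }
    }
    if (sd$complete > 1e-12) {
      recurse(idx + 1L, prob * sd$complete, stops)
    }
    invisible()
  }
  recurse(1L, 1, rep(NA_integer_, length(episodes)))
  out
}

trajectory_schedule <- function(cfg, strategy, stops, n_cycles) {
  st <- new_treatment_status()
  rr_hip <- rr_vert <- rep(1, n_cycles)
  cost <- numeric(n_cycles)
  for (t in seq_len(n_cycles)) {
    persisted <- TRUE
    # peek at which episode-year this advance would put us in
    st_next <- advance_status(st, TRUE, strategy, cfg)
    if (st_next$phase == "on") {
      k <- stops[st_next$episode_index]
      persisted <- is.na(k) || st_next$episode_year < k
    }
    st <- advance_status(st, persisted, strategy, cfg)
    rr_hip[t] <- cycle_rr(st, "hip", cfg)
    rr_vert[t] <- cycle_rr(st, "vert", cfg)
    cost[t] <- status_cycle_cost(st, cfg)
  }
  list(rr_hip = rr_hip, rr_vert = rr_vert, cost = cost)
}

#' Build the per-trajectory schedules for one arm
#'
#' Because discontinuation is the only stochastic element of a treatment
#' trajectory, each arm reduces to a small set of deterministic schedules:
#' per trajectory, the cycle-by-cycle relative risks for hip and vertebral
#' fracture and the cycle-by-cycle treatment cost. The microsimulation then
#' assigns each individual a trajectory with a single uniform draw.
#'
#' @param cfg Configuration.
#' @param strategy One entry of `cfg$strategies`, or `NULL` for no
#'   intervention.
#' @return A list with `prob` (length K), and K x T matrices `rr_hip`,
#'   `rr_vert`, `cost`.
#' @export
build_strategy_schedules <- function(cfg, strategy) {
  n_cycles <- cfg$horizon_age - cfg$start_age
  if (is.null(strategy)) {
    return(list(prob = 1,
                rr_hip = matrix(1, 1, n_cycles),
                rr_vert = matrix(1, 1, n_cycles),
                cost = matrix(0, 1, n_cycles),
                trajectories = list(list(prob = 1, stops = integer(0)))))
  }
  strategy <- resolve_strategy(cfg, strategy)
  traj <- enumerate_trajectories(strategy)
  K <- length(traj)
  rr_hip <- rr_vert <- cost <- matrix(NA_real_, K, n_cycles)
  for (i in seq_len(K)) {
    s <- trajectory_schedule(cfg, strategy, traj[[i]]$stops, n_cycles)
    rr_hip[i, ] <- s$rr_hip
    rr_vert[i, ] <- s$rr_vert
    cost[i, ] <- s$cost
  }
  list(prob = vapply(traj, `[[`, numeric(1), "prob"),
       rr_hip = rr_hip, rr_vert = rr_vert, cost = cost,
       trajectories = traj)
}
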