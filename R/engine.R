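# Cohort engine: a time-inhomogeneous Markov model over rhythm, post-stroke
# and post-ICH states, with an irreversible-pulmonary-toxicity overlay
# carried as a parallel set of flagged states. The first model year is run
# as the first 1/cycle_length cycles of the same engine with strategy
# overlays (procedure costs and complications at cycle 0, the 12-month
# rhythm split applied as the entry distribution, recurrence suppressed
# until the rhythm outcome is resolved), so stroke, bleeding and mortality
# risk accrue during year 1.

# state-space layout for a given number of tunnel cycles per year
state_space <- function(n_tunnel) {
  base <- c("NSR", "AF",
            paste0("S1_", seq_len(n_tunnel) - 1), "SL",
            paste0("H1_", seq_len(n_tunnel) - 1), "HL")
  c(base, paste0(base, "_tox"), "DEAD")
}

n_tunnel_cycles <- function(ps) {
  nt <- 1 / ps$cycle_length
  if (abs(nt - round(nt)) > 1e-9) {
    stop("cycle_length must divide one year evenly", call. = FALSE)
  }
  as.integer(round(nt))
}

total_cycles <- function(ps) {
  nt <- n_tunnel_cycles(ps)
  n <- round(ps$horizon / ps$cycle_length)
  if (!ps$horizon_includes_first_year) n <- n + nt
  as.integer(n)
}

match_strategy <- function(strategy) {
  match.arg(strategy, c("ablation", "aad"))
}

# treatment attribution for rhythm-state occupants at a given cycle.
# In the ablation arm nobody is on amiodarone during year 1 (failures switch
# to drug therapy when the 12-month rhythm outcome is resolved); afterwards
# only the AF (switched) states are. Warfarin is stopped in the ablation arm
# after `warfarin_stop_cycle_ablation` cycles and re-acquired (at the cohort
# proportion) on recurrence.
treatment_status <- function(strategy, ps, profile, cycle, n_tunnel) {
  if (strategy == "aad") {
    amio_nsr <- TRUE
    amio_af <- !ps$amiodarone_stop_in_af
    w_nsr <- profile$prop_warfarin
    w_af <- profile$prop_warfarin
  } else {
    post_y1 <- cycle >= n_tunnel
    amio_nsr <- FALSE
    amio_af <- post_y1 && !ps$amiodarone_stop_in_af
    pre_stop <- cycle < ps$warfarin_stop_cycle_ablation
    w_nsr <- if (pre_stop) profile$prop_warfarin else 0
    w_af <- if (pre_stop) {
      profile$prop_warfarin
    } else if (post_y1 && ps$warfarin_resume_on_recurrence) {
      profile$prop_warfarin
    } else 0
  }
  list(amio_nsr = amio_nsr, amio_af = amio_af, w_nsr = w_nsr, w_af = w_af)
}

#' Single-cycle transition probabilities of the cohort model
#'
#' `transition_matrix()` builds the full state-to-state transition matrix
#' for one model cycle; `cycle_transition()` returns the row for one state
#' as a named probability vector. Within a cycle, risks are composed
#' sequentially (death, then ischemic stroke, then major bleed, then
#' pulmonary toxicity and rhythm recurrence), so each row sums to one by
#' construction. Gastrointestinal bleeds and pulmonary-toxicity events that
#' leave the health state unchanged are returned as per-occupant event rates
#' in the `"gi_rate"` and `"tox_rate"` attributes.
#'
#' @param strategy `"ablation"` or `"aad"`.
#' @param ps an [af_parameters()] object.
#' @param profile an [af_profile()] object.
#' @param fixtures an [af_fixtures()] bundle.
#' @param cycle 0-based cycle index (cycle 0 starts at the profile's
#'   starting age; four cycles per year at the default cycle length).
#' @return `transition_matrix()`: a square matrix with one row and column
#'   per state; `cycle_transition()`: one named row.
#' @export
transition_matrix <- function(strategy, ps, profile, fixtures, cycle) {
  strategy <- match_strategy(strategy)
  nt <- n_tunnel_cycles(ps)
  states <- state_space(nt)
  ns <- length(states)
  idx <- function(nm) match(nm, states)
  cl <- ps$cycle_length
  age <- profile$start_age + cycle * cl
  sex <- profile$sex

  q_bg <- lookup_value(fixtures$life_table, age, sex)
  d_bg <- annual_to_cycle_prob(q_bg, cl)
  ts <- treatment_status(strategy, ps, profile, cycle, nt)

  p_af_stroke <- ps$chads2_stroke_table[[as.character(profile$chads2)]]
  p_nsr_stroke <- apply_relative_risk(p_af_stroke, 1 / ps$rr_stroke_af_vs_nsr)
  p_bleed_warf <- warfarin_bleed_prob(ps$p_bleed_no_warfarin,
                                      ps$rr_bleed_placebo_vs_warfarin)
  recur_annual <- if (strategy == "ablation") ps$p_recur_ablation else
    ps$p_recur_aad
  r_cycle <- if (cycle < nt) 0 else annual_to_cycle_prob(recur_annual, cl)
  x_cycle <- annual_to_cycle_prob(ps$p_pulm_tox_annual, cl)

  m28 <- lookup_value(fixtures$event_mortality, age, sex, "ischemic")
  m30 <- lookup_value(fixtures$event_mortality, age, sex, "ich")
  d_s1 <- annual_to_cycle_prob(min(1, m28 * ps$mort_mult_stroke_1y), cl)
  d_sl <- annual_to_cycle_prob(min(1, q_bg * ps$mort_mult_stroke_later), cl)
  d_h1 <- annual_to_cycle_prob(min(1, m30 * ps$mort_mult_ich_1y), cl)
  d_hl <- d_bg

  M <- matrix(0, ns, ns, dimnames = list(states, states))
  gi_rate <- stats::setNames(numeric(ns), states)
  tox_rate <- stats::setNames(numeric(ns), states)
  DEAD <- idx("DEAD")
  M[DEAD, DEAD] <- 1

  fill_rhythm <- function(from, stroke_to, ich_to, nsr_to, af_to,
                          s_annual, w, amio, tox_possible, recur) {
    s <- annual_to_cycle_prob(s_annual, cl)
    b_annual <- w * p_bleed_warf + (1 - w) * ps$p_bleed_no_warfarin
    b <- annual_to_cycle_prob(b_annual, cl)
    x <- if (amio && tox_possible) x_cycle else 0
    i <- ps$prop_bleed_ich
    m <- (1 - d_bg) * (1 - s) * (1 - b * i)
    q_toxdeath <- x * ps$p_pulm_tox_death
    q_irrev <- x * (1 - ps$p_pulm_tox_death) * ps$prop_pulm_tox_irreversible
    q_clean <- 1 - q_toxdeath - q_irrev
    fi <- idx(from)
    M[fi, DEAD] <<- d_bg + m * q_toxdeath
    M[fi, idx(stroke_to)] <<- (1 - d_bg) * s
    M[fi, idx(ich_to)] <<- (1 - d_bg) * (1 - s) * b * i
    # clean and newly-irreversible occupants resolve rhythm the same way
    M[fi, idx(af_to[1])] <<- M[fi, idx(af_to[1])] + m * q_clean * recur
    M[fi, idx(nsr_to[1])] <<- M[fi, idx(nsr_to[1])] + m * q_clean * (1 - recur)
    M[fi, idx(af_to[2])] <<- M[fi, idx(af_to[2])] + m * q_irrev * recur
    M[fi, idx(nsr_to[2])] <<- M[fi, idx(nsr_to[2])] + m * q_irrev * (1 - recur)
    gi_rate[fi] <<- (1 - d_bg) * (1 - s) * b * (1 - i)
    tox_rate[fi] <<- m * x
  }

  fill_rhythm("NSR", "S1_0", "H1_0", c("NSR", "NSR_tox"), c("AF", "AF_tox"),
              p_nsr_stroke, ts$w_nsr, ts$amio_nsr, TRUE, r_cycle)
  fill_rhythm("AF", "S1_0", "H1_0", c("AF", "AF_tox"), c("AF", "AF_tox"),
              p_af_stroke, ts$w_af, ts$amio_af, TRUE, 0)
  fill_rhythm("NSR_tox", "S1_0_tox", "H1_0_tox",
              c("NSR_tox", "NSR_tox"), c("AF_tox", "AF_tox"),
              p_nsr_stroke, ts$w_nsr, ts$amio_nsr, FALSE, r_cycle)
  fill_rhythm("AF_tox", "S1_0_tox", "H1_0_tox",
              c("AF_tox", "AF_tox"), c("AF_tox", "AF_tox"),
              p_af_stroke, ts$w_af, ts$amio_af, FALSE, 0)

  fill_chain <- function(prefix, suffix, d_y1, d_later) {
    for (j in seq_len(nt) - 1) {
      from <- paste0(prefix, "_", j, suffix)
      to <- if (j == nt - 1) paste0(sub("1$", "L", prefix), suffix) else
        paste0(prefix, "_", j + 1, suffix)
      M[idx(from), DEAD] <<- d_y1
      M[idx(from), idx(to)] <<- 1 - d_y1
    }
    late <- paste0(sub("1$", "L", prefix), suffix)
    M[idx(late), DEAD] <<- d_later
    M[idx(late), idx(late)] <<- 1 - d_later
  }
  fill_chain("S1", "", d_s1, d_sl)
  fill_chain("S1", "_tox", d_s1, d_sl)
  fill_chain("H1", "", d_h1, d_hl)
  fill_chain("H1", "_tox", d_h1, d_hl)

  if (any(M < -1e-12)) {
    bad <- which(M < -1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("negative transition probability from %s to %s at cycle %d",
                 states[bad[1]], states[bad[2]], cycle), call. = FALSE)
  }
  attr(M, "gi_rate") <- gi_rate
  attr(M, "tox_rate") <- tox_rate
  M
}

#' @rdname transition_matrix
#' @param state a state label (see the matrix dimnames), e.g. `"NSR"`,
#'   `"AF"`, `"S1_0"`, `"SL"`, `"H1_0"`, `"HL"`, `"DEAD"` and their `_tox`
#'   variants.
#' @export
cycle_transition <- function(state, strategy, ps, profile, fixtures,
                             cycle = 0) {
  M <- transition_matrix(strategy, ps, profile, fixtures, cycle)
  if (!state %in% rownames(M)) {
    stop("unknown state '", state, "'; valid states: ",
         paste(rownames(M), collapse = ", "), call. = FALSE)
  }
  M[state, ]
}

# per-state utility (annual scale) and cost (annual rate) vectors at a cycle
reward_vectors <- function(strategy, ps, profile, fixtures, cycle) {
  nt <- n_tunnel_cycles(ps)
  states <- state_space(nt)
  age <- profile$start_age + cycle * ps$cycle_length
  U <- lookup_value(fixtures$utility, age, profile$sex)
  ts <- treatment_status(strategy, ps, profile, cycle, nt)

  u <- stats::setNames(numeric(length(states)), states)
  cost <- stats::setNames(numeric(length(states)), states)
  s1 <- paste0("S1_", seq_len(nt) - 1)
  h1 <- paste0("H1_", seq_len(nt) - 1)
  base_u <- c(NSR = U, AF = max(0, U - ps$disutility_af),
              stats::setNames(rep(ps$utility_ischemic_stroke, nt + 1),
                              c(s1, "SL")),
              stats::setNames(rep(ps$utility_ich, nt + 1), c(h1, "HL")))
  u[names(base_u)] <- base_u
  u[paste0(names(base_u), "_tox")] <- base_u * ps$utility_pulm_tox_irrev

  warf_cost <- ps$cost_warfarin_annual + ps$cost_warfarin_monitoring_annual
  cost["NSR"] <- ts$amio_nsr * ps$cost_amiodarone_annual + ts$w_nsr * warf_cost
  cost["AF"] <- ts$amio_af * ps$cost_amiodarone_annual + ts$w_af * warf_cost
  # first-year event costs are either a one-off at the event (default) or
  # spread over the four tunnel cycles, prorated by survival
  if (!ps$stroke_cost_at_event) {
    cost[s1] <- ps$cost_ischemic_stroke_y1
    cost[h1] <- ps$cost_ich_y1
  }
  cost["SL"] <- ps$cost_ischemic_stroke_later_annual
  cost["HL"] <- ps$cost_ich_later_annual
  base_states <- c("NSR", "AF", s1, "SL", h1, "HL")
  cost[paste0(base_states, "_tox")] <-
    cost[base_states] + ps$cost_pulm_tox_irrev_annual
  list(u = u, cost = cost)
}

# iterate the chain over the given 0-based cycle indices, accumulating
# per-cycle (undiscounted) rewards and event flows
simulate_cycles <- function(occ0, cycles, strategy, ps, profile, fixtures) {
  nt <- n_tunnel_cycles(ps)
  states <- state_space(nt)
  ns <- length(states)
  stopifnot(length(occ0) == ns)
  nk <- length(cycles)
  occupancy <- matrix(0, nk + 1, ns, dimnames = list(NULL, states))
  occupancy[1, ] <- occ0
  out <- data.frame(cycle = cycles, time = cycles * ps$cycle_length,
                    cost = 0, qaly = 0, strokes = 0, ich = 0,
                    gi_bleeds = 0, tox_events = 0, deaths = 0)
  stroke_cols <- match(c("S1_0", "S1_0_tox"), states)
  ich_cols <- match(c("H1_0", "H1_0_tox"), states)
  cl <- ps$cycle_length
  occ <- occ0
  for (j in seq_len(nk)) {
    k <- cycles[j]
    M <- transition_matrix(strategy, ps, profile, fixtures, k)
    rw <- reward_vectors(strategy, ps, profile, fixtures, k)
    occ_next <- as.numeric(occ %*% M)
    occ_reward <- if (ps$half_cycle_correction) (occ + occ_next) / 2 else occ
    gi <- sum(occ * attr(M, "gi_rate"))
    tox <- sum(occ * attr(M, "tox_rate"))
    strokes_j <- sum(occ * M[, stroke_cols[1]]) +
      sum(occ * M[, stroke_cols[2]])
    ich_j <- sum(occ * M[, ich_cols[1]]) + sum(occ * M[, ich_cols[2]])
    event_cost <- if (ps$stroke_cost_at_event) {
      strokes_j * ps$cost_ischemic_stroke_y1 + ich_j * ps$cost_ich_y1
    } else 0
    out$cost[j] <- sum(occ_reward * rw$cost) * cl +
      gi * ps$cost_gi_bleed + tox * ps$cost_pulm_tox_acute + event_cost
    out$qaly[j] <- sum(occ_reward * rw$u) * cl -
      tox * ps$pulm_tox_disutility_days / 365.25
    out$strokes[j] <- strokes_j
    out$ich[j] <- ich_j
    out$gi_bleeds[j] <- gi
    out$tox_events[j] <- tox
    out$deaths[j] <- occ_next[ns] - occ[ns]
    occ <- occ_next
    occupancy[j + 1, ] <- occ
  }
  list(occupancy = occupancy, cycles = out)
}

#' Run the first model year (decision-tree phase)
#'
#' The first year is run as the first four (at the default 3-month cycle)
#' cycles of the cohort engine, with the strategy-specific overlays of the
#' short-term decision tree: for ablation, procedure and follow-up costs and
#' procedural complications at cycle 0 (complication probabilities scaled by
#' the mean number of procedures, procedural strokes entering the
#' post-stroke tunnel); for drug therapy, pulmonary-toxicity risk through
#' the engine itself. The 12-month rhythm outcome (pooled trial probability,
#' times the ablation relative risk in the ablation arm) is applied as the
#' entry split, with recurrence suppressed until the outcome is resolved at
#' one year.
#'
#' @inheritParams transition_matrix
#' @return an object of class `af_first_year`: undiscounted first-year
#'   `cost`, `qaly`, `strokes`, `ich`, cumulative `deaths`, the
#'   `entry_distribution` over states at the end of year 1 (masses, so
#'   `sum(entry_distribution) + deaths == 1` up to the dead-state mass), the
#'   irreversible-toxicity fraction, and the per-cycle trace fragment.
#' @export
run_first_year <- function(strategy, ps, profile, fixtures = af_fixtures()) {
  strategy <- match_strategy(strategy)
  viol <- validate_parameters(ps)
  if (nrow(viol)) {
    stop("invalid parameters: ",
         paste(viol$field, viol$rule, sep = " violates ", collapse = "; "),
         call. = FALSE)
  }
  nt <- n_tunnel_cycles(ps)
  states <- state_space(nt)
  occ0 <- stats::setNames(numeric(length(states)), states)

  p_nsr <- if (strategy == "ablation") {
    apply_relative_risk(ps$p_nsr_aad_1y, ps$rr_nsr_ablation)
  } else ps$p_nsr_aad_1y

  overlay_cost <- 0
  overlay_disutility <- 0
  proc_strokes <- 0
  if (strategy == "ablation") {
    scale <- if (ps$scale_complications_by_procedures) ps$n_procedures else 1
    proc_strokes <- scale * ps$p_complication_stroke
    comp_cost <- scale * (ps$p_complication_stroke * ps$cost_complication_stroke +
                          ps$p_complication_tia * ps$cost_complication_tia +
                          ps$p_complication_tamponade * ps$cost_complication_tamponade +
                          ps$p_complication_pv_stenosis * ps$cost_complication_pv_stenosis)
    overlay_cost <- ps$n_procedures * ps$cost_ablation_total_per_procedure +
      ps$cost_ablation_followup_y1 + comp_cost +
      if (ps$stroke_cost_at_event) {
        # procedural strokes enter the tunnel as starting mass, so their
        # first-year stroke cost is applied here rather than as a flow
        proc_strokes * ps$cost_ischemic_stroke_y1
      } else 0
    overlay_disutility <- scale *
      (ps$p_complication_tia + ps$p_complication_tamponade +
       ps$p_complication_pv_stenosis) *
      ps$complication_disutility_days / 365.25
    if (proc_strokes > 1) {
      stop("procedural stroke mass exceeds 1; check complication inputs",
           call. = FALSE)
    }
    occ0["S1_0"] <- proc_strokes
    occ0["NSR"] <- (1 - proc_strokes) * p_nsr
    occ0["AF"] <- (1 - proc_strokes) * (1 - p_nsr)
  } else {
    occ0["NSR"] <- p_nsr
    occ0["AF"] <- 1 - p_nsr
  }
  if (abs(sum(occ0) - 1) > 1e-9) {
    stop("entry masses do not sum to 1", call. = FALSE)
  }

  sim <- simulate_cycles(occ0, seq_len(nt) - 1, strategy, ps, profile,
                         fixtures)
  sim$cycles$cost[1] <- sim$cycles$cost[1] + overlay_cost
  sim$cycles$qaly[1] <- sim$cycles$qaly[1] - overlay_disutility
  sim$cycles$strokes[1] <- sim$cycles$strokes[1] + proc_strokes

  final <- sim$occupancy[nt + 1, ]
  alive <- final[names(final) != "DEAD"]
  tox_frac <- sum(alive[grepl("_tox$", names(alive))])
  structure(list(strategy = strategy,
                 cost = sum(sim$cycles$cost),
                 qaly = sum(sim$cycles$qaly),
                 strokes = sum(sim$cycles$strokes),
                 ich = sum(sim$cycles$ich),
                 deaths = unname(final["DEAD"]),
                 entry_distribution = alive,
                 tox_frac = tox_frac,
                 occupancy = sim$occupancy, cycles = sim$cycles,
                 ps = ps, profile = profile),
            class = "af_first_year")
}

#' @export
print.af_first_year <- function(x, ...) {
  cat(sprintf("First model year, %s arm\n", x$strategy))
  cat(sprintf("  cost $%.0f, QALYs %.4f, strokes %.4f, deaths %.4f\n",
              x$cost, x$qaly, x$strokes, x$deaths))
  ent <- x$entry_distribution[x$entry_distribution > 1e-12]
  cat("  entry distribution:",
      paste(sprintf("%s %.4f", names(ent), ent), collapse = ", "), "\n")
  invisible(x)
}

#' Run the long-term Markov phase from a first-year result
#'
#' Iterates the cohort over the remaining cycles of the horizon, ageing the
#' cohort a cycle length per cycle, accumulating undiscounted per-cycle
#' costs, QALYs and incident events.
#'
#' @param first_year an [run_first_year()] result.
#' @inheritParams transition_matrix
#' @return an object of class `af_trace` with the occupancy matrix (rows:
#'   start of each cycle plus the final state) and per-cycle accumulators.
#' @export
run_markov <- function(first_year, strategy = first_year$strategy,
                       ps = first_year$ps, profile = first_year$profile,
                       fixtures = af_fixtures()) {
  strategy <- match_strategy(strategy)
  nt <- n_tunnel_cycles(ps)
  n_total <- total_cycles(ps)
  states <- state_space(nt)
  occ0 <- stats::setNames(numeric(length(states)), states)
  occ0[names(first_year$entry_distribution)] <- first_year$entry_distribution
  occ0["DEAD"] <- first_year$deaths
  if (abs(sum(occ0) - 1) > 1e-9) {
    stop("entry distribution plus deaths must sum to 1", call. = FALSE)
  }
  cycles <- if (n_total > nt) seq.int(nt, n_total - 1) else integer(0)
  sim <- simulate_cycles(occ0, cycles, strategy, ps, profile, fixtures)
  structure(list(strategy = strategy, occupancy = sim$occupancy,
                 cycles = sim$cycles, ps = ps, profile = profile),
            class = "af_trace")
}

#' @export
print.af_trace <- function(x, ...) {
  cat(sprintf("Markov trace, %s arm: %d cycles, %d states\n", x$strategy,
              nrow(x$cycles), ncol(x$occupancy)))
  cat(sprintf("  final survival %.4f, undiscounted cost $%.0f, QALYs %.4f\n",
              1 - x$occupancy[nrow(x$occupancy), "DEAD"],
              sum(x$cycles$cost), sum(x$cycles$qaly)))
  invisible(x)
}

#' Discounted strategy totals from the two model phases
#'
#' Discounts each cycle's cost and QALY at the annual discount rate with
#' yearly compounding (`(1 + r)^-floor(t)`), so the first model year is
#' undiscounted. Stroke counts are left undiscounted; ischemic strokes
#' (procedural plus incident) are the headline count, intracranial
#' haemorrhages are tracked separately.
#'
#' @param first_year an [run_first_year()] result.
#' @param trace an [run_markov()] trace.
#' @param ps an [af_parameters()] object.
#' @return an object of class `af_strategy_result` with `expected_cost`,
#'   `expected_qaly`, `expected_strokes`, `expected_ich` and settings used.
#' @export
accumulate_results <- function(first_year, trace, ps = first_year$ps) {
  cyc <- rbind(first_year$cycles, trace$cycles)
  year <- floor(cyc$time + 1e-9)
  disc <- (1 + ps$discount_rate)^(-year)
  structure(list(strategy = first_year$strategy,
                 expected_cost = sum(cyc$cost * disc),
                 expected_qaly = sum(cyc$qaly * disc),
                 expected_strokes = sum(cyc$strokes),
                 expected_ich = sum(cyc$ich),
                 undiscounted_cost = sum(cyc$cost),
                 undiscounted_qaly = sum(cyc$qaly),
                 deaths = unname(trace$occupancy[nrow(trace$occupancy),
                                                 "DEAD"]),
                 horizon = ps$horizon, discount_rate = ps$discount_rate,
                 profile = first_year$profile),
            class = "af_strategy_result")
}

#' @export
print.af_strategy_result <- function(x, ...) {
  cat(sprintf("%s arm: expected cost $%s, QALYs %.3f, strokes %.3f (ICH %.3f)\n",
              x$strategy, format(round(x$expected_cost), big.mark = ","),
              x$expected_qaly, x$expected_strokes, x$expected_ich))
  invisible(x)
}

#' Run one treatment strategy end to end
#'
#' Convenience wrapper chaining [run_first_year()], [run_markov()] and
#' [accumulate_results()].
#'
#' @inheritParams transition_matrix
#' @return an `af_strategy_result` with the first-year result and trace
#'   attached as `first_year` and `trace`.
#' @export
run_strategy <- function(strategy, ps = af_parameters(),
                         profile = af_profile(),
                         fixtures = af_fixtures()) {
  fy <- run_first_year(strategy, ps, profile, fixtures)
  tr <- run_markov(fy, strategy, ps, profile, fixtures)
  res <- accumulate_results(fy, tr, ps)
  res$first_year <- fy
  res$trace <- tr
  res
}
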