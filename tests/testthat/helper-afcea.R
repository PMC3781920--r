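# shared fixtures for the test suite -- all built in code

# default external tables, built once
fx <- af_fixtures()

# fixtures with no background mortality (life table all zero)
fx_no_mort <- af_fixtures(life_table = make_life_table(0, 0.09, 0, 1))

# fixtures with no mortality of any kind and flat utility
fx_inert <- af_fixtures(
  life_table = make_life_table(0, 0.09, 0, 1),
  event_mortality = make_event_mortality_table(c(ischemic = 0, ich = 0)),
  utility = make_utility_table(0.83, 0))

# a parameter set with every stochastic event switched off
params_no_events <- function(...) {
  af_parameters(
    chads2_stroke_table = stats::setNames(rep(0, 7), 0:6),
    p_bleed_no_warfarin = 0,
    p_pulm_tox_annual = 0,
    p_complication_stroke = 0, p_complication_tia = 0,
    p_complication_tamponade = 0, p_complication_pv_stenosis = 0,
    p_recur_ablation = 0, p_recur_aad = 0,
    ...)
}

# microsimulation oracle: individual-level simulation under the same
# per-cycle transition rows, for validating the cohort expectation
microsimulate <- function(n_ind, cycles, strategy, ps, profile, fixtures,
                          init_state = "NSR", seed = 42) {
  set.seed(seed)
  M0 <- transition_matrix(strategy, ps, profile, fixtures, 0)
  states <- rownames(M0)
  cur <- rep(match(init_state, states), n_ind)
  strokes <- 0
  s1 <- match(c("S1_0", "S1_0_tox"), states)
  for (k in cycles) {
    M <- transition_matrix(strategy, ps, profile, fixtures, k)
    nxt <- integer(n_ind)
    for (s in unique(cur)) {
      sel <- cur == s
      nxt[sel] <- sample.int(length(states), sum(sel), replace = TRUE,
                             prob = M[s, ])
    }
    strokes <- strokes + sum(nxt %in% s1 & !(cur %in% s1))
    cur <- nxt
  }
  list(strokes = strokes / n_ind,
       dead = mean(cur == match("DEAD", states)),
       final = tabulate(cur, length(states)) / n_ind)
}
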