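#' Sample one parameter set from the probabilistic distribution map
#'
#' Draws each uncertain parameter independently from its [af_distributions()]
#' specification and rebuilds a full [af_parameters()] set. Derived values
#' are kept coherent: the CHADS2 stroke table is rescaled proportionally to
#' the sampled reference (score 2) probability; the combined warfarin cost
#' draw replaces drug plus monitoring; the sampled warfarin proportion is
#' returned in the `prop_warfarin` attribute for the caller to place in the
#' cohort profile.
#'
#' @param dists named list of `af_dist` objects (default
#'   [af_distributions()]).
#' @param base an [af_parameters()] set supplying non-sampled fields.
#' @return an `af_parameters` object with attribute `prop_warfarin`.
#' @export
sample_parameter_set <- function(dists = af_distributions(),
                                 base = af_parameters()) {
  draw <- lapply(dists, dist_sample)
  ps <- unclass(base)
  direct <- intersect(names(draw), names(ps))
  ps[direct] <- draw[direct]
  if (!is.null(draw$p_stroke_chads2_ref)) {
    ref <- base$chads2_stroke_table[["2"]]
    ps$chads2_stroke_table <- pmin(base$chads2_stroke_table *
                                     draw$p_stroke_chads2_ref / ref, 1)
  }
  if (!is.null(draw$cost_warfarin_combined_annual)) {
    ps$cost_warfarin_annual <- draw$cost_warfarin_combined_annual
    ps$cost_warfarin_monitoring_annual <- 0
  }
  ps$cost_ablation_total_per_procedure <- NULL
  out <- do.call(af_parameters, ps)
  attr(out, "prop_warfarin") <- draw$prop_warfarin
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo re-evaluation of both treatment arms under parameter sets
#' sampled from the probabilistic distribution map (1000 draws in the
#' published analysis). Reproducible given `seed`.
#'
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed for the random draws.
#' @param profile an [af_profile()] (its warfarin proportion is replaced by
#'   the sampled value each draw).
#' @param ps basecase [af_parameters()] supplying non-sampled fields.
#' @param fixtures an [af_fixtures()] bundle.
#' @param dists distribution map, default [af_distributions()].
#' @return an object of class `af_psa`: a data frame with one row per draw
#'   (per-arm cost and QALYs, incremental cost and QALYs) plus the sampled
#'   headline parameters, with the call settings in attributes.
#' @export
#' @examples
#' \donttest{
#' psa <- run_psa(25, seed = 1)
#' head(psa)
#' }
run_psa <- function(n_draws, seed = 1, profile = af_profile(),
                    ps = af_parameters(), fixtures = af_fixtures(),
                    dists = af_distributions()) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    psi <- sample_parameter_set(dists, ps)
    pw <- attr(psi, "prop_warfarin")
    prof_i <- if (is.null(pw)) profile else
      af_profile(profile$start_age, profile$sex, profile$chads2, pw)
    abl <- run_strategy("ablation", psi, prof_i, fixtures)
    aad <- run_strategy("aad", psi, prof_i, fixtures)
    rows[[i]] <- data.frame(
      draw = i,
      cost_ablation = abl$expected_cost, qaly_ablation = abl$expected_qaly,
      cost_aad = aad$expected_cost, qaly_aad = aad$expected_qaly,
      delta_cost = abl$expected_cost - aad$expected_cost,
      delta_qaly = abl$expected_qaly - aad$expected_qaly,
      p_nsr_aad_1y = psi$p_nsr_aad_1y,
      rr_nsr_ablation = psi$rr_nsr_ablation,
      disutility_af = psi$disutility_af)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "profile") <- profile
  class(out) <- c("af_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that ablation is
#' cost-effective is the fraction of Monte-Carlo draws with positive
#' incremental net monetary benefit,
#' \eqn{\lambda \Delta QALY - \Delta Cost > 0}. At \eqn{\lambda = 0} this is
#' the fraction of draws in which ablation is cheaper; as
#' \eqn{\lambda \to \infty} it tends to the fraction in which ablation gains
#' QALYs.
#'
#' @param draws an [run_psa()] result.
#' @param wtp numeric vector of willingness-to-pay thresholds ($/QALY).
#' @return a data frame of class `af_ceac` with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(draws, wtp = seq(0, 200000, by = 5000)) {
  stopifnot(nrow(draws) >= 1)
  prob <- vapply(wtp, function(l) {
    mean(l * draws$delta_qaly - draws$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp, probability = prob),
            class = c("af_ceac", "data.frame"))
}

#' @export
plot.af_psa <- function(x, wtp = seq(0, 200000, by = 5000), ...) {
  cc <- ceac(x, wtp)
  graphics::plot(cc$wtp, cc$probability, type = "l", ylim = c(0, 1),
       xlab = "Willingness to pay ($/QALY)",
       ylab = "P(ablation cost-effective)",
       main = "Cost-effectiveness acceptability curve", ...)
  invisible(cc)
}
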