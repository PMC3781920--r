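#' Convert an annual probability to a shorter-cycle probability
#'
#' Uses constant-hazard (exponential) compounding: the event rate implied by
#' the annual probability is assumed uniform through the year, so the
#' probability over a cycle of length \code{cycle_years} is
#' \eqn{1 - (1 - p)^{t}} with \eqn{t} in years.
#'
#' @param p_annual annual event probability, in \code{[0, 1]}.
#' @param cycle_years cycle length in years (e.g. 0.25 for a 3-month cycle).
#' @return probability of the event over one cycle.
#' @seealso [cycle_to_annual_prob()] for the inverse.
#' @export
#' @examples
#' annual_to_cycle_prob(0.04, 0.25)
annual_to_cycle_prob <- function(p_annual, cycle_years) {
  stopifnot(is.numeric(p_annual), is.numeric(cycle_years))
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  }
  if (any(cycle_years <= 0)) stop("cycle_years must be > 0", call. = FALSE)
  1 - (1 - p_annual)^cycle_years
}

#' @rdname annual_to_cycle_prob
#' @param p_cycle per-cycle probability to convert back to the annual scale.
#' @export
cycle_to_annual_prob <- function(p_cycle, cycle_years) {
  stopifnot(is.numeric(p_cycle), is.numeric(cycle_years))
  if (any(p_cycle < 0 | p_cycle > 1)) {
    stop("p_cycle must lie in [0, 1]", call. = FALSE)
  }
  if (any(cycle_years <= 0)) stop("cycle_years must be > 0", call. = FALSE)
  1 - (1 - p_cycle)^(1 / cycle_years)
}

#' Convert a cumulative probability over a follow-up window to an annual one
#'
#' Assumes a constant event rate over the follow-up period, so a cumulative
#' probability \code{p_cum} observed over \code{followup_months} months
#' corresponds to an annual probability
#' \eqn{1 - (1 - p_{cum})^{12/m}}.
#'
#' @param p_cum cumulative probability over the follow-up window, in
#'   \code{[0, 1)}.
#' @param followup_months length of the follow-up window in months.
#' @return annual event probability.
#' @export
#' @examples
#' # 1.9 percent pulmonary toxicity over a mean 27.54 months of follow-up
#' cumulative_to_annual_prob(0.019, 27.54)
cumulative_to_annual_prob <- function(p_cum, followup_months) {
  stopifnot(is.numeric(p_cum), is.numeric(followup_months))
  if (any(p_cum < 0 | p_cum >= 1)) {
    stop("p_cum must lie in [0, 1); p_cum = 1 implies an infinite rate",
         call. = FALSE)
  }
  if (any(followup_months <= 0)) {
    stop("followup_months must be > 0", call. = FALSE)
  }
  1 - (1 - p_cum)^(12 / followup_months)
}

#' Apply a relative risk to a baseline probability
#'
#' Multiplies on the probability scale and caps the result at 1. The cap is a
#' documented model convention: risk ratios applied to small probabilities
#' (as everywhere in this model) stay far from the cap.
#'
#' @param p baseline probability, in \code{[0, 1]}.
#' @param rr relative risk, \code{>= 0}.
#' @return \code{min(p * rr, 1)}.
#' @export
#' @examples
#' apply_relative_risk(0.04, 0.625) # stroke risk in sinus rhythm vs AF
apply_relative_risk <- function(p, rr) {
  stopifnot(is.numeric(p), is.numeric(rr))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(rr < 0)) stop("rr must be >= 0", call. = FALSE)
  pmin(p * rr, 1)
}

#' Annual major-bleed probability on warfarin from the no-therapy rate
#'
#' The published comparison reports the relative risk of major bleeding for
#' placebo relative to warfarin, so the on-warfarin probability is the
#' no-therapy probability divided by that relative risk (capped at 1).
#'
#' @param p_no_therapy annual major-bleed probability without antithrombotic
#'   therapy.
#' @param rr_placebo_vs_warfarin relative risk of bleeding for placebo vs
#'   warfarin (expected < 1: untreated patients bleed less).
#' @return annual major-bleed probability on warfarin.
#' @export
#' @examples
#' warfarin_bleed_prob(0.0058, 0.45)
warfarin_bleed_prob <- function(p_no_therapy, rr_placebo_vs_warfarin) {
  stopifnot(is.numeric(p_no_therapy), is.numeric(rr_placebo_vs_warfarin))
  if (any(p_no_therapy < 0)) stop("p_no_therapy must be >= 0", call. = FALSE)
  if (any(rr_placebo_vs_warfarin <= 0)) {
    stop("rr_placebo_vs_warfarin must be > 0", call. = FALSE)
  }
  pmin(p_no_therapy / rr_placebo_vs_warfarin, 1)
}
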