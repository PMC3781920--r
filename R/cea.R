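#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes incremental costs, QALYs and stroke counts (ablation minus drug
#' therapy) and the incremental cost-effectiveness ratio, with dominance
#' handling: a strategy that is cheaper and more effective `"dominates"`;
#' costlier and less effective is `"dominated"`; a zero QALY difference
#' leaves the ratio `"undefined"`.
#'
#' @param ablation,aad `af_strategy_result` objects from [run_strategy()]
#'   (or [accumulate_results()]) computed under identical profile, horizon
#'   and discount settings.
#' @return an object of class `af_cea` with per-strategy values, incremental
#'   values, `icer` (numeric or `NA`) and `label` (`"icer"`, `"dominates"`,
#'   `"dominated"`, `"undefined"`).
#' @export
compare_strategies <- function(ablation, aad) {
  stopifnot(inherits(ablation, "af_strategy_result"),
            inherits(aad, "af_strategy_result"))
  same <- isTRUE(all.equal(ablation$horizon, aad$horizon)) &&
    isTRUE(all.equal(ablation$discount_rate, aad$discount_rate)) &&
    identical(unclass(ablation$profile), unclass(aad$profile))
  if (!same) {
    stop("strategy results were produced under different settings",
         call. = FALSE)
  }
  dc <- ablation$expected_cost - aad$expected_cost
  dq <- ablation$expected_qaly - aad$expected_qaly
  ds <- ablation$expected_strokes - aad$expected_strokes
  if (dq == 0) {
    label <- "undefined"; icer <- NA_real_
  } else if (dc < 0 && dq > 0) {
    label <- "dominates"; icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    label <- "dominated"; icer <- NA_real_
  } else {
    label <- "icer"; icer <- dc / dq
  }
  structure(list(ablation = ablation, aad = aad,
                 delta_cost = dc, delta_qaly = dq, delta_strokes = ds,
                 icer = icer, label = label),
            class = "af_cea")
}

#' Cost-effectiveness analysis of ablation versus antiarrhythmic drugs
#'
#' The package's central function: runs both treatment arms of the combined
#' decision-tree/Markov model deterministically and returns the incremental
#' comparison.
#'
#' @param profile an [af_profile()] cohort description.
#' @param ps an [af_parameters()] parameter set.
#' @param fixtures an [af_fixtures()] bundle of external tables.
#' @return an object of class `af_cea` (see [compare_strategies()]), with
#'   the full per-arm results attached.
#' @export
#' @examples
#' \donttest{
#' fit <- af_cea()
#' fit
#' summary(fit)
#' }
af_cea <- function(profile = af_profile(), ps = af_parameters(),
                   fixtures = af_fixtures()) {
  abl <- run_strategy("ablation", ps, profile, fixtures)
  aad <- run_strategy("aad", ps, profile, fixtures)
  out <- compare_strategies(abl, aad)
  out$ps <- ps
  out$profile <- profile
  out
}

format_icer <- function(x) {
  if (x$label == "icer") {
    paste0("$", format(round(x$icer), big.mark = ","), "/QALY")
  } else if (x$label == "dominates") {
    "AF ablation dominates"
  } else if (x$label == "dominated") {
    "AF ablation dominated"
  } else "undefined"
}

#' @export
print.af_cea <- function(x, ...) {
  cat("Cost-effectiveness of catheter ablation vs antiarrhythmic drugs\n")
  fmt <- function(r) sprintf("  %-10s $%-9s %8.3f %10.3f",
                             r$strategy,
                             format(round(r$expected_cost), big.mark = ","),
                             r$expected_strokes, r$expected_qaly)
  cat("             cost       strokes      QALYs\n")
  cat(fmt(x$ablation), "\n")
  cat(fmt(x$aad), "\n")
  cat(sprintf("  increment  $%-9s %8.3f %10.3f   %s\n",
              format(round(x$delta_cost), big.mark = ","),
              x$delta_strokes, x$delta_qaly, format_icer(x)))
  invisible(x)
}

#' @export
summary.af_cea <- function(object, ...) {
  x <- object
  out <- data.frame(
    strategy = c("ablation", "aad", "incremental"),
    expected_cost = c(x$ablation$expected_cost, x$aad$expected_cost,
                      x$delta_cost),
    expected_strokes = c(x$ablation$expected_strokes,
                         x$aad$expected_strokes, x$delta_strokes),
    expected_qaly = c(x$ablation$expected_qaly, x$aad$expected_qaly,
                      x$delta_qaly),
    icer = c(NA, NA, x$icer),
    stringsAsFactors = FALSE)
  attr(out, "label") <- x$label
  class(out) <- c("summary.af_cea", "data.frame")
  out
}

#' @export
print.summary.af_cea <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 6)
  if (attr(x, "label") != "icer") {
    cat("decision:", attr(x, "label"), "\n")
  }
  invisible(x)
}
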