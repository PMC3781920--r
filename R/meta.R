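#' Trial arms used to estimate 12-month sinus rhythm on antiarrhythmic drugs
#'
#' The five randomised-trial antiarrhythmic-drug arms (patients and number in
#' normal sinus rhythm at 12 months) pooled by the model, shipped as a
#' delimited fixture under `inst/extdata/aad_nsr_trials.tsv`.
#'
#' @param path optional path to a tab-delimited file with columns `label`,
#'   `n`, `events`; defaults to the shipped table.
#' @return a data frame with columns `label`, `n`, `events`.
#' @export
#' @examples
#' af_trials()
af_trials <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aad_nsr_trials.tsv", package = "afcea",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "n", "events") %in% names(tab))) {
    stop("trial table must have columns label, n, events", call. = FALSE)
  }
  validate_study_arms(tab)
  tab
}

validate_study_arms <- function(studies) {
  if (nrow(studies) < 1) stop("at least one study required", call. = FALSE)
  if (any(studies$n <= 0)) stop("study n must be > 0", call. = FALSE)
  if (any(studies$events < 0 | studies$events > studies$n)) {
    stop("events must lie in [0, n]", call. = FALSE)
  }
  invisible(studies)
}

#' DerSimonian-Laird random-effects pooling of proportions
#'
#' Pools study proportions on the untransformed scale with binomial
#' within-study variance \eqn{p(1-p)/n}, the scale that reproduces both the
#' published pooled estimate and the published per-study weights. The
#' between-study variance \eqn{\tau^2} is the DerSimonian-Laird moment
#' estimator; the 95 percent interval is the normal approximation. Boundary event
#' counts (0 or n) are handled with the continuity rule
#' \eqn{p = (events + 0.5) / (n + 1)} so the binomial variance is positive.
#'
#' @param studies data frame with columns `n` and `events` (and optionally
#'   `label`), one row per study arm.
#' @return an object of class `af_pooled`: a list with `estimate`, `ci_low`,
#'   `ci_high`, `se`, `tau2`, `weights` (normalised random-effects weights)
#'   and the per-study inputs.
#' @export
#' @examples
#' pool_proportions(af_trials())
pool_proportions <- function(studies) {
  validate_study_arms(studies)
  n <- studies$n
  ev <- studies$events
  boundary <- ev == 0 | ev == n
  p <- ifelse(boundary, (ev + 0.5) / (n + 1), ev / n)
  v <- p * (1 - p) / n
  k <- length(p)
  if (k == 1) {
    est <- p
    se <- sqrt(v)
    tau2 <- 0
    w_re <- 1
  } else {
    w <- 1 / v
    p_fe <- sum(w * p) / sum(w)
    Q <- sum(w * (p - p_fe)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (v + tau2)
    est <- sum(w_star * p) / sum(w_star)
    se <- sqrt(1 / sum(w_star))
    w_re <- w_star / sum(w_star)
  }
  structure(list(estimate = est,
                 ci_low = est - stats::qnorm(0.975) * se,
                 ci_high = est + stats::qnorm(0.975) * se,
                 se = se, tau2 = tau2, weights = w_re,
                 k = k, p = p, v = v,
                 label = if (is.null(studies$label)) NULL else studies$label),
            class = "af_pooled")
}

#' @export
print.af_pooled <- function(x, ...) {
  cat(sprintf("Random-effects pooled proportion: %.3f (95%% CI %.3f, %.3f)\n",
              x$estimate, x$ci_low, x$ci_high))
  cat(sprintf("  k = %d studies, tau^2 = %.5f\n", x$k, x$tau2))
  lab <- if (is.null(x$label)) paste0("study ", seq_len(x$k)) else x$label
  for (i in seq_len(x$k)) {
    cat(sprintf("  %-28s p = %.3f  weight = %.1f%%\n", lab[i], x$p[i],
                100 * x$weights[i]))
  }
  invisible(x)
}
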