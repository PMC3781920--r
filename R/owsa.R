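#' Scenario specification for one-way sensitivity analysis
#'
#' A scenario is a named patch against the basecase: parameter overrides
#' (any [af_parameters()] field) and/or cohort-profile overrides (any
#' [af_profile()] field). Unknown fields are rejected with the list of valid
#' ones.
#'
#' @param name scenario label.
#' @param params named list of parameter overrides.
#' @param profile named list of profile overrides.
#' @return an object of class `af_scenario`.
#' @export
#' @examples
#' scenario("no stroke benefit of NSR", params = list(rr_stroke_af_vs_nsr = 1))
scenario <- function(name, params = list(), profile = list()) {
  stopifnot(is.character(name), length(name) == 1)
  valid_ps <- names(unclass(af_parameters()))
  valid_prof <- c("start_age", "sex", "chads2", "prop_warfarin")
  bad <- setdiff(names(params), valid_ps)
  if (length(bad)) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         "\nvalid fields: ", paste(valid_ps, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(names(profile), valid_prof)
  if (length(bad)) {
    stop("unknown profile override(s): ", paste(bad, collapse = ", "),
         "\nvalid fields: ", paste(valid_prof, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, params = params, profile = profile),
            class = "af_scenario")
}

#' Built-in one-way sensitivity scenarios
#'
#' The published sensitivity grid: starting ages 55-75 by sex (with the
#' stroke risk held at its CHADS2 value for every age), CHADS2 scores 0-4,
#' time horizons of 3/5/10/20 years, discount rates of 0, 3 and 5 percent, the
#' no-stroke-benefit-of-sinus-rhythm assumption, the AF-disutility grid
#' 0-0.08, the post-ablation recurrence grid 0-0.05, and discontinuation of
#' amiodarone for patients out of sinus rhythm.
#'
#' @return a list of [scenario()] objects (first entry is the basecase).
#' @export
builtin_scenarios <- function() {
  sc <- list(scenario("basecase"))
  for (sex in c("male", "female")) {
    for (age in c(55, 60, 65, 70, 75)) {
      sc <- c(sc, list(scenario(sprintf("age %d, %s", age, sex),
                                profile = list(start_age = age, sex = sex))))
    }
  }
  for (s in 0:4) {
    sc <- c(sc, list(scenario(sprintf("CHADS2 = %d", s),
                              profile = list(chads2 = s))))
  }
  for (h in c(3, 5, 10, 20)) {
    sc <- c(sc, list(scenario(sprintf("horizon %d years", h),
                              params = list(horizon = h))))
  }
  for (d in c(0, 0.03, 0.05)) {
    sc <- c(sc, list(scenario(sprintf("discount rate %g%%", 100 * d),
                              params = list(discount_rate = d))))
  }
  sc <- c(sc, list(scenario("no stroke benefit of NSR",
                            params = list(rr_stroke_af_vs_nsr = 1))))
  for (u in c(0, 0.02, 0.04, 0.06, 0.08)) {
    sc <- c(sc, list(scenario(sprintf("AF disutility %g", u),
                              params = list(disutility_af = u))))
  }
  for (p in seq(0, 0.05, by = 0.01)) {
    sc <- c(sc, list(scenario(sprintf("ablation recurrence %g", p),
                              params = list(p_recur_ablation = p))))
  }
  sc <- c(sc, list(scenario("amiodarone stopped in AF",
                            params = list(amiodarone_stop_in_af = TRUE))))
  sc
}

#' Run a list of sensitivity scenarios
#'
#' Deterministically re-runs both treatment arms for each scenario patch and
#' tabulates incremental cost, QALYs, strokes and the cost-effectiveness
#' ratio (or dominance label).
#'
#' @param specs list of [scenario()] objects (default
#'   [builtin_scenarios()]). Duplicate scenario names are an error.
#' @param ps basecase [af_parameters()].
#' @param profile basecase [af_profile()].
#' @param fixtures an [af_fixtures()] bundle.
#' @return a data frame of class `af_owsa` with one row per scenario:
#'   `name`, `delta_cost`, `delta_qaly`, `delta_strokes`, `icer`, `label`.
#' @export
run_scenarios <- function(specs = builtin_scenarios(), ps = af_parameters(),
                          profile = af_profile(),
                          fixtures = af_fixtures()) {
  stopifnot(is.list(specs))
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate scenario names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(specs, function(s) {
    psi <- unclass(ps)
    psi[names(s$params)] <- s$params
    psi$cost_ablation_total_per_procedure <- NULL
    psi <- do.call(af_parameters, psi)
    prof <- unclass(profile)
    prof[names(s$profile)] <- s$profile
    prof <- do.call(af_profile, prof)
    fit <- af_cea(prof, psi, fixtures)
    data.frame(name = s$name, delta_cost = fit$delta_cost,
               delta_qaly = fit$delta_qaly,
               delta_strokes = fit$delta_strokes,
               icer = fit$icer, label = fit$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("af_owsa", "data.frame")
  out
}

#' @export
print.af_owsa <- function(x, ...) {
  y <- x
  y$icer <- ifelse(y$label == "icer",
                   paste0("$", format(round(y$icer), big.mark = ",")),
                   y$label)
  y$label <- NULL
  y$delta_cost <- round(y$delta_cost)
  y$delta_qaly <- round(y$delta_qaly, 3)
  y$delta_strokes <- round(y$delta_strokes, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
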