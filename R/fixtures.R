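#' Synthetic stand-in tables for unpublished external inputs
#'
#' The model consumes three external tables that the published analysis drew
#' from national statistics and registry studies but did not print: an
#' age/sex life table, age/sex 28-to-30-day case fatality after ischemic
#' stroke and intracranial haemorrhage, and age/sex general-population
#' utilities. These generators produce deterministic parametric stand-ins
#' with the statistical structure the model assumes (monotone mortality in
#' age, non-increasing utility in age, event mortality anchored to published
#' cohort-level figures). They are synthetic fixtures, not the source data;
#' real tables in the same `age, sex, value` delimited schema can be dropped
#' in via the `read_*` functions.
#'
#' `make_life_table()` uses a Gompertz-Makeham hazard
#' \eqn{\mu(age) = c + a e^{b \cdot age}}, with the female hazard scaled by
#' `sex_gap`. The defaults are tuned so a 65-year-old male has an annual
#' death probability of about 0.015 and five-year survival of about 0.92.
#'
#' @param a Makeham level of the senescent hazard component (>= 0).
#' @param b Gompertz slope per year of age (>= 0).
#' @param c age-independent background hazard (>= 0).
#' @param sex_gap female/male hazard ratio.
#' @param ages integer vector of single-year ages covered by the table.
#' @return `make_life_table()`: a data frame of class `af_life_table` with
#'   columns `age`, `sex`, `value` (annual all-cause death probability).
#' @export
#' @examples
#' lt <- make_life_table()
#' subset(lt, age == 65)
make_life_table <- function(a = 4.21e-5, b = 0.09, c = 5e-4,
                            sex_gap = 0.65, ages = 18:110) {
  stopifnot(a >= 0, b >= 0, c >= 0, sex_gap >= 0)
  grid <- expand.grid(age = ages, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  hazard <- (c + a * exp(b * grid$age)) *
    ifelse(grid$sex == "female", sex_gap, 1)
  p <- 1 - exp(-hazard)
  if (any(p > 1)) {
    warning("life-table probabilities clamped to 1")
    p <- pmin(p, 1)
  }
  structure(data.frame(grid, value = p), class = c("af_life_table",
                                                   "data.frame"))
}

#' @rdname make_life_table
#' @param base_28d named probabilities `c(ischemic = ..., ich = ...)`: the
#'   short-term (28-to-30-day) case fatality for the model's reference
#'   cohort. Defaults anchor ischemic-stroke 30-day mortality at 0.189 and
#'   ICH 30-day mortality at 0.48, the published cohort-level figures.
#' @param age_slope per-year log-odds increase of case fatality with age.
#' @param ref_age age at which the table equals `base_28d`.
#' @return `make_event_mortality_table()`: a data frame of class
#'   `af_event_mortality` with columns `age`, `sex`, `event`
#'   (`"ischemic"`/`"ich"`), `value` (28-to-30-day death probability).
#' @export
make_event_mortality_table <- function(base_28d = c(ischemic = 0.189,
                                                    ich = 0.48),
                                       age_slope = 0.03, ref_age = 67.5,
                                       ages = 18:110) {
  stopifnot(all(base_28d >= 0 & base_28d <= 1),
            all(c("ischemic", "ich") %in% names(base_28d)))
  grid <- expand.grid(age = ages, sex = c("male", "female"),
                      event = c("ischemic", "ich"),
                      stringsAsFactors = FALSE)
  base <- base_28d[grid$event]
  p <- ifelse(base == 0, 0,
              stats::plogis(stats::qlogis(pmin(pmax(base, 1e-12), 1 - 1e-12)) +
                            age_slope * (grid$age - ref_age)))
  p[base == 1] <- 1
  structure(data.frame(grid, value = p, row.names = NULL),
            class = c("af_event_mortality", "data.frame"))
}

#' @rdname make_life_table
#' @param u65 general-population utility at age 65.
#' @param slope_per_decade utility decline per decade of age.
#' @return `make_utility_table()`: a data frame of class `af_utility_table`
#'   with columns `age`, `sex`, `value` (utility weight), linear in age and
#'   clamped to `[0, 1]`.
#' @export
make_utility_table <- function(u65 = 0.83, slope_per_decade = 0.03,
                               ages = 18:110) {
  stopifnot(u65 >= 0, u65 <= 1)
  grid <- expand.grid(age = ages, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  u <- pmin(pmax(u65 - slope_per_decade / 10 * (grid$age - 65), 0), 1)
  structure(data.frame(grid, value = u), class = c("af_utility_table",
                                                   "data.frame"))
}

#' Bundle the three external tables used by the cohort engine
#'
#' @param life_table an `af_life_table` (default: [make_life_table()]).
#' @param event_mortality an `af_event_mortality`
#'   (default: [make_event_mortality_table()]).
#' @param utility an `af_utility_table` (default: [make_utility_table()]).
#' @return an object of class `af_fixtures`.
#' @export
af_fixtures <- function(life_table = make_life_table(),
                        event_mortality = make_event_mortality_table(),
                        utility = make_utility_table()) {
  structure(list(life_table = life_table,
                 event_mortality = event_mortality,
                 utility = utility),
            class = "af_fixtures")
}

#' @export
print.af_fixtures <- function(x, ...) {
  cat("External tables (life table, event mortality, population utility)\n")
  cat(sprintf("  ages %d-%d; annual mortality at 65 (male): %.4f; utility at 65: %.3f\n",
              min(x$life_table$age), max(x$life_table$age),
              lookup_value(x$life_table, 65, "male"),
              lookup_value(x$utility, 65, "male")))
  invisible(x)
}

# age/sex (and optionally event) lookup with clamping to the table's range
lookup_value <- function(tab, age, sex, event = NULL) {
  age <- floor(age)
  age <- pmin(pmax(age, min(tab$age)), max(tab$age))
  sel <- tab$sex == sex & tab$age == age
  if (!is.null(event)) sel <- sel & tab$event == event
  v <- tab$value[sel]
  if (length(v) != 1) {
    stop(sprintf("lookup failed for age %s, sex %s%s", age, sex,
                 if (is.null(event)) "" else paste0(", event ", event)),
         call. = FALSE)
  }
  v
}

read_age_sex_table <- function(path, cls, extra_cols = character()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", extra_cols, "value")
  if (!all(need %in% names(tab))) {
    stop("table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$value < 0 | tab$value > 1)) {
    stop("values must lie in [0, 1]", call. = FALSE)
  }
  key <- do.call(paste, tab[, setdiff(need, "value"), drop = FALSE])
  if (anyDuplicated(key)) {
    stop("duplicate rows for the same age/sex combination", call. = FALSE)
  }
  structure(tab[, need], class = c(cls, "data.frame"))
}

#' Read external tables from delimited files
#'
#' Tab-delimited files with header columns `age`, `sex`, `value` (and
#' `event` for the event-mortality table; values `"ischemic"` or `"ich"`).
#' This is the drop-in path for real life tables, registry case-fatality
#' tables and population utility norms.
#'
#' @param path file path.
#' @return the corresponding table object (see [make_life_table()]).
#' @export
read_life_table <- function(path) read_age_sex_table(path, "af_life_table")

#' @rdname read_life_table
#' @export
read_event_mortality_table <- function(path) {
  read_age_sex_table(path, "af_event_mortality", "event")
}

#' @rdname read_life_table
#' @export
read_utility_table <- function(path) {
  read_age_sex_table(path, "af_utility_table")
}
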