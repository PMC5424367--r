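#' Five-year reproductive age groups
#'
#' The seven conventional 5-year age groups of the reproductive span,
#' 15-19 through 45-49. Bins are closed on the left: completed age a falls
#' in group `[15,20), [20,25), ..., [45,50)`.
#'
#' @return Character vector of the seven group labels.
#' @export
age_groups <- function() {
  c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
}

#' Map completed ages to 5-year age-group labels
#'
#' @param age Integer vector of completed ages in years.
#' @return Character vector of group labels; `NA` outside 15-49.
#' @export
age_group_of <- function(age) {
  idx <- (age - 15L) %/% 5L + 1L
  idx[age < 15L | age > 49L] <- NA_integer_
  age_groups()[idx]
}

#' Construct an age schedule
#'
#' An age schedule is a named numeric vector with one value per 5-year age
#' group 15-19 ... 45-49 (an ASFR schedule, proportions married, exposure
#' person-years, birth counts...).
#'
#' @param values Numeric vector of length 7, optionally named by age group.
#' @param kind Optional character tag carried as an attribute
#'   (`"asfr"`, `"asmfr"`, `"proportion_married"`, `"exposure"`, `"births"`).
#' @return Named numeric vector of length 7 with class `age_schedule`.
#' @export
age_schedule <- function(values, kind = NULL) {
  grps <- age_groups()
  if (!is.null(names(values))) {
    stopifnot(setequal(names(values), grps))
    values <- values[grps]
  } else {
    stopifnot(length(values) == 7L)
    names(values) <- grps
  }
  stopifnot(is.numeric(values), !anyNA(values))
  if (!is.null(kind) && kind == "proportion_married" &&
      any(values < 0 | values > 1)) {
    stop("proportions married must lie in [0, 1]")
  }
  if (!is.null(kind) && kind %in% c("exposure", "births") && any(values < 0)) {
    stop(kind, " values must be nonnegative")
  }
  structure(setNames(as.numeric(values), grps),
            kind = kind, class = "age_schedule")
}

empty_schedule <- function(kind = NULL) {
  age_schedule(rep(0, 7L), kind = kind)
}

#' @export
print.age_schedule <- function(x, ...) {
  kind <- attr(x, "kind")
  cat("<age_schedule", if (!is.null(kind)) paste0(": ", kind), ">\n", sep = "")
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Per-group ratio of two schedules (rates)
#'
#' Divides a births schedule by an exposure schedule to give rates per
#' woman-year. Groups with zero exposure yield rate 0 and are flagged with a
#' warning rather than an error, so small strata in a decomposition do not
#' abort the run.
#'
#' @param births,exposure `age_schedule`s (weighted birth counts,
#'   person-years).
#' @param kind Kind tag for the result (default `"asfr"`).
#' @return An `age_schedule` of rates; zero-exposure groups carry a
#'   `zero_exposure` attribute listing them.
#' @export
rate_schedule <- function(births, exposure, kind = "asfr") {
  stopifnot(length(births) == 7L, length(exposure) == 7L)
  zero <- as.numeric(exposure) == 0
  r <- ifelse(zero, 0, as.numeric(births) / as.numeric(exposure))
  if (any(zero)) {
    warning("zero exposure in age group(s) ",
            paste(age_groups()[zero], collapse = ", "),
            "; rate set to 0 there")
  }
  out <- age_schedule(r, kind = kind)
  attr(out, "zero_exposure") <- age_groups()[zero]
  out
}

#' Total rate over the reproductive span
#'
#' Sums a rate schedule across the seven age groups and multiplies by 5
#' (years per group): applied to an ASFR schedule this is the total
#' fertility rate (TFR), to an ASMFR schedule the total marital fertility
#' rate (TMFR).
#'
#' @param schedule An `age_schedule` of rates.
#' @return Nonnegative scalar.
#' @export
total_rate <- function(schedule) {
  stopifnot(length(schedule) == 7L)
  5 * sum(as.numeric(schedule))
}

#' Export a schedule as a data frame
#'
#' @param schedule An `age_schedule`.
#' @return Data frame with `age_group`, `value` and a logical `flag` column
#'   marking zero-exposure groups (if the schedule carries that attribute).
#' @export
schedule_to_df <- function(schedule) {
  flagged <- attr(schedule, "zero_exposure")
  data.frame(age_group = names(schedule),
             value = as.numeric(schedule),
             flag = names(schedule) %in% (flagged %||% character()),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
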