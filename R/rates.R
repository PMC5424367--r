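#' Person-years of exposure by age group
#'
#' For each woman, each of the `window_months` months m in
#' `[interview_cm - window_months, interview_cm - 1]` contributes
#' `weight / 12` person-years to the age group of her completed age in
#' month m (`floor((m - dob_cm)/12)` years). Months at completed ages
#' below 15 or above 49 are dropped.
#'
#' @param women Validated women's data frame.
#' @param window_months Reference window length in months (>= 1).
#' @return An `age_schedule` of weighted person-years.
#' @export
exposure_by_age <- function(women, window_months = 36L) {
  stopifnot(window_months >= 1L)
  if (nrow(women) == 0L) {
    warning("empty input: all-zero exposure schedule")
    return(empty_schedule("exposure"))
  }
  age_months_now <- women$interview_cm - women$dob_cm
  acc <- rep(0, 7L)
  for (k in seq_len(window_months)) {        # month interview_cm - k
    age <- (age_months_now - k) %/% 12L
    keep <- age >= 15L & age <= 49L
    if (!any(keep)) next
    grp <- (age[keep] - 15L) %/% 5L + 1L
    acc <- acc + vapply(seq_len(7L),
                        function(g) sum(women$weight[keep][grp == g]),
                        numeric(1)) / 12
  }
  age_schedule(acc, kind = "exposure")
}

#' Weighted births by age group of mother at birth
#'
#' Counts births with `1 <= interview_cm - birth_cm <= window_months`,
#' attributed to the mother's completed-age group in the birth month. With
#' `married_only = TRUE` only births to currently married women count --
#' the standard current-status approximation to marital fertility when no
#' marriage histories are collected (a known bias: births to women who
#' married or separated within the window are misclassified).
#'
#' @inheritParams exposure_by_age
#' @param married_only Restrict to currently married mothers.
#' @return An `age_schedule` of weighted birth counts.
#' @export
births_by_age <- function(women, window_months = 36L, married_only = FALSE) {
  stopifnot(window_months >= 1L)
  acc <- rep(0, 7L)
  rows <- seq_len(nrow(women))
  if (married_only) rows <- rows[women$marital_status == "married"]
  for (i in rows) {
    b <- women$births[[i]]
    if (!length(b)) next
    lag <- women$interview_cm[i] - b
    b <- b[lag >= 1L & lag <= window_months]
    if (!length(b)) next
    age <- (b - women$dob_cm[i]) %/% 12L
    age <- age[age >= 15L & age <= 49L]
    if (!length(age)) next
    grp <- (age - 15L) %/% 5L + 1L
    for (g in grp) acc[g] <- acc[g] + women$weight[i]
  }
  age_schedule(acc, kind = "births")
}

#' Weighted proportion currently married by age group
#'
#' m(a): weighted number of currently married women over weighted number of
#' all women, per 5-year age group at interview. Empty groups yield 0 with
#' a warning.
#'
#' @param women Validated women's data frame.
#' @return An `age_schedule` of proportions in `[0, 1]`.
#' @export
proportion_married_by_age <- function(women) {
  age <- age_at_interview(women)
  grp <- (age - 15L) %/% 5L + 1L
  num <- den <- rep(0, 7L)
  for (g in seq_len(7L)) {
    sel <- grp == g
    den[g] <- sum(women$weight[sel])
    num[g] <- sum(women$weight[sel & women$marital_status == "married"])
  }
  if (any(den == 0)) {
    warning("no women in age group(s) ",
            paste(age_groups()[den == 0], collapse = ", "),
            "; proportion married set to 0 there")
  }
  age_schedule(ifelse(den == 0, 0, num / den), kind = "proportion_married")
}

#' Fertility-rate schedules and their totals
#'
#' Computes the age-specific fertility rate schedule (ASFR, all women), the
#' age-specific marital fertility rate schedule (ASMFR, births to currently
#' married women over married women's exposure), the proportions currently
#' married m(a), and the totals TFR = 5 * sum(ASFR) and TMFR = 5 * sum(ASMFR).
#'
#' @inheritParams exposure_by_age
#' @return A list of class `rate_set` with elements `asfr`, `asmfr`,
#'   `prop_married`, `tfr`, `tmfr` plus the underlying `births`/`exposure`
#'   schedules.
#' @export
rate_set <- function(women, window_months = 36L) {
  exp_all <- exposure_by_age(women, window_months)
  married <- women[women$marital_status == "married", , drop = FALSE]
  exp_mar <- suppressWarnings(exposure_by_age(married, window_months))
  b_all <- births_by_age(women, window_months, married_only = FALSE)
  b_mar <- births_by_age(women, window_months, married_only = TRUE)
  asfr <- rate_schedule(b_all, exp_all, kind = "asfr")
  asmfr <- rate_schedule(b_mar, exp_mar, kind = "asmfr")
  structure(list(asfr = asfr, asmfr = asmfr,
                 prop_married = proportion_married_by_age(women),
                 tfr = total_rate(asfr), tmfr = total_rate(asmfr),
                 births = b_all, births_married = b_mar,
                 exposure = exp_all, exposure_married = exp_mar),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>  TFR =", format(x$tfr, digits = 4),
      " TMFR =", format(x$tmfr, digits = 4), "\n")
  m <- rbind(asfr = as.numeric(x$asfr), asmfr = as.numeric(x$asmfr),
             prop_married = as.numeric(x$prop_married))
  colnames(m) <- age_groups()
  print(round(m, 4))
  invisible(x)
}
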