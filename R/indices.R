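#' Index of marriage (Cm)
#'
#' Quantifies the fertility-inhibiting effect of non-marriage. The default
#' estimator is the weighted-sum formula
#' `Cm = sum(m(a) g(a)) / sum(g(a))`, where m(a) are the age-specific
#' proportions currently married and g(a) the age-specific marital
#' fertility rates: g(a) weights the married proportions by where marital
#' fertility is concentrated, so married women in the central childbearing
#' ages count more. The alternative is the ratio of the total fertility
#' rate to the total marital fertility rate, `TFR/TMFR`; the two agree
#' exactly when all fertility is marital (`f(a) = m(a) g(a)`) and can
#' differ when nonmarital childbearing exists.
#'
#' @param prop_married `age_schedule` of proportions currently married, m(a).
#' @param asmfr `age_schedule` of marital fertility rates, g(a).
#' @param method `"formula"` (default) or `"ratio"`.
#' @param rates A `rate_set` (required for `method = "ratio"`).
#' @return Scalar Cm. Values outside `[0, 1]` are returned as-is with a
#'   warning, never clamped.
#' @export
index_marriage <- function(prop_married, asmfr,
                           method = c("formula", "ratio"), rates = NULL) {
  method <- match.arg(method)
  if (method == "formula") {
    g <- as.numeric(asmfr)
    m <- as.numeric(prop_married)
    if (sum(g) <= 0) stop("undefined index of marriage: sum of marital ",
                          "fertility rates g(a) is zero")
    cm <- sum(m * g) / sum(g)
  } else {
    if (is.null(rates)) stop("method = 'ratio' requires a rate_set")
    if (rates$tmfr <= 0) stop("undefined index of marriage: TMFR is zero")
    cm <- rates$tfr / rates$tmfr
  }
  if (cm < 0 || cm > 1) {
    warning(sprintf("index of marriage %.4f outside [0, 1]", cm))
  }
  cm
}

#' Contraceptive prevalence and mean use-effectiveness among married women
#'
#' u is the weighted share of currently married women using any method
#' (modern or traditional -- each method enters with its own
#' effectiveness); e is the weighted mean use-effectiveness over current
#' users' methods. When no married woman uses contraception, `e = 0` by
#' convention.
#'
#' @param women Validated women's data frame.
#' @param effectiveness Named method -> effectiveness table.
#' @return List with elements `u` and `e`, both in `[0, 1]`.
#' @export
contraceptive_summary <- function(women,
                                  effectiveness = default_effectiveness()) {
  mar <- women[women$marital_status == "married", , drop = FALSE]
  if (nrow(mar) == 0L || sum(mar$weight) == 0) {
    stop("undefined contraceptive summary: no married women")
  }
  using <- mar$current_method != "none"
  u <- sum(mar$weight[using]) / sum(mar$weight)
  if (u == 0) return(list(u = 0, e = 0))
  meth <- mar$current_method[using]
  unknown <- setdiff(unique(meth), names(effectiveness))
  if (length(unknown)) stop("no effectiveness value for method(s): ",
                            paste(unknown, collapse = ", "))
  e <- weighted.mean(effectiveness[meth], mar$weight[using])
  list(u = u, e = e)
}

#' Index of contraception (Cc)
#'
#' `Cc = 1 - correction * u * e` with the standard sterility correction
#' 1.08 (married non-users include women who know themselves sterile, so
#' observed prevalence understates use among the fecund). Equals 1 when no
#' contraception is used, and falls towards 0 as prevalence and
#' effectiveness rise.
#'
#' @param u Prevalence of any-method use among married women, in `[0, 1]`.
#' @param e Mean use-effectiveness among users, in `[0, 1]`.
#' @param sterility_correction Positive multiplier (default 1.08).
#' @return Scalar Cc in `[0, 1)`; a negative result (possible only when
#'   `correction * u * e > 1`) is a domain error.
#' @export
index_contraception <- function(u, e, sterility_correction = 1.08) {
  stopifnot(u >= 0, u <= 1, e >= 0, e <= 1, sterility_correction > 0)
  cc <- 1 - sterility_correction * u * e
  if (cc < 0) {
    stop(sprintf(
      "index of contraception is negative (%.4f): u = %.3f, e = %.3f are inconsistent with correction %.2f",
      cc, u, e, sterility_correction))
  }
  cc
}

#' Mean duration of postpartum insusceptibility (i), in months
#'
#' The default is the current-status (prevalence/incidence) estimator:
#' the weighted number of women currently postpartum insusceptible
#' (amenorrheic or abstaining) divided by the mean weighted number of
#' births per month over the reference window. Under a stationary birth
#' process the expected number of women in a state equals the entry rate
#' times its mean duration, so the ratio estimates mean duration in
#' months. The alternative averages reported completed durations (column
#' `insusc_duration`, months), when collected.
#'
#' @param women Validated women's data frame.
#' @param window_months Reference window (>= 12) for the incidence
#'   denominator.
#' @param estimator `"prevalence_incidence"` (default) or
#'   `"reported_duration"`.
#' @return Scalar i >= 0, in months.
#' @export
mean_insusceptibility <- function(women, window_months = 36L,
                                  estimator = c("prevalence_incidence",
                                                "reported_duration")) {
  estimator <- match.arg(estimator)
  if (estimator == "reported_duration") {
    if (is.null(women$insusc_duration)) {
      stop("reported_duration estimator requires an insusc_duration column")
    }
    ok <- !is.na(women$insusc_duration)
    if (!any(ok)) stop("no reported insusceptibility durations")
    return(weighted.mean(women$insusc_duration[ok], women$weight[ok]))
  }
  stopifnot(window_months >= 12L)
  births_w <- sum(as.numeric(births_by_age(women, window_months)))
  if (births_w <= 0) {
    stop("undefined mean insusceptibility: no births in the reference window")
  }
  prevalence <- sum(women$weight[women$insusceptible_now])
  prevalence / (births_w / window_months)
}

#' Index of postpartum infecundability (Ci)
#'
#' `Ci = 20 / (18.5 + i)` with i the mean months of postpartum
#' insusceptibility. Without breastfeeding or postpartum abstinence the
#' average birth interval is about 20 months (1.5 months minimum postpartum
#' anovulation + 7.5 months waiting time to conception + 2 months added by
#' intrauterine mortality + 9 months gestation); with them it is 18.5 + i,
#' so the ratio measures the interval lengthening. `i < 1.5` yields a value
#' above 1, which is reported with a warning rather than clamped --
#' surfacing data problems beats masking them.
#'
#' @param i Mean postpartum insusceptibility, months (>= 0).
#' @return Scalar Ci.
#' @export
index_postpartum <- function(i) {
  if (i < 0) stop("mean insusceptibility i must be >= 0")
  ci <- 20 / (18.5 + i)
  if (ci > 1) {
    warning(sprintf("index of postpartum infecundability %.4f > 1 (i = %.2f < 1.5 months)",
                    ci, i))
  }
  ci
}

#' Index of abortion (Ca)
#'
#' `Ca = TFR / (TFR + b * TA)` with `b = 0.4 (1 + u)` the births averted
#' per induced abortion (0.4 for non-users, 0.8 for perfectly prevalent
#' use, since contracepting women who abort avert less exposure). `Ca = 1`
#' when the total abortion rate TA is 0.
#'
#' @param tfr Total fertility rate (>= 0).
#' @param ta Total abortion rate (>= 0).
#' @param u Contraceptive prevalence among married women, in `[0, 1]`.
#' @return Scalar Ca in `[0, 1]`.
#' @export
index_abortion <- function(tfr, ta, u) {
  stopifnot(tfr >= 0, ta >= 0, u >= 0, u <= 1)
  if (ta == 0) {
    if (tfr == 0) warning("index of abortion is vacuous: TFR = TA = 0")
    return(1)
  }
  if (tfr == 0) return(0)
  b <- 0.4 * (1 + u)
  tfr / (tfr + b * ta)
}

#' Predicted total fertility rate
#'
#' The aggregate model: `TFR = Cm * Cc * Ci * Ca * TF`, the total fecundity
#' TF (15.3 births under continuous marriage, no contraception, no
#' breastfeeding, no abortion) scaled down multiplicatively by the four
#' indices.
#'
#' @param cm,cc,ci,ca The four indices (>= 0).
#' @param tf Total fecundity (default 15.3).
#' @return Scalar predicted TFR.
#' @export
predicted_tfr <- function(cm, cc, ci, ca, tf = 15.3) {
  stopifnot(cm >= 0, cc >= 0, ci >= 0, ca >= 0, tf >= 0)
  cm * cc * ci * ca * tf
}

#' Fit the full set of proximate-determinant indices
#'
#' Runs the whole estimation pipeline on one population: fertility-rate
#' schedules, Cm (per `config$cm_method`), the contraceptive summary (u, e)
#' and Cc, the mean insusceptibility i and Ci, Ca from `config$ta`, and the
#' predicted TFR `Cm*Cc*Ci*Ca*tf` alongside the observed (birth-history)
#' TFR. All warnings raised along the way are collected into the result.
#'
#' @param women Validated women's data frame.
#' @param config An `analysis_config`.
#' @return A list of class `index_set`: `u, e, i, ta, cm, cc, ci, ca, tf,
#'   tfr_observed, tfr_predicted, n_unweighted, n_weighted, warnings`.
#' @export
fit_index_set <- function(women, config = analysis_config()) {
  if (nrow(women) == 0L) stop("cannot fit indices on an empty table")
  warns <- character(0)
  capture <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  rates <- capture(rate_set(women, config$window_months))
  cm <- capture(index_marriage(rates$prop_married, rates$asmfr,
                               method = config$cm_method, rates = rates))
  ue <- contraceptive_summary(women, config$effectiveness)
  cc <- index_contraception(ue$u, ue$e, config$sterility_correction)
  i <- capture(mean_insusceptibility(women, config$window_months,
                                     config$i_estimator))
  ci <- capture(index_postpartum(i))
  ca <- capture(index_abortion(rates$tfr, config$ta, ue$u))
  structure(list(u = ue$u, e = ue$e, i = i, ta = config$ta,
                 cm = cm, cc = cc, ci = ci, ca = ca, tf = config$tf,
                 tfr_observed = rates$tfr,
                 tfr_predicted = predicted_tfr(cm, cc, ci, ca, config$tf),
                 n_unweighted = nrow(women), n_weighted = sum(women$weight),
                 rates = rates, warnings = warns),
            class = "index_set")
}

#' Flatten an index set to a one-row data frame
#'
#' @param x An `index_set`.
#' @return One-row data frame with the scalar fields and a collapsed
#'   `warnings` string.
#' @export
index_set_row <- function(x) {
  data.frame(u = x$u, e = x$e, i = x$i, ta = x$ta,
             cm = x$cm, cc = x$cc, ci = x$ci, ca = x$ca, tf = x$tf,
             tfr_observed = x$tfr_observed, tfr_predicted = x$tfr_predicted,
             n_unweighted = x$n_unweighted, n_weighted = x$n_weighted,
             warnings = paste(x$warnings, collapse = " | "))
}

#' @export
print.index_set <- function(x, ...) {
  cat("<index_set>  n =", x$n_unweighted,
      sprintf("(weighted %.1f)\n", x$n_weighted))
  cat(sprintf("  u = %.4f  e = %.4f  i = %.2f mo  TA = %.2f\n",
              x$u, x$e, x$i, x$ta))
  cat(sprintf("  Cm = %.6f  Cc = %.6f  Ci = %.6f  Ca = %.6f\n",
              x$cm, x$cc, x$ci, x$ca))
  cat(sprintf("  TFR observed = %.2f   predicted = %.2f  (TF = %.1f)\n",
              x$tfr_observed, x$tfr_predicted, x$tf))
  if (length(x$warnings)) {
    cat("  warnings:", paste(unique(x$warnings), collapse = "; "), "\n")
  }
  invisible(x)
}
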