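#' Parameters of the synthetic survey cohort
#'
#' Defines a seeded monthly microsimulation of a DHS-style women's sample
#' whose true proximate-determinant parameters are known. The defaults
#' emulate a high-fertility East African survey population: the age
#' distribution and per-age-group proportions currently married
#' approximate the Uganda 2011 DHS women's sample (overall about 62%
#' currently married), any-method contraceptive prevalence among married
#' women 0.30, an injection-heavy method mix, mean postpartum
#' insusceptibility 11.5 months, and monthly fecundability 0.2 for exposed
#' non-users.
#'
#' @param n_women Number of women to simulate.
#' @param seed Integer RNG seed; output is deterministic in (seed, params).
#' @param interview_cm Interview month index (all women interviewed in the
#'   same month).
#' @param age_distribution Probabilities over the seven age groups 15-19
#'   ... 45-49.
#' @param marriage_schedule Per-age-group probability of being currently
#'   married (the target m(a)).
#' @param u_true Probability a married woman currently uses any method.
#' @param method_mix Probabilities over methods given use (named).
#' @param effectiveness Method -> use-effectiveness table; acts
#'   multiplicatively on fecundability (conception probability while using
#'   method m is `fecundability * (1 - e_m)`).
#' @param fecundability Monthly conception probability for exposed
#'   non-users, in `[0, 1]`.
#' @param insusceptibility_mean Mean postpartum insusceptibility i_true in
#'   months; durations are geometric (discrete, memoryless, support 0, 1,
#'   2, ...) with this mean.
#' @param gestation_months Gestation length (9).
#' @param nonmarital_exposure_factor Multiplier on fecundability for women
#'   not currently married (0 = no nonmarital fertility; histories start at
#'   exact age 15 with no premarital exposure unless this is positive).
#' @param stratifiers Named list describing categorical stratifiers: each
#'   element is `list(levels =, probs =, overrides =)` where `overrides` is
#'   an optional named list (by level) of parameter overrides among
#'   `u_true`, `method_mix`, `fecundability`, `insusceptibility_mean`,
#'   `nonmarital_exposure_factor`. The default draws residence, region,
#'   education, religion and wealth quintile with marginals close to the
#'   Uganda 2011 DHS women's sample and no parameter overrides (see
#'   [default_stratifiers()]).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_women = 2000L,
                       seed = 1L,
                       interview_cm = 1345L,
                       age_distribution = c(0.236, 0.188, 0.181, 0.125,
                                            0.118, 0.084, 0.068),
                       marriage_schedule = c(0.20, 0.64, 0.79, 0.83,
                                             0.82, 0.78, 0.71),
                       u_true = 0.30,
                       method_mix = c(injection = 0.40, pill = 0.10,
                                      condom = 0.10, sterilization = 0.05,
                                      implant = 0.05, iud = 0.02,
                                      lam = 0.03, rhythm = 0.15,
                                      withdrawal = 0.07, folk = 0.03),
                       effectiveness = default_effectiveness(),
                       fecundability = 0.2,
                       insusceptibility_mean = 11.5,
                       gestation_months = 9L,
                       nonmarital_exposure_factor = 0,
                       stratifiers = default_stratifiers()) {
  p <- list(n_women = as.integer(n_women), seed = as.integer(seed),
            interview_cm = as.integer(interview_cm),
            age_distribution = age_distribution / sum(age_distribution),
            marriage_schedule = marriage_schedule,
            u_true = u_true, method_mix = method_mix / sum(method_mix),
            effectiveness = effectiveness, fecundability = fecundability,
            insusceptibility_mean = insusceptibility_mean,
            gestation_months = as.integer(gestation_months),
            nonmarital_exposure_factor = nonmarital_exposure_factor,
            stratifiers = stratifiers)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

#' Default stratifier specification
#'
#' Residence, region, education (four ingest levels), religion and wealth
#' quintile, drawn independently with category probabilities close to the
#' weighted marginals of the Uganda 2011 DHS women's sample, and no
#' per-category parameter overrides.
#'
#' @return Named list suitable for the `stratifiers` argument of
#'   [sim_params()].
#' @export
default_stratifiers <- function() {
  list(
    residence = list(levels = c("urban", "rural"),
                     probs = c(0.198, 0.802)),
    region = list(levels = c("Kampala", "Central", "Eastern", "Northern",
                             "Western"),
                  probs = c(0.097, 0.214, 0.246, 0.176, 0.267)),
    education = list(levels = c("none", "primary", "secondary", "higher"),
                     probs = c(0.129, 0.594, 0.225, 0.052)),
    religion = list(levels = c("Catholic", "Protestant", "Muslim", "Other"),
                    probs = c(0.406, 0.433, 0.130, 0.031)),
    wealth_quintile = list(levels = c("poorest", "poorer", "middle",
                                      "richer", "richest"),
                           probs = c(0.175, 0.182, 0.185, 0.199, 0.259)))
}

validate_sim_params <- function(p) {
  stopifnot(p$n_women >= 1L, length(p$age_distribution) == 7L,
            length(p$marriage_schedule) == 7L)
  probs <- c(p$age_distribution, p$marriage_schedule, p$u_true,
             p$method_mix, p$fecundability, p$nonmarital_exposure_factor)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (p$insusceptibility_mean < 0) stop("insusceptibility_mean must be >= 0")
  if (p$gestation_months < 1L) stop("gestation_months must be >= 1")
  bad <- setdiff(names(p$method_mix), names(p$effectiveness))
  if (length(bad)) stop("method_mix names without effectiveness: ",
                        paste(bad, collapse = ", "))
  for (v in names(p$stratifiers)) {
    s <- p$stratifiers[[v]]
    if (length(s$levels) != length(s$probs) || any(s$probs < 0)) {
      stop("stratifier '", v, "': levels and probs must match, probs >= 0")
    }
    if (!is.null(s$overrides) &&
        length(setdiff(names(s$overrides), s$levels))) {
      stop("stratifier '", v, "': overrides name unknown levels")
    }
  }
  invisible(p)
}

# Geometric insusceptibility duration, support {0, 1, 2, ...}, given mean.
draw_insusc_months <- function(n, mean_months) {
  if (mean_months <= 0) return(rep(0L, n))
  rgeom(n, 1 / (1 + mean_months))
}

# Reproductive history of one woman from exact age 15 to the interview
# month, as an alternating exposure / gestation / insusceptibility process.
# Conception in an exposed month m (probability p per month) leads to a
# birth at m + gestation; each birth starts an insusceptible spell of
# geometric duration D occupying months [birth, birth + D - 1].
simulate_history <- function(dob_cm, interview_cm, p_conc, i_mean,
                             gestation) {
  births <- integer(0)
  insusceptible_now <- FALSE
  t <- dob_cm + 180L                        # month of exact age 15
  if (p_conc > 0) {
    while (t <= interview_cm) {
      conception <- t + rgeom(1L, p_conc)
      birth <- conception + gestation
      if (conception > interview_cm || birth > interview_cm) break
      births <- c(births, birth)
      d <- draw_insusc_months(1L, i_mean)
      insusceptible_now <- interview_cm <= birth + d - 1L
      t <- birth + max(d, 0L)
    }
  }
  list(births = births, insusceptible_now = insusceptible_now)
}

#' Simulate a synthetic survey cohort
#'
#' Draws each woman's age, stratifiers, current marital status and current
#' contraceptive method, then simulates her reproductive history month by
#' month from exact age 15 to the interview through the states exposed /
#' pregnant (`gestation_months`) / postpartum insusceptible (geometric
#' duration, mean `insusceptibility_mean`). The monthly conception
#' probability is `fecundability * (1 - e_method)` while using a method,
#' and is scaled by `nonmarital_exposure_factor` for women not currently
#' married. `insusceptible_now` is the woman's state in the interview
#' month. Output is deterministic given `(seed, params)`.
#'
#' @param params A `sim_params` object.
#' @return A validated women's data frame in the standard schema (weight 1
#'   for every woman), with stratifier columns as specified.
#' @export
simulate_cohort <- function(params = sim_params()) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_women
  grp <- sample.int(7L, n, replace = TRUE, prob = params$age_distribution)
  age_months <- (15L + 5L * (grp - 1L)) * 12L +
    sample.int(60L, n, replace = TRUE) - 1L
  dob_cm <- params$interview_cm - age_months

  strat <- list()
  for (v in names(params$stratifiers)) {
    s <- params$stratifiers[[v]]
    strat[[v]] <- sample(s$levels, n, replace = TRUE,
                         prob = s$probs / sum(s$probs))
  }

  # per-woman effective generative parameters (stratifier overrides applied
  # in declaration order, later variables winning)
  overridable <- c("u_true", "method_mix", "fecundability",
                   "insusceptibility_mean", "nonmarital_exposure_factor")
  eff_par <- function(i) {
    p <- params[overridable]
    for (v in names(params$stratifiers)) {
      ov <- params$stratifiers[[v]]$overrides[[strat[[v]][i]]]
      for (k in intersect(names(ov), overridable)) p[[k]] <- ov[[k]]
    }
    p
  }
  per_woman <- lapply(seq_len(n), eff_par)

  married <- rbinom(n, 1L, params$marriage_schedule[grp]) == 1L
  method <- rep("none", n)
  for (i in seq_len(n)) {
    pw <- per_woman[[i]]
    if (married[i] && rbinom(1L, 1L, pw$u_true) == 1L) {
      mix <- pw$method_mix / sum(pw$method_mix)
      method[i] <- sample(names(mix), 1L, prob = mix)
    }
  }

  births <- vector("list", n)
  insusc <- logical(n)
  for (i in seq_len(n)) {
    pw <- per_woman[[i]]
    e <- if (method[i] == "none") 0 else params$effectiveness[[method[i]]]
    expo <- if (married[i]) 1 else pw$nonmarital_exposure_factor
    p_conc <- pw$fecundability * (1 - e) * expo
    h <- simulate_history(dob_cm[i], params$interview_cm, p_conc,
                          pw$insusceptibility_mean, params$gestation_months)
    births[[i]] <- h$births
    insusc[i] <- h$insusceptible_now
  }

  women <- data.frame(
    woman_id = sprintf("w%05d", seq_len(n)),
    weight = 1,
    dob_cm = dob_cm,
    interview_cm = params$interview_cm,
    marital_status = ifelse(married, "married", "never_married"),
    current_method = method,
    insusceptible_now = insusc,
    stringsAsFactors = FALSE)
  for (v in names(strat)) women[[v]] <- strat[[v]]
  women$births <- births
  suppressWarnings(validate_women(women))
}

#' True index set implied by simulation parameters
#'
#' Applies the model's defining formulas to the generative parameters:
#' `Cc_true = 1 - 1.08 * u_true * e_bar` with `e_bar` the mix-weighted mean
#' effectiveness, `Ci_true = 20 / (18.5 + i_true)`, `Ca_true = 1` (the
#' generator has no induced abortion), and `Cm_true` from the weighted-sum
#' formula using the target m(a) and the marital fertility schedule g(a)
#' realised on a large reference run (returned as exactly 1 when the
#' marriage schedule is all-married, where no run is needed).
#'
#' @param params A `sim_params` object.
#' @param n_ref Reference-run size for realising g(a) (only used when some
#'   age group is not all-married).
#' @return List with `u, e, i, cm, cc, ci, ca, tf, tfr_predicted`.
#' @export
true_index_set <- function(params = sim_params(), n_ref = 10000L) {
  mix <- params$method_mix / sum(params$method_mix)
  e_bar <- sum(mix * params$effectiveness[names(mix)])
  cc <- 1 - 1.08 * params$u_true * e_bar
  ci <- 20 / (18.5 + params$insusceptibility_mean)
  if (all(params$marriage_schedule == 1)) {
    cm <- 1
  } else {
    ref <- params
    ref$n_women <- as.integer(n_ref)
    ref$seed <- params$seed + 10000L
    cohort <- simulate_cohort(ref)
    rs <- suppressWarnings(rate_set(cohort))
    cm <- suppressWarnings(index_marriage(
      age_schedule(params$marriage_schedule, "proportion_married"),
      rs$asmfr))
  }
  tf <- 15.3
  list(u = params$u_true, e = e_bar, i = params$insusceptibility_mean,
       cm = cm, cc = cc, ci = ci, ca = 1, tf = tf,
       tfr_predicted = cm * cc * ci * 1 * tf)
}
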