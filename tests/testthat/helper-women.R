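# In-code fixtures and independent brute-force oracles.

# Build a women's table from parallel vectors; births is a list of integer
# month vectors. All validation is left to the caller.
make_women <- function(age_years, marital_status = "married",
                       current_method = "none", weight = 1,
                       insusceptible_now = FALSE, births = NULL,
                       interview_cm = 1345L, age_extra_months = 0L, ...) {
  n <- length(age_years)
  dob <- interview_cm - (age_years * 12L + age_extra_months)
  w <- data.frame(
    woman_id = sprintf("t%03d", seq_len(n)),
    weight = rep_len(weight, n),
    dob_cm = as.integer(dob),
    interview_cm = as.integer(interview_cm),
    marital_status = rep_len(marital_status, n),
    current_method = rep_len(current_method, n),
    insusceptible_now = rep_len(insusceptible_now, n),
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (v in names(extra)) w[[v]] <- rep_len(extra[[v]], n)
  w$births <- if (is.null(births)) rep(list(integer()), n) else births
  w
}

# Independent per-woman per-month exposure oracle: walks every month of the
# window for every woman, one at a time.
brute_force_exposure <- function(women, window_months) {
  acc <- setNames(rep(0, 7), age_groups())
  for (i in seq_len(nrow(women))) {
    for (m in (women$interview_cm[i] - window_months):
              (women$interview_cm[i] - 1L)) {
      age <- (m - women$dob_cm[i]) %/% 12L
      if (age >= 15L && age <= 49L) {
        g <- age_group_of(age)
        acc[g] <- acc[g] + women$weight[i] / 12
      }
    }
  }
  acc
}

# Independent birth-count oracle.
brute_force_births <- function(women, window_months, married_only = FALSE) {
  acc <- setNames(rep(0, 7), age_groups())
  for (i in seq_len(nrow(women))) {
    if (married_only && women$marital_status[i] != "married") next
    for (b in women$births[[i]]) {
      lag <- women$interview_cm[i] - b
      if (lag >= 1L && lag <= window_months) {
        age <- (b - women$dob_cm[i]) %/% 12L
        if (age >= 15L && age <= 49L) {
          g <- age_group_of(age)
          acc[g] <- acc[g] + women$weight[i]
        }
      }
    }
  }
  acc
}

# A small mixed cohort used across files (deterministic).
demo_cohort <- function(n = 300, seed = 42, ...) {
  suppressWarnings(simulate_cohort(sim_params(n_women = n, seed = seed, ...)))
}
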