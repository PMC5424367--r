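test_that("index of marriage is the g-weighted mean of proportions married", {
  g <- age_schedule(c(0.1, 0.3, 0.3, 0.2, 0.1, 0.05, 0.01), "asmfr")
  expect_equal(index_marriage(age_schedule(rep(1, 7)), g), 1.0)
  expect_equal(index_marriage(age_schedule(rep(0.5, 7)), g), 0.5)

  g1 <- age_schedule(c(0, 0.3, 0, 0, 0, 0, 0), "asmfr")
  m <- age_schedule(c(0.1, 0.8, 0.9, 0.9, 0.9, 0.9, 0.9))
  expect_equal(index_marriage(m, g1), 0.8)

  expect_error(index_marriage(m, age_schedule(rep(0, 7))), "undefined")
  expect_error(index_marriage(m, g1, method = "ratio"), "rate_set")
})

test_that("formula and ratio marriage estimators agree when f = m * g", {
  set.seed(99)
  for (rep in 1:25) {
    m <- age_schedule(runif(7), "proportion_married")
    g <- age_schedule(runif(7, 0, 0.4), "asmfr")
    f <- age_schedule(as.numeric(m) * as.numeric(g), "asfr")
    rates <- list(tfr = total_rate(f), tmfr = total_rate(g))
    expect_equal(index_marriage(m, g, "formula"),
                 index_marriage(m, g, "ratio", rates = rates),
                 tolerance = 1e-9)
  }
})

test_that("contraceptive summary gives weighted any-method u and user-mean e", {
  w <- make_women(rep(25L, 4),
                  current_method = c("none", "none", "pill", "sterilization"))
  s <- contraceptive_summary(w)
  expect_equal(s$u, 0.5)
  expect_equal(s$e, 0.95)

  # weights enter both the numerator of u and the mean of e
  w$weight <- c(1, 1, 3, 1)
  s2 <- contraceptive_summary(w)
  expect_equal(s2$u, 4 / 6)
  expect_equal(s2$e, (3 * 0.90 + 1 * 1.00) / 4)

  # unmarried users never count
  w$marital_status <- c("married", "married", "never_married", "formerly_married")
  s3 <- contraceptive_summary(w)
  expect_equal(s3$u, 0)
  expect_equal(s3$e, 0)

  expect_error(contraceptive_summary(w[w$marital_status == "never_married", ]),
               "no married women")
})

test_that("index of contraception follows 1 - 1.08ue with domain checks", {
  expect_equal(index_contraception(0, 0.9), 1.0)
  expect_equal(index_contraception(0.5, 0.9), 0.514)
  expect_equal(index_contraception(0.5, 0.9, sterility_correction = 1), 0.55)
  expect_error(index_contraception(1, 1), "negative")
  expect_error(index_contraception(1.2, 0.5))
})

test_that("current-status estimator recovers mean insusceptibility", {
  # 36 births spread 1/month over the window and 8 currently insusceptible
  # women: i = 8 / (36/36) = 8
  mothers <- make_women(rep(30L, 36),
                        births = as.list(1345L - 1:36))
  extra <- make_women(rep(25L, 8), insusceptible_now = TRUE,
                      births = as.list(rep(1345L - 2L, 8)))
  w <- rbind(mothers, extra)
  w_no_recent <- w
  w_no_recent$births[37:44] <- list(integer())  # keep incidence at 36 births
  expect_equal(mean_insusceptibility(w_no_recent, 36L), 8.0)

  none <- mothers
  none$insusceptible_now <- FALSE
  expect_equal(mean_insusceptibility(none, 36L), 0)

  empty <- make_women(25L)
  expect_error(mean_insusceptibility(empty, 36L), "no births")

  # reported-duration alternative is a plain weighted mean
  rep_w <- make_women(c(25L, 30L), weight = c(1, 3),
                      insusc_duration = c(8, 12))
  expect_equal(mean_insusceptibility(rep_w, estimator = "reported_duration"),
               11)
  expect_error(mean_insusceptibility(make_women(25L),
                                     estimator = "reported_duration"),
               "insusc_duration")
})

test_that("index of postpartum infecundability is 20/(18.5 + i)", {
  expect_equal(index_postpartum(1.5), 1.0)
  expect_equal(index_postpartum(21.5), 0.5)
  expect_equal(index_postpartum(7.75), 0.761905, tolerance = 1e-6)
  expect_warning(ci <- index_postpartum(0), "> 1")
  expect_gt(ci, 1)
  expect_error(index_postpartum(-1), ">= 0")
})

test_that("index of abortion follows TFR/(TFR + 0.4(1+u)TA)", {
  expect_equal(index_abortion(6, 0, 0.3), 1.0)
  expect_equal(index_abortion(6, 1, 0.25), 6 / 6.5)
  expect_equal(index_abortion(0, 1, 0.3), 0)
  expect_warning(ca <- index_abortion(0, 0, 0), "vacuous")
  expect_equal(ca, 1.0)
})

test_that("predicted TFR is the product of the indices and total fecundity", {
  expect_equal(predicted_tfr(1, 1, 1, 1, 15.3), 15.3)
  expect_equal(predicted_tfr(0.5, 0, 0.9, 1, 15.3), 0)
  expect_equal(predicted_tfr(0.722717, 0.78179, 0.73502, 1.0, 15.3),
               6.35, tolerance = 1e-2)
})

test_that("indices are monotone in their inputs", {
  u <- seq(0.1, 0.9, by = 0.1)
  cc <- vapply(u, index_contraception, numeric(1), e = 0.8)
  expect_true(all(diff(cc) < 0))
  e <- seq(0.1, 0.9, by = 0.1)
  cce <- vapply(e, function(x) index_contraception(0.5, x), numeric(1))
  expect_true(all(diff(cce) < 0))
  i <- seq(2, 24, by = 2)
  ci <- vapply(i, index_postpartum, numeric(1))
  expect_true(all(diff(ci) < 0))
  ta <- seq(0.5, 3, by = 0.5)
  ca <- vapply(ta, function(x) index_abortion(6, x, 0.3), numeric(1))
  expect_true(all(diff(ca) < 0))
})

test_that("fit_index_set composes the pipeline and keeps its identity", {
  w <- demo_cohort(400, seed = 31)
  fit <- suppressWarnings(fit_index_set(w))
  expect_equal(fit$tfr_predicted,
               fit$cm * fit$cc * fit$ci * fit$ca * fit$tf, tolerance = 1e-15)
  expect_true(all(c(fit$cm, fit$cc, fit$ca) >= 0))
  expect_equal(fit$n_unweighted, nrow(w))

  # duplicating every record leaves every index unchanged
  w2 <- rbind(w, w)
  fit2 <- suppressWarnings(fit_index_set(w2))
  for (f in c("u", "e", "i", "cm", "cc", "ci", "ca", "tfr_observed",
              "tfr_predicted")) {
    expect_equal(fit2[[f]], fit[[f]], tolerance = 1e-12)
  }
})

test_that("the no-inhibition cohort pushes every index towards one", {
  # all married, no contraception, negligible insusceptibility
  w <- demo_cohort(500, seed = 77, marriage_schedule = rep(1, 7),
                   u_true = 0, insusceptibility_mean = 0)
  fit <- suppressWarnings(fit_index_set(w))
  expect_equal(fit$cm, 1.0)
  expect_equal(fit$cc, 1.0)
  expect_equal(fit$u, 0)
  expect_equal(fit$i, 0)
  expect_equal(fit$ca, 1.0)
  expect_gt(fit$ci, 1.0)  # i < 1.5 months reports Ci > 1 with a warning
  expect_true(any(grepl("> 1", fit$warnings)))
})
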