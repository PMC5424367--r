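cfg_small <- analysis_config(min_stratum_n = 10L)

test_that("partition symmetry: identical halves reproduce the total row", {
  base <- demo_cohort(200, seed = 6)
  a <- base; a$region <- "A"
  b <- base; b$region <- "B"
  w <- rbind(a, b)
  d <- suppressWarnings(decompose(w, "region", cfg_small))
  rowA <- d[d$category == "A", ]
  rowB <- d[d$category == "B", ]
  tot <- d[d$category == "TOTAL", ]
  for (f in c("u", "e", "i", "cm", "cc", "ci", "ca", "tfr_observed",
              "tfr_predicted")) {
    expect_equal(rowA[[f]], rowB[[f]], tolerance = 1e-12)
    expect_equal(rowA[[f]], tot[[f]], tolerance = 1e-12)
  }
})

test_that("a single-category variable reproduces the whole-table fit exactly", {
  w <- demo_cohort(250, seed = 14)
  w$onecat <- "all"
  d <- suppressWarnings(decompose(w, "onecat", cfg_small))
  fit <- suppressWarnings(fit_index_set(w, cfg_small))
  row <- d[d$category == "all", ]
  ref <- index_set_row(fit)
  for (f in c("u", "e", "i", "cm", "cc", "ci", "ca", "tfr_observed",
              "tfr_predicted", "n_weighted")) {
    expect_identical(row[[f]], ref[[f]])
  }
})

test_that("weighted category counts reconcile with the total", {
  w <- demo_cohort(400, seed = 25)
  w$weight <- runif(nrow(w), 0.2, 3)
  d <- suppressWarnings(decompose(w, c("residence", "region"), cfg_small))
  for (v in c("residence", "region")) {
    expect_equal(sum(d$n_weighted[d$variable == v]), sum(w$weight),
                 tolerance = 1e-9)
  }
})

test_that("stratum failures and small strata are flagged, not fatal", {
  w <- demo_cohort(200, seed = 36)
  # a sterile micro-stratum: one childless woman
  w$group <- "big"
  w$group[1] <- "tiny"
  w$births[[1]] <- integer()
  w$insusceptible_now[1] <- FALSE
  d <- suppressWarnings(decompose(w, "group", cfg_small))
  tiny <- d[d$category == "tiny", ]
  expect_true(is.na(tiny$cm))
  expect_match(tiny$flags, "small stratum")
  expect_false(is.na(d[d$category == "big", "cm"]))

  expect_error(decompose(w, "no_such_var", cfg_small), "available")
})

test_that("missing stratifier values form an explicit category", {
  w <- demo_cohort(150, seed = 44)
  w$residence[1:5] <- NA
  d <- suppressWarnings(decompose(w, "residence", cfg_small))
  expect_true("(missing)" %in% d$category)
  t <- tabulate_weighted(w, "residence")
  expect_true("(missing)" %in% t$category)
})

test_that("weighted tabulation percentages behave", {
  w <- make_women(rep(25L, 4), residence = c("a", "a", "a", "b"))
  t <- tabulate_weighted(w, "residence")
  expect_equal(t$percent[t$category == "a"], 75)
  expect_equal(t$percent[t$category == "b"], 25)

  w2 <- make_women(rep(25L, 3), weight = c(2, 1, 1),
                   residence = c("A", "A", "B"))
  t2 <- tabulate_weighted(w2, "residence")
  expect_equal(t2$percent[t2$category == "A"], 75)
  expect_equal(t2$n[t2$category == "A"], 2L)

  w3 <- demo_cohort(600, seed = 3)
  for (v in stratifier_names(w3)) {
    t3 <- tabulate_weighted(w3, v)
    expect_equal(sum(t3$percent), 100, tolerance = 0.1)
    expect_equal(sum(t3$weighted_n), sum(w3$weight), tolerance = 1e-9)
  }
  expect_error(tabulate_weighted(w3, "nope"), "available")
})

test_that("simulated stratifier shares match their target probabilities", {
  w <- demo_cohort(2000, seed = 55)
  t <- tabulate_weighted(w, "residence")
  p_urban <- t$percent[t$category == "urban"] / 100
  expect_lt(abs(p_urban - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
})

test_that("education re-binning pools secondary and higher", {
  w <- make_women(rep(25L, 4),
                  education = c("none", "primary", "secondary", "higher"))
  w2 <- rebin_education(w)
  expect_equal(w2$education, c("none", "primary", "secondary+", "secondary+"))
})

test_that("rendered tables and output files are deterministic", {
  w <- demo_cohort(200, seed = 66)
  d <- suppressWarnings(decompose(w, "residence", cfg_small))
  lines <- render_decomposition(d)
  expect_match(lines[1], "Cm")
  expect_equal(length(lines), nrow(d) + 2L)
  # indices to 6 decimals, TFR to 1 decimal, half-up
  tot <- d[d$category == "TOTAL", ]
  expect_match(lines[length(lines)], sprintf("%.6f", tot$cm), fixed = TRUE)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_decomposition(d, dir1, config = cfg_small)
  p2 <- write_decomposition(d, dir2, config = cfg_small)
  expect_true(all(file.exists(p1)))
  expect_identical(readLines(p1[["csv"]]), readLines(p2[["csv"]]))
  expect_identical(readLines(p1[["table"]]), readLines(p2[["table"]]))
  man <- jsonlite::read_json(p1[["manifest"]])
  expect_equal(length(man$outputs), 2L)
  expect_equal(man$config$tf, 15.3)
})
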