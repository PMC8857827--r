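test_that("term optimal weight is the printed linear model", {
  # all covariates zero -> intercept only
  rec0 <- data.frame(maternal_age = 0, pregestational_weight = 0,
                     maternal_height = 0, sex = "female")
  expect_equal(term_optimal_weight(rec0), 1407.501)

  # sex coefficient is exactly the male offset
  recs <- data.frame(maternal_age = 30, pregestational_weight = 70,
                     maternal_height = 165, sex = c("male", "female"))
  tow <- term_optimal_weight(recs)
  expect_equal(tow[1] - tow[2], 150.375)

  # frozen value from an independent spreadsheet-style evaluation:
  # 1407.501 + 32.6*4.087 + 78.5*6.506 + 162.02*8.716 + 150.375
  rec <- data.frame(maternal_age = 32.6, pregestational_weight = 78.5,
                    maternal_height = 162.02, sex = "male")
  expect_equal(term_optimal_weight(rec), 3613.99952, tolerance = 1e-12)
})

test_that("missing covariates raise explicit errors, never impute", {
  rec <- data.frame(maternal_age = 30, pregestational_weight = 70,
                    maternal_height = NA_real_, sex = "male")
  expect_error(term_optimal_weight(rec), "missing")
  expect_error(term_optimal_weight(rec[, -3]), "maternal_height")
})

test_that("sex coding is male = 1 / female = 0 and rejects ambiguity", {
  expect_identical(sex_code(c("male", "F", "M", "female")),
                   c(1L, 0L, 1L, 0L))
  expect_identical(sex_code(c(1, 0)), c(1L, 0L))
  expect_error(sex_code("boy"), "unrecognized")
  expect_error(sex_code(2), "coded 1")
})

test_that("proportionality polynomial reproduces printed and derived values", {
  expect_equal(round(proportionality_fraction(34), 2), 66.21)
  # 40 weeks is the ~100% anchor (raw polynomial, not renormalized)
  expect_lt(abs(proportionality_fraction(40) - 100), 0.5)
  # Horner-form cross-check at the low end of the range and on a grid
  ga <- seq(20, 44, by = 0.5)
  expect_equal(proportionality_fraction(ga),
               horner_cubic(ga, 299.1, -31.85, 1.094, -0.01055),
               tolerance = 1e-12)
  expect_equal(proportionality_fraction(20), 15.3, tolerance = 1e-10)
  expect_error(proportionality_fraction(19.9), "outside")
  expect_error(proportionality_fraction(44.1), "outside")
})

test_that("expected weight composes term weight and fraction", {
  rec <- data.frame(maternal_age = 28, pregestational_weight = 64,
                    maternal_height = 158, sex = "female")
  expect_equal(expected_weight(rec, 40),
               term_optimal_weight(rec) * proportionality_fraction(40) / 100)
  # printed worked example: a 3000 g term weight at 34 weeks
  frac34 <- proportionality_fraction(34)
  expect_equal(3000 * frac34 / 100, 3000 * 0.662068, tolerance = 1e-6)
  # independent two-call composition on a random record
  set.seed(5)
  rr <- data.frame(maternal_age = runif(1, 20, 40),
                   pregestational_weight = runif(1, 50, 100),
                   maternal_height = runif(1, 150, 180), sex = "male")
  ga <- runif(1, 24, 42)
  expect_equal(expected_weight(rr, ga),
               term_optimal_weight(rr) *
                 horner_cubic(ga, 299.1, -31.85, 1.094, -0.01055) / 100)
})

test_that("z-scores and centiles behave as defined", {
  expect_equal(weight_zscore(2500, 2500), 0)
  expect_equal(weight_zscore(1.12 * 2500, 2500, cv = 0.12), 1)
  expect_equal(weight_zscore(0.88 * 2500, 2500, cv = 0.12), -1)
  expect_error(weight_zscore(2500, 0), "> 0")
  expect_equal(centile_from_z(0), 50)
  expect_equal(centile_from_z(-1.2816), 10, tolerance = 1e-3)
  expect_equal(centile_from_z(1.96), 97.5, tolerance = 1e-3)
  expect_error(centile_from_z(Inf), "finite")
  # rescaling both weights by the same constant leaves the centile unchanged
  k <- 2.7
  expect_equal(centile_from_z(weight_zscore(2100 * k, 2400 * k)),
               centile_from_z(weight_zscore(2100, 2400)))
})

test_that("size classification thresholds and AGA boundary ties", {
  expect_equal(as.character(classify_size(c(9.99, 10, 50, 90, 90.01))),
               c("SGA", "AGA", "AGA", "AGA", "LGA"))
  expect_error(classify_size(0), "strictly inside")
  expect_error(classify_size(100), "strictly inside")
  # partition: every cohort member lands in exactly one class
  set.seed(3)
  cls <- classify_size(runif(500, 0.01, 99.99))
  expect_equal(sum(table(cls)), 500L)
})

test_that("expected weight is strictly increasing in GA over [26, 40]", {
  rec <- data.frame(maternal_age = 32, pregestational_weight = 75,
                    maternal_height = 162, sex = "male")
  ew <- expected_weight(rec, seq(26, 40, by = 0.1))
  expect_true(all(diff(ew) > 0))
})

test_that("hadlock EFW follows the configured coefficient table", {
  # degenerate table: only the intercept
  k <- list(b0 = 3, b_bpd = 0, b_hc = 0, b_ac = 0, b_fl = 0, b_acfl = 0)
  expect_equal(hadlock_efw(hc = 31, ac = 27, fl = 6.5, coef = k), 1000)
  # inputs with zero coefficients are ignored (and may be missing)
  expect_equal(hadlock_efw(bpd = 9, hc = 31, ac = 27, fl = 6.5, coef = k),
               hadlock_efw(hc = 31, ac = 27, fl = 6.5, coef = k))
  # default table vs independent hand evaluation of the log10 polynomial
  expect_equal(hadlock_efw(hc = 30, ac = 26, fl = 6),
               10^(1.326 + 0.0107 * 30 + 0.0438 * 26 + 0.158 * 6 -
                     0.00326 * 26 * 6))
  expect_error(hadlock_efw(hc = 30, fl = 6), "`ac` required")
})

test_that("coefficient config files round-trip", {
  p <- withr::local_tempfile(fileext = ".conf")
  writeLines(c("# comment", "b0 = 2.5", "b_ac = 0.01"), p)
  co <- hadlock_coefficients(p)
  expect_equal(co$b0, 2.5)
  expect_equal(co$b_ac, 0.01)
  expect_equal(co$b_fl, 0)
  writeLines("b0 2.5", p)
  expect_error(hadlock_coefficients(p), "malformed")
})
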