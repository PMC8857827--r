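test_that("build_table counts and exclusion precedence", {
  sc <- c("SGA", "SGA", "AGA", "AGA")
  nu <- c("undernourished", "normal", "undernourished", "normal")
  tab <- build_table(sc, nu)
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(1L, 1L, 1L, 1L))
  # one LGA record changes only the audit trail
  tab2 <- build_table(c(sc, "LGA"), c(nu, "undernourished"))
  expect_equal(c(tab2$tp, tab2$fp, tab2$fn, tab2$tn), c(1L, 1L, 1L, 1L))
  expect_equal(tab2$excluded_lga, 1L)
  # overnourished and NA exclusions
  tab3 <- build_table(c(sc, "SGA", NA), c(nu, "overnourished", "normal"))
  expect_equal(tab3$excluded_overnourished, 1L)
  expect_equal(tab3$excluded_out_of_coverage, 1L)
  expect_error(build_table("LGA", "normal"), "empty eligible set")
})

test_that("build_table matches brute-force enumeration on random cohorts", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    sc <- sample(c("SGA", "AGA", "LGA", NA), n, replace = TRUE,
                 prob = c(.3, .4, .2, .1))
    nu <- sample(c("undernourished", "normal", "overnourished", NA), n,
                 replace = TRUE, prob = c(.2, .5, .2, .1))
    o <- oracle_build_table(sc, nu)
    tab <- tryCatch(build_table(sc, nu), error = function(e) NULL)
    if (is.null(tab)) {
      expect_equal(sum(o[c("tp", "fp", "fn", "tn")]), 0)
      next
    }
    expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn),
                 unname(o[c("tp", "fp", "fn", "tn")]))
    # conservation
    expect_equal(tab$tp + tab$fp + tab$fn + tab$tn + tab$excluded_lga +
                   tab$excluded_overnourished +
                   tab$excluded_out_of_coverage, n)
  }
})

test_that("operating-point identities reproduce the published metric grid", {
  # customized standard, BMI outcome (sens 60.00, spec 78.74)
  m <- operating_point_metrics(0.60, 0.7874)
  expect_equal(m$lr_pos, 2.82, tolerance = 0.01 / 2.82)
  expect_equal(m$lr_neg, 0.51, tolerance = 0.01 / 0.51)
  expect_equal(m$dor, 5.56, tolerance = 0.02 / 5.56)
  expect_equal(m$youden, 0.39, tolerance = 0.01 / 0.39)
  # population standard, BMI outcome (sens 40.00, spec 87.90)
  m2 <- operating_point_metrics(0.40, 0.879)
  expect_equal(m2$lr_pos, 3.31, tolerance = 0.01 / 3.31)
  expect_equal(m2$lr_neg, 0.68, tolerance = 0.01 / 0.68)
  expect_equal(m2$dor, 4.84, tolerance = 0.02 / 4.84)
  expect_equal(m2$youden, 0.28, tolerance = 0.01 / 0.28)
})

test_that("diagnostic_summary: uninformative table and identities", {
  tab <- contingency_table(7, 7, 7, 7)
  ds <- diagnostic_summary(tab, youden_ci = "delta")
  expect_equal(ds$sensitivity$estimate, 0.5)
  expect_equal(ds$specificity$estimate, 0.5)
  expect_equal(ds$ppv$estimate, 0.5)
  expect_equal(ds$npv$estimate, 0.5)
  expect_equal(ds$lr_pos$estimate, 1)
  expect_equal(ds$lr_neg$estimate, 1)
  expect_equal(ds$dor$estimate, 1)
  expect_equal(ds$youden$estimate, 0)
  expect_equal(ds$youden$estimate,
               ds$sensitivity$estimate + ds$specificity$estimate - 1)
})

test_that("DOR == (tp*tn)/(fp*fn) == LR+/LR- and CIs bracket estimates", {
  set.seed(7)
  for (i in 1:400) {
    tab <- random_table()
    ds <- diagnostic_summary(tab, youden_ci = "delta")
    cross <- (tab$tp * tab$tn) / (tab$fp * tab$fn)
    expect_equal(ds$dor$estimate, cross, tolerance = 1e-9)
    expect_equal(ds$dor$estimate,
                 ds$lr_pos$estimate / ds$lr_neg$estimate, tolerance = 1e-9)
    for (m in c("sensitivity", "specificity", "ppv", "npv", "lr_pos",
                "lr_neg", "dor", "youden")) {
      expect_lte(ds[[m]]$ci_low, ds[[m]]$estimate)
      expect_gte(ds[[m]]$ci_high, ds[[m]]$estimate)
    }
  }
})

test_that("swapping labels maps the battery onto its mirror", {
  tab <- contingency_table(9, 14, 5, 40)
  ds <- diagnostic_summary(tab, youden_ci = "delta")
  # swap both exposure and outcome polarity: tp<->tn, fp<->fn
  sw <- diagnostic_summary(contingency_table(40, 5, 14, 9),
                           youden_ci = "delta")
  expect_equal(sw$sensitivity$estimate, ds$specificity$estimate)
  expect_equal(sw$specificity$estimate, ds$sensitivity$estimate)
  expect_equal(sw$ppv$estimate, ds$npv$estimate)
  expect_equal(sw$npv$estimate, ds$ppv$estimate)
  expect_equal(sw$lr_pos$estimate, 1 / ds$lr_neg$estimate)
  expect_equal(sw$lr_neg$estimate, 1 / ds$lr_pos$estimate)
  expect_equal(sw$dor$estimate, ds$dor$estimate)
  # swapping the outcome labels only inverts the DOR
  out_sw <- diagnostic_summary(contingency_table(14, 9, 40, 5),
                               youden_ci = "delta")
  expect_equal(out_sw$dor$estimate, 1 / ds$dor$estimate)
})

test_that("undefined metrics are flagged, not silent NaN", {
  ds <- diagnostic_summary(contingency_table(0, 0, 3, 17),
                           youden_ci = "delta")
  expect_true(is.na(ds$ppv$estimate))
  expect_true(all(c("ppv", "lr_pos", "lr_neg", "dor") %in% ds$undefined))
  expect_message(
    ds2 <- diagnostic_summary(contingency_table(0, 2, 3, 17),
                              youden_ci = "delta", continuity = TRUE),
    "continuity")
  expect_false(is.na(ds2$dor$estimate))
})

test_that("Youden bootstrap CI is seeded, reproducible and sane", {
  tab <- contingency_table(9, 14, 5, 40)
  a <- diagnostic_summary(tab, youden_ci = "bootstrap", boot_seed = 42)
  b <- diagnostic_summary(tab, youden_ci = "bootstrap", boot_seed = 42)
  expect_identical(a$youden, b$youden)
  expect_lt(a$youden$ci_low, a$youden$estimate)
  expect_gt(a$youden$ci_high, a$youden$estimate)
  d <- diagnostic_summary(tab, youden_ci = "delta")
  expect_lt(abs(a$youden$ci_low - d$youden$ci_low), 0.15)
})

test_that("relative risk matches hand arithmetic and the Katz CI", {
  tab <- contingency_table(9, 36, 6, 155)
  rr <- relative_risk(tab)
  expect_equal(rr$rr, (9 / 45) / (6 / 161), tolerance = 1e-12)
  expect_equal(rr$log_se,
               sqrt(1 / 9 - 1 / 45 + 1 / 6 - 1 / 161), tolerance = 1e-12)
  expect_equal(rr$ci_low, rr$rr * exp(-qnorm(0.975) * rr$log_se))
  # identical risks -> RR 1 with CI spanning 1
  rr1 <- relative_risk(contingency_table(10, 90, 10, 90))
  expect_equal(rr1$rr, 1)
  expect_lt(rr1$ci_low, 1); expect_gt(rr1$ci_high, 1)
  # brute-force ratio of proportions on random tables
  set.seed(21)
  for (i in 1:100) {
    tb <- random_table()
    expect_equal(relative_risk(tb)$rr,
                 (tb$tp / (tb$tp + tb$fp)) / (tb$fn / (tb$fn + tb$tn)))
  }
})

test_that("Altman-Bland RR comparison", {
  tab <- contingency_table(9, 36, 6, 155)
  rr <- relative_risk(tab)
  same <- compare_rr(rr, rr)
  expect_equal(same$ratio, 1)
  expect_equal(same$p, 1)
  # 3-4-5 standard errors
  r1 <- structure(list(rr = 2, log_se = 0.3), class = "risk_ratio")
  r2 <- structure(list(rr = 2, log_se = 0.4), class = "risk_ratio")
  cr <- compare_rr(r1, r2)
  expect_equal(cr$ci_high / cr$ratio, exp(qnorm(0.975) * 0.5))
  # direct formula evaluation as the oracle
  r3 <- structure(list(rr = 3.1, log_se = 0.35), class = "risk_ratio")
  cr2 <- compare_rr(r1, r3)
  z <- (log(2) - log(3.1)) / sqrt(0.3^2 + 0.35^2)
  expect_equal(cr2$p, 2 * pnorm(-abs(z)))
})

test_that("McNemar: exact for few discordant pairs, chi2 beyond 25", {
  expect_equal(mcnemar_test(b = 5, c = 5)$p, 1)
  m <- mcnemar_test(b = 9, c = 0)
  expect_equal(m$p, 2 * 0.5^9, tolerance = 1e-12)
  expect_identical(m$method, "exact")
  big <- mcnemar_test(b = 20, c = 10)
  expect_identical(big$method, "chi-square (continuity corrected)")
  expect_equal(big$statistic, (abs(20 - 10) - 1)^2 / 30)
  expect_warning(z <- mcnemar_test(b = 0, c = 0), "no discordant")
  expect_equal(z$p, 1)
  # random paired cohorts vs brute-force binomial tail sums
  set.seed(13)
  for (i in 1:100) {
    f1 <- runif(40) < 0.4
    f2 <- runif(40) < 0.4
    b <- sum(f1 & !f2); c <- sum(!f1 & f2)
    if (b + c == 0 || b + c >= 25) next
    expect_equal(mcnemar_test(f1, f2)$p, oracle_mcnemar_exact(b, c),
                 tolerance = 1e-12)
  }
})

test_that("chi-square proportion comparison", {
  expect_equal(compare_proportions(20, 100, 20, 100)$chi2, 0)
  expect_equal(compare_proportions(20, 100, 20, 100)$p, 1)
  # textbook arithmetic for the in-cohort SGA frequencies
  res <- compare_proportions(45, 226, 27, 226)
  m <- matrix(c(45, 181, 27, 199), 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$chi2, sum((m - e)^2 / e))
  expect_lt(res$p, 0.05)
  # doubling all counts doubles the statistic
  res2 <- compare_proportions(90, 452, 54, 452)
  expect_equal(res2$chi2, 2 * res$chi2, tolerance = 1e-12)
  expect_warning(compare_proportions(0, 3, 1, 3), "Fisher")
})
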