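test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n = 100, seed = 5)
  a <- suppressMessages(simulate_cohort(cfg))
  b <- suppressMessages(simulate_cohort(cfg))
  expect_identical(a, b)
  c_ <- suppressMessages(simulate_cohort(simulation_config(n = 100,
                                                           seed = 6)))
  expect_false(identical(a$birthweight, c_$birthweight))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_cohort(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("records are valid pipeline input with coherent covariates", {
  coh <- toy_cohort(n = 80)
  val <- validate_cohort(coh[, customgrowth:::COHORT_COLUMNS])
  expect_equal(nrow(val), 80)
  expect_equal(nrow(attr(val, "rejects")), 0)
  # maternal weight is BMI-derived: implied BMI within the truncation range
  implied_bmi <- coh$pregestational_weight / (coh$maternal_height / 100)^2
  expect_true(all(implied_bmi >= 15 & implied_bmi <= 55))
  expect_true(all(coh$ga_birth >= 32 & coh$ga_birth <= 42))
  expect_true(all(coh$ga_scan <= coh$ga_birth &
                    coh$ga_scan >= coh$ga_birth - 2))
  expect_true(all(coh$true_weight_centile > 0 &
                    coh$true_weight_centile < 100))
})

test_that("covariate moments converge to the configured parameters", {
  n <- 10000
  cfg <- simulation_config(n = n, seed = 31)
  coh <- suppressMessages(simulate_cohort(cfg))
  se <- function(sd) 3 * sd / sqrt(n)
  expect_lt(abs(mean(coh$maternal_age) - 32.6), se(5.3))
  expect_lt(abs(mean(coh$maternal_height) - 162.02), se(6.16))
  implied_bmi <- coh$pregestational_weight / (coh$maternal_height / 100)^2
  expect_lt(abs(mean(implied_bmi) - 29.93), se(6.52))
  expect_lt(abs(mean(coh$sex == "male") - 0.492), 3 * sqrt(0.25 / n))
  # truncation pulls the GA mean slightly below 37.7; allow for it
  expect_lt(abs(mean(coh$ga_birth) - 37.7), 0.15)
})

test_that("the latent copula achieves the requested correlation", {
  n <- 10000
  for (rho in c(0, 0.6)) {
    coh <- suppressMessages(simulate_cohort(
      simulation_config(n = n, seed = 41, rho = rho)))
    r <- cor(qnorm(coh$true_weight_centile / 100),
             qnorm(coh$true_nutrition_centile / 100))
    expect_lt(abs(r - rho), 0.05)
  }
})

test_that("with no restriction the customized SGA rate is nominal; a
          negative shift raises it", {
  n <- 10000
  cust <- customized_standard()
  coh0 <- suppressMessages(simulate_cohort(
    simulation_config(n = n, seed = 51, rho = 0, hdp_shift = 0)))
  rate0 <- mean(classify_weight(cust, coh0$birthweight, coh0$ga_birth,
                                coh0$sex, coh0) == "SGA")
  expect_lt(abs(rate0 - 0.10), 2 * sqrt(0.1 * 0.9 / n))
  cohS <- suppressMessages(simulate_cohort(
    simulation_config(n = 226, seed = 51, rho = 0, hdp_shift = -0.8)))
  rateS <- mean(classify_weight(cust, cohS$birthweight, cohS$ga_birth,
                                cohS$sex, cohS) == "SGA")
  expect_gt(rateS, 0.15)
})

test_that("end-to-end prevalence recovery through the pipeline", {
  n <- 10000
  cfg <- simulation_config(n = n, seed = 61, rho = 0.6, hdp_shift = -0.8,
                           nutrition_index = "PI")
  coh <- suppressMessages(simulate_cohort(cfg))
  pi_ <- ponderal_index(coh$birthweight, coh$birth_length)
  cent <- nutrition_centile(pi_, coh$sex, coh$ga_birth,
                            nutrition_reference("PI"))
  expect_lt(abs(mean(cent < 10) - 0.10), 2 * sqrt(0.1 * 0.9 / n))
})

test_that("operating-characteristic recovery: coupling rewards the
          generating standard", {
  # rho = 0: the test is uninformative under either standard
  oc0 <- recover_operating_characteristics(
    simulation_config(n = 400, seed = 71, rho = 0, hdp_shift = -0.8),
    n_reps = 40)
  s <- oc0$summary
  sens_c <- s$mean[s$metric == "sens_customized"]
  # sensitivity ~ SGA flag rate under independence (~Phi(-1.28+0.8)=0.315)
  expect_lt(abs(sens_c - 0.315), 0.08)
  expect_lt(abs(s$mean[s$metric == "dor_customized"] - 1), 0.6)
  # strong coupling: generating standard dominates in nearly every replicate
  oc <- recover_operating_characteristics(
    simulation_config(n = 226, seed = 81, rho = 0.6, hdp_shift = -0.8),
    n_reps = 60)
  frac_dom <- mean(oc$replicates$sens_customized >
                     oc$replicates$sens_table)
  expect_gt(frac_dom, 0.9)
})
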