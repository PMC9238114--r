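test_that("participation effects satisfy the logistic liability identity exactly", {
  mafs <- runif(200, 0.05, 0.5)

  # h2 = 0.5: Var(eta) = h/(1-h) * pi^2/3 = pi^2/3
  eff <- draw_participation_effects(mafs, 0.5, 0.5, "sex_independent", seed = 3)
  expect_equal(genetic_variance(eff$b_female, mafs), pi^2 / 3, tolerance = 1e-10)
  expect_equal(genetic_variance(eff$b_female, mafs), 3.2899, tolerance = 1e-4)

  # the identity h2 = V/(V + pi^2/3) recovers the input heritabilities
  eff <- draw_participation_effects(mafs, 0.17, 0.42, "sex_differential", seed = 4)
  expect_equal(liability_h2(eff$b_female, mafs), 0.17, tolerance = 1e-6)
  expect_equal(liability_h2(eff$b_male, mafs), 0.42, tolerance = 1e-6)

  # h2 = 0 gives exactly zero effects
  eff0 <- draw_participation_effects(mafs, 0, 0.3, "sex_differential", seed = 5)
  expect_identical(eff0$b_female, numeric(200))
  expect_error(draw_participation_effects(mafs, 1, 0.3), "h")
})

test_that("scenario controls the between-sex structure of the effects", {
  mafs <- rep(0.3, 10000)
  # sex_independent: identical vectors, equal heritabilities enforced
  eff <- draw_participation_effects(mafs, 0.3, 0.3, "sex_independent", seed = 8)
  expect_identical(eff$b_female, eff$b_male)
  expect_error(
    draw_participation_effects(mafs, 0.2, 0.3, "sex_independent"),
    "sex_independent"
  )
  # sex_differential with correlation 0: empirical correlation 0 +- 0.04
  eff <- draw_participation_effects(mafs, 0.3, 0.3, "sex_differential",
                                    correlation = 0, seed = 9)
  expect_lt(abs(cor(eff$b_female, eff$b_male)), 0.04)
  # intermediate correlation is respected
  eff <- draw_participation_effects(mafs, 0.3, 0.3, "sex_differential",
                                    correlation = 0.7, seed = 10)
  expect_equal(cor(eff$b_female, eff$b_male), 0.7, tolerance = 0.04)
})

test_that("intercept calibration matches closed forms and a grid-search oracle", {
  # flat linear predictor: alpha = logit(pi)
  expect_equal(calibrate_intercept(rep(0, 100), 0.05), qlogis(0.05), tolerance = 1e-8)
  expect_equal(calibrate_intercept(rep(0, 100), 0.05), -2.9444, tolerance = 1e-4)
  expect_equal(calibrate_intercept(rep(0, 100), 0.5), 0, tolerance = 1e-10)
  expect_identical(calibrate_intercept(rnorm(100), 1), Inf)

  # Gaussian predictors: cross-check against a fine grid search
  set.seed(14)
  eta <- rnorm(20000)
  alpha <- calibrate_intercept(eta, 0.05)
  grid <- seq(qlogis(0.05) - 2, qlogis(0.05) + 2, by = 1e-4)
  rate_at <- vapply(grid, function(a) mean(plogis(a + eta)), numeric(1))
  alpha_grid <- grid[which.min(abs(rate_at - 0.05))]
  expect_equal(alpha, alpha_grid, tolerance = 1e-3)
  expect_lt(abs(mean(plogis(alpha + eta)) - 0.05), 1e-4)

  expect_error(calibrate_intercept(rep(0, 10), 0), "pi")
  expect_error(calibrate_intercept(rep(0, 10), 1.2), "pi")
})

test_that("calibration is idempotent at the achieved rates", {
  coh <- make_selected_cohort(n = 30000L, m = 10L, pi = 0.1, seed = 15)
  s <- coh$participation_summary
  eff <- draw_participation_effects(coh$maf, 0, 0.2, "sex_differential", seed = 15)
  mod <- participation_model(s$realized_rate_female, s$realized_rate_male,
                             b_female = eff$b_female, b_male = eff$b_male)
  mod1 <- calibrate_participation(mod, coh)
  eta <- partbias:::participation_eta(coh, mod1)
  mod2 <- mod1
  mod2$pi_female <- mean(plogis(mod1$alpha_female + eta[coh$sex == 0]))
  mod2$pi_male <- mean(plogis(mod1$alpha_male + eta[coh$sex == 1]))
  mod2 <- calibrate_participation(mod2, coh)
  expect_equal(mod1$alpha_female, mod2$alpha_female, tolerance = 1e-6)
  expect_equal(mod1$alpha_male, mod2$alpha_male, tolerance = 1e-6)
})

test_that("participation indicators are Bernoulli with the modeled rates", {
  n <- 50000L
  cfg <- population_config(n, 2L, maf = 0.3, seed = 16)
  coh <- simulate_cohort(cfg)

  # no effects: realized rate 0.1 within 4 binomial SE, rate difference ~ 0
  mod <- calibrate_participation(participation_model(0.1), coh)
  coh1 <- simulate_participation(coh, mod, seed = 16)
  s <- coh1$participation_summary
  tol <- 4 * sqrt(0.1 * 0.9 / (n / 2))
  expect_lt(abs(s$realized_rate_female - 0.1), tol)
  expect_lt(abs(s$realized_rate_male - 0.1), tol)
  expect_equal(s$rate_difference, s$realized_rate_male - s$realized_rate_female)
  expect_lt(abs(s$rate_difference), 2 * tol)

  # pi = 1: everyone participates, participants == population
  mod1 <- calibrate_participation(participation_model(1), coh)
  coh2 <- simulate_participation(coh, mod1, seed = 17)
  expect_true(all(coh2$participation == 1L))
  expect_identical(participants(coh2)$genotypes, coh$genotypes)

  # uncalibrated model is a state error
  expect_error(simulate_participation(coh, participation_model(0.1)),
               "calibrat")
})

test_that("per-cell participation probabilities match exact enumeration", {
  # single variant, maf 0.3, b_m = 0.2, b_f = 0, pi = 0.01 both sexes:
  # compare empirical participation rate in each (genotype, sex) cell with
  # the exact logit probability, within 4 binomial SE per cell
  n <- 200000L
  cfg <- population_config(n, 1L, maf = 0.3, seed = 18)
  coh <- simulate_cohort(cfg)
  mod <- participation_model(0.01, 0.01, b_female = 0, b_male = 0.2)
  mod <- calibrate_participation(mod, coh)
  coh <- simulate_participation(coh, mod, seed = 18)
  for (s in 0:1) {
    b <- if (s == 1) mod$b_male else mod$b_female
    a <- if (s == 1) mod$alpha_male else mod$alpha_female
    for (g in 0:2) {
      cell <- coh$sex == s & coh$genotypes[, 1] == g
      p_exact <- plogis(a + b * (g - 2 * 0.3))
      se <- sqrt(p_exact * (1 - p_exact) / sum(cell))
      expect_lt(abs(mean(coh$participation[cell]) - p_exact), 4 * se)
    }
  }
})
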