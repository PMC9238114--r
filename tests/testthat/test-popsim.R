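test_that("genotype columns follow Hardy-Weinberg at the configured MAF", {
  n <- 100000L
  cfg <- population_config(n, 3L, maf = c(0.2, 0.35, 0.5), seed = 11)
  g <- simulate_genotypes(cfg)

  # maf = 0.2: class frequencies (1-p)^2, 2p(1-p), p^2 within 4 binomial SE
  expected <- c(0.64, 0.32, 0.04)
  observed <- tabulate(g[, 1] + 1L, 3L) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(observed - expected) < 4 * se))

  # maf = 0.5: mean dosage 1.0 +- 0.02 by symmetry
  expect_equal(mean(g[, 3]), 1.0, tolerance = 0.02)

  # chi-square goodness of fit across all columns, 4-SE-level equivalent
  for (j in 1:3) {
    exp_j <- dbinom(0:2, 2, cfg$maf[j]) * n
    chi <- sum((tabulate(g[, j] + 1L, 3L) - exp_j)^2 / exp_j)
    expect_lt(chi, qchisq(1 - 2 * pnorm(-4), df = 2))
  }
})

test_that("genotype simulation is reproducible and validates its inputs", {
  cfg <- population_config(500L, 4L, maf = 0.25, seed = 7)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  expect_error(population_config(100, 2, maf = 0), "maf")
  expect_error(population_config(100, 2, maf = 0.6), "maf")
  expect_error(population_config(0, 2), "n_individuals")
  # boundary: tiny but positive frequency is accepted, column almost all 0
  g <- simulate_genotypes(population_config(10000L, 1L, maf = 1e-6, seed = 3))
  expect_lte(sum(g), 1)
})

test_that("trait effects are rescaled exactly to the target liability variance", {
  # single causal variant: closed-form |b| = sqrt(h2 / (2 p (1-p)))
  arch <- trait_architecture(0.25, h2_liability = 0.1, prevalence = 0.2,
                             causal_mask = 1L, seed = 5)
  expect_equal(abs(arch$effects), sqrt(0.1 / (2 * 0.25 * 0.75)), tolerance = 1e-10)
  expect_equal(abs(arch$effects), 0.5164, tolerance = 1e-4)

  # many causal variants: analytic genetic variance matches h2 to 1e-12
  mafs <- runif(100, 0.05, 0.5)
  arch <- trait_architecture(mafs, 0.3, 0.1, seed = 6)
  expect_equal(genetic_variance(arch$effects, mafs), 0.3, tolerance = 1e-12)

  # h2 = 0: all effects exactly zero
  arch0 <- trait_architecture(mafs, 0, 0.1, seed = 6)
  expect_identical(arch0$effects, numeric(100))

  # masked variants have effect exactly 0
  arch <- trait_architecture(mafs, 0.3, 0.1, causal_mask = 1:10, seed = 6)
  expect_identical(arch$effects[11:100], numeric(90))
  expect_error(trait_architecture(mafs, 0.3, 0.1, causal_mask = integer(0)),
               "causal_mask")
})

test_that("liability-threshold traits hit their prevalence and respect the null", {
  n <- 50000L
  cfg <- population_config(n, 5L, maf = 0.3, seed = 21)
  g <- simulate_genotypes(cfg)

  # pure-noise trait: prevalence within 4 binomial SE of K
  arch <- trait_architecture(cfg$maf, 0, 0.1)
  x <- simulate_binary_trait(g, arch, seed = 2)
  expect_lt(abs(mean(x) - 0.1), 4 * sqrt(0.1 * 0.9 / n))

  # h2 = 0, K = 0.5: trait independent of every variant, mean chi2 ~ 1
  cfg2 <- population_config(10000L, 200L, maf = 0.3, seed = 22)
  g2 <- simulate_genotypes(cfg2)
  arch5 <- trait_architecture(cfg2$maf, 0, 0.5)
  x5 <- simulate_binary_trait(g2, arch5, seed = 3)
  res <- logistic_gwas(x5, g2)
  expect_lt(abs(mean(res$chi2) - 1), 4 * sqrt(2 / 200))
})

test_that("single-causal-variant association matches the liability-model oracle", {
  # oracle: exact P(trait | g) integrated over the Gaussian liability noise,
  # converted to the large-sample logistic slope on exact HWE cells
  maf <- 0.3; h2 <- 0.2; K <- 0.3; n <- 80000L
  cfg <- population_config(n, 1L, maf = maf, seed = 31)
  g <- simulate_genotypes(cfg)
  arch <- trait_architecture(maf, h2, K, causal_mask = 1L, seed = 31)
  x <- simulate_binary_trait(g, arch, seed = 32)
  p_by_g <- liability_trait_prob(0:2, arch$effects[1], maf, h2, K)
  oracle_slope <- cell_logistic_slope(p_by_g, maf)
  res <- logistic_gwas(x, g)
  expect_lt(abs(res$beta - oracle_slope), 4 * res$se)
})

test_that("traits with disjoint causal masks are phenotypically independent", {
  n <- 50000L
  cfg <- population_config(n, 40L, maf = 0.3, seed = 41)
  a1 <- trait_architecture(cfg$maf, 0.4, 0.3, causal_mask = 1:20, seed = 1)
  a2 <- trait_architecture(cfg$maf, 0.4, 0.3, causal_mask = 21:40, seed = 2)
  coh <- simulate_cohort(cfg, list(t1 = a1, t2 = a2))
  expect_lt(abs(cor(coh$traits[, 1], coh$traits[, 2])), 4 / sqrt(n))
})

test_that("cohort TSV serialization round-trips exactly", {
  coh <- make_selected_cohort(n = 300L, m = 5L, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(coh, path)
  back <- read_cohort_tsv(path, maf = coh$maf)
  expect_identical(unname(back$genotypes), unname(coh$genotypes))
  expect_identical(back$sex, coh$sex)
  expect_identical(back$participation, coh$participation)
})
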