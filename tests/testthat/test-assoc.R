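test_that("per-variant logistic fit matches the closed-form 2x2 estimator", {
  # carrier-coded variant: ML logistic beta equals the log odds ratio and
  # its Wald SE equals the Woolf SE, both available in closed form
  tab <- table_2x2(40, 10, 30, 20)
  res <- logistic_gwas(tab$y, tab$g)
  expect_equal(res$beta, log(40 * 20 / (10 * 30)), tolerance = 1e-6)
  expect_equal(res$se, sqrt(1 / 40 + 1 / 10 + 1 / 30 + 1 / 20), tolerance = 1e-6)
  expect_equal(res$beta, 0.9808, tolerance = 1e-4)
  expect_equal(res$se, 0.4564, tolerance = 1e-4)
})

test_that("GWAS records satisfy the Wald identity and flag degenerate variants", {
  set.seed(51)
  n <- 2000L
  g <- cbind(
    v1 = rbinom(n, 2, 0.3),
    v2 = rep(0L, n),                       # monomorphic
    v3 = rbinom(n, 2, 0.3)
  )
  y <- rbinom(n, 1, 0.4)
  res <- logistic_gwas(y, g)
  ok <- res$flag == "ok"
  expect_equal(res$chi2[ok], (res$beta[ok] / res$se[ok])^2, tolerance = 1e-10)
  expect_equal(res$flag[2], "monomorphic")
  expect_true(is.na(res$beta[2]))
  # flagged variants are excluded from the inflation summary, not the table
  infl <- inflation_summary(res)
  expect_equal(infl$n_variants, sum(ok))
  expect_equal(nrow(res), 3L)

  # permuted labels: exchangeability null, beta within 4 SE of zero
  yp <- sample(y)
  resp <- logistic_gwas(yp, g[, c(1, 3)])
  expect_true(all(abs(resp$beta) < 4 * resp$se))
})

test_that("separated fits are flagged rather than thrown", {
  # outcome perfectly determined by the variant: complete separation
  g <- matrix(c(rep(0L, 50), rep(2L, 50)), ncol = 1, dimnames = list(NULL, "v1"))
  y <- c(rep(0L, 50), rep(1L, 50))
  res <- logistic_gwas(y, g)
  expect_true(res$flag %in% c("separation", "not_converged"))
  expect_true(is.na(res$beta))
})

test_that("linear GWAS handles perfect fits, nulls, and matches logistic at p = 0.5", {
  set.seed(52)
  n <- 4000L
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))

  # exact linear outcome: beta = c, zero-residual flagged
  res <- linear_gwas(3 * g[, 1], g)
  expect_equal(res$beta, 3, tolerance = 1e-12)
  expect_equal(res$flag, "zero_residual")
  expect_equal(res$se, 0)

  expect_error(linear_gwas(rep(1, n), g), "zero variance")

  # independent standard-normal outcome over many variants: mean chi2 ~ 1
  m <- 1000L
  gm <- matrix(rbinom(500L * m, 2, 0.3), 500L, m)
  yn <- rnorm(500L)
  resn <- linear_gwas(yn, gm)
  expect_lt(abs(mean(resn$chi2[resn$flag == "ok"]) - 1), 4 * sqrt(2 / m))

  # balanced binary outcome, small effect: linear beta ~ logistic beta / 4
  n2 <- 50000L
  g2 <- matrix(rbinom(n2, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  p <- plogis(qlogis(0.5) + 0.15 * (g2[, 1] - 2 * 0.3))
  y2 <- rbinom(n2, 1, p)
  b_log <- logistic_gwas(y2, g2)$beta
  b_lin <- linear_gwas(y2, g2)$beta
  expect_equal(b_lin / b_log, 0.25, tolerance = 0.05)
})

test_that("sex GWAS runs on participants and demands both sexes", {
  coh <- make_selected_cohort(n = 20000L, m = 10L, pi = 0.2, seed = 53)
  out <- run_sex_gwas(coh)
  expect_equal(nrow(out$results), 10L)
  expect_equal(unique(out$results$outcome), "sex")
  expect_equal(out$results$n[1], sum(coh$participation))
  expect_gt(out$inflation$ratio, 0)

  coh_f <- coh
  coh_f$participation[coh_f$sex == 1L] <- 0L # select females only
  expect_error(run_sex_gwas(coh_f), "single sex")
  coh_np <- coh
  coh_np$participation <- NULL
  expect_error(run_sex_gwas(coh_np), "participation")
})

test_that("combined and stratified-meta trait GWAS agree without selection", {
  n <- 30000L
  cfg <- population_config(n, 30L, maf = 0.3, seed = 54)
  arch <- trait_architecture(cfg$maf, 0.3, 0.3, seed = 54)
  coh <- simulate_cohort(cfg, list(t = arch))
  mod <- calibrate_participation(participation_model(1), coh)
  coh <- simulate_participation(coh, mod, seed = 54)
  comb <- run_trait_gwas(coh, 1L, "combined")
  strat <- run_trait_gwas(coh, 1L, "stratified")
  meta <- meta_analyze(strat)
  expect_equal(nrow(strat), 60L)
  expect_setequal(unique(strat$stratum), c("female", "male"))
  # asymptotically equivalent estimators on the same data: differences are
  # an order of magnitude below the sampling noise
  expect_lt(mean(abs(comb$beta - meta$beta)), 0.2 * mean(comb$se))
  # small strata are flagged, not fitted
  few <- coh
  few$participation[501:n] <- 0L
  few$participation[coh$sex == 0L] <- 0L
  strat2 <- run_trait_gwas(few, 1L, "stratified", min_stratum = 40L)
  expect_true(all(strat2$flag[strat2$stratum == "female"] == "small_stratum"))
})

test_that("null p-values are uniform (KS) without selection", {
  set.seed(55)
  n <- 1500L
  m <- 400L
  g <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rbinom(n, 1, 0.5)
  res <- logistic_gwas(y, g)
  ks <- suppressWarnings(ks.test(res$p[res$flag == "ok"], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("summary statistics round-trip through TSV bit-exactly", {
  coh <- make_selected_cohort(n = 10000L, m = 6L, pi = 0.3, seed = 56)
  res <- run_sex_gwas(coh)$results
  res$flag[2] <- "low_count" # exercise a flagged row
  res$beta[2] <- NA; res$se[2] <- NA; res$chi2[2] <- NA; res$p[2] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(res, path)
  back <- read_sumstats(path)
  expect_identical(back$beta, res$beta)
  expect_identical(back$se, res$se)
  expect_identical(back$chi2, res$chi2)
  expect_identical(back$p, res$p)
  expect_identical(back$variant_id, res$variant_id)
  expect_identical(back$stratum, res$stratum)
  expect_identical(back$flag, res$flag)
})
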