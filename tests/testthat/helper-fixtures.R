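# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small enough that the whole suite runs in minutes.

# A cohort with sex-differential genetic participation effects, calibrated
# and with participation drawn.
make_selected_cohort <- function(n = 20000L, m = 20L, pi = 0.05,
                                 h2_female = 0, h2_male = 0.2, maf = 0.3,
                                 seed = 1L) {
  cfg <- population_config(n, m, maf = maf, seed = seed)
  coh <- simulate_cohort(cfg)
  eff <- draw_participation_effects(cfg$maf, h2_female, h2_male,
                                    scenario = "sex_differential", seed = seed)
  mod <- participation_model(pi, pi, b_female = eff$b_female,
                             b_male = eff$b_male)
  mod <- calibrate_participation(mod, coh)
  simulate_participation(coh, mod, seed = seed)
}

# Expand a 2x2 carrier table into individual-level vectors.
# a: g=1,y=1; b: g=1,y=0; c: g=0,y=1; d: g=0,y=0
table_2x2 <- function(a, b, c, d) {
  g <- rep(c(1, 1, 0, 0), times = c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), times = c(a, b, c, d))
  list(g = matrix(g, ncol = 1, dimnames = list(NULL, "v1")), y = y)
}

# Exact per-genotype trait probability under the liability-threshold model
# with a single causal variant: the independent oracle for association
# strength (numerical expectation over the Gaussian noise is closed-form).
liability_trait_prob <- function(g, b, maf, h2, prevalence) {
  thr <- qnorm(1 - prevalence)
  1 - pnorm((thr - b * (g - 2 * maf)) / sqrt(1 - h2))
}

# Large-sample logistic slope implied by exact 3-cell outcome probabilities
# at HWE genotype weights: weighted ML logistic fit on the cells.
cell_logistic_slope <- function(p_by_g, maf) {
  w <- dbinom(0:2, 2, maf)
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, g = 0:2), p_by_g, weights = w,
    family = stats::quasibinomial(),
    control = list(epsilon = 1e-13, maxit = 100)
  ))
  unname(fit$coefficients["g"])
}
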