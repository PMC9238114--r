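# Closed-form predictions for the post-selection sex-genotype association
# under the logit participation model, and an exact 6-cell enumeration
# oracle that verifies the Monte-Carlo engine without sampling error.
#
# The mechanism in one line: among participants, Bayes gives
#   P(male | g, participate) proportional to
#   P(male) * expit(alpha_m + b_m (g - 2p)),
# so the log-odds of male at genotype g is
#   logit(male_fraction) + log expit(alpha_m + b_m gc) - log expit(alpha_f + b_f gc).
# When participation is rare, log expit(z) ~ z, and the slope in g collapses
# to b_m - b_f: the between-sex difference of the participation effects is
# the whole signal, whatever the effect levels.

#' Rare-participation-limit sex-GWAS effect
#'
#' In the limit of vanishing participation rate, the log-odds of being male
#' among participants is exactly linear in dosage with slope
#' `b_male - b_female`: the sex-GWAS effect of a variant depends only on the
#' between-sex difference of its participation effects, not on their levels.
#'
#' @param b_female,b_male Logit-scale participation effects (vectorized).
#' @return `b_male - b_female`.
#' @export
rare_limit_sex_effect <- function(b_female, b_male) {
  b_male - b_female
}

#' Calibrate oracle intercepts for target participation rates
#'
#' Solves, per sex, \eqn{E_g[\mathrm{expit}(\alpha_s + b_s (g - 2p))] = \pi_s}
#' with the expectation taken over the exact HWE genotype distribution
#' (3-point), by monotone root finding. The deterministic counterpart of
#' [calibrate_participation()] for the single-variant enumeration oracle.
#'
#' @param maf Allele frequency.
#' @param b_female,b_male Participation effects for the variant.
#' @param pi_female,pi_male Target rates in (0, 1].
#' @return List `alpha_female`, `alpha_male`.
#' @export
oracle_calibrate <- function(maf, b_female, b_male, pi_female, pi_male = pi_female) {
  check_prob(maf, "maf", hi = 0.5, hi_open = FALSE)
  hwe <- stats::dbinom(0:2, 2, maf)
  gc_ <- 0:2 - 2 * maf
  solve_alpha <- function(b, pi) {
    check_prob(pi, "pi", hi_open = FALSE)
    if (pi == 1) return(Inf)
    f <- function(a) sum(hwe * stats::plogis(a + b * gc_)) - pi
    lo <- stats::qlogis(pi) - max(b * gc_)
    hi <- stats::qlogis(pi) - min(b * gc_)
    if (lo == hi) return(lo)
    stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  }
  list(alpha_female = solve_alpha(b_female, pi_female),
       alpha_male = solve_alpha(b_male, pi_male))
}

#' Exact enumeration oracle for the post-selection sex-genotype association
#'
#' Enumerates the six cells (genotype 0/1/2 x sex) with exact weights
#' `HWE(g) * P(s) * expit(alpha_s + b_s (g - 2 maf))` and returns, without
#' any sampling: the exact log-odds of male at each genotype, the weighted
#' maximum-likelihood logistic slope of sex on dosage fitted to those cell
#' weights (the large-n limit of the simulated sex-GWAS estimate), and the
#' per-participant chi-squared non-centrality of the Wald test of that
#' slope (model-based information at the projected fit).
#'
#' @param maf Allele frequency.
#' @param b_female,b_male Logit-scale participation effects.
#' @param alpha_female,alpha_male Logit intercepts (from
#'   [oracle_calibrate()] or [calibrate_participation()]). `Inf` means
#'   certain participation.
#' @param male_fraction Population male fraction (default 0.5).
#' @return List with `log_odds_male` (length 3, genotypes 0/1/2), `slope`,
#'   `intercept`, `nonc_per_participant`, `participation_rate` (overall),
#'   and `cell_weights` (2 x 3 matrix female/male by genotype).
#' @export
exact_sex_effect_oracle <- function(maf, b_female, b_male,
                                    alpha_female, alpha_male,
                                    male_fraction = 0.5) {
  check_prob(maf, "maf", hi = 0.5, hi_open = FALSE)
  check_prob(male_fraction, "male_fraction")
  hwe <- stats::dbinom(0:2, 2, maf)
  gc_ <- 0:2 - 2 * maf
  p_f <- stats::plogis(alpha_female + b_female * gc_)
  p_m <- stats::plogis(alpha_male + b_male * gc_)
  w_f <- (1 - male_fraction) * hwe * p_f
  w_m <- male_fraction * hwe * p_m
  cells <- rbind(female = w_f, male = w_m)
  colnames(cells) <- paste0("g", 0:2)
  log_odds <- log(w_m) - log(w_f)
  # weighted logistic MLE of male vs dosage on the exact cell weights: the
  # KL projection the finite-sample GWAS estimator converges to
  tot <- w_f + w_m
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, g = 0:2), w_m / tot, weights = tot / sum(tot),
    family = stats::quasibinomial(),
    control = list(epsilon = 1e-13, maxit = 100)
  ))
  slope <- unname(fit$coefficients["g"])
  intercept <- unname(fit$coefficients[1])
  # per-participant expected information at the projected fit
  q <- tot / sum(tot)
  ph <- stats::plogis(intercept + slope * (0:2))
  X <- cbind(1, 0:2)
  info <- t(X) %*% (X * (q * ph * (1 - ph)))
  nonc <- slope^2 / solve(info)[2, 2]
  list(log_odds_male = unname(log_odds), slope = slope, intercept = intercept,
       nonc_per_participant = unname(nonc),
       participation_rate = sum(cells), cell_weights = cells)
}

#' Regress estimated sex-GWAS effects on participation effect differences
#'
#' Ordinary least squares of per-variant sex-GWAS effect estimates on the
#' per-variant between-sex participation effect differences. In the
#' rare-participation regime the theoretical slope is 1 on the log-odds
#' scale; on the linear-probability scale, with marginal probability-scale
#' effect differences as predictor, the slope is compared against the
#' realized between-sex participation rate difference.
#'
#' @param estimated_effects Per-variant estimated sex-GWAS effects.
#' @param effect_differences Per-variant participation effect differences
#'   (male minus female), on the matching scale.
#' @return List with `slope`, `intercept`, `ci` (95% on the slope),
#'   `se_slope`, `r_squared`, `n`.
#' @export
predicted_vs_estimated_slope <- function(estimated_effects, effect_differences) {
  use <- is.finite(estimated_effects) & is.finite(effect_differences)
  y <- estimated_effects[use]
  x <- effect_differences[use]
  if (length(y) < 10L) {
    stop("need at least 10 variants with valid estimates", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("participation effect differences are constant; slope is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = 0.95)
  list(slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)[1]),
       ci = unname(ci[1, ]), se_slope = sm$coefficients["x", "Std. Error"],
       r_squared = sm$r.squared, n = length(y))
}

#' Oracle predictions over a parameter grid, as JSON-ready records
#'
#' Convenience sweep of [exact_sex_effect_oracle()] keyed by
#' `(maf, b_female, b_male, pi_female, pi_male)`, with intercepts calibrated
#' per point.
#'
#' @param grid Data.frame with columns `maf`, `b_female`, `b_male`,
#'   `pi_female`, `pi_male`.
#' @param male_fraction Population male fraction.
#' @param path Optional path to write JSON records.
#' @return Data.frame of the grid plus `slope`, `log_odds_g0/g1/g2`,
#'   `nonc_per_participant`.
#' @export
oracle_grid <- function(grid, male_fraction = 0.5, path = NULL) {
  need <- c("maf", "b_female", "b_male", "pi_female", "pi_male")
  stopifnot(all(need %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gr <- grid[i, ]
    al <- oracle_calibrate(gr$maf, gr$b_female, gr$b_male, gr$pi_female, gr$pi_male)
    or <- exact_sex_effect_oracle(gr$maf, gr$b_female, gr$b_male,
                                  al$alpha_female, al$alpha_male, male_fraction)
    cbind(gr, data.frame(
      slope = or$slope, log_odds_g0 = or$log_odds_male[1],
      log_odds_g1 = or$log_odds_male[2], log_odds_g2 = or$log_odds_male[3],
      nonc_per_participant = or$nonc_per_participant
    ))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}
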