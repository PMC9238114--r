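# Logistic liability noise variance: Var of the standard logistic, pi^2/3.
LOGISTIC_VAR <- pi^2 / 3

#' Draw per-sex genetic participation effects at target liability heritabilities
#'
#' Participation follows a logit model, equivalently a liability threshold
#' with standard-logistic noise. The liability-scale heritability of
#' participation for sex s is \eqn{h^2_s = V_s / (V_s + \pi^2/3)} where
#' \eqn{V_s} is the variance of the genetic linear predictor. Effects are
#' drawn i.i.d. normal on standardized genotypes and rescaled exactly so
#' that \eqn{V_s = h^2_s/(1-h^2_s) \cdot \pi^2/3}, making the identity hold
#' analytically.
#'
#' Under `scenario = "sex_independent"` the two sexes share one effect
#' vector (which requires `h2_female == h2_male`); under `"sex_differential"`
#' the vectors are drawn jointly with between-sex correlation `correlation`.
#'
#' @param mafs Per-variant allele frequencies.
#' @param h2_female,h2_male Liability-scale heritabilities of participation,
#'   each in [0, 1).
#' @param scenario `"sex_differential"` or `"sex_independent"`.
#' @param correlation Between-sex effect correlation in [-1, 1]; forced to 1
#'   under `sex_independent`.
#' @param causal_mask Index of participation-associated variants (default all).
#' @param seed Integer RNG seed.
#' @return List with `b_female`, `b_male` (length `length(mafs)`).
#' @export
draw_participation_effects <- function(mafs, h2_female, h2_male,
                                       scenario = c("sex_differential", "sex_independent"),
                                       correlation = 0,
                                       causal_mask = seq_along(mafs),
                                       seed = 1L) {
  scenario <- match.arg(scenario)
  for (h in c(h2_female, h2_male)) {
    stopifnot(is.numeric(h), length(h) == 1L, h >= 0, h < 1)
  }
  stopifnot(correlation >= -1, correlation <= 1)
  if (is.logical(causal_mask)) causal_mask <- which(causal_mask)
  if ((h2_female > 0 || h2_male > 0) && length(causal_mask) == 0L) {
    stop("nonzero participation heritability requires a non-empty causal_mask",
         call. = FALSE)
  }
  if (scenario == "sex_independent") {
    if (h2_female != h2_male) {
      stop("sex_independent requires h2_female == h2_male", call. = FALSE)
    }
    correlation <- 1
  }
  m <- length(mafs)
  k <- length(causal_mask)
  set.seed(derive_seed(seed, 6L))
  u1 <- stats::rnorm(k)
  u2 <- if (correlation == 1) u1 else {
    correlation * u1 + sqrt(1 - correlation^2) * stats::rnorm(k)
  }
  scale_to <- function(u, h2) {
    b <- numeric(m)
    if (h2 > 0) {
      raw <- u / sqrt(dosage_var(mafs[causal_mask]))
      v_target <- h2 / (1 - h2) * LOGISTIC_VAR
      v_raw <- sum(dosage_var(mafs[causal_mask]) * raw^2)
      b[causal_mask] <- raw * sqrt(v_target / v_raw)
    }
    b
  }
  b_f <- scale_to(u1, h2_female)
  b_m <- if (scenario == "sex_independent") b_f else scale_to(u2, h2_male)
  list(b_female = b_f, b_male = b_m)
}

#' Participation model
#'
#' The logit participation model: individual i of sex s participates with
#' probability \eqn{\mathrm{expit}(\alpha_s + \sum_j b_{s,j}(g_{ij} - 2p_j)
#' + \sum_t \gamma_{s,t} x_{it})}. Per-sex intercepts \eqn{\alpha_s} are
#' solved by [calibrate_participation()] so the realized participation rates
#' hit their targets `pi_female`, `pi_male`.
#'
#' @param pi_female,pi_male Target participation rates in (0, 1].
#' @param b_female,b_male Per-variant logit-scale participation effects
#'   (defaults: none).
#' @param gamma_female,gamma_male Per-trait logit-scale participation
#'   effects (defaults: none).
#' @param h2_female,h2_male Liability-scale heritabilities the genetic
#'   effects were drawn at (bookkeeping; optional).
#' @param scenario Scenario label; `"sex_independent"` asserts elementwise
#'   equality of the per-sex effect vectors.
#' @return Object of class `participation_model` (uncalibrated:
#'   `alpha_female`/`alpha_male` are `NA` until calibration).
#' @export
participation_model <- function(pi_female, pi_male = pi_female,
                                b_female = numeric(0), b_male = numeric(0),
                                gamma_female = numeric(0), gamma_male = numeric(0),
                                h2_female = NA_real_, h2_male = NA_real_,
                                scenario = c("sex_differential", "sex_independent")) {
  scenario <- match.arg(scenario)
  check_prob(pi_female, "pi_female", hi_open = FALSE)
  check_prob(pi_male, "pi_male", hi_open = FALSE)
  stopifnot(length(b_female) == length(b_male),
            length(gamma_female) == length(gamma_male))
  if (scenario == "sex_independent" &&
      (!isTRUE(all.equal(b_female, b_male)) ||
       !isTRUE(all.equal(gamma_female, gamma_male)))) {
    stop("sex_independent scenario requires identical effect vectors across sexes",
         call. = FALSE)
  }
  structure(
    list(pi_female = pi_female, pi_male = pi_male,
         alpha_female = NA_real_, alpha_male = NA_real_,
         b_female = b_female, b_male = b_male,
         gamma_female = gamma_female, gamma_male = gamma_male,
         h2_female = h2_female, h2_male = h2_male, scenario = scenario),
    class = "participation_model"
  )
}

#' @export
print.participation_model <- function(x, ...) {
  cat(sprintf(
    "<participation_model> scenario=%s, pi=(%.4g, %.4g), %d variant effect(s), %d trait effect(s), %s\n",
    x$scenario, x$pi_female, x$pi_male, length(x$b_female), length(x$gamma_female),
    if (is.na(x$alpha_female)) "uncalibrated"
    else sprintf("alpha=(%.4g, %.4g)", x$alpha_female, x$alpha_male)
  ))
  invisible(x)
}

#' Solve a logit intercept for a target participation rate
#'
#' Finds alpha such that `mean(plogis(alpha + eta)) == pi` over the supplied
#' linear-predictor sample, by monotone bracketing root-finding
#' (deterministic given inputs). `pi = 1` returns `Inf` (everyone
#' participates).
#'
#' @param eta Numeric sample of the genetic+trait linear predictor.
#' @param pi Target rate in (0, 1].
#' @param tolerance Absolute tolerance on the achieved rate (default 1e-4).
#' @return The intercept alpha.
#' @export
calibrate_intercept <- function(eta, pi, tolerance = 1e-4) {
  check_prob(pi, "pi", hi_open = FALSE)
  stopifnot(all(is.finite(eta)), tolerance > 0)
  if (pi == 1) return(Inf)
  if (diff(range(eta)) == 0) return(stats::qlogis(pi) - eta[1])
  f <- function(a) mean(stats::plogis(a + eta)) - pi
  lo <- stats::qlogis(pi) - max(eta)
  hi <- stats::qlogis(pi) - min(eta)
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf("failed to bracket intercept for pi=%g (f(lo)=%.3g, f(hi)=%.3g)",
                 pi, f(lo), f(hi)), call. = FALSE)
  }
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(f(alpha)) > tolerance) {
    stop(sprintf("calibration missed target rate by %.3g (> tolerance %g)",
                 abs(f(alpha)), tolerance), call. = FALSE)
  }
  alpha
}

# internal: per-individual linear predictor using each individual's own sex's
# effects; genotype dosages mean-centered at 2*maf
participation_eta <- function(cohort, model) {
  n <- length(cohort$sex)
  eta <- numeric(n)
  male <- cohort$sex == 1L
  gc_ <- sweep(cohort$genotypes, 2L, 2 * cohort$maf)
  if (length(model$b_female)) {
    stopifnot(ncol(gc_) == length(model$b_female))
    eta[!male] <- drop(gc_[!male, , drop = FALSE] %*% model$b_female)
    eta[male] <- drop(gc_[male, , drop = FALSE] %*% model$b_male)
  }
  if (length(model$gamma_female)) {
    stopifnot(ncol(cohort$traits) == length(model$gamma_female))
    eta[!male] <- eta[!male] +
      drop(cohort$traits[!male, , drop = FALSE] %*% model$gamma_female)
    eta[male] <- eta[male] +
      drop(cohort$traits[male, , drop = FALSE] %*% model$gamma_male)
  }
  eta
}

#' Calibrate per-sex intercepts against a cohort
#'
#' Computes each sex's linear predictors in `cohort` and solves the two
#' intercepts so the expected participation rates equal the model's targets
#' (Monte-Carlo root finding on the simulated predictors, so calibration is
#' exact for the population at hand whatever the effect distribution).
#'
#' Under the `sex_independent` scenario with equal target rates the model
#' has a single intercept by construction, so calibration is pooled across
#' sexes and both alphas are set exactly equal (the configuration in which
#' the post-selection sex-genotype association vanishes identically).
#'
#' @param model A [participation_model()].
#' @param cohort A `cohort`.
#' @param tolerance Absolute rate tolerance (default 1e-4).
#' @return The model with `alpha_female`, `alpha_male` filled in.
#' @export
calibrate_participation <- function(model, cohort, tolerance = 1e-4) {
  stopifnot(inherits(model, "participation_model"), inherits(cohort, "cohort"))
  eta <- participation_eta(cohort, model)
  male <- cohort$sex == 1L
  if (model$scenario == "sex_independent" && model$pi_female == model$pi_male) {
    a <- calibrate_intercept(eta, model$pi_female, tolerance)
    model$alpha_female <- model$alpha_male <- a
  } else {
    model$alpha_female <- calibrate_intercept(eta[!male], model$pi_female, tolerance)
    model$alpha_male <- calibrate_intercept(eta[male], model$pi_male, tolerance)
  }
  model
}

#' Simulate study participation
#'
#' Draws the participation indicator under the calibrated logit model and
#' attaches it to the cohort. Equivalently (the liability view): individual
#' i participates iff \eqn{\alpha_s + \eta_i + \epsilon_i > 0} with
#' \eqn{\epsilon_i} standard logistic.
#'
#' @param cohort A `cohort`.
#' @param model A calibrated [participation_model()].
#' @param seed Integer RNG seed.
#' @return The cohort with `$participation` set and `$participation_summary`
#'   holding realized per-sex rates, their male-minus-female difference, and
#'   per-variant marginal participation effects per sex on the probability
#'   scale (logit coefficient times the mean of p(1-p) within the sex).
#' @export
simulate_participation <- function(cohort, model, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), inherits(model, "participation_model"))
  if (is.na(model$alpha_female) || is.na(model$alpha_male)) {
    stop("participation model is not calibrated; run calibrate_participation() first",
         call. = FALSE)
  }
  male <- cohort$sex == 1L
  eta <- participation_eta(cohort, model)
  p <- stats::plogis(ifelse(male, model$alpha_male, model$alpha_female) + eta)
  set.seed(derive_seed(seed, 7L))
  part <- stats::rbinom(length(p), 1L, p)
  rate_f <- mean(part[!male])
  rate_m <- mean(part[male])
  deriv_f <- mean(p[!male] * (1 - p[!male]))
  deriv_m <- mean(p[male] * (1 - p[male]))
  cohort$participation <- part
  cohort$participation_summary <- list(
    realized_rate_female = rate_f,
    realized_rate_male = rate_m,
    rate_difference = rate_m - rate_f,
    marginal_effects_female = if (length(model$b_female)) model$b_female * deriv_f else numeric(0),
    marginal_effects_male = if (length(model$b_male)) model$b_male * deriv_m else numeric(0)
  )
  cohort
}

#' Restrict a cohort to its participants
#'
#' @param cohort A `cohort` with a participation indicator.
#' @return A `cohort` containing only participating individuals (the
#'   participation summary is carried over).
#' @export
participants <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort[["participation"]])) {
    stop("cohort has no participation indicator", call. = FALSE)
  }
  keep <- cohort$participation == 1L
  out <- cohort
  out$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  out$sex <- cohort$sex[keep]
  out$traits <- cohort$traits[keep, , drop = FALSE]
  out$participation <- cohort$participation[keep]
  out
}

#' Liability-scale heritability implied by an effect vector
#'
#' \eqn{h^2 = V/(V + \pi^2/3)} with \eqn{V = \sum_j 2p_j(1-p_j) b_j^2}
#' computed analytically from allele frequencies, i.e. the heritability of
#' participation on the logistic liability scale.
#'
#' @param effects Logit-scale per-variant effects.
#' @param mafs Allele frequencies.
#' @return A single number in [0, 1).
#' @export
liability_h2 <- function(effects, mafs) {
  v <- genetic_variance(effects, mafs)
  v / (v + LOGISTIC_VAR)
}
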