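# Per-variant association engine on the participant subsample.
#
# Every fit is a plain ML logistic (IRLS via glm.fit) or OLS regression of
# the outcome on allele dosage plus covariates, reported with Wald
# statistics. Variants that cannot support a stable Wald test are flagged,
# never silently dropped; inflation summaries use only clean fits.

GWAS_COLUMNS <- c("variant_id", "beta", "se", "chi2", "p", "n", "stratum",
                  "outcome", "flag")

gwas_row <- function(variant_id, beta, se, n, stratum, outcome, flag = "ok") {
  chi2 <- (beta / se)^2
  data.frame(
    variant_id = variant_id, beta = beta, se = se, chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    n = n, stratum = stratum, outcome = outcome, flag = flag,
    stringsAsFactors = FALSE
  )
}

na_row <- function(variant_id, n, stratum, outcome, flag) {
  data.frame(
    variant_id = variant_id, beta = NA_real_, se = NA_real_, chi2 = NA_real_,
    p = NA_real_, n = n, stratum = stratum, outcome = outcome, flag = flag,
    stringsAsFactors = FALSE
  )
}

# internal: se of the dosage coefficient (column 2) from a glm.fit/lm.fit qr,
# respecting pivoting; scale = dispersion (1 for logistic, sigma^2 for OLS)
coef_se2 <- function(fit, scale = 1) {
  r <- fit$rank
  Rm <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  covmat <- chol2inv(Rm) * scale
  pos <- which(fit$qr$pivot[seq_len(r)] == 2L)
  if (!length(pos)) return(NA_real_)
  covmat[pos, pos]
}

#' Per-variant logistic GWAS
#'
#' Maximum-likelihood logistic regression of a binary outcome on each
#' variant's allele dosage (plus optional covariates), one fit per variant,
#' reporting the Wald effect, standard error, chi-squared and p-value.
#' Monomorphic variants, fits that fail to converge and (quasi-)separated
#' fits are flagged with `NA` statistics; variants with any
#' genotype-by-outcome cell below `min_count` keep their estimates but are
#' flagged `low_count` and excluded from inflation summaries.
#'
#' @param outcome Binary 0/1 vector.
#' @param genotypes Dosage matrix (individuals x variants).
#' @param covariates Optional numeric matrix/vector of covariates.
#' @param min_count Minimum count per genotype-by-outcome cell (default 5).
#' @param variant_ids Variant labels (default from column names).
#' @param stratum,outcome_label Labels copied into the result.
#' @param tol,max_iter IRLS convergence tolerance and iteration cap.
#' @return A data.frame with columns
#'   `variant_id, beta, se, chi2, p, n, stratum, outcome, flag`.
#' @export
logistic_gwas <- function(outcome, genotypes, covariates = NULL, min_count = 5,
                          variant_ids = NULL, stratum = "combined",
                          outcome_label = "outcome", tol = 1e-8, max_iter = 50) {
  genotypes <- as.matrix(genotypes)
  stopifnot(all(outcome %in% 0:1), length(outcome) == nrow(genotypes))
  n <- length(outcome)
  m <- ncol(genotypes)
  variant_ids <- variant_ids %||% colnames(genotypes) %||% paste0("v", seq_len(m))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  fam <- stats::binomial()
  ctrl <- list(epsilon = tol, maxit = max_iter, trace = FALSE)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    if (length(unique(g)) < 2L) {
      out[[j]] <- na_row(variant_ids[j], n, stratum, outcome_label, "monomorphic")
      next
    }
    X <- cbind(`(Intercept)` = 1, g = g, covariates)
    fit <- suppressWarnings(stats::glm.fit(X, outcome, family = fam, control = ctrl))
    flag <- "ok"
    if (min(table(g, outcome)) < min_count) flag <- "low_count"
    beta <- unname(fit$coefficients["g"])
    se2 <- coef_se2(fit)
    bad <- !fit$converged || is.na(beta) || is.na(se2) || se2 <= 0 ||
      abs(beta) > 12 || sqrt(se2) > 50
    if (bad) {
      reason <- if (!fit$converged) "not_converged" else "separation"
      out[[j]] <- na_row(variant_ids[j], n, stratum, outcome_label, reason)
    } else {
      out[[j]] <- gwas_row(variant_ids[j], beta, sqrt(se2), n, stratum,
                           outcome_label, flag)
    }
  }
  do.call(rbind, out)
}

#' Per-variant linear (OLS) GWAS
#'
#' Ordinary least squares of a numeric outcome on each variant's dosage plus
#' covariates, with Wald statistics. Useful for continuous outcomes and as a
#' linear-probability fallback for binary ones.
#'
#' @inheritParams logistic_gwas
#' @param outcome Finite numeric vector with nonzero variance.
#' @return A GWAS result data.frame (see [logistic_gwas()]).
#' @export
linear_gwas <- function(outcome, genotypes, covariates = NULL,
                        variant_ids = NULL, stratum = "combined",
                        outcome_label = "outcome") {
  genotypes <- as.matrix(genotypes)
  stopifnot(all(is.finite(outcome)), length(outcome) == nrow(genotypes))
  if (stats::var(outcome) == 0) {
    stop("outcome has zero variance", call. = FALSE)
  }
  n <- length(outcome)
  m <- ncol(genotypes)
  variant_ids <- variant_ids %||% colnames(genotypes) %||% paste0("v", seq_len(m))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    if (length(unique(g)) < 2L) {
      out[[j]] <- na_row(variant_ids[j], n, stratum, outcome_label, "monomorphic")
      next
    }
    X <- cbind(`(Intercept)` = 1, g = g, covariates)
    fit <- stats::lm.fit(X, outcome)
    df <- n - fit$rank
    rss <- sum(fit$residuals^2)
    beta <- unname(fit$coefficients["g"])
    if (df <= 0 || rss < 1e-12 * max(1, sum(outcome^2))) {
      # perfect (or saturated) fit: se -> 0 limit
      out[[j]] <- gwas_row(variant_ids[j], beta, 0, n, stratum, outcome_label,
                           "zero_residual")
      out[[j]]$p <- 0
      next
    }
    se2 <- coef_se2(fit, scale = rss / df)
    if (is.na(beta) || is.na(se2) || se2 <= 0) {
      out[[j]] <- na_row(variant_ids[j], n, stratum, outcome_label, "rank_deficient")
    } else {
      out[[j]] <- gwas_row(variant_ids[j], beta, sqrt(se2), n, stratum, outcome_label)
    }
  }
  do.call(rbind, out)
}

#' Mean chi-squared inflation summary
#'
#' The observed-over-expected mean chi-squared of a GWAS result set: under a
#' global null the per-variant Wald chi-squared has expectation 1, so the
#' ratio is a direct readout of participation-induced (collider) inflation.
#' Only cleanly estimated variants (`flag == "ok"`) enter.
#'
#' @param results A GWAS result data.frame.
#' @return List with `mean_chi2`, `expected_chi2` (1), `ratio`, `n_variants`.
#' @export
inflation_summary <- function(results) {
  ok <- results$flag == "ok" & is.finite(results$chi2)
  mean_chi2 <- mean(results$chi2[ok])
  list(mean_chi2 = mean_chi2, expected_chi2 = 1, ratio = mean_chi2 / 1,
       n_variants = sum(ok))
}

#' Sex GWAS on the participant subsample
#'
#' Logistic regression of biological sex (1 = male) on each variant's dosage
#' among participants, with no covariates. Autosomal variants have no causal
#' effect on sex, so any systematic inflation of the mean chi-squared above
#' 1 measures participation bias.
#'
#' @param cohort A `cohort` with a participation indicator (the analysis is
#'   restricted to participants internally).
#' @param min_count Passed to [logistic_gwas()].
#' @return List with `results` (GWAS data.frame, outcome `"sex"`) and
#'   `inflation` (see [inflation_summary()]).
#' @export
run_sex_gwas <- function(cohort, min_count = 5) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort[["participation"]])) {
    stop("cohort has no participation indicator; run simulate_participation()",
         call. = FALSE)
  }
  part <- participants(cohort)
  if (length(unique(part$sex)) < 2L) {
    stop("participant set contains a single sex; sex GWAS is undefined",
         call. = FALSE)
  }
  res <- logistic_gwas(part$sex, part$genotypes, min_count = min_count,
                       stratum = "combined", outcome_label = "sex")
  list(results = res, inflation = inflation_summary(res))
}

#' Trait GWAS on the participant subsample, combined or sex-stratified
#'
#' `mode = "combined"` fits one logistic regression per variant on all
#' participants (with sex as a covariate by default); `mode = "stratified"`
#' fits separately within females and within males and returns both result
#' sets (strata `"female"` and `"male"`), ready for
#' [meta_analyze()]. A stratum smaller than `min_stratum` is flagged
#' `small_stratum` rather than fitted.
#'
#' @param cohort A `cohort` with participation simulated.
#' @param trait Trait column index or name (default 1).
#' @param mode `"combined"` or `"stratified"`.
#' @param sex_covariate Include sex as a covariate in the combined fit
#'   (default TRUE).
#' @param min_count Passed to [logistic_gwas()].
#' @param min_stratum Minimum per-stratum sample size (default 30).
#' @return A GWAS result data.frame.
#' @export
run_trait_gwas <- function(cohort, trait = 1L,
                           mode = c("combined", "stratified"),
                           sex_covariate = TRUE, min_count = 5,
                           min_stratum = 30L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort[["participation"]])) {
    stop("cohort has no participation indicator; run simulate_participation()",
         call. = FALSE)
  }
  part <- participants(cohort)
  y <- part$traits[, trait]
  label <- if (is.character(trait)) trait else
    (colnames(part$traits)[trait] %||% paste0("trait", trait))
  if (mode == "combined") {
    covs <- if (sex_covariate) cbind(sex = part$sex) else NULL
    return(logistic_gwas(y, part$genotypes, covariates = covs,
                         min_count = min_count, stratum = "combined",
                         outcome_label = label))
  }
  pieces <- lapply(c(female = 0L, male = 1L), function(s) {
    keep <- part$sex == s
    sname <- if (s == 0L) "female" else "male"
    if (sum(keep) < min_stratum) {
      ids <- colnames(part$genotypes) %||% paste0("v", seq_len(ncol(part$genotypes)))
      return(na_row(ids, sum(keep), sname, label, "small_stratum"))
    }
    logistic_gwas(y[keep], part$genotypes[keep, , drop = FALSE],
                  min_count = min_count, stratum = sname, outcome_label = label)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write / read GWAS summary statistics as TSV
#'
#' Tab-separated interchange format with header
#' `variant_id beta se chi2 p n stratum outcome flag`. Numeric columns are
#' written with 17 significant digits so the round trip is bit-exact.
#'
#' @param results GWAS result data.frame.
#' @param path File path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats`
#'   returns the data.frame.
#' @export
write_sumstats <- function(results, path) {
  stopifnot(all(GWAS_COLUMNS %in% names(results)))
  df <- results[, GWAS_COLUMNS]
  for (col in c("beta", "se", "chi2", "p")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(
    path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = c(variant_id = "character", beta = "numeric", se = "numeric",
                   chi2 = "numeric", p = "numeric", n = "integer",
                   stratum = "character", outcome = "character",
                   flag = "character")
  )
  df
}
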