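# Evidence combination on summary statistics. The correction studied here is
# deliberately simple: run the GWAS within each sex, then pool the two
# estimates with fixed-effects inverse-variance weights. Information is
# never discarded (se_meta <= min stratum se), and with a single usable
# stratum the meta result reduces to that stratum's estimate exactly.

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-stratum estimates with weights \eqn{w_s = 1/se_s^2}:
#' \eqn{\hat\beta = \sum_s w_s \beta_s / \sum_s w_s},
#' \eqn{se = (\sum_s w_s)^{-1/2}}. Vectorized over variants; accepts any
#' number of strata (columns), so the same operation serves stratifications
#' of multi-valued variables. `NA` entries mark missing strata.
#'
#' @param beta Matrix of estimates (variants x strata), or a vector of one
#'   estimate per stratum for a single variant.
#' @param se Matching matrix/vector of standard errors (all positive where
#'   not `NA`).
#' @return A data.frame with `beta_meta`, `se_meta`, `chi2`, `p`,
#'   `n_strata` (contributing strata) and `strata` (comma-separated labels).
#'   Variants with no usable stratum get `NA` estimates.
#' @export
fixed_effects_meta <- function(beta, se) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  if (is.null(dim(se))) se <- matrix(se, nrow = 1)
  stopifnot(all(dim(beta) == dim(se)))
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive", call. = FALSE)
  labels <- colnames(beta) %||% paste0("s", seq_len(ncol(beta)))
  w <- 1 / se^2
  use <- is.finite(beta) & is.finite(w)
  w[!use] <- NA
  wsum <- rowSums(w, na.rm = TRUE)
  bsum <- rowSums(w * beta, na.rm = TRUE)
  n_strata <- rowSums(use)
  beta_meta <- ifelse(n_strata > 0, bsum / wsum, NA_real_)
  se_meta <- ifelse(n_strata > 0, 1 / sqrt(wsum), NA_real_)
  chi2 <- (beta_meta / se_meta)^2
  data.frame(
    beta_meta = beta_meta, se_meta = se_meta, chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    n_strata = n_strata,
    strata = vapply(seq_len(nrow(beta)), function(i) {
      paste(labels[use[i, ]], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Meta-analyze sex-stratified GWAS summary statistics
#'
#' Takes a stratified GWAS result table (as produced by
#' [run_trait_gwas()] with `mode = "stratified"`, or read back via
#' [read_sumstats()]), groups rows by variant, and applies
#' [fixed_effects_meta()] across strata. Flagged stratum results count as
#' missing; a variant with no clean stratum is emitted flagged `"missing"`.
#'
#' @param stratified GWAS result data.frame containing >= 1 stratum.
#' @return A GWAS-format data.frame with `stratum = "meta"` (so it can be
#'   written with [write_sumstats()] and fed to [mr_ivw()] like any other
#'   result set).
#' @export
meta_analyze <- function(stratified) {
  stopifnot(all(c("variant_id", "beta", "se", "stratum", "flag") %in% names(stratified)))
  ids <- unique(stratified$variant_id)
  strata <- unique(stratified$stratum)
  get <- function(col) {
    m <- matrix(NA_real_, length(ids), length(strata),
                dimnames = list(ids, strata))
    ok <- stratified$flag == "ok"
    m[cbind(match(stratified$variant_id[ok], ids),
            match(stratified$stratum[ok], strata))] <- stratified[[col]][ok]
    m
  }
  meta <- fixed_effects_meta(get("beta"), get("se"))
  nmat <- get("n")
  out <- data.frame(
    variant_id = ids, beta = meta$beta_meta, se = meta$se_meta,
    chi2 = meta$chi2, p = meta$p,
    n = as.integer(round(rowSums(nmat, na.rm = TRUE))),
    stratum = "meta",
    outcome = stratified$outcome[match(ids, stratified$variant_id)],
    flag = ifelse(meta$n_strata > 0, "ok", "missing"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' The standard MR-IVW estimator: a zero-intercept regression of
#' outcome-GWAS effects on exposure-GWAS effects across instruments, with
#' first-order weights \eqn{1/se_{Y,k}^2} (exposure-side uncertainty
#' ignored, no random-effects scaling):
#' \deqn{\hat\theta = \frac{\sum_k \beta_{X,k}\beta_{Y,k}/se_{Y,k}^2}
#'                         {\sum_k \beta_{X,k}^2/se_{Y,k}^2},\qquad
#'       se(\hat\theta) = \Big(\sum_k \beta_{X,k}^2/se_{Y,k}^2\Big)^{-1/2}.}
#' With one instrument this is the Wald ratio. Cochran's Q over the
#' per-instrument Wald ratios is reported as a heterogeneity diagnostic.
#'
#' @param beta_exposure,beta_outcome Per-instrument effect estimates.
#' @param se_outcome Per-instrument outcome standard errors (positive).
#' @param source Provenance label stored in the result (e.g. `"combined"`
#'   or `"stratified_meta"`).
#' @return An object of class `mr_result`: list with `estimate`, `se`, `p`,
#'   `n_instruments`, `Q`, `source`.
#' @export
mr_ivw <- function(beta_exposure, beta_outcome, se_outcome,
                   source = "combined") {
  stopifnot(length(beta_exposure) == length(beta_outcome),
            length(beta_outcome) == length(se_outcome))
  use <- is.finite(beta_exposure) & is.finite(beta_outcome) &
    is.finite(se_outcome) & se_outcome > 0
  bx <- beta_exposure[use]
  by <- beta_outcome[use]
  sy <- se_outcome[use]
  if (!length(bx) || all(bx == 0)) {
    stop("MR-IVW requires at least one instrument with a nonzero exposure effect",
         call. = FALSE)
  }
  w <- 1 / sy^2
  denom <- sum(bx^2 * w)
  estimate <- sum(bx * by * w) / denom
  se <- 1 / sqrt(denom)
  z2 <- (estimate / se)^2
  q <- sum(w * (by - estimate * bx)^2)
  structure(
    list(estimate = estimate, se = se,
         p = stats::pchisq(z2, df = 1, lower.tail = FALSE),
         n_instruments = length(bx), Q = q, source = source),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result> source=%s: estimate=%.4g (se %.4g, p %.3g), %d instrument(s), Q=%.3g\n",
    x$source, x$estimate, x$se, x$p, x$n_instruments, x$Q
  ))
  invisible(x)
}

#' Serialize MR results to JSON records
#'
#' @param results An `mr_result` or list of them.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON text (invisibly when written to file).
#' @export
mr_to_json <- function(results, path = NULL) {
  if (inherits(results, "mr_result")) results <- list(results)
  recs <- lapply(results, function(r) {
    r[c("estimate", "se", "p", "n_instruments", "source")]
  })
  txt <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
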