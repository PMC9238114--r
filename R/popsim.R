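#' Population configuration
#'
#' Describes the simulated target (pre-selection) population: its size, the
#' number of unlinked biallelic variants, their minor allele frequencies and
#' the sex composition. Genotypes are minor-allele dosages drawn under
#' Hardy-Weinberg equilibrium; variants are unlinked (no LD), since the bias
#' mechanism studied here is marginal and per-variant.
#'
#' @param n_individuals Positive integer, population size.
#' @param n_variants Positive integer, number of variants.
#' @param maf Either a single allele frequency, a vector of length
#'   `n_variants`, or a length-2 range `c(lo, hi)` from which per-variant
#'   frequencies are drawn uniformly. All frequencies must lie in (0, 0.5].
#' @param male_fraction Probability that an individual is male, in (0, 1).
#' @param seed Integer RNG seed.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_individuals, n_variants, maf = 0.3,
                              male_fraction = 0.5, seed = 1L) {
  stopifnot(
    length(n_individuals) == 1L, n_individuals >= 1, n_individuals == round(n_individuals),
    length(n_variants) == 1L, n_variants >= 1, n_variants == round(n_variants)
  )
  check_prob(male_fraction, "male_fraction")
  if (length(maf) == 2L && n_variants != 2L) {
    check_prob(maf, "maf range", hi = 0.5, hi_open = FALSE)
    set.seed(derive_seed(seed, 104729L))
    maf <- stats::runif(n_variants, maf[1], maf[2])
  } else if (length(maf) == 1L) {
    maf <- rep(maf, n_variants)
  }
  if (length(maf) != n_variants) {
    stop("`maf` must be a scalar, a range, or one value per variant", call. = FALSE)
  }
  check_prob(maf, "maf", hi = 0.5, hi_open = FALSE)
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_variants = as.integer(n_variants),
      maf = maf, male_fraction = male_fraction, seed = as.integer(seed)
    ),
    class = "population_config"
  )
}

#' Simulate HWE genotype dosages
#'
#' Each column j is drawn i.i.d. Binomial(2, maf_j) across individuals:
#' unlinked variants in Hardy-Weinberg equilibrium, coded as minor-allele
#' counts 0/1/2.
#'
#' @param config A [population_config()].
#' @return An `n_individuals x n_variants` integer matrix with column names
#'   `v1, v2, ...`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_individuals
  m <- config$n_variants
  set.seed(derive_seed(config$seed, 1L))
  g <- matrix(
    stats::rbinom(n * m, 2L, rep(config$maf, each = n)),
    nrow = n, ncol = m, dimnames = list(NULL, paste0("v", seq_len(m)))
  )
  g
}

#' Trait architecture: per-variant liability effects at a target heritability
#'
#' Draws additive effect sizes for a liability-threshold binary trait.
#' Effects are drawn i.i.d. normal on the standardized-genotype scale for the
#' variants in `causal_mask`, then rescaled so that the analytic genetic
#' liability variance \eqn{\sum_j 2 p_j (1-p_j) b_j^2} equals `h2_liability`
#' exactly (not just in expectation); the environmental liability variance is
#' then `1 - h2_liability`. Variants outside the mask get effect exactly 0.
#'
#' @param mafs Per-variant allele frequencies.
#' @param h2_liability Liability-scale heritability in [0, 1).
#' @param prevalence Trait prevalence K in (0, 1).
#' @param causal_mask Integer or logical index of causal variants; must be
#'   non-empty when `h2_liability > 0`. Default: all variants.
#' @param seed Integer RNG seed.
#' @return An object of class `trait_architecture` with fields `effects`
#'   (length `length(mafs)`), `h2_liability`, `prevalence`, `causal_mask`,
#'   `mafs`.
#' @export
trait_architecture <- function(mafs, h2_liability, prevalence,
                               causal_mask = seq_along(mafs), seed = 1L) {
  stopifnot(is.numeric(h2_liability), length(h2_liability) == 1L,
            h2_liability >= 0, h2_liability < 1)
  check_prob(prevalence, "prevalence")
  if (is.logical(causal_mask)) causal_mask <- which(causal_mask)
  if (h2_liability > 0 && length(causal_mask) == 0L) {
    stop("h2_liability > 0 requires a non-empty causal_mask", call. = FALSE)
  }
  effects <- numeric(length(mafs))
  if (h2_liability > 0) {
    set.seed(derive_seed(seed, 2L))
    u <- stats::rnorm(length(causal_mask))
    b <- u / sqrt(dosage_var(mafs[causal_mask]))
    v <- sum(dosage_var(mafs[causal_mask]) * b^2)
    effects[causal_mask] <- b * sqrt(h2_liability / v)
  }
  structure(
    list(effects = effects, h2_liability = h2_liability,
         prevalence = prevalence, causal_mask = causal_mask, mafs = mafs),
    class = "trait_architecture"
  )
}

#' Analytic genetic variance of an effect vector
#'
#' \eqn{\sum_j 2 p_j (1-p_j) b_j^2}: the population variance of the genetic
#' liability component under HWE, computed from allele frequencies rather
#' than a genotype sample.
#'
#' @param effects Per-variant effect sizes (per dosage unit).
#' @param mafs Per-variant allele frequencies.
#' @return A single number.
#' @export
genetic_variance <- function(effects, mafs) {
  stopifnot(length(effects) == length(mafs))
  sum(dosage_var(mafs) * effects^2)
}

#' Simulate a liability-threshold binary trait
#'
#' Liability \eqn{L_i = \sum_j b_j (g_{ij} - 2 p_j) + e_i} with Gaussian
#' noise \eqn{e_i \sim N(0, 1 - h^2)}; the trait is 1 iff the liability
#' exceeds \eqn{\Phi^{-1}(1 - K)}. Dosages are mean-centered so the
#' threshold maps directly to the prevalence.
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param arch A [trait_architecture()].
#' @param seed Integer RNG seed.
#' @return Integer 0/1 vector of length `nrow(genotypes)`.
#' @export
simulate_binary_trait <- function(genotypes, arch, seed = 1L) {
  stopifnot(inherits(arch, "trait_architecture"),
            ncol(genotypes) == length(arch$effects))
  n <- nrow(genotypes)
  gc_ <- sweep(genotypes, 2L, 2 * arch$mafs)
  set.seed(derive_seed(seed, 3L))
  liability <- drop(gc_ %*% arch$effects) +
    stats::rnorm(n, 0, sqrt(1 - arch$h2_liability))
  as.integer(liability > stats::qnorm(1 - arch$prevalence))
}

#' Simulate a cohort: genotypes, sex and optional binary traits
#'
#' Bundles the population pieces into a `cohort` list, the container consumed
#' by the participation and association stages. Traits are appended as
#' columns of a 0/1 matrix; the participation indicator is absent until
#' [simulate_participation()] runs.
#'
#' @param config A [population_config()].
#' @param trait_archs Optional named list of [trait_architecture()] objects.
#' @return An object of class `cohort`: list with `genotypes`, `sex`
#'   (0 = female, 1 = male), `traits` (n x n_traits matrix, possibly
#'   0 columns), `maf`, `config`.
#' @export
simulate_cohort <- function(config, trait_archs = list()) {
  g <- simulate_genotypes(config)
  set.seed(derive_seed(config$seed, 4L))
  sex <- stats::rbinom(config$n_individuals, 1L, config$male_fraction)
  traits <- matrix(0L, config$n_individuals, 0L)
  if (length(trait_archs)) {
    traits <- vapply(
      seq_along(trait_archs),
      function(t) simulate_binary_trait(g, trait_archs[[t]],
                                        seed = derive_seed(config$seed, 5L, t)),
      integer(config$n_individuals)
    )
    colnames(traits) <- names(trait_archs) %||% paste0("trait", seq_along(trait_archs))
  }
  structure(
    list(genotypes = g, sex = sex, traits = traits,
         maf = config$maf, config = config, participation = NULL),
    class = "cohort"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d individuals, %d variants, %d trait(s); %s\n",
    nrow(x$genotypes), ncol(x$genotypes), ncol(x$traits),
    if (is.null(x$participation)) "participation not simulated"
    else sprintf("%d participants (%.2f%%)", sum(x$participation),
                 100 * mean(x$participation))
  ))
  invisible(x)
}

#' Write / read a cohort as plain TSV
#'
#' One row per individual: `sex`, trait columns, `participation` (if
#' present), then one integer dosage column per variant. The round trip is
#' exact because every stored value is a small integer.
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @return `write_cohort_tsv` returns `path` invisibly; `read_cohort_tsv`
#'   returns a `cohort` (with `config` reduced to the recoverable fields:
#'   MAFs are re-estimated from the stored dosages unless provided).
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- data.frame(sex = cohort$sex)
  if (ncol(cohort$traits)) df <- cbind(df, as.data.frame(cohort$traits))
  if (!is.null(cohort[["participation"]])) df$participation <- cohort$participation
  df <- cbind(df, as.data.frame(cohort$genotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @param maf Optional true allele frequencies to attach on read.
#' @export
read_cohort_tsv <- function(path, maf = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  vcols <- grep("^v[0-9]+$", names(df))
  g <- as.matrix(df[, vcols, drop = FALSE])
  storage.mode(g) <- "integer"
  part <- if ("participation" %in% names(df)) as.integer(df$participation) else NULL
  tcols <- setdiff(names(df), c("sex", "participation", colnames(g)))
  traits <- as.matrix(df[, tcols, drop = FALSE])
  storage.mode(traits) <- "integer"
  structure(
    list(genotypes = g, sex = as.integer(df$sex), traits = traits,
         maf = maf %||% colMeans(g) / 2, config = NULL, participation = part),
    class = "cohort"
  )
}
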