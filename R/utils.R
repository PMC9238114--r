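#' Deterministic seed derivation
#'
#' Derives a child RNG seed from a master seed and a sequence of integer
#' keys (cell index, replicate number, ...). The same `(master, keys)`
#' always yields the same child seed, and distinct keys yield distinct
#' streams for all practical purposes. Used by the experiment runners so
#' that every cell/replicate of a sweep is independently reproducible.
#'
#' @param master Integer master seed.
#' @param ... Integer keys identifying the sub-stream.
#' @return A single integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  keys <- c(...)
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483563 # < 2^31, prime; multiplier kept small so the product
  x <- (abs(master) %% m) # stays exactly representable in doubles
  for (k in c(keys, 0)) {
    stopifnot(is.finite(k))
    x <- (x * 7919 + abs(k) + 1) %% m
  }
  as.integer(x + 1)
}

# internal: scalar probability check
check_prob <- function(x, name, lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (lo_open) x > lo else x >= lo) &
    (if (hi_open) x < hi else x <= hi)
  if (!all(ok)) {
    stop(sprintf(
      "`%s` must lie in %s%g, %g%s; got %s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
      paste(format(x[!ok]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

# internal: 2*p*(1-p), the variance of a HWE dosage at allele frequency p
dosage_var <- function(maf) 2 * maf * (1 - maf)
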