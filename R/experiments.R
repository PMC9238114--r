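# Scenario sweeps: participation-rate grids for the sex GWAS, the
# stratify-then-meta correction, MR robustness, power at full participation,
# and the effect-difference slope. Each runner emits a tidy long-format
# table (one metric value per row) carrying the derived seed that
# reproduces it; reruns with the same config and master seed are
# bit-identical.

experiment_row <- function(scenario, pi_female, pi_male, h2_female, h2_male,
                           estimator, replicate, seed, metric, value) {
  data.frame(scenario = scenario, pi_female = pi_female, pi_male = pi_male,
             h2_female = h2_female, h2_male = h2_male, estimator = estimator,
             replicate = replicate, seed = seed, metric = metric,
             value = value, stringsAsFactors = FALSE)
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Default experiment configurations
#'
#' Returns the package's default configuration for one of the scenario
#' sweeps. All values can be overridden by the `config` argument of the
#' runner (a partial nested list) or via a YAML file read with
#' [read_config()]. The defaults describe a desk-scale study: 100,000
#' individuals, 1,000 variants of which 200 drive participation, 50
#' replicates.
#'
#' @param experiment One of `"pi_grid"`, `"correction"`, `"mr"`, `"power"`,
#'   `"slope"`.
#' @return A nested list.
#' @export
default_config <- function(experiment = c("pi_grid", "correction", "mr",
                                          "power", "slope")) {
  experiment <- match.arg(experiment)
  base <- list(
    population = list(n = 100000L, n_variants = 1000L, maf = c(0.1, 0.5),
                      male_fraction = 0.5),
    experiment = list(replicates = 50L, seed = 1L)
  )
  extra <- switch(experiment,
    pi_grid = list(participation = list(
      pi_grid = c(0.01, 0.05, 0.2, 1.0),
      h2_pairs = list(c(0.2, 0)),          # (h2_female, h2_male) per line
      scenarios = c("sex_differential", "sex_independent"),
      correlation = 0, n_participation_variants = 200L, rate_difference = 0
    )),
    correction = list(
      population = list(n = 200000L, n_variants = 50L, maf = c(0.2, 0.5)),
      participation = list(
        pi = 0.01, h2_female = 0, h2_male = 0.3,
        n_participation_variants = 20L,
        gamma_female = 0, gamma_male = 2
      ),
      trait = list(prevalence = 0.3, h2 = 0),
      gwas = list(sex_covariate = FALSE)
    ),
    mr = list(
      population = list(n = 100000L, n_variants = 80L, maf = c(0.2, 0.5)),
      participation = list(pi = 0.01,
                           gamma_female = c(0, 0), gamma_male = c(2, 2)),
      traits = list(
        exposure = list(prevalence = 0.3, h2 = 0.3, n_causal = 40L),
        outcome = list(prevalence = 0.3, h2 = 0.3, n_causal = 40L)
      ),
      gwas = list(sex_covariate = FALSE),
      experiment = list(replicates = 30L, seed = 1L)
    ),
    power = list(
      population = list(n = 3000L, n_variants = 8L, maf = 0.3),
      participation = list(pi = 1),
      trait = list(prevalence = 0.3, h2 = 0.056, n_causal = 8L),
      gwas = list(sex_covariate = TRUE, alpha = 5e-4),
      experiment = list(replicates = 500L, seed = 1L)
    ),
    slope = list(
      population = list(n = 1000000L, n_variants = 250L, maf = 0.3,
                        block_size = 50000L),
      participation = list(pi = 0.001, h2_female = 0.42, h2_male = 0.42,
                           correlation = 0)
    )
  )
  merge_config(base, extra)
}

#' Read a scenario configuration from YAML
#'
#' Reads a YAML file with (any subset of) `population`, `participation`,
#' `trait`/`traits`, `gwas` and `experiment` blocks and merges it over the
#' package defaults for the named experiment.
#'
#' @param path YAML file path.
#' @param experiment Experiment name (see [default_config()]).
#' @return A nested configuration list.
#' @export
read_config <- function(path, experiment = "pi_grid") {
  # keep YAML-1.1 boolean-like keys ("n", "y", ...) as literal strings while
  # still honouring spelled-out booleans as values
  as_bool <- function(x) {
    lx <- tolower(x)
    if (lx %in% c("true", "yes", "on")) return(TRUE)
    if (lx %in% c("false", "no", "off")) return(FALSE)
    x
  }
  raw <- yaml::yaml.load_file(path, handlers = list(`bool#yes` = as_bool,
                                                    `bool#no` = as_bool))
  merge_config(default_config(experiment), raw)
}

#' Participation-rate grid for the sex GWAS
#'
#' For every cell (scenario x participation rate x heritability pair):
#' draw per-sex participation effects, then over replicates simulate the
#' population, calibrate intercepts, draw participation and run the sex
#' GWAS, recording the mean chi-squared ratio. The exact enumeration
#' oracle's predicted ratio at matched parameters (per-variant
#' non-centralities, marginally calibrated) is emitted per cell as
#' estimator `"oracle"`, together with the Monte-Carlo/oracle discrepancy.
#'
#' Under `sex_independent` the heritability pair is collapsed to its first
#' element for both sexes (the scenario requires equal effects); the
#' `rate_difference` config entry shifts the male target rate.
#'
#' @param config Partial configuration list (see [default_config()]).
#' @return A long-format `data.frame` (scenario, pi, h2 pair, estimator,
#'   replicate, seed, metric, value).
#' @export
run_pi_grid <- function(config = list()) {
  cfg <- merge_config(default_config("pi_grid"), config)
  pop <- cfg$population
  par <- cfg$participation
  if (!length(par$pi_grid)) stop("empty participation-rate grid", call. = FALSE)
  master <- cfg$experiment$seed
  rows <- list()
  cell <- 0L
  for (scenario in par$scenarios) {
    for (h2_pair in par$h2_pairs) {
      h2_f <- h2_pair[1]
      h2_m <- if (scenario == "sex_independent") h2_pair[1] else h2_pair[2]
      for (pi in par$pi_grid) {
        cell <- cell + 1L
        pi_m <- min(pi + (par$rate_difference %||% 0), 1)
        cseed <- derive_seed(master, 11L, cell)
        mask <- seq_len(min(par$n_participation_variants, pop$n_variants))
        mafs <- population_config(pop$n, pop$n_variants, pop$maf,
                                  pop$male_fraction, seed = cseed)$maf
        eff <- draw_participation_effects(
          mafs, h2_f, h2_m, scenario = scenario,
          correlation = par$correlation, causal_mask = mask, seed = cseed
        )
        model <- participation_model(pi, pi_m, b_female = eff$b_female,
                                     b_male = eff$b_male, h2_female = h2_f,
                                     h2_male = h2_m, scenario = scenario)
        ratios <- numeric(cfg$experiment$replicates)
        for (r in seq_len(cfg$experiment$replicates)) {
          rseed <- derive_seed(master, 11L, cell, r)
          pcfg <- population_config(pop$n, pop$n_variants, mafs,
                                    pop$male_fraction, seed = rseed)
          coh <- simulate_cohort(pcfg)
          m <- calibrate_participation(model, coh)
          coh <- simulate_participation(coh, m, seed = rseed)
          ratios[r] <- run_sex_gwas(coh)$inflation$ratio
          rows[[length(rows) + 1L]] <- experiment_row(
            scenario, pi, pi_m, h2_f, h2_m, "sex_gwas", r, rseed,
            "mean_chi2_ratio", ratios[r]
          )
        }
        # oracle prediction: expected chi2 = 1 + per-participant nonc * N
        n_part <- pop$n * ((1 - pop$male_fraction) * pi + pop$male_fraction * pi_m)
        nonc <- vapply(mask, function(j) {
          al <- oracle_calibrate(mafs[j], eff$b_female[j], eff$b_male[j], pi, pi_m)
          exact_sex_effect_oracle(mafs[j], eff$b_female[j], eff$b_male[j],
                                  al$alpha_female, al$alpha_male,
                                  pop$male_fraction)$nonc_per_participant
        }, numeric(1))
        oracle_ratio <- 1 + sum(nonc) * n_part / pop$n_variants
        rows[[length(rows) + 1L]] <- experiment_row(
          scenario, pi, pi_m, h2_f, h2_m, "oracle", NA_integer_, cseed,
          "mean_chi2_ratio", oracle_ratio
        )
        rows[[length(rows) + 1L]] <- experiment_row(
          scenario, pi, pi_m, h2_f, h2_m, "oracle", NA_integer_, cseed,
          "mc_oracle_discrepancy", mean(ratios) - oracle_ratio
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: one correction-experiment replicate
correction_replicate <- function(cfg, rseed) {
  pop <- cfg$population
  par <- cfg$participation
  pcfg <- population_config(pop$n, pop$n_variants, pop$maf, pop$male_fraction,
                            seed = rseed)
  mask <- seq_len(par$n_participation_variants)
  arch <- trait_architecture(pcfg$maf, cfg$trait$h2, cfg$trait$prevalence,
                             causal_mask = if (cfg$trait$h2 > 0) mask else integer(0),
                             seed = rseed)
  coh <- simulate_cohort(pcfg, list(trait = arch))
  eff <- draw_participation_effects(pcfg$maf, par$h2_female, par$h2_male,
                                    scenario = "sex_differential",
                                    causal_mask = mask,
                                    seed = derive_seed(rseed, 21L))
  model <- participation_model(
    par$pi, par$pi, b_female = eff$b_female, b_male = eff$b_male,
    gamma_female = par$gamma_female, gamma_male = par$gamma_male,
    h2_female = par$h2_female, h2_male = par$h2_male
  )
  model <- calibrate_participation(model, coh)
  coh <- simulate_participation(coh, model, seed = rseed)
  combined <- run_trait_gwas(coh, 1L, "combined",
                             sex_covariate = cfg$gwas$sex_covariate)
  strat <- run_trait_gwas(coh, 1L, "stratified")
  meta <- meta_analyze(strat)
  keep <- paste0("v", mask)
  list(combined = combined[combined$variant_id %in% keep, ],
       stratified = strat[strat$variant_id %in% keep, ],
       meta = meta[meta$variant_id %in% keep, ])
}

#' Stratify-then-meta correction experiment
#'
#' Simulates a binary trait with no genetic effects whose value drives
#' participation sex-differentially, alongside variants that drive
#' participation sex-differentially. At those trait-null,
#' participation-associated variants it records the mean chi-squared of the
#' sex-combined GWAS, of each sex-stratified GWAS, and of the fixed-effects
#' meta-analysis of the strata, paired per replicate. Under sex-differential
#' participation the combined scan is inflated while stratified and meta
#' scans stay near the null expectation of 1.
#'
#' @param config Partial configuration list (see
#'   `default_config("correction")`). The combined GWAS runs without a sex
#'   covariate by default (`gwas$sex_covariate`); see the methods vignette
#'   for the rationale.
#' @return A long-format experiment `data.frame` with estimators
#'   `combined`, `stratified_f`, `stratified_m`, `meta` and metric
#'   `mean_chi2_ratio`.
#' @export
run_correction_experiment <- function(config = list()) {
  cfg <- merge_config(default_config("correction"), config)
  par <- cfg$participation
  master <- cfg$experiment$seed
  rows <- list()
  for (r in seq_len(cfg$experiment$replicates)) {
    rseed <- derive_seed(master, 22L, r)
    rep <- correction_replicate(cfg, rseed)
    vals <- c(
      combined = inflation_summary(rep$combined)$ratio,
      stratified_f = inflation_summary(
        rep$stratified[rep$stratified$stratum == "female", ])$ratio,
      stratified_m = inflation_summary(
        rep$stratified[rep$stratified$stratum == "male", ])$ratio,
      meta = inflation_summary(rep$meta)$ratio
    )
    for (est in names(vals)) {
      rows[[length(rows) + 1L]] <- experiment_row(
        "sex_differential", par$pi, par$pi, par$h2_female, par$h2_male,
        est, r, rseed, "mean_chi2_ratio", unname(vals[est])
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: one MR replicate; returns mr_result objects for both sources
mr_replicate <- function(cfg, rseed) {
  pop <- cfg$population
  tx <- cfg$traits$exposure
  ty <- cfg$traits$outcome
  stopifnot(tx$n_causal + ty$n_causal <= pop$n_variants)
  pcfg <- population_config(pop$n, pop$n_variants, pop$maf, pop$male_fraction,
                            seed = rseed)
  mask_x <- seq_len(tx$n_causal)
  mask_y <- tx$n_causal + seq_len(ty$n_causal)
  arch_x <- trait_architecture(pcfg$maf, tx$h2, tx$prevalence, mask_x,
                               seed = derive_seed(rseed, 31L))
  arch_y <- trait_architecture(pcfg$maf, ty$h2, ty$prevalence, mask_y,
                               seed = derive_seed(rseed, 32L))
  coh <- simulate_cohort(pcfg, list(exposure = arch_x, outcome = arch_y))
  model <- participation_model(
    cfg$participation$pi,
    gamma_female = cfg$participation$gamma_female,
    gamma_male = cfg$participation$gamma_male
  )
  model <- calibrate_participation(model, coh)
  coh <- simulate_participation(coh, model, seed = rseed)
  # instruments: the exposure's true causal variants (oracle instruments)
  inst <- participants(coh)
  inst$genotypes <- inst$genotypes[, mask_x, drop = FALSE]
  run_one <- function(trait) {
    comb <- run_trait_gwas(inst, trait, "combined",
                           sex_covariate = cfg$gwas$sex_covariate)
    meta <- meta_analyze(run_trait_gwas(inst, trait, "stratified"))
    list(combined = comb, meta = meta)
  }
  gx <- run_one("exposure")
  gy <- run_one("outcome")
  list(
    combined = mr_ivw(gx$combined$beta, gy$combined$beta, gy$combined$se,
                      source = "combined"),
    meta = mr_ivw(gx$meta$beta, gy$meta$beta, gy$meta$se,
                  source = "stratified_meta")
  )
}

#' MR robustness experiment
#'
#' Two causally independent binary traits (disjoint causal variants,
#' independent noise) both drive participation sex-differentially. MR-IVW of
#' the outcome on the exposure is estimated per replicate twice: from
#' sex-combined GWAS summary statistics and from sex-stratified,
#' meta-analyzed ones. The true causal effect is 0 by construction, so any
#' systematic displacement measures participation-induced bias.
#'
#' @param config Partial configuration list (see `default_config("mr")`).
#' @return A long-format experiment `data.frame` with estimators
#'   `mr_combined`, `mr_meta` and metrics `estimate`, `se`.
#' @export
run_mr_experiment <- function(config = list()) {
  cfg <- merge_config(default_config("mr"), config)
  master <- cfg$experiment$seed
  pi <- cfg$participation$pi
  rows <- list()
  for (r in seq_len(cfg$experiment$replicates)) {
    rseed <- derive_seed(master, 33L, r)
    rep <- mr_replicate(cfg, rseed)
    sources <- c(mr_combined = "combined", mr_meta = "meta")
    for (nm in names(sources)) {
      mr <- rep[[sources[[nm]]]]
      for (metric in c("estimate", "se")) {
        rows[[length(rows) + 1L]] <- experiment_row(
          "sex_differential", pi, pi, NA_real_, NA_real_, nm, r, rseed,
          metric, mr[[metric]]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Power experiment at full participation
#'
#' At participation rate 1 (a representative sample, no selection) a binary
#' trait with true causal variants is scanned by the sex-combined GWAS and
#' by the stratify-then-meta pipeline; empirical power at level `alpha`
#' is recorded per replicate for each, paired, together with their
#' difference. Equivalence of the two powers shows the correction costs
#' nothing when there is no bias to correct.
#'
#' @param config Partial configuration list (see `default_config("power")`).
#' @return A long-format experiment `data.frame` with estimators `combined`,
#'   `meta` (metric `power`) and `difference` (metric `power_difference`,
#'   combined minus meta).
#' @export
run_power_experiment <- function(config = list()) {
  cfg <- merge_config(default_config("power"), config)
  pop <- cfg$population
  tr <- cfg$trait
  alpha <- cfg$gwas$alpha
  master <- cfg$experiment$seed
  rows <- list()
  for (r in seq_len(cfg$experiment$replicates)) {
    rseed <- derive_seed(master, 44L, r)
    pcfg <- population_config(pop$n, pop$n_variants, pop$maf,
                              pop$male_fraction, seed = rseed)
    mask <- seq_len(tr$n_causal)
    arch <- trait_architecture(pcfg$maf, tr$h2, tr$prevalence, mask,
                               seed = derive_seed(rseed, 45L))
    coh <- simulate_cohort(pcfg, list(trait = arch))
    model <- participation_model(cfg$participation$pi)
    model <- calibrate_participation(model, coh)
    coh <- simulate_participation(coh, model, seed = rseed)
    comb <- run_trait_gwas(coh, 1L, "combined",
                           sex_covariate = cfg$gwas$sex_covariate)
    meta <- meta_analyze(run_trait_gwas(coh, 1L, "stratified"))
    keep <- paste0("v", mask)
    pow <- function(res) {
      res <- res[res$variant_id %in% keep & res$flag == "ok", ]
      mean(res$p < alpha)
    }
    p_comb <- pow(comb)
    p_meta <- pow(meta)
    vals <- c(combined = p_comb, meta = p_meta)
    for (est in names(vals)) {
      rows[[length(rows) + 1L]] <- experiment_row(
        "no_selection", 1, 1, NA_real_, NA_real_, est, r, rseed,
        "power", unname(vals[est])
      )
    }
    rows[[length(rows) + 1L]] <- experiment_row(
      "no_selection", 1, 1, NA_real_, NA_real_, "difference", r, rseed,
      "power_difference", p_comb - p_meta
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: stream a large population in blocks, keeping only participants.
# Intercepts are calibrated on the first block's linear predictors. Returns
# a participant-only cohort plus realized-rate bookkeeping.
simulate_participants_stream <- function(pcfg, model, seed,
                                         block_size = 50000L) {
  n_left <- pcfg$n_individuals
  block_id <- 0L
  keep_g <- list()
  keep_sex <- list()
  tot <- c(f = 0, m = 0)
  part <- c(f = 0, m = 0)
  while (n_left > 0L) {
    block_id <- block_id + 1L
    nb <- min(block_size, n_left)
    n_left <- n_left - nb
    bcfg <- population_config(nb, pcfg$n_variants, pcfg$maf,
                              pcfg$male_fraction,
                              seed = derive_seed(seed, 55L, block_id))
    coh <- simulate_cohort(bcfg)
    if (block_id == 1L) model <- calibrate_participation(model, coh)
    coh <- simulate_participation(coh, model,
                                  seed = derive_seed(seed, 56L, block_id))
    male <- coh$sex == 1L
    tot <- tot + c(sum(!male), sum(male))
    part <- part + c(sum(coh$participation[!male]), sum(coh$participation[male]))
    sel <- coh$participation == 1L
    keep_g[[block_id]] <- coh$genotypes[sel, , drop = FALSE]
    keep_sex[[block_id]] <- coh$sex[sel]
  }
  g <- do.call(rbind, keep_g)
  sex <- unlist(keep_sex)
  out <- structure(
    list(genotypes = g, sex = sex, traits = matrix(0L, length(sex), 0L),
         maf = pcfg$maf, config = pcfg, participation = rep(1L, length(sex))),
    class = "cohort"
  )
  list(cohort = out, model = model,
       realized_rate_female = part["f"] / tot["f"],
       realized_rate_male = part["m"] / tot["m"])
}

#' Effect-difference slope experiment
#'
#' Simulates a large population at a very low participation rate with
#' sex-differential per-variant participation effects, runs the sex GWAS on
#' the participants, and regresses the estimated per-variant sex effects on
#' the between-sex participation effect differences. On the log-odds scale
#' the rare-participation theory predicts slope 1. The same regression is
#' also run on the linear-probability scale (linear sex GWAS vs marginal
#' probability-scale effect differences), whose slope is reported alongside
#' the realized between-sex participation rate difference for comparison.
#'
#' @param config Partial configuration list (see `default_config("slope")`).
#' @return A long-format experiment `data.frame` with estimator
#'   `slope_regression` and metrics `slope_logit`, `slope_logit_ci_lo/hi`,
#'   `intercept_logit`, `slope_prob`, `rate_difference`,
#'   `n_participants`.
#' @export
run_slope_experiment <- function(config = list()) {
  cfg <- merge_config(default_config("slope"), config)
  pop <- cfg$population
  par <- cfg$participation
  master <- cfg$experiment$seed
  pcfg <- population_config(pop$n, pop$n_variants, pop$maf, pop$male_fraction,
                            seed = derive_seed(master, 66L))
  eff <- draw_participation_effects(
    pcfg$maf, par$h2_female, par$h2_male, scenario = "sex_differential",
    correlation = par$correlation, seed = derive_seed(master, 67L)
  )
  model <- participation_model(par$pi, par$pi, b_female = eff$b_female,
                               b_male = eff$b_male,
                               h2_female = par$h2_female, h2_male = par$h2_male)
  str <- simulate_participants_stream(pcfg, model, seed = master,
                                      block_size = pop$block_size %||% 50000L)
  coh <- str$cohort
  sg <- logistic_gwas(coh$sex, coh$genotypes, stratum = "combined",
                      outcome_label = "sex")
  bdiff <- rare_limit_sex_effect(eff$b_female, eff$b_male)
  fit_logit <- predicted_vs_estimated_slope(sg$beta, bdiff)
  # linear-probability scale: linear sex GWAS vs marginal effect differences
  lg <- linear_gwas(coh$sex, coh$genotypes, stratum = "combined",
                    outcome_label = "sex")
  # marginal probability-scale participation effects: logit effect times the
  # per-sex mean of p(1-p) at the calibrated intercepts (rare pi: ~ pi)
  d_f <- str$realized_rate_female * (1 - str$realized_rate_female)
  d_m <- str$realized_rate_male * (1 - str$realized_rate_male)
  mdiff <- eff$b_male * d_m - eff$b_female * d_f
  fit_prob <- predicted_vs_estimated_slope(lg$beta, mdiff)
  rate_diff <- unname(str$realized_rate_male - str$realized_rate_female)
  vals <- c(
    slope_logit = fit_logit$slope, slope_logit_ci_lo = fit_logit$ci[1],
    slope_logit_ci_hi = fit_logit$ci[2], intercept_logit = fit_logit$intercept,
    slope_prob = fit_prob$slope, rate_difference = rate_diff,
    n_participants = nrow(coh$genotypes)
  )
  out <- do.call(rbind, lapply(names(vals), function(metric) {
    experiment_row("sex_differential", par$pi, par$pi, par$h2_female,
                   par$h2_male, "slope_regression", 1L, master, metric,
                   unname(vals[metric]))
  }))
  rownames(out) <- NULL
  out
}

#' Write an experiment table with a JSON manifest
#'
#' Writes the tidy table as TSV plus a `<name>.manifest.json` recording the
#' configuration, row count, a content hash of the TSV text and the runtime
#' stamp, so a sweep's outputs are self-describing.
#'
#' @param table Experiment data.frame.
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @param config The configuration used.
#' @return Path of the TSV, invisibly.
#' @export
write_experiment <- function(table, dir, name, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(table, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- readChar(tsv, file.info(tsv)$size, useBytes = TRUE)
  manifest <- list(name = name, rows = nrow(table),
                   content_hash = content_hash(txt),
                   config = config, r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, paste0(name, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tsv)
}

# internal: small polynomial rolling hash over text, hex-encoded (the
# multiplier keeps every intermediate product exactly representable)
content_hash <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
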