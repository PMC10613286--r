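tryStage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    message("stage '", name, "' failed: ", conditionMessage(e))
    NULL
  })
}

configHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% .Machine$integer.max)
}

#' Default association model subset (enumeration off)
#'
#' A small, fixed set of representative full/reduced model pairs for runs
#' where fitting the complete enumerated space (2430 or 728 full models) is
#' not the goal; spans no-control, fixed-control, intercept-only and
#' intercept+slope random structures.
#'
#' @param study 1 or 2.
#' @return List of `list(full, reduced)` pairs as in [enumerateModelSubsets()].
#' @export
defaultModelSpecs <- function(study = 1) {
  all_pairs <- enumerateModelSubsets(study)
  sig <- function(spec) paste(paste(spec$fixed, collapse = "+"), spec$lang_int,
                              paste(spec$groups, collapse = ""))
  if (study == 1) {
    gn <- c("corpus", "family", "macro_area", "country", "script")
    want <- list(
      list(fixed = character(0), lang_int = FALSE, g = c(0, 0, 0, 0, 0)),
      list(fixed = c("h", "L"), lang_int = FALSE, g = c(0, 0, 0, 0, 0)),
      list(fixed = character(0), lang_int = FALSE, g = c(1, 1, 0, 0, 0)),
      list(fixed = c("h", "L"), lang_int = FALSE, g = c(1, 1, 0, 0, 1)),
      list(fixed = character(0), lang_int = FALSE, g = c(0, 2, 0, 0, 0)),
      list(fixed = c("h", "L"), lang_int = FALSE, g = c(1, 2, 1, 0, 0))
    )
  } else {
    gn <- c("script", "macro_area", "country", "family", "subfamily",
            "sub_branch")
    want <- list(
      list(fixed = character(0), lang_int = FALSE, g = c(1, 0, 0, 0, 0, 0)),
      list(fixed = character(0), lang_int = FALSE, g = c(0, 1, 0, 1, 0, 0)),
      list(fixed = character(0), lang_int = FALSE, g = c(0, 0, 0, 2, 0, 0)),
      list(fixed = character(0), lang_int = FALSE, g = c(1, 1, 0, 1, 1, 0))
    )
  }
  keys <- vapply(want, function(w)
    paste(paste(w$fixed, collapse = "+"), w$lang_int,
          paste(w$g, collapse = "")), "")
  sigs <- vapply(all_pairs, function(p) sig(p$full), "")
  all_pairs[match(keys, sigs)]
}

fitModelSet <- function(data, pairs, iter_cap = NULL) {
  fulls <- lapply(pairs, function(p) fitAssociationLmer(data, p$full, iter_cap))
  reds <- lapply(pairs, function(p) fitAssociationLmer(data, p$reduced, iter_cap))
  cmp <- mapply(function(f, r) deltaAicCompare(f, r)$delta_aic, fulls, reds)
  verdict <- mapply(function(f, r) deltaAicCompare(f, r)$verdict, fulls, reds)
  table <- data.frame(
    model = seq_along(pairs),
    beta = vapply(fulls, `[[`, 0, "beta"),
    se = vapply(fulls, `[[`, 0, "se"),
    aic_full = vapply(fulls, `[[`, 0, "aic"),
    aic_reduced = vapply(reds, `[[`, 0, "aic"),
    delta_aic = as.numeric(cmp),
    verdict = as.character(verdict),
    converged = vapply(fulls, `[[`, TRUE, "converged"))
  list(full_fits = fulls, reduced_fits = reds, table = table)
}

#' Run the learning-curve study end to end
#'
#' For each language of a (typically synthetic) world: tokenize the full
#' document, compute the incremental-compression learning curve, fit the
#' ansatz to obtain the difficulty parameter `b`, then run the association
#' stage: mixed-model set + frequentist model averaging, double-selection
#' lasso, and the Freedman-Lane permutation test, all against log speaker
#' population size.
#'
#' @param world a `synthetic_world` (with corpus), from [generateWorld()].
#' @param config a [compressorConfig()] for the learning curves.
#' @param level tokenization level for the curves.
#' @param model_pairs association model pairs; `NULL` uses
#'   [defaultModelSpecs()], `"all"` the full enumeration (2430 pairs).
#' @param ds_tier candidate-set tier for the double-selection lasso.
#' @param n_perm permutations for the Freedman-Lane test.
#' @param seed seed for the stochastic stages.
#' @return A results bundle: `difficulty` (per-language ansatz table),
#'   `assoc` (per-model table), `fma`, `ds`, `fl`, `manifest`.
#' @export
runStudy1 <- function(world, config = compressorConfig("ppm", order = 2),
                      level = "word", model_pairs = NULL, ds_tier = "small",
                      n_perm = 1000, seed = 1) {
  langs <- corpusLanguages(world$corpus)
  diff_tab <- do.call(rbind, lapply(langs, function(lg) {
    sym <- tokenize(world$corpus$text[, lg], level)
    ids <- encodeSymbols(sym)$ids
    cbind(language = lg, estimateDifficulty(ids, config))
  }))
  df <- merge(diff_tab[!diff_tab$excluded, ], world$metadata, by = "language")
  df$log_pop <- log(df$population)
  # log scale stabilizes the heavy right tail of fitted b (near-flat curves
  # leave b ill-identified upward); standardization per corpus as in the
  # mixed-model design
  df$difficulty <- log(df$b)
  sdf <- standardizePerCorpus(df)
  if (is.null(model_pairs)) model_pairs <- defaultModelSpecs(1)
  else if (identical(model_pairs, "all")) model_pairs <- enumerateModelSubsets(1)
  ms <- fitModelSet(sdf, model_pairs)
  fma <- tryStage("fma", fmaEstimate(ms$full_fits))
  cand <- suppressWarnings(buildCandidateSet(df, ds_tier))
  ds <- tryStage("double-selection", doubleSelection(
    log(df$b), df$log_pop, cand, cluster = df$language, seed = seed))
  fl <- tryStage("freedman-lane", {
    ctrl <- if (!is.null(ds) && length(ds$selected) > 0)
      scale(cand)[, ds$selected, drop = FALSE] else NULL
    freedmanLaneTest(log(df$b), df$log_pop, ctrl, n_perm = n_perm,
                     seed = seed)
  })
  list(difficulty = diff_tab, assoc = ms$table, fma = fma, ds = ds, fl = fl,
       manifest = list(hash = configHash(list(world$config, config, level,
                                              ds_tier, n_perm, seed)),
                       seed = seed, n_languages = length(langs)))
}

#' Run the fold-rotation study end to end
#'
#' Stratified fold assignment, shared random training schedules, cross-entropy
#' series per language, the REML slope model whose per-language BLUPs measure
#' learning difficulty, then the association stage: mixed-model set + FMA,
#' phylogenetic GLS, and the two-matrix spatial error model with permutation
#' inference.
#'
#' @param world a `synthetic_world` (with corpus).
#' @param config a [compressorConfig()].
#' @param level `"word"` or `"bpe"`.
#' @param n_folds folds for the rotation (default 10).
#' @param n_test_folds rotations to run (10 = full design, 90 records per
#'   language).
#' @param model_pairs as in [runStudy1()] (Study-2 grammar; `"all"` = 728
#'   pairs).
#' @param n_perm permutations for the SAR test.
#' @param seed seed for folds, schedules and permutations.
#' @return A results bundle: `xent`, `slope_model`, `mu` (per-language BLUPs),
#'   `assoc`, `fma`, `pgls`, `sar`, `sar_perm`, `manifest`.
#' @export
runStudy2 <- function(world, config = compressorConfig("ppm", order = 2),
                      level = "word", n_folds = 10,
                      n_test_folds = n_folds, model_pairs = NULL,
                      n_perm = 1000, seed = 1) {
  folds <- assignFolds(world$corpus, n_folds, seed = seed)
  sched <- makeTrainingSchedule(n_folds, seed = seed + 1)
  xent <- corpusCrossEntropy(world$corpus, folds, sched, config, level,
                             n_test_folds)
  sm <- fitSlopeModel(xent)
  df <- world$metadata
  df$difficulty <- sm$mu[df$language]
  df$log_pop <- log(df$population)
  if (is.null(model_pairs)) model_pairs <- defaultModelSpecs(2)
  else if (identical(model_pairs, "all")) model_pairs <- enumerateModelSubsets(2)
  ms <- fitModelSet(df, model_pairs)
  fma <- tryStage("fma", fmaEstimate(ms$full_fits))
  mu <- stats::setNames(df$difficulty, df$language)
  pgls <- tryStage("pgls", fitPGLS(
    mu, stats::setNames(df$log_pop, df$language), world$tree))
  W1 <- inverseDistanceWeights(world$d_geo[df$language, df$language])
  W2 <- inverseDistanceWeights(world$d_lex[df$language, df$language])
  sar <- tryStage("sar", fitSAR(df$difficulty, df$log_pop, W1, W2))
  sar_perm <- tryStage("sar-permutation", sarPermutationTest(
    df$difficulty, df$log_pop, W1, W2, n_perm = n_perm, seed = seed))
  list(xent = xent, slope_model = sm, mu = mu, assoc = ms$table, fma = fma,
       pgls = pgls, sar = sar, sar_perm = sar_perm,
       manifest = list(hash = configHash(list(world$config, config, level,
                                              n_folds, n_test_folds, n_perm,
                                              seed)),
                       seed = seed))
}

#' Sign-recovery benchmark across replicate synthetic worlds
#'
#' Generates `n_worlds` independent worlds from the same configuration,
#' estimates Study-1 difficulty (`b`) per language with the PPM backend, and
#' records the sign of the population coefficient under frequentist model
#' averaging, double-selection lasso, PGLS and the two-matrix spatial error
#' model, plus the Spearman correlation between the injected hardness and the
#' fitted difficulty.
#'
#' @param config a [worldConfig()] (its `beta_true` is the injected effect).
#' @param n_worlds number of replicate worlds.
#' @param compressor a [compressorConfig()].
#' @param seed base seed; world `i` uses `seed + 1000 * i`.
#' @return A `recovery_report` list with a per-world data.frame (`betas`) and
#'   the `sign_rates` summary.
#' @export
runRecoveryBenchmark <- function(config = worldConfig(), n_worlds = 20,
                                 compressor = compressorConfig("ppm", order = 2),
                                 seed = 1) {
  rows <- vector("list", n_worlds)
  for (i in seq_len(n_worlds)) {
    cfg <- config
    cfg$seed <- seed + 1000L * i
    world <- generateWorld(cfg)
    s1 <- runStudy1(world, compressor, seed = cfg$seed, n_perm = 200)
    dt <- s1$difficulty[!s1$difficulty$excluded, ]
    md <- world$metadata[match(dt$language, world$metadata$language), ]
    tr <- world$truth[match(dt$language, world$truth$language), ]
    lp <- stats::setNames(log(md$population), md$language)
    logb <- stats::setNames(log(dt$b), dt$language)
    pgls <- fitPGLS(logb, lp, world$tree)
    W1 <- inverseDistanceWeights(world$d_geo[dt$language, dt$language])
    W2 <- inverseDistanceWeights(world$d_lex[dt$language, dt$language])
    sar <- fitSAR(log(dt$b), lp, W1, W2)
    val <- function(x) if (is.null(x)) NA_real_ else x
    rows[[i]] <- data.frame(
      world = i, beta_fma = val(s1$fma$beta_fma), beta_ds = val(s1$ds$beta),
      beta_pgls = pgls$beta, beta_sar = sar$beta,
      spearman_b_dtrue = stats::cor(dt$b, tr$d_true, method = "spearman"),
      fl_p = val(s1$fl$p))
  }
  betas <- do.call(rbind, rows)
  sign_rates <- colMeans(betas[, c("beta_fma", "beta_ds", "beta_pgls",
                                   "beta_sar")] * sign(config$beta_true) > 0)
  structure(list(betas = betas, sign_rates = sign_rates,
                 config = config, n_worlds = n_worlds,
                 hash = configHash(list(config, n_worlds, seed))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Sign-recovery over", x$n_worlds, "worlds (beta_true =",
      x$config$beta_true, "):\n")
  print(round(x$sign_rates, 3))
  invisible(x)
}

#' Null calibration of the Freedman-Lane permutation test
#'
#' Simulates datasets in which the outcome depends on the controls but not on
#' the exposure (the exposure is itself correlated with the controls, so naive
#' inference is confounded), runs the permutation test on each, and reports
#' the rejection rate at `alpha`.
#'
#' @param n_datasets simulated datasets.
#' @param n observations per dataset.
#' @param n_controls number of control covariates.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return list with `rejection_rate` and the vector of `p` values.
#' @export
calibrateFreedmanLane <- function(n_datasets = 400, n = 100, n_controls = 4,
                                  n_perm = 500, alpha = 0.05, seed = 1) {
  set.seed(seed)
  pvals <- vapply(seq_len(n_datasets), function(i) {
    C <- matrix(stats::rnorm(n * n_controls), n)
    x <- C %*% stats::rnorm(n_controls, 0, 0.5) + stats::rnorm(n)
    y <- C %*% stats::rnorm(n_controls, 0, 1) + stats::rnorm(n)
    freedmanLaneTest(as.vector(y), as.vector(x), C, n_perm = n_perm,
                     seed = seed + i)$p
  }, 0)
  list(rejection_rate = mean(pvals <= alpha), p = pvals)
}

#' Null calibration of the spatial-error permutation test
#'
#' Simulates datasets with exchangeable exposure and spatially correlated
#' errors (`u = lambda1 W1 u + lambda2 W2 u + eps`), runs the SAR permutation
#' test on each, and reports the rejection rate at `alpha`.
#'
#' @param n_datasets simulated datasets.
#' @param n observations.
#' @param lambda true error-dependence parameters.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return list with `rejection_rate` and `p`.
#' @export
calibrateSAR <- function(n_datasets = 300, n = 100, lambda = c(0.4, 0.3),
                         n_perm = 500, alpha = 0.05, seed = 1) {
  set.seed(seed)
  pvals <- vapply(seq_len(n_datasets), function(i) {
    W1 <- inverseDistanceWeights(as.matrix(stats::dist(
      cbind(stats::runif(n), stats::runif(n)))))
    W2 <- inverseDistanceWeights(as.matrix(stats::dist(
      cbind(stats::runif(n), stats::runif(n)))))
    A <- diag(n) - lambda[1] * W1 - lambda[2] * W2
    u <- solve(A, stats::rnorm(n))
    x <- stats::rnorm(n)
    y <- 1 + u
    sarPermutationTest(y, x, W1, W2, n_perm = n_perm, seed = seed + i)$p
  }, 0)
  list(rejection_rate = mean(pvals <= alpha), p = pvals)
}
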