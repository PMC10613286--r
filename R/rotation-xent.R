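#' Stratified fold assignment
#'
#' Randomly assigns each available verse from each available book to one of
#' `n_folds` folds, stratified by book (per-book fold sizes differ by at most
#' one). The assignment is shared across languages, so fold contents are
#' parallel by construction.
#'
#' @param corpus a [parallelCorpus()].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return A `fold_assignment` data.frame: `book`, `chapter`, `verse`, `fold`,
#'   plus a `row` column indexing the corpus verse order.
#' @export
assignFolds <- function(corpus, n_folds = 10, seed = 1) {
  keys <- corpus$keys
  set.seed(seed)
  fold <- integer(nrow(keys))
  for (b in unique(keys$book)) {
    idx <- which(keys$book == b)
    if (length(idx) < n_folds)
      stop("book ", b, " has ", length(idx), " verses; need >= ", n_folds)
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  out <- cbind(keys, fold = fold, row = seq_len(nrow(keys)))
  class(out) <- c("fold_assignment", "data.frame")
  out
}

#' Random training schedules for the fold rotation
#'
#' For each test fold, one uniformly random permutation of the remaining
#' folds; the incremental training sets `T_f` are the concatenation of the
#' first `f` scheduled folds. Schedules are shared across languages.
#'
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return A list of integer vectors; element `t` is the training permutation
#'   for test fold `t` (length `n_folds - 1`, excluding `t` itself).
#' @export
makeTrainingSchedule <- function(n_folds = 10, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_folds), function(t) sample(setdiff(seq_len(n_folds), t)))
}

#' Fold-rotation cross-entropy series
#'
#' For each test fold and each number of training folds `f = 1..n_folds-1`,
#' computes the cross entropy
#' `H_f = (R(T_f T_test) - R(T_f)) / N_v` (bits per test verse), where `R(X)`
#' is the code length of `X` under the configured backend plus the compressed
#' size of the symbol table mapping types to 4-byte codes, and `N_v` is the
#' number of verses in the test fold. At the BPE level the merge table is
#' learned from the training text `T_f` only, then applied to both training
#' and test text.
#'
#' @param corpus a [parallelCorpus()].
#' @param language language id.
#' @param folds a [assignFolds()] result.
#' @param schedule a [makeTrainingSchedule()] result.
#' @param config a [compressorConfig()].
#' @param level `"word"` or `"bpe"`.
#' @param n_test_folds number of rotations to run (default: all folds; the full
#'   10-fold design yields 90 records per language).
#' @return An `xent_series` data.frame: `language`, `test_fold`, `f`, `H`,
#'   `N_v`. Negative `H` records (possible with real container formats on tiny
#'   inputs) are dropped with a warning.
#' @export
crossEntropySeries <- function(corpus, language, folds, schedule,
                               config = compressorConfig(), level = "word",
                               n_test_folds = length(schedule)) {
  n_folds <- length(schedule)
  fold_rows <- split(folds$row, folds$fold)
  txt <- corpus$text[, language]
  out <- vector("list", n_test_folds * (n_folds - 1))
  k <- 0
  for (t in seq_len(n_test_folds)) {
    test_rows <- fold_rows[[t]]
    N_v <- length(test_rows)
    test_txt <- txt[test_rows]
    perm <- schedule[[t]]
    for (f in seq_len(n_folds - 1)) {
      train_rows <- unlist(fold_rows[perm[seq_len(f)]], use.names = FALSE)
      train_txt <- txt[train_rows]
      if (level == "bpe") {
        bpe <- learnBPE(train_txt)
        train_sym <- tokenize(train_txt, "bpe", bpe)
        test_sym <- tokenize(test_txt, "bpe", bpe)
      } else {
        train_sym <- tokenize(train_txt, level)
        test_sym <- tokenize(test_txt, level)
      }
      R <- function(sym) {
        enc <- encodeSymbols(sym)
        backendCodelength(enc$ids, config) + symbolTableBits(enc$table, config)
      }
      H <- (R(c(train_sym, test_sym)) - R(train_sym)) / N_v
      k <- k + 1
      out[[k]] <- data.frame(language = language, test_fold = t, f = f,
                             H = H, N_v = N_v, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  neg <- res$H <= 0
  if (any(neg)) {
    warning(sum(neg), " non-positive H_f record(s) dropped for ", language)
    res <- res[!neg, , drop = FALSE]
  }
  class(res) <- c("xent_series", "data.frame")
  res
}

#' Mixed-effects slope model of the cross-entropy series
#'
#' Fits, by REML, `log(H) ~ log(f)` with crossed random intercepts for
#' language and test fold and a per-language random slope of `log(f)` with an
#' unstructured intercept-slope covariance. The per-language best linear
#' unbiased predictions (BLUPs) of the random slope, `mu`, measure learning
#' difficulty: higher `mu` indicates faster learning (a language whose cross
#' entropy has already converged declines less steeply than one still
#' learning).
#'
#' @param xent an `xent_series` (rows from all languages, via `rbind`).
#' @param max_iter optimizer function-evaluation budget.
#' @return A `slope_model_fit`: `fixef` (intercept, slope of `log(f)`), `mu`
#'   (named per-language BLUP vector), `sigma2` (variance of the random
#'   slope), `vc` (variance components), `fit` (the `lme4` object).
#' @export
fitSlopeModel <- function(xent, max_iter = 10000) {
  stopifnot(length(unique(xent$language)) >= 2, length(unique(xent$f)) >= 2)
  d <- data.frame(logH = log(xent$H), logf = log(xent$f),
                  language = factor(xent$language),
                  test_fold = factor(xent$test_fold))
  fit <- lme4::lmer(
    logH ~ logf + (1 + logf | language) + (1 | test_fold),
    data = d, REML = TRUE,
    control = lme4::lmerControl(optCtrl = list(maxfun = max_iter),
                                calc.derivs = FALSE))
  re <- lme4::ranef(fit)$language
  mu <- stats::setNames(re[, "logf"], rownames(re))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- vc$vcov[vc$grp == "language" & vc$var1 == "logf" &
                      is.na(vc$var2)]
  structure(list(fixef = lme4::fixef(fit), mu = mu, sigma2 = sigma2,
                 vc = vc, fit = fit),
            class = "slope_model_fit")
}

#' @export
print.slope_model_fit <- function(x, ...) {
  cat(sprintf("Slope model: fixed slope %.4f, slope variance %.4g, %d languages\n",
              x$fixef["logf"], x$sigma2, length(x$mu)))
  invisible(x)
}

#' Cross-entropy series for every language of a corpus
#'
#' Runs [crossEntropySeries()] for each language under the shared fold
#' assignment and schedule (the parallel-design invariant), returning the
#' stacked table ready for [fitSlopeModel()].
#'
#' @inheritParams crossEntropySeries
#' @export
corpusCrossEntropy <- function(corpus, folds, schedule,
                               config = compressorConfig(), level = "word",
                               n_test_folds = length(schedule)) {
  res <- lapply(corpusLanguages(corpus), function(lg)
    crossEntropySeries(corpus, lg, folds, schedule, config, level,
                       n_test_folds))
  out <- do.call(rbind, res)
  class(out) <- c("xent_series", "data.frame")
  out
}
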