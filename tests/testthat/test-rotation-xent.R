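test_that("fold assignment is a stratified, balanced, reproducible partition", {
  corp <- makeTinyCorpus(langs = "aaa", n_books = 10, per_book = 100)
  fa <- assignFolds(corp, n_folds = 10, seed = 2)
  expect_equal(as.integer(table(fa$fold)), rep(100L, 10))
  expect_true(all(table(fa$fold, fa$book) == 10L))
  expect_setequal(fa$row, seq_len(1000))
  expect_identical(assignFolds(corp, 10, seed = 2), fa)
  small <- makeTinyCorpus(langs = "aaa", n_books = 1, per_book = 5)
  expect_error(assignFolds(small, 10), "need >=")
})

test_that("training schedules exclude the test fold and are reproducible", {
  s <- makeTrainingSchedule(10, seed = 4)
  expect_length(s, 10)
  for (t in 1:10) {
    expect_length(s[[t]], 9)
    expect_setequal(s[[t]], setdiff(1:10, t))
  }
  expect_identical(makeTrainingSchedule(10, seed = 4), s)
})

test_that("cross entropy follows the incremental-compression formula", {
  # degenerate backend: bits = 8 * byte length; with a vocabulary shared by
  # all folds, symbol-table terms cancel and H_f = 32 * L_test / N_v for all f
  registerBackend("ident8", function(raw) 8 * length(raw))
  corp <- makeTinyCorpus(langs = "aaa", n_books = 2, per_book = 10,
                         words = c("ka", "lo"), verse_len = 4, seed = 6)
  fa <- assignFolds(corp, n_folds = 4, seed = 6)
  sched <- makeTrainingSchedule(4, seed = 7)
  xe <- crossEntropySeries(corp, "aaa", fa, sched,
                           compressorConfig("ident8"), "word")
  expect_equal(nrow(xe), 4 * 3)
  expect_true(all(abs(xe$H - 32 * 4) < 1e-9))  # 4 words/verse, 32 bits/word
})

test_that("the full 10-fold design yields 90 records per language", {
  registerBackend("ident8", function(raw) 8 * length(raw))
  corp <- makeTinyCorpus(langs = c("aaa", "bbb"), n_books = 2, per_book = 50,
                         verse_len = 3, seed = 8)
  fa <- assignFolds(corp, n_folds = 10, seed = 8)
  sched <- makeTrainingSchedule(10, seed = 9)
  xe <- corpusCrossEntropy(corp, fa, sched, compressorConfig("ident8"), "word")
  expect_equal(as.integer(table(xe$language)), rep(90L, 2))
  expect_setequal(unique(xe$f), 1:9)
})

test_that("non-positive cross entropies are dropped with a warning", {
  registerBackend("shrinking", function(raw) max(0, 1e4 - 8 * length(raw)))
  corp <- makeTinyCorpus(langs = "aaa", n_books = 2, per_book = 10,
                         verse_len = 4, seed = 10)
  fa <- assignFolds(corp, n_folds = 4, seed = 10)
  sched <- makeTrainingSchedule(4, seed = 11)
  expect_warning(
    xe <- crossEntropySeries(corp, "aaa", fa, sched,
                             compressorConfig("shrinking"), "word"),
    "non-positive")
  expect_true(all(xe$H > 0))
})

test_that("BPE models for the series are learned from training text only", {
  corp <- makeTinyCorpus(langs = "aaa", n_books = 2, per_book = 8,
                         words = c("lowest", "lower", "newest"),
                         verse_len = 3, seed = 12)
  fa <- assignFolds(corp, n_folds = 4, seed = 12)
  sched <- makeTrainingSchedule(4, seed = 13)
  xe <- crossEntropySeries(corp, "aaa", fa, sched,
                           compressorConfig("ppm", order = 1), "bpe",
                           n_test_folds = 1)
  expect_equal(nrow(xe), 3)
  expect_true(all(xe$H > 0))
})

test_that("slope-model BLUPs recover known per-language slopes", {
  set.seed(14)
  n_lang <- 50; n_fold <- 10
  mu_true <- rnorm(n_lang, 0, 0.10)
  grid <- expand.grid(language = sprintf("L%02d", 1:n_lang),
                      test_fold = 1:n_fold, f = 1:9)
  a_i <- rnorm(n_lang, 0, 0.2)
  fold_e <- rnorm(n_fold, 0, 0.05)
  li <- as.integer(factor(grid$language))
  logH <- 3 + a_i[li] + (-0.4 + mu_true[li]) * log(grid$f) +
    fold_e[grid$test_fold] + rnorm(nrow(grid), 0, 0.05)
  xe <- data.frame(language = grid$language, test_fold = grid$test_fold,
                   f = grid$f, H = exp(logH), N_v = 10)
  sm <- fitSlopeModel(xe)
  expect_gt(cor(sm$mu[sprintf("L%02d", 1:n_lang)], mu_true), 0.9)
  expect_lt(abs(mean(sm$mu)), 1e-6)
  expect_equal(sm$fixef[["logf"]], -0.4, tolerance = 0.1)
  expect_gte(sm$sigma2, 0)

  # homogeneous languages shrink harder toward zero
  logH0 <- 3 + (-0.4) * log(grid$f) + fold_e[grid$test_fold] +
    rnorm(nrow(grid), 0, 0.05)
  xe0 <- data.frame(language = grid$language, test_fold = grid$test_fold,
                    f = grid$f, H = exp(logH0), N_v = 10)
  sm0 <- suppressMessages(fitSlopeModel(xe0))
  expect_lt(max(abs(sm0$mu)), max(abs(sm$mu)))
})

test_that("cross entropy declines with training folds on a learning source", {
  cfg <- worldConfig(n_languages = 2, n_verses = 1000, verse_length = 12,
                     vocab_range = c(32, 40), order_range = c(1, 1),
                     seed = 15)
  w <- generateWorld(cfg)
  fa <- assignFolds(w$corpus, n_folds = 10, seed = 15)
  sched <- makeTrainingSchedule(10, seed = 16)
  xe <- crossEntropySeries(w$corpus, "L002", fa, sched,
                           compressorConfig("ppm", order = 2), "word")
  # strongly negative log-log relation within each rotation; at these small
  # fold sizes the pooled correlation is diluted by fold-composition noise
  perfold <- vapply(split(xe, xe$test_fold),
                    function(d) cor(log(d$H), log(d$f)), 0)
  expect_lte(median(perfold), -0.8)
  expect_lt(cor(log(xe$H), log(xe$f)), 0)
  med <- tapply(xe$H, xe$f, median)
  expect_true(all(diff(med) < 0))
})
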