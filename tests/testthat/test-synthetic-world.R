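test_that("pure-birth phylogeny is unit-height, labeled, reproducible", {
  t2 <- simulatePhylogeny(2, seed = 3)
  d2 <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d2, c(1, 1))
  expect_identical(t2$tip.label, c("L001", "L002"))
  expect_error(simulatePhylogeny(1), "at least 2")
  ta <- simulatePhylogeny(50, seed = 9)
  tb <- simulatePhylogeny(50, seed = 9)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
})

test_that("patristic distances agree with an independent edge-list traversal", {
  tr <- simulatePhylogeny(12, seed = 4)
  D_ref <- refPatristic(tr)
  D_ape <- ape::cophenetic.phylo(tr)[rownames(D_ref), colnames(D_ref)]
  expect_equal(D_ref, D_ape, tolerance = 1e-10)
  expect_equal(mean(D_ref[upper.tri(D_ref)]),
               mean(D_ape[upper.tri(D_ape)]), tolerance = 1e-10)
})

test_that("markov sources hit their target entropy in closed form", {
  src <- markovSource(8, 2.0, 1)
  expect_equal(src$h_true, 2.0, tolerance = 1e-9)
  expect_equal(sum(src$p), 1, tolerance = 1e-12)
  u <- markovSource(4, 2.0, 0)  # maximal entropy -> uniform
  expect_equal(u$p, rep(0.25, 4))
  expect_error(markovSource(4, 2.5, 1), "entropy")
})

test_that("an order-matched adaptive model approaches h_true", {
  src <- markovSource(8, 2.0, 1)
  ids <- sampleSource(src, 1e5, seed = 42)
  rate <- ppmCodelength(ids, compressorConfig("ppm", order = 1),
                        alphabet = 8) / 1e5
  expect_lt(abs(rate - src$h_true) / src$h_true, 0.05)
})

test_that("trait simulation honours nulls, effects and nesting", {
  big <- simulatePhylogeny(1000, seed = 5)
  cfg0 <- worldConfig(n_languages = 1000, beta_true = 0, sigma_phylo = 0,
                      sigma_noise = 0.3, seed = 5)
  tr0 <- simulateLanguageTraits(big, cfg0)
  expect_lt(abs(cor(tr0$truth$log_pop, tr0$truth$trait)), 0.1)

  cfg1 <- worldConfig(n_languages = 200, beta_true = -0.3, seed = 6)
  t200 <- simulatePhylogeny(200, seed = 6)
  tr1 <- simulateLanguageTraits(t200, cfg1)
  expect_lt(cor(tr1$truth$log_pop, tr1$truth$trait), -0.3)
  # countries nested in macro areas: each country in exactly one area
  tab <- unique(tr1$metadata[, c("country", "macro_area")])
  expect_equal(anyDuplicated(tab$country), 0L)
  # subfamilies nested in families, sub-branches in subfamilies
  expect_equal(anyDuplicated(unique(tr1$metadata[, c("subfamily", "family")])$subfamily), 0L)
  expect_equal(anyDuplicated(unique(tr1$metadata[, c("sub_branch", "subfamily")])$sub_branch), 0L)
  # populations inside the stated range, coordinates valid
  expect_true(all(tr1$metadata$population >= 1e2 - 1e-6 &
                    tr1$metadata$population <= 1e9 + 1))
  expect_true(all(abs(tr1$metadata$latitude) <= 90))
  expect_true(all(abs(tr1$metadata$longitude) <= 180))
  expect_true(all(tr1$metadata$egids %in% 1:10))
  # hardness knob is monotone in d_true
  expect_true(all(diff(tr1$truth$vocab_size[order(tr1$truth$d_true)]) >= 0))
})

test_that("synthesized corpora are parallel and reproducible", {
  cfg <- worldConfig(n_languages = 6, n_verses = 60, verse_length = 8,
                     seed = 8)
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(w1$corpus$text, w2$corpus$text)
  expect_identical(w1$truth, w2$truth)
  expect_equal(nrow(w1$corpus$keys), 60)
  expect_false(any(w1$corpus$text == ""))
  expect_equal(length(unique(w1$corpus$keys$book)), cfg$n_books)
  # identical sources and seeds give identical token-count profiles
  src <- markovSource(8, 2.2, 1)
  a <- sampleSource(src, 500, seed = 77)
  b <- sampleSource(src, 500, seed = 77)
  expect_identical(a, b)
})

test_that("a generated world round-trips through the exchange formats", {
  cfg <- worldConfig(n_languages = 5, n_verses = 40, verse_length = 6,
                     seed = 10)
  w <- generateWorld(cfg)
  dir <- withr::local_tempdir()
  writeWorld(w, dir)
  back <- readParallelCorpus(file.path(dir, "corpus"))
  expect_identical(back$text, w$corpus$text)
  inp <- loadComparativeInputs(file.path(dir, "metadata.csv"),
                               file.path(dir, "tree.nwk"),
                               c(geo = file.path(dir, "dist_geo.tsv"),
                                 lex = file.path(dir, "dist_lex.tsv")))
  expect_identical(inp$metadata$language, sort(w$metadata$language))
  expect_equal(inp$matrices$geo, w$d_geo[inp$metadata$language,
                                         inp$metadata$language],
               tolerance = 1e-6)
})

test_that("harder sources converge more slowly (difficulty monotonicity)", {
  # small vs large effective state space at equal entropy: the harder source
  # stays further from its entropy rate at every prefix length
  easy <- markovSource(8, 2.0, 1)
  hard <- markovSource(64, 2.0, 2)
  cfg <- compressorConfig("ppm", order = 2)
  cv_e <- compressionCurve(sampleSource(easy, 2e4, seed = 1), cfg)
  cv_h <- compressionCurve(sampleSource(hard, 2e4, seed = 1), cfg)
  expect_true(all(cv_h$r_l > cv_e$r_l))
  expect_gt(fitAnsatz(cv_e)$b, fitAnsatz(cv_h)$b)
})
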