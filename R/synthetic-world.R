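#' Configuration for a synthetic world of languages
#'
#' The generator produces a phylogeny of languages, per-language text sources
#' with controllable learning difficulty, population sizes with a programmable
#' effect on difficulty, coordinates, metadata and distance matrices, so that
#' every downstream stage of the pipeline can be checked against known ground
#' truth.
#'
#' The latent trait is a learnability score on the scale of the fitted
#' difficulty measures (higher = faster learning, like the ansatz parameter
#' `b` or the slope BLUP `mu`):
#' `trait = beta_true * log(population) + Brownian(sigma_phylo) + N(0, sigma_noise)`.
#' The hardness knob `d_true = -trait` is realized as a larger effective state
#' space (vocabulary size and context order) of the language's Markov source,
#' which provably slows the empirical convergence of adaptive compressors while
#' leaving the entropy rate controllable in closed form.
#'
#' @param n_languages number of languages (tree tips).
#' @param n_verses total verses per language (split equally over `n_books`).
#' @param verse_length mean symbols (words) per verse.
#' @param beta_true effect of natural-log population on the latent trait.
#' @param sigma_phylo Brownian rate of the phylogenetic trait component.
#' @param sigma_noise residual standard deviation of the trait.
#' @param vocab_range range of source vocabulary sizes (difficulty knob).
#' @param order_range range of Markov context orders (difficulty knob).
#' @param entropy_range range of per-language source entropy rates
#'   (bits/symbol); must not exceed `log2(min(vocab_range))`.
#' @param n_books number of synthetic book labels (equal verse counts enable
#'   the stratified fold assignment).
#' @param n_corpora synthetic corpus labels assigned to languages (Study-1
#'   grouping/standardization unit).
#' @param seed master seed; the world is fully reproducible from
#'   `(config, seed)`.
#' @return A `world_config` list.
#' @export
worldConfig <- function(n_languages = 60, n_verses = 5000, verse_length = 25,
                        beta_true = -0.3, sigma_phylo = 0.25, sigma_noise = 0.25,
                        vocab_range = c(28, 96), order_range = c(1, 2),
                        entropy_range = c(2.0, 2.8), n_books = 10,
                        n_corpora = 3, seed = 1) {
  stopifnot(n_languages >= 2, n_verses > 0, verse_length > 0,
            sigma_phylo >= 0, sigma_noise >= 0,
            max(entropy_range) <= log2(min(vocab_range)) + 1e-9)
  structure(list(n_languages = n_languages, n_verses = n_verses,
                 verse_length = verse_length, beta_true = beta_true,
                 sigma_phylo = sigma_phylo, sigma_noise = sigma_noise,
                 vocab_range = vocab_range, order_range = order_range,
                 entropy_range = entropy_range, n_books = n_books,
                 n_corpora = n_corpora, seed = seed),
            class = "world_config")
}

#' Simulate a pure-birth language phylogeny
#'
#' Yule tree conditioned on `n` tips, rescaled to unit height, tips labeled
#' `L001, L002, ...`; deterministic given the seed.
#'
#' @param n_languages number of tips (>= 2).
#' @param seed integer seed.
#' @return An `ape::phylo` tree.
#' @export
simulatePhylogeny <- function(n_languages, seed = 1) {
  if (n_languages < 2) stop("need at least 2 languages")
  set.seed(seed)
  tree <- ape::rphylo(n_languages, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("L%03d", seq_len(n_languages))
  tree
}

#' Markov text source with closed-form entropy rate
#'
#' The next-symbol distribution is a fixed weight vector `p` cyclically shifted
#' by the sum of the last `order` symbols (mod vocabulary size). The stationary
#' distribution over histories is uniform, so the entropy rate is exactly
#' `H(p) = -sum(p * log2(p))`, tunable via a softmax temperature solved by
#' root-finding to hit the requested entropy.
#'
#' @param vocab_size number of symbol types.
#' @param entropy_bits target entropy rate in bits/symbol
#'   (`0 < entropy_bits <= log2(vocab_size)`).
#' @param order Markov context order (0 = i.i.d.).
#' @return A `language_source` with fields `vocab_size`, `order`, `p`,
#'   `h_true`.
#' @export
markovSource <- function(vocab_size, entropy_bits, order = 1) {
  stopifnot(vocab_size >= 2, entropy_bits > 0,
            entropy_bits <= log2(vocab_size) + 1e-12, order >= 0)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  pOf <- function(theta) { w <- exp(-theta * (seq_len(vocab_size) - 1)); w / sum(w) }
  if (abs(entropy_bits - log2(vocab_size)) < 1e-12) {
    p <- rep(1 / vocab_size, vocab_size)
  } else {
    theta <- stats::uniroot(function(t) ent(pOf(t)) - entropy_bits,
                            c(1e-9, 60), tol = 1e-12)$root
    p <- pOf(theta)
  }
  structure(list(vocab_size = vocab_size, order = as.integer(order), p = p,
                 h_true = ent(p)),
            class = "language_source")
}

#' @rdname markovSource
#' @param source a `language_source`.
#' @param n number of symbols to draw.
#' @param seed optional seed (if `NULL`, continues the current RNG stream).
#' @return Integer vector of 0-based symbol ids.
#' @export
sampleSource <- function(source, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .markov_sample_cpp(as.integer(n), source$p, source$order)
}

#' Simulate language metadata and the ground-truth table
#'
#' Log-population follows Brownian motion on the tree plus independent noise
#' (populations span roughly 10^2 to 10^9); the latent trait adds the
#' population effect, a Brownian component and Gaussian noise (see
#' [worldConfig()]). Families / subfamilies / sub-branches are clades at three
#' depth cuts of the tree; countries are spatial clusters of the (phylogenetically
#' autocorrelated) coordinates and are explicitly nested within macro areas.
#'
#' @param tree an `ape::phylo` (unit height, >= 2 tips).
#' @param config a [worldConfig()].
#' @return list with `metadata` (data.frame, one row per language) and `truth`
#'   (data.frame with the latent values: `log_pop`, `trait`, `d_true`,
#'   `vocab_size`, `order`, `h_true`).
#' @export
simulateLanguageTraits <- function(tree, config) {
  n <- length(tree$tip.label)
  stopifnot(n >= 2)
  set.seed(config$seed + 1L)
  V <- ape::vcv(tree)
  Lc <- t(chol(V + diag(1e-10, n)))
  # Brownian draws conditioned to their nominal per-world spread: tips on a
  # Yule tree are strongly correlated, so a raw draw's realized variance is
  # tree- and draw-dependent; rescaling keeps the correlation structure while
  # delivering the configured effect sizes uniformly across replicate worlds.
  bm <- function(sigma) {
    z <- as.vector(Lc %*% stats::rnorm(n))
    z <- z - mean(z)
    s <- stats::sd(z)
    if (s > 0) z * (sigma / s) else z * 0
  }

  log_pop <- log(1e5) + bm(2.3) + stats::rnorm(n, 0, 0.6)
  log_pop <- pmin(pmax(log_pop, log(1e2)), log(1e9))
  trait <- config$beta_true * log_pop + bm(config$sigma_phylo) +
    stats::rnorm(n, 0, config$sigma_noise)
  d_true <- -trait

  # difficulty knob -> source complexity: hardness rank maps onto the full
  # log-vocabulary range (and context order), so every world realizes the
  # whole difficulty spectrum; the mapping is strictly monotone in d_true
  rk <- (rank(d_true, ties.method = "first") - 0.5) / n
  vr <- log(config$vocab_range)
  vocab <- pmax(2L, as.integer(round(exp(vr[1] + rk * (vr[2] - vr[1])))))
  or <- config$order_range
  ord <- as.integer(or[1] + floor(rk * (or[2] - or[1] + 1) * 0.999999))
  er <- config$entropy_range
  h_true_target <- stats::runif(n, er[1], min(er[2], log2(min(vocab))))

  # taxonomy from clades at three depth cuts (patristic average-linkage)
  dmat <- stats::as.dist(ape::cophenetic.phylo(tree))
  hc <- stats::hclust(dmat, method = "average")
  family <- paste0("F", formatC(stats::cutree(hc, h = 1.5), width = 2, flag = "0"))
  subfam <- paste0("S", formatC(stats::cutree(hc, h = 1.0), width = 2, flag = "0"))
  subbr <- paste0("B", formatC(stats::cutree(hc, h = 0.5), width = 2, flag = "0"))

  lon <- 150 * tanh(0.6 * (bm(1.5) + stats::rnorm(n, 0, 0.3)))
  lat <- 60 * tanh(0.6 * (bm(1.5) + stats::rnorm(n, 0, 0.3)))
  k_country <- max(1L, min(12L, n %/% 5L, n - 1L))
  cl <- stats::kmeans(cbind(lon, lat), centers = k_country, nstart = 5)
  k_macro <- max(1L, min(4L, k_country %/% 2L))
  mcl <- stats::kmeans(cl$centers, centers = k_macro, nstart = 5)
  country <- paste0("C", formatC(cl$cluster, width = 2, flag = "0"))
  macro_area <- paste0("M", mcl$cluster[cl$cluster])  # nested: country -> one area

  fam_idx <- as.integer(factor(family))
  metadata <- data.frame(
    language = tree$tip.label,
    corpus = paste0("corpus", (seq_len(n) - 1L) %% config$n_corpora + 1L),
    family = family, subfamily = subfam, sub_branch = subbr,
    macro_area = macro_area, country = country,
    script = paste0("script", (fam_idx - 1L) %% 4L + 1L),
    egids = pmin(10L, pmax(1L, as.integer(round(
      10 - 9 * (log_pop - log(1e2)) / (log(1e9) - log(1e2)) +
        stats::rnorm(n, 0, 0.7))))),
    population = exp(log_pop),
    longitude = lon, latitude = lat,
    n_countries = 1L + stats::rpois(n, 1.2),
    range_size = exp(stats::rnorm(n, 11, 1.5)),
    altitude = exp(stats::rnorm(n, 6, 1)),
    distance_to_water = exp(stats::rnorm(n, 3, 1)),
    climate_pc1 = stats::rnorm(n), climate_pc2 = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(language = tree$tip.label, log_pop = log_pop,
                      trait = trait, d_true = d_true, vocab_size = vocab,
                      order = ord, h_true = h_true_target,
                      stringsAsFactors = FALSE)
  list(metadata = metadata, truth = truth)
}

#' Synthesize a verse-parallel corpus from language sources
#'
#' Each language's text is one continuous draw from its Markov source, split
#' into verses; verse keys (book, chapter, verse) are identical across
#' languages, with equal verse counts per book. Deterministic given the
#' config seed.
#'
#' @param traits output of [simulateLanguageTraits()].
#' @param config a [worldConfig()].
#' @return list with `corpus` (a [parallelCorpus()]) and `sources` (named list
#'   of `language_source` objects; `truth` gains the realized entropy `h_true`).
#' @export
synthesizeParallelCorpus <- function(traits, config) {
  truth <- traits$truth
  n <- nrow(truth)
  set.seed(config$seed + 2L)
  per_book <- config$n_verses %/% config$n_books
  n_verses <- per_book * config$n_books
  keys <- data.frame(
    book = rep(sprintf("B%02d", seq_len(config$n_books)), each = per_book),
    chapter = rep(1L, n_verses),
    verse = rep(seq_len(per_book), times = config$n_books)
  )
  sources <- list()
  text <- matrix("", nrow = n_verses, ncol = n,
                 dimnames = list(NULL, truth$language))
  for (i in seq_len(n)) {
    src <- markovSource(truth$vocab_size[i], truth$h_true[i], truth$order[i])
    sources[[truth$language[i]]] <- src
    lens <- 1L + stats::rpois(n_verses, config$verse_length - 1)
    ids <- sampleSource(src, sum(lens), seed = config$seed + 1000L + i)
    words <- sprintf("w%03d", ids)
    grp <- rep.int(seq_len(n_verses), lens)
    text[, i] <- vapply(split(words, grp), paste, "", collapse = " ")
  }
  list(corpus = parallelCorpus(keys, text), sources = sources)
}

#' Generate a complete synthetic world
#'
#' Tree, metadata + truth table, verse-parallel corpus, sources, and the two
#' distance matrices used by the spatial error model: a Haversine geographic
#' matrix from the simulated coordinates and a synthetic lexical-dissimilarity
#' matrix (patristic distance plus multiplicative noise).
#'
#' @param config a [worldConfig()].
#' @param corpus generate the text corpus (set `FALSE` to skip the expensive
#'   text synthesis when only metadata-level stages are exercised).
#' @return A `synthetic_world` list: `config`, `tree`, `metadata`, `truth`,
#'   `corpus`, `sources`, `d_geo`, `d_lex`.
#' @export
generateWorld <- function(config = worldConfig(), corpus = TRUE) {
  tree <- simulatePhylogeny(config$n_languages, config$seed)
  traits <- simulateLanguageTraits(tree, config)
  cs <- if (corpus) synthesizeParallelCorpus(traits, config) else
    list(corpus = NULL, sources = NULL)
  d_geo <- haversineMatrix(traits$metadata$latitude, traits$metadata$longitude,
                           traits$metadata$language)
  set.seed(config$seed + 3L)
  pat <- ape::cophenetic.phylo(tree)[traits$metadata$language,
                                     traits$metadata$language]
  noise <- matrix(stats::runif(length(pat), 0.9, 1.1), nrow = nrow(pat))
  noise <- (noise + t(noise)) / 2
  d_lex <- pat * noise
  diag(d_lex) <- 0
  structure(list(config = config, tree = tree, metadata = traits$metadata,
                 truth = traits$truth, corpus = cs$corpus, sources = cs$sources,
                 d_geo = d_geo, d_lex = d_lex),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d languages%s\n", nrow(x$metadata),
              if (is.null(x$corpus)) "" else
                sprintf(", %d parallel verses", nrow(x$corpus$keys))))
  invisible(x)
}

#' Write a synthetic world to disk in the package's exchange formats
#'
#' Emits the same verse-TSV / CSV / newick / TSV-matrix formats that
#' [readParallelCorpus()] and [loadComparativeInputs()] read, plus the truth
#' table as CSV.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(world$corpus))
    writeParallelCorpus(world$corpus, file.path(dir, "corpus"))
  utils::write.csv(world$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(world$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  ape::write.tree(world$tree, file.path(dir, "tree.nwk"))
  writeDistanceMatrix(world$d_geo, file.path(dir, "dist_geo.tsv"))
  writeDistanceMatrix(world$d_lex, file.path(dir, "dist_lex.tsv"))
  invisible(dir)
}
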