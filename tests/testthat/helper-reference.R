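# Independent pure-R reference evaluator of the adaptive-context model:
# method-C escape counts with full blending, back-off to uniform over the
# alphabet. Written against the model definition, not the C++ code, so it can
# serve as an oracle for exact bit accounting.

refContextProb <- function(ids, t, sym, tabs, alphabet, order) {
  p <- 1 / alphabet
  for (k in 0:min(order, t - 1)) {
    key <- if (k == 0) "." else paste(ids[(t - k):(t - 1)], collapse = ",")
    nd <- tabs[[k + 1]][[key]]
    if (is.null(nd) || nd$total == 0) next
    d <- length(nd$counts)
    denom <- nd$total + d
    cx <- nd$counts[[as.character(sym)]]
    if (is.null(cx)) cx <- 0
    p <- cx / denom + (d / denom) * p
  }
  p
}

# returns list(bits, probs): probs[t, a+1] = P(symbol a | history) before
# observing position t
refPPM <- function(ids, alphabet, order, full_probs = FALSE) {
  tabs <- replicate(order + 1, list(), simplify = FALSE)
  bits <- 0
  probs <- if (full_probs) matrix(NA_real_, length(ids), alphabet) else NULL
  for (t in seq_along(ids)) {
    x <- ids[t]
    if (full_probs)
      probs[t, ] <- vapply(0:(alphabet - 1), function(a)
        refContextProb(ids, t, a, tabs, alphabet, order), 0)
    bits <- bits - log2(refContextProb(ids, t, x, tabs, alphabet, order))
    for (k in 0:min(order, t - 1)) {
      key <- if (k == 0) "." else paste(ids[(t - k):(t - 1)], collapse = ",")
      nd <- tabs[[k + 1]][[key]]
      if (is.null(nd)) nd <- list(counts = list(), total = 0)
      cx <- nd$counts[[as.character(x)]]
      nd$counts[[as.character(x)]] <- (if (is.null(cx)) 0 else cx) + 1
      nd$total <- nd$total + 1
      tabs[[k + 1]][[key]] <- nd
    }
  }
  list(bits = bits, probs = probs)
}

# brute-force patristic distances from the edge list (independent traversal)
refPatristic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  # paths[[i]][v] = distance from tip i up to ancestor node v
  pathToRoot <- function(v) {
    anc <- c()
    d <- c()
    while (v != root) {
      anc <- c(anc, parent[v])  # after climbing the edge above v we sit at
      d <- c(d, plen[v])        # parent[v], having walked plen[v]
      v <- parent[v]
    }
    stats::setNames(cumsum(d), anc)
  }
  paths <- lapply(seq_len(n), pathToRoot)
  depth <- vapply(paths, function(p) unname(p[length(p)]), 0)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    anc_i <- names(paths[[i]])
    anc_j <- names(paths[[j]])
    mrca <- anc_i[anc_i %in% anc_j][1]
    D[i, j] <- D[j, i] <- paths[[i]][mrca] + paths[[j]][mrca]
  }
  D
}

# tiny deterministic parallel corpus: n_books books x per_book verses, each
# verse drawn from the supplied word pool (recycled), identical keys per lang
makeTinyCorpus <- function(langs = c("aaa", "bbb"), n_books = 2, per_book = 12,
                           words = c("ka", "lo", "mi", "na"), verse_len = 6,
                           seed = 1) {
  set.seed(seed)
  nv <- n_books * per_book
  keys <- data.frame(book = rep(sprintf("B%02d", seq_len(n_books)),
                                each = per_book),
                     chapter = 1L, verse = rep(seq_len(per_book), n_books))
  text <- vapply(langs, function(lg)
    vapply(seq_len(nv), function(i)
      paste(sample(words, verse_len, replace = TRUE), collapse = " "), ""),
    character(nv))
  parallelCorpus(keys, text)
}
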