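#' Verse-parallel corpus objects
#'
#' A `parallel_corpus` holds verse-aligned text in several languages: every
#' (book, chapter, verse) key carries exactly one text string per language and
#' the verse order is identical across languages. This is the structure of
#' massively parallel translation corpora, where each fold of a cross-validation
#' split contains text drawn from the same underlying message.
#'
#' @param keys data.frame with columns `book` (character), `chapter` (integer),
#'   `verse` (integer), one row per verse.
#' @param text character matrix, `nrow(keys)` rows, one column per language
#'   (column names are the language ids).
#' @return An object of class `parallel_corpus`.
#' @export
parallelCorpus <- function(keys, text) {
  stopifnot(is.data.frame(keys), all(c("book", "chapter", "verse") %in% names(keys)))
  text <- as.matrix(text)
  if (nrow(text) != nrow(keys)) stop("text must have one row per verse key")
  if (is.null(colnames(text))) stop("text columns must be named by language id")
  ord <- order(keys$book, keys$chapter, keys$verse)
  keys <- keys[ord, c("book", "chapter", "verse"), drop = FALSE]
  rownames(keys) <- NULL
  structure(list(keys = keys, text = text[ord, , drop = FALSE]),
            class = "parallel_corpus")
}

#' @export
print.parallel_corpus <- function(x, ...) {
  cat("Parallel corpus:", ncol(x$text), "languages,", nrow(x$keys), "verses,",
      length(unique(x$keys$book)), "books\n")
  invisible(x)
}

#' @rdname parallelCorpus
#' @param corpus a `parallel_corpus`.
#' @export
corpusLanguages <- function(corpus) colnames(corpus$text)

#' @rdname parallelCorpus
#' @export
verseKeys <- function(corpus) corpus$keys

#' @rdname parallelCorpus
#' @param language language id.
#' @param rows optional integer row subset (verses), in corpus order.
#' @export
corpusText <- function(corpus, language, rows = NULL) {
  if (!language %in% colnames(corpus$text)) stop("unknown language: ", language)
  v <- corpus$text[, language]
  if (!is.null(rows)) v <- v[rows]
  v
}

#' Read a verse-parallel corpus from a directory of per-language TSV files
#'
#' Expects one UTF-8 TSV per language named `<language>.tsv` with a header line
#' and columns `book`, `chapter`, `verse`, `text`. Verses missing in any
#' language are dropped (with a message reporting the count) so the returned
#' corpus is fully parallel; languages and verse keys are sorted
#' deterministically.
#'
#' @param path directory containing the per-language TSV files.
#' @return A `parallel_corpus`.
#' @export
readParallelCorpus <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop("no .tsv corpus files found in ", path)
  per_lang <- list()
  for (f in files) {
    lang <- sub("\\.tsv$", "", basename(f))
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    if (length(lines) < 1) stop("empty corpus file: ", f)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    header <- parts[[1]]
    if (!identical(header[1:3], c("book", "chapter", "verse")))
      stop("malformed header in ", f)
    bad <- which(vapply(parts[-1], length, 1L) != 4L)
    if (length(bad) > 0)
      stop("malformed record in ", f, " at line ", bad[1] + 1L,
           ": expected 4 tab-separated fields")
    body <- parts[-1]
    per_lang[[lang]] <- data.frame(
      book = vapply(body, `[[`, "", 1L),
      chapter = as.integer(vapply(body, `[[`, "", 2L)),
      verse = as.integer(vapply(body, `[[`, "", 3L)),
      text = vapply(body, `[[`, "", 4L),
      stringsAsFactors = FALSE
    )
  }
  langs <- names(per_lang)
  key_str <- function(d) paste(d$book, d$chapter, d$verse, sep = "\r")
  common <- Reduce(intersect, lapply(per_lang, key_str))
  n_all <- length(unique(unlist(lapply(per_lang, key_str))))
  dropped <- n_all - length(common)
  if (length(common) == 0) stop("no verse is complete across all languages")
  if (dropped > 0)
    message("dropped ", dropped, " incomplete verse(s) not present in every language")
  ref <- per_lang[[1]]
  keep <- key_str(ref) %in% common
  keys <- ref[keep, c("book", "chapter", "verse")]
  ord <- order(keys$book, keys$chapter, keys$verse)
  keys <- keys[ord, ]
  kref <- paste(keys$book, keys$chapter, keys$verse, sep = "\r")
  text <- vapply(langs, function(lg) {
    d <- per_lang[[lg]]
    d$text[match(kref, key_str(d))]
  }, character(nrow(keys)))
  parallelCorpus(keys, text)
}

#' Write a verse-parallel corpus as per-language TSV files
#'
#' @param corpus a `parallel_corpus`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
writeParallelCorpus <- function(corpus, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (lg in corpusLanguages(corpus)) {
    lines <- c("book\tchapter\tverse\ttext",
               paste(corpus$keys$book, corpus$keys$chapter, corpus$keys$verse,
                     corpus$text[, lg], sep = "\t"))
    writeLines(lines, file.path(path, paste0(lg, ".tsv")), useBytes = TRUE)
  }
  invisible(path)
}

#' Tokenize text into word, character or byte-pair-encoded symbols
#'
#' Word level splits on single spaces (the corpora are pre-tokenized and
#' space-separated); character level yields one symbol per code point; BPE level
#' applies the learned merges greedily, in learned order, within words.
#'
#' @param text character vector; elements are concatenated with single spaces.
#' @param level one of `"word"`, `"character"`, `"bpe"`.
#' @param bpe_model a model from [learnBPE()]; required for `level = "bpe"`.
#' @return Character vector of symbols (a symbol sequence; its length is the
#'   text length L in symbols).
#' @export
tokenize <- function(text, level = c("word", "character", "bpe"), bpe_model = NULL) {
  level <- match.arg(level)
  joined <- paste(text, collapse = " ")
  if (level == "character") {
    syms <- strsplit(joined, "", fixed = FALSE)[[1]]
    return(syms)
  }
  words <- strsplit(joined, " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  if (level == "word") return(words)
  if (is.null(bpe_model)) stop("level = 'bpe' requires a bpe_model")
  applyBPE(words, bpe_model)
}

applyBPE <- function(words, bpe_model) {
  uw <- unique(words)
  seg <- lapply(strsplit(uw, "", fixed = FALSE), function(chs) {
    for (m in bpe_model$merges) {
      repeat {
        hit <- which(chs[-length(chs)] == m[1] & chs[-1] == m[2])
        if (length(hit) == 0 || length(chs) < 2) break
        i <- hit[1]
        chs <- c(chs[seq_len(i - 1)], paste0(m[1], m[2]),
                 if (i + 2 <= length(chs)) chs[(i + 2):length(chs)])
      }
      if (length(chs) < 2) break
    }
    chs
  })
  unlist(seg[match(words, uw)], use.names = FALSE)
}

#' Learn a byte-pair-encoding model
#'
#' Merges are learned from training text only. The number of merges is
#' `floor(0.4 * C)` where `C` is the number of distinct word types in the
#' training text; each merge joins the most frequent adjacent symbol pair
#' (ties broken lexicographically on the concatenated pair, for determinism).
#'
#' @param training_text character vector of training text (space-separated words).
#' @return A list with `merges` (ordered list of length-2 character vectors)
#'   and `n_merges`, of class `bpe_model`.
#' @export
learnBPE <- function(training_text) {
  words <- tokenize(training_text, "word")
  if (length(words) == 0) stop("empty training text")
  tab <- table(words)
  types <- names(tab)
  freq <- as.integer(tab)
  n_merges <- floor(0.4 * length(types))
  seqs <- strsplit(types, "", fixed = FALSE)
  merges <- vector("list", n_merges)
  for (k in seq_len(n_merges)) {
    counts <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      if (length(s) < 2) next
      pr <- paste(s[-length(s)], s[-1], sep = "\r")
      for (p in pr) {
        prev <- counts[[p]]
        counts[[p]] <- (if (is.null(prev)) 0L else prev) + freq[i]
      }
    }
    keys <- ls(counts)
    if (length(keys) == 0) { merges <- merges[seq_len(k - 1)]; break }
    vals <- vapply(keys, function(p) counts[[p]], 0L)
    best <- keys[vals == max(vals)]
    pick <- sort(gsub("\r", "", best, fixed = TRUE))[1]  # lexicographic tie-break
    pair <- strsplit(best[match(pick, gsub("\r", "", best, fixed = TRUE))], "\r",
                     fixed = TRUE)[[1]]
    merges[[k]] <- pair
    seqs <- lapply(seqs, function(s) {
      repeat {
        hit <- which(s[-length(s)] == pair[1] & s[-1] == pair[2])
        if (length(hit) == 0 || length(s) < 2) break
        i <- hit[1]
        s <- c(s[seq_len(i - 1)], paste0(pair[1], pair[2]),
               if (i + 2 <= length(s)) s[(i + 2):length(s)])
      }
      s
    })
  }
  structure(list(merges = merges, n_merges = length(merges)), class = "bpe_model")
}

#' Map symbol types to fixed-width 4-byte codes
#'
#' Each distinct symbol type is assigned a unique 4-byte code in order of first
#' appearance, so the encoded stream has exactly `4 * L` bytes. Decoding with
#' the returned table inverts the encoding exactly.
#'
#' @param symbols character vector of symbols (from [tokenize()]).
#' @return list with `bytes` (raw vector), `ids` (0-based integer codes) and
#'   `table` (a `symbol_table`: `symbols` in first-appearance order and the
#'   type count `C`).
#' @export
encodeSymbols <- function(symbols) {
  ids <- if (length(symbols) == 0) integer(0) else match(symbols, unique(symbols)) - 1L
  types <- unique(symbols)
  bytes <- if (length(ids) == 0) raw(0) else {
    m <- rbind(bitwAnd(bitwShiftR(ids, 24L), 255L),
               bitwAnd(bitwShiftR(ids, 16L), 255L),
               bitwAnd(bitwShiftR(ids, 8L), 255L),
               bitwAnd(ids, 255L))
    as.raw(as.vector(m))
  }
  tab <- structure(list(symbols = types, C = length(types)), class = "symbol_table")
  list(bytes = bytes, ids = ids, table = tab)
}

#' @rdname encodeSymbols
#' @param bytes raw vector from [encodeSymbols()].
#' @param table the matching `symbol_table`.
#' @export
decodeSymbols <- function(bytes, table) {
  if (length(bytes) == 0) return(character(0))
  m <- matrix(as.integer(bytes), nrow = 4)
  ids <- m[1, ] * 2^24 + m[2, ] * 2^16 + m[3, ] * 256 + m[4, ]
  table$symbols[ids + 1L]
}

#' Serialized, compressed size of a symbol table in bits
#'
#' The mapping is serialized as a sorted two-column `symbol<TAB>code` table and
#' compressed by the active backend; the compressed length (in bits) is what
#' cross-entropy bookkeeping adds to each code length.
#'
#' @param table a `symbol_table`.
#' @param config a [compressorConfig()]; the table is compressed with the same
#'   backend as the text.
#' @return Bits (numeric scalar), strictly positive for nonempty tables.
#' @export
symbolTableBits <- function(table, config = compressorConfig()) {
  rows <- paste(table$symbols, seq_len(table$C) - 1L, sep = "\t")
  serial <- charToRaw(paste(sort(rows), collapse = "\n"))
  backendCodelength(serial, config)
}

#' Load and align the comparative-analysis inputs
#'
#' Reads a per-language metadata table (CSV/TSV by extension), a newick
#' phylogeny and any number of square labeled distance matrices (TSV), then
#' restricts all of them to the common language set, reporting dropped
#' languages.
#'
#' @param metadata_path CSV/TSV with a `language` column and the metadata fields.
#' @param tree_path newick file.
#' @param matrix_paths named character vector of TSV matrix paths (may be empty).
#' @param tol symmetry tolerance for distance matrices.
#' @return list with `metadata`, `tree` (`ape::phylo`, pruned), `matrices`
#'   (list of aligned symmetric matrices) and `dropped` (language ids not
#'   present in all inputs).
#' @export
loadComparativeInputs <- function(metadata_path, tree_path,
                                  matrix_paths = character(0), tol = 1e-8) {
  sep <- if (grepl("\\.csv$", metadata_path)) "," else "\t"
  md <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  if (!"language" %in% names(md)) stop("metadata must have a 'language' column")
  tree <- ape::read.tree(tree_path)
  mats <- lapply(matrix_paths, readDistanceMatrix)
  sets <- c(list(md$language, tree$tip.label), lapply(mats, rownames))
  common <- sort(Reduce(intersect, sets))
  if (length(common) == 0) stop("no language common to all inputs")
  dropped <- sort(setdiff(unique(unlist(sets)), common))
  if (length(dropped) > 0)
    message("dropped ", length(dropped), " language(s) absent from some input: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  md <- md[match(common, md$language), , drop = FALSE]
  rownames(md) <- NULL
  tree <- ape::keep.tip(tree, common)
  mats <- lapply(mats, function(m) {
    if (max(abs(m - t(m))) > tol) stop("distance matrix asymmetric beyond tolerance")
    m[common, common, drop = FALSE]
  })
  list(metadata = md, tree = tree, matrices = mats, dropped = dropped)
}

readDistanceMatrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching labels")
  m
}

#' @rdname loadComparativeInputs
#' @param m square labeled matrix.
#' @param path output path.
#' @export
writeDistanceMatrix <- function(m, path) {
  df <- data.frame(language = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
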