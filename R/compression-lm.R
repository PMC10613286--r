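#' Compressor configuration
#'
#' Language models enter the pipeline as code-length oracles: a callable that
#' maps a stream to the number of bits needed to encode it. Two backends ship
#' with the package: an internal adaptive-context (PPM-style) model with exact
#' bit accounting, and an `xz`/LZMA dictionary-coder adapter. Further backends
#' can be registered with [registerBackend()].
#'
#' @param backend `"ppm"`, `"lzma"`, or the name of a registered backend.
#' @param order context length `o` for the PPM model (number of previous
#'   symbols used to predict the next one, e.g. 2 or 6).
#' @param memory_cap optional context-trie node budget for PPM; when the budget
#'   is reached the model structure is frozen (counts still update).
#' @return A `compressor_config`.
#' @export
compressorConfig <- function(backend = c("ppm", "lzma"), order = 2,
                             memory_cap = Inf) {
  if (length(backend) > 1) backend <- backend[1]
  if (!is.numeric(order) || order < 0) stop("order must be >= 0")
  structure(list(backend = backend, order = as.integer(order),
                 memory_cap = memory_cap),
            class = "compressor_config")
}

.backend_registry <- new.env(parent = emptyenv())

#' Register an external code-length backend
#'
#' The backend contract is minimal: any function mapping a raw byte stream to a
#' total bit count can stand in for an external compressor.
#'
#' @param name backend name usable in [compressorConfig()].
#' @param fun `function(raw) -> numeric bits`.
#' @export
registerBackend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .backend_registry)
  invisible(name)
}

asSymbolIds <- function(stream) {
  if (is.raw(stream)) {
    list(ids = as.integer(stream), alphabet = 256L)
  } else if (is.numeric(stream)) {
    ids <- as.integer(stream)
    if (length(ids) > 0 && min(ids) < 0) stop("symbol ids must be >= 0")
    list(ids = ids, alphabet = max(c(ids, -1L)) + 1L)
  } else if (is.character(stream)) {
    enc <- encodeSymbols(stream)
    list(ids = enc$ids, alphabet = enc$table$C)
  } else stop("stream must be raw, integer symbol ids, or character symbols")
}

idsToRaw <- function(ids) {
  if (length(ids) == 0) return(raw(0))
  m <- rbind(bitwAnd(bitwShiftR(ids, 24L), 255L),
             bitwAnd(bitwShiftR(ids, 16L), 255L),
             bitwAnd(bitwShiftR(ids, 8L), 255L),
             bitwAnd(ids, 255L))
  as.raw(as.vector(m))
}

#' PPM code length
#'
#' Ideal arithmetic-coding length of a stream under the adaptive context model:
#' to predict the next symbol, the model uses the last `o` symbols, escaping
#' (method-C style counts, full blending) down through shorter contexts to a
#' uniform distribution over the alphabet. Returns `sum(-log2 p_t)`,
#' deterministic in its inputs.
#'
#' @param stream raw vector (alphabet 256), nonnegative integer symbol ids, or
#'   character symbols.
#' @param config a [compressorConfig()] (its `order` and `memory_cap` are used).
#' @param per_position also return the per-position bit vector.
#' @param alphabet optional alphabet size override (defaults to 256 for raw
#'   input, max id + 1 for ids).
#' @return Total bits, or (with `per_position = TRUE`) a list with `bits` and
#'   `per_position`.
#' @export
ppmCodelength <- function(stream, config = compressorConfig("ppm", order = 2),
                          per_position = FALSE, alphabet = NULL) {
  s <- asSymbolIds(stream)
  if (!is.null(alphabet)) s$alphabet <- as.integer(alphabet)
  if (length(s$ids) == 0)
    return(if (per_position) list(bits = 0, per_position = numeric(0)) else 0)
  cap <- if (is.finite(config$memory_cap)) as.numeric(config$memory_cap) else -1
  res <- .ppm_bits_cpp(s$ids, s$alphabet, config$order, cap, per_position)
  if (per_position) list(bits = res$bits, per_position = res$per_position)
  else res$bits
}

#' Backend code length
#'
#' Dispatches to the configured backend: `"ppm"` uses [ppmCodelength()];
#' `"lzma"` reports `8 *` the compressed byte length under `memCompress(type =
#' "xz")` (symbol ids are first expanded to their 4-byte codes); any registered
#' backend is called on the raw byte stream.
#'
#' @inheritParams ppmCodelength
#' @return Total bits.
#' @export
backendCodelength <- function(stream, config = compressorConfig()) {
  if (inherits(config, "character")) config <- compressorConfig(config)
  b <- config$backend
  if (b == "ppm") return(ppmCodelength(stream, config))
  toRaw <- function(x) {
    if (is.raw(x)) x
    else if (is.numeric(x)) idsToRaw(as.integer(x))
    else idsToRaw(encodeSymbols(x)$ids)
  }
  if (b == "lzma") {
    return(8 * length(memCompress(toRaw(stream), type = "xz")))
  }
  if (exists(b, envir = .backend_registry, inherits = FALSE)) {
    fun <- get(b, envir = .backend_registry)
    return(fun(toRaw(stream)))
  }
  stop("unknown backend: ", b)
}

#' Incremental compression learning curve
#'
#' Compresses a document at `n_checkpoints` evenly spaced prefixes (every
#' `100/n_checkpoints` per cent of all symbols; 20 checkpoints = every 5%) and
#' records `r_l`, the bits per symbol needed to compress the first `l` symbols.
#' For the PPM backend the model is trained incrementally, so all prefixes
#' share one pass.
#'
#' @param stream document stream (raw, integer ids or character symbols).
#' @param config a [compressorConfig()].
#' @param n_checkpoints number of curve points (default 20).
#' @return A `learning_curve`: data.frame with columns `l` and `r_l`, with the
#'   total length `L` as an attribute.
#' @export
compressionCurve <- function(stream, config = compressorConfig(),
                             n_checkpoints = 20) {
  s <- asSymbolIds(stream)
  L <- length(s$ids)
  if (L < n_checkpoints)
    stop("document has ", L, " symbols; need at least ", n_checkpoints)
  l <- unique(round(seq_len(n_checkpoints) * L / n_checkpoints))
  l <- l[l >= 1]
  if (config$backend == "ppm") {
    pp <- ppmCodelength(s$ids, config, per_position = TRUE,
                        alphabet = s$alphabet)$per_position
    bits <- cumsum(pp)[l]
  } else {
    bits <- vapply(l, function(k)
      backendCodelength(s$ids[seq_len(k)], config), 0)
  }
  out <- data.frame(l = l, r_l = bits / l)
  attr(out, "L") <- L
  class(out) <- c("learning_curve", "data.frame")
  out
}
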