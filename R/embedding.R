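# Protein/peptide input encodings: one-hot over the 21-letter alphabet and
# a pluggable frozen per-residue language-model embedding. The "mock"
# embedder is a deterministic stand-in with the same interface as a real
# language-model adapter so that tests and desk-scale runs never download
# weights; it is NOT a trained language model.

#' One-hot encoding of an amino-acid sequence
#'
#' @param seq character scalar over the 20 canonical letters plus `X`
#'   (unknown).
#' @return L x 21 indicator matrix (columns in `AA_ALPHABET` order).
#' @export
one_hot_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  chars <- strsplit(toupper(seq), "")[[1L]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("illegal amino-acid character '%s' at position %d",
                 chars[bad], bad))
  }
  m <- matrix(0, length(chars), 21L,
              dimnames = list(NULL, AA_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Embedder specification
#'
#' @param name `"onehot"`, `"mock"` (deterministic 32-dim stand-in) or
#'   `"protbert"` (external language-model adapter; requires downloaded
#'   weights and is never used in the test path).
#' @param dim embedding dimension; fixed per embedder (21 for onehot, 32
#'   for mock, 1024 for protbert).
#' @return list of class `embedder_spec` (always frozen).
#' @export
embedder_spec <- function(name = c("mock", "onehot", "protbert"), dim = NULL) {
  name <- match.arg(name)
  dim <- if (!is.null(dim)) as.integer(dim) else
    switch(name, onehot = 21L, mock = 32L, protbert = 1024L)
  out <- list(name = name, dim = dim, frozen = TRUE)
  class(out) <- "embedder_spec"
  out
}

#' Per-residue protein embedding
#'
#' Deterministic given `(seq, spec)`. The mock embedder maps each (residue
#' identity, position) pair to a fixed sinusoidal 32-dim vector: rows depend
#' on position, repeat runs are bit-identical, and no random state is
#' consumed.
#'
#' @param seq amino-acid sequence (character scalar).
#' @param spec an [embedder_spec()].
#' @return L x dim numeric matrix.
#' @export
embed_protein <- function(seq, spec = embedder_spec("mock")) {
  stopifnot(inherits(spec, "embedder_spec"))
  switch(spec$name,
    onehot = one_hot_sequence(seq),
    mock = {
      idx <- match(strsplit(toupper(seq), "")[[1L]], AA_ALPHABET)
      if (anyNA(idx)) stop("illegal character in sequence")
      d <- seq_len(spec$dim)
      # fixed incommensurate frequencies: identity channel, position
      # channel and a per-dimension phase
      freq_aa <- 0.6180339887 * d
      freq_pos <- 1 / (50 ^ (d / spec$dim))
      phase <- 2.3999632297 * d
      L <- length(idx)
      sin(outer(idx, freq_aa) + outer(seq_len(L), freq_pos) +
            matrix(phase, L, spec$dim, byrow = TRUE))
    },
    protbert = stop("ProtBert weights are not bundled with this package; ",
                    "download them separately or use embedder 'mock' for ",
                    "offline work"))
}
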