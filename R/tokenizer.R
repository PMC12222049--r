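#' Build a k-mer vocabulary
#'
#' The vocabulary holds the four special tokens \code{[CLS]}, \code{[EOS]},
#' \code{[PAD]}, \code{[UNK]} (ids 1-4) followed by all \code{4^k} k-mers over
#' \{A,C,G,T\} in lexicographic order.
#'
#' @param k k-mer length (default 6).
#' @return a [KmerVocab].
#' @export
kmerVocab <- function(k = 6L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, bases, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, rev(grid))
  new("KmerVocab", k = k, tokens = c("[CLS]", "[EOS]", "[PAD]", "[UNK]", kmers))
}

specialId <- function(vocab, token) match(token, vocab@tokens)

#' Split a sequence into overlapping k-mers
#'
#' Window \code{i} starts at position \code{(i-1) * stride + 1}; the number of
#' windows is \code{floor((|seq| - k) / stride) + 1}.
#'
#' @param seq nucleotide string with \code{|seq| >= k}.
#' @param k k-mer length.
#' @param stride step between consecutive windows (3 for the CDS task, 1 for
#'   the TIS task).
#' @return character vector of k-mers.
#' @export
kmerize <- function(seq, k = 6L, stride = 1L) {
  stopifnot(k >= 1L, stride >= 1L)
  n <- nchar(seq)
  if (n < k) stop("kmerize: sequence shorter than k")
  starts <- seq.int(1L, n - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

# Vectorized k-mer -> token id. Lexicographic k-mers are base-4 numerals
# (A=0, C=1, G=2, T=3) offset by the 4 specials; anything containing a
# non-ACGT character maps to [UNK].
kmerIds <- function(kmers, vocab) {
  v <- strtoi(chartr("ACGT", "0123", kmers), base = 4L)
  ids <- v + 5L
  ids[is.na(v) | nchar(kmers) != vocab@k] <- specialId(vocab, "[UNK]")
  ids
}

#' Encode k-mers as a padded token sequence
#'
#' Produces \code{[CLS] + k-mer ids + [EOS]} right-padded with \code{[PAD]} to
#' \code{maxLen}, with a binary mask marking real tokens.
#'
#' @param kmers character vector of k-mers (see [kmerize()]).
#' @param vocab a [KmerVocab].
#' @param maxLen total encoded length; must be at least \code{length(kmers)+2}.
#' @return list with \code{ids} (integer vector of length \code{maxLen}),
#'   \code{mask} (1 = real token, 0 = padding) and \code{n_real}.
#' @export
encodeTokens <- function(kmers, vocab, maxLen) {
  nReal <- length(kmers) + 2L
  if (nReal > maxLen)
    stop(sprintf("encodeTokens: %d tokens exceed maxLen %d; truncate upstream",
                 nReal, maxLen))
  ids <- c(specialId(vocab, "[CLS]"), kmerIds(kmers, vocab),
           specialId(vocab, "[EOS]"),
           rep(specialId(vocab, "[PAD]"), maxLen - nReal))
  list(ids = as.integer(ids), mask = c(rep(1L, nReal), rep(0L, maxLen - nReal)),
       n_real = nReal)
}

# Reconstruct the nucleotide sequence from a stride-1 encoding (first k-mer in
# full, then the last base of each subsequent k-mer). Used in tests for the
# overlap-consistency property.
decodeTokens <- function(ids, vocab) {
  toks <- vocab@tokens[ids]
  toks <- toks[!toks %in% c("[CLS]", "[EOS]", "[PAD]")]
  if (length(toks) == 0L) return("")
  paste0(toks[1L], paste(substr(toks[-1L], vocab@k, vocab@k), collapse = ""))
}

#' Serialize / load a vocabulary as plain text
#'
#' One token per line; the line number is the token id.
#'
#' @param vocab a [KmerVocab].
#' @param path file path.
#' @return `writeVocab()` returns `path` invisibly; `readVocab()` a [KmerVocab].
#' @export
writeVocab <- function(vocab, path) {
  writeLines(vocab@tokens, path)
  invisible(path)
}

#' @rdname writeVocab
#' @export
readVocab <- function(path) {
  tokens <- readLines(path)
  k <- as.integer(round(log(length(tokens) - 4L, base = 4)))
  new("KmerVocab", k = k, tokens = tokens)
}
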