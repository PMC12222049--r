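#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show
#' @importFrom stats rgamma rbinom runif rnorm pnorm dnorm
#' @importFrom utils head write.csv read.csv
NULL

# Row-wise softmax that tolerates large negative masking values.
softmaxRows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softmaxVec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Reverse complement of a plain character string (delegates to Biostrings).
revcompChr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Run an expression under a fixed RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a 32-bit-safe child seed from a base seed and an index.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

START_CODONS <- c("ATG", "TTG", "GTG", "CTG")
STOP_CODONS  <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a
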