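# Shared fixtures: tiny vocabularies/models, small simulated corpora and the
# independent brute-force ORF oracle. Heavyweight objects are memoised in a
# package-local environment so the suite builds them once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

vocab6 <- function() memo("vocab6", function() kmerVocab(6))
vocab2 <- function() memo("vocab2", function() kmerVocab(2))

# Tiny k=2 transformer for structural/mechanical tests (fast to run).
tinyModel <- function(maxPositions = 12L, nHeads = 2L, nLayers = 2L,
                      stride = 1L, seed = 42L) {
  cfg <- transformerConfig(nLayers = nLayers, dHidden = 8L, nHeads = nHeads,
                           maxPositions = maxPositions, vocabSize = 20L,
                           dropout = 0, k = 2L, stride = stride)
  newTransformer(cfg, vocab2(), seed = seed)
}

# Desk-geometry TIS model (k=6, stride 1, 57 positions), untrained.
tisShapeModel <- function(seed = 3L) {
  memo("tisShapeModel", function() {
    cfg <- transformerConfig(nLayers = 2L, dHidden = 16L, nHeads = 2L,
                             maxPositions = 57L, vocabSize = 4100L,
                             dropout = 0, k = 6L, stride = 1L)
    newTransformer(cfg, vocab6(), seed = seed)
  })
}

smallCorpus <- function() {
  memo("smallCorpus", function()
    simulateCorpus(simConfig(nOrganisms = 3L, genesPerGenome = 8L,
                             genomeLen = 8000L, seed = 99L)))
}

randomGenomeSeq <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Independent brute-force ORF oracle: walk every position of each oriented
# strand; at each start codon, step forward codon by codon to the first stop.
# Deliberately naive; shares no code with extractOrfs().
bruteForceOrfs <- function(seq, minLen = 6L) {
  n <- nchar(seq)
  rows <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (i in seq_len(n - 2L)) {
      if (!substr(s, i, i + 2L) %in% c("ATG", "TTG", "GTG", "CTG")) next
      j <- i
      repeat {
        j <- j + 3L
        if (j + 2L > n) break
        if (substr(s, j, j + 2L) %in% c("TAA", "TAG", "TGA")) {
          if (j + 3L - i >= minLen) {
            a <- i - 1L; b <- j + 2L   # 0-based half-open on scanned strand
            rows[[length(rows) + 1L]] <-
              if (strand == "+") c(a, b, 1L) else c(n - b, n - a, -1L)
          }
          break
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(), strand = character()))
  m <- do.call(rbind, rows)
  data.frame(start = m[, 1], end = m[, 2],
             strand = ifelse(m[, 3] == 1L, "+", "-"))
}

orfKey <- function(df) sort(paste(df$strand, df$start, df$end))

# Independent dense oracle for one attention head: the scaled-dot-product
# formula computed step by step with explicit loops, no masking shortcuts.
denseHeadOracle <- function(M, Wq, Wk, Wv) {
  Q <- M %*% Wq; K <- M %*% Wk; V <- M %*% Wv
  n <- nrow(M); dk <- ncol(Wk)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    e <- exp(s - max(s))
    W[i, ] <- e / sum(e)
  }
  list(values = W %*% V, weights = W)
}

# A minimal valid GenePredictionSet from coordinate columns.
predSet <- function(genomeId, strand, start, end, pCds = 0.9, pTis = 0.8,
                    flag = 1L) {
  n <- length(start)
  new("GenePredictionSet", genomeId = genomeId,
      predictions = data.frame(
        strand = strand, start = as.integer(start), end = as.integer(end),
        p_cds = rep_len(pCds, n), p_tis = rep_len(pTis, n),
        prediction_max_likelihood = rep_len(as.integer(flag), n),
        stringsAsFactors = FALSE),
      provenance = list())
}
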