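# Attention-based interpretability: mean attention landscapes over true-TIS
# windows, [CLS]-row nucleotide importance, and attention-guided sequence
# disruption.

#' Mean attention landscape over a set of windows
#'
#' For each window the per-head attention matrices of one layer are averaged
#' over heads, then the per-window means are averaged over all windows. The
#' average of row-stochastic matrices is row-stochastic.
#'
#' @param model TIS-task [TransformerModel].
#' @param windows character vector of fixed-length nucleotide windows (all the
#'   same length).
#' @param layer layer to read (default: the final layer).
#' @return list with \code{layer}, \code{matrix} (square, side = encoded token
#'   count) and \code{n_sequences}.
#' @export
meanAttention <- function(model, windows, layer = NULL) {
  if (length(windows) == 0L) stop("meanAttention: no windows supplied")
  cfg <- model@config
  layer <- layer %||% cfg$n_layers
  stopifnot(layer >= 1L, layer <= cfg$n_layers)
  if (length(unique(nchar(windows))) != 1L)
    stop("meanAttention: windows must all have the same length")
  acc <- NULL
  for (w in windows) {
    enc <- encodeTokens(kmerize(w, cfg$k, cfg$stride), model@vocab,
                        cfg$max_positions)
    maps <- getAttentionMaps(model, enc)[[layer]]$weights
    headMean <- apply(maps, c(1L, 2L), mean)
    acc <- if (is.null(acc)) headMean else acc + headMean
  }
  list(layer = layer, matrix = acc / length(windows),
       n_sequences = length(windows))
}

#' Rank nucleotide positions by attention received from a query row
#'
#' Token-level attention is spread uniformly over the k bases each k-mer token
#' covers; special tokens contribute nothing. Positions are sorted by
#' descending importance, ties broken by position index.
#'
#' @param weights square attention matrix (rows = query positions) from
#'   [meanAttention()] or one head of [getAttentionMaps()].
#' @param seqLen nucleotide length of the underlying window.
#' @param k,stride tokenization parameters used to encode the window.
#' @param row query row to read (default 1, the \code{[CLS]} position).
#' @return list with \code{importance} (per-base scores, length \code{seqLen})
#'   and \code{ranking} (base positions, most-attended first).
#' @export
rankPositions <- function(weights, seqLen, k = 6L, stride = 1L, row = 1L) {
  scores <- weights[row, ]
  nTok <- length(scores) - 2L            # exclude [CLS] and [EOS]
  imp <- numeric(seqLen)
  for (t in seq_len(nTok)) {
    lo <- (t - 1L) * stride + 1L
    hi <- min(lo + k - 1L, seqLen)
    imp[lo:hi] <- imp[lo:hi] + scores[t + 1L] / k
  }
  list(importance = imp, ranking = order(-imp, seq_len(seqLen)))
}

#' Attention-guided sequence disruption
#'
#' Ranks the window's nucleotide positions by the attention they receive from
#' the \code{[CLS]} token in the final layer (head-averaged, computed from the
#' model itself on this window), substitutes the \code{ceiling(ratio * |seq|)}
#' top-ranked (\code{mode = "high"}) or bottom-ranked (\code{mode = "low"})
#' positions with bases drawn uniformly from the three alternatives, and
#' rescores the disrupted window. \code{ratio = 0} returns the undisrupted
#' probability bit-exactly.
#'
#' @param seq nucleotide window (length \code{2 * flank}, typically 60 nt).
#' @param model TIS-task [TransformerModel].
#' @param ratio disruption ratio in \code{[0, 1]}.
#' @param mode \code{"high"} or \code{"low"} attention disruption.
#' @param seed RNG seed; results are reproducible bit-exactly.
#' @return predicted positive-class probability of the (possibly disrupted)
#'   window.
#' @export
disruptAndScore <- function(seq, model, ratio, mode = c("high", "low"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (ratio < 0 || ratio > 1) stop("disruptAndScore: ratio must be in [0, 1]")
  cfg <- model@config
  score <- function(s) {
    enc <- encodeTokens(kmerize(s, cfg$k, cfg$stride), model@vocab,
                        cfg$max_positions)
    unname(classify(model, enc)["p_pos"])
  }
  if (ratio == 0) return(score(seq))
  n <- nchar(seq)
  enc <- encodeTokens(kmerize(seq, cfg$k, cfg$stride), model@vocab,
                      cfg$max_positions)
  maps <- getAttentionMaps(model, enc)[[cfg$n_layers]]$weights
  headMean <- apply(maps, c(1L, 2L), mean)
  ranking <- rankPositions(headMean, n, cfg$k, cfg$stride)$ranking
  score(disruptSequence(seq, ranking, ratio, mode, seed))
}

# Substitute the ceiling(ratio * n) top-ranked (high) or bottom-ranked (low)
# positions with bases drawn uniformly from the three alternatives, so at
# ratio 1 no position keeps its original base. Deterministic under the seed.
disruptSequence <- function(seq, ranking, ratio, mode, seed) {
  n <- nchar(seq)
  nSub <- ceiling(ratio * n)
  targets <- if (mode == "high") ranking[seq_len(nSub)] else
    ranking[n + 1L - seq_len(nSub)]
  bases <- strsplit(seq, "")[[1]]
  withSeed(seed, {
    for (i in targets)
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  })
  paste(bases, collapse = "")
}

#' Disruption curve over a ratio sweep
#'
#' Applies [disruptAndScore()] to every window at every ratio and collects the
#' predicted probability distributions.
#'
#' @param windows character vector of true-TIS windows.
#' @param model TIS-task [TransformerModel].
#' @param ratios ordered disruption ratios (0 = undisrupted).
#' @param mode \code{"high"} or \code{"low"}.
#' @param seed base RNG seed; each window/ratio pair gets a derived seed.
#' @return list with \code{mode}, \code{ratios}, \code{probs} (matrix, one row
#'   per window, one column per ratio) and \code{mean} (column means).
#' @export
disruptionCurve <- function(windows, model, ratios = seq(0, 1, by = 0.2),
                            mode = c("high", "low"), seed = 1L) {
  mode <- match.arg(mode)
  probs <- matrix(NA_real_, length(windows), length(ratios))
  for (i in seq_along(windows))
    for (j in seq_along(ratios))
      probs[i, j] <- disruptAndScore(windows[i], model, ratios[j], mode,
                                     seed = childSeed(seed, i * 131L + j))
  list(mode = mode, ratios = ratios, probs = probs, mean = colMeans(probs))
}
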