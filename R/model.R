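# Transformer encoder for k-mer token classification.
#
# The encoder follows the BERT layout: token + learned absolute position
# embeddings with layer normalization, then n_layers blocks of multi-head
# self-attention and a position-wise feed-forward network (GELU), each with a
# residual connection and post-layer normalization. Classification reads the
# [CLS] position through a tanh pooler, a linear layer to 2 logits and a
# softmax. Forward and backward passes are written in base R matrix algebra;
# there is no external deep-learning runtime.

#' Transformer model configuration
#'
#' @param nLayers number of encoder blocks (full-scale 12; desk default 2).
#' @param dHidden hidden width (full-scale 768; desk default 64).
#' @param nHeads attention heads (full-scale 12; desk default 4); must divide
#'   \code{dHidden}.
#' @param maxPositions maximum encoded sequence length (512 for the CDS task,
#'   57 for the TIS task).
#' @param vocabSize token vocabulary size (\code{4^k + 4}).
#' @param nClasses output classes (2).
#' @param dropout dropout fraction applied after embeddings, attention and
#'   feed-forward outputs during training.
#' @param k,stride tokenization parameters the model expects (k-mer length and
#'   window stride).
#' @return named configuration list with the derived fields \code{d_head} and
#'   \code{d_ff} (\code{4 * dHidden}).
#' @export
transformerConfig <- function(nLayers = 2L, dHidden = 64L, nHeads = 4L,
                              maxPositions = 512L, vocabSize = 4100L,
                              nClasses = 2L, dropout = 0, k = 6L, stride = 3L) {
  stopifnot(dHidden %% nHeads == 0L, maxPositions >= 3L)
  list(n_layers = as.integer(nLayers), d_hidden = as.integer(dHidden),
       n_heads = as.integer(nHeads), d_head = as.integer(dHidden / nHeads),
       d_ff = 4L * as.integer(dHidden), max_positions = as.integer(maxPositions),
       vocab_size = as.integer(vocabSize), n_classes = as.integer(nClasses),
       dropout = dropout, k = as.integer(k), stride = as.integer(stride))
}

# normal(0, 0.02) truncated at two standard deviations
initMat <- function(nr, nc) {
  matrix(pmin(pmax(rnorm(nr * nc, 0, 0.02), -0.04), 0.04), nr, nc)
}

#' Initialize a transformer classifier
#'
#' Weights are drawn from a truncated normal(0, 0.02); layer-norm gains start
#' at 1, all biases at 0. Initialization is deterministic given the seed.
#'
#' @param config a [transformerConfig()] list.
#' @param vocab a [KmerVocab]; its size must match \code{config$vocab_size}.
#' @param seed RNG seed for initialization.
#' @return a [TransformerModel].
#' @export
newTransformer <- function(config, vocab, seed = 1L) {
  stopifnot(length(vocab@tokens) == config$vocab_size)
  d <- config$d_hidden; ff <- config$d_ff
  params <- withSeed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) list(
      Wq = initMat(d, d), bq = numeric(d), Wk = initMat(d, d), bk = numeric(d),
      Wv = initMat(d, d), bv = numeric(d), Wo = initMat(d, d), bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      W1 = initMat(d, ff), b1 = numeric(ff), W2 = initMat(ff, d),
      b2 = numeric(d), ln2_g = rep(1, d), ln2_b = numeric(d)))
    list(tok_emb = initMat(config$vocab_size, d),
         pos_emb = initMat(config$max_positions, d),
         emb_g = rep(1, d), emb_b = numeric(d),
         layers = layers,
         pool_W = initMat(d, d), pool_b = numeric(d),
         cls_W = initMat(d, config$n_classes), cls_b = numeric(config$n_classes))
  })
  new("TransformerModel", config = config, params = params, vocab = vocab)
}

addBias <- function(M, b) M + rep(b, each = nrow(M))

gelu <- function(x) x * pnorm(x)
geluGrad <- function(x) pnorm(x) + x * dnorm(x)

layerNormFwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + 1e-12)
  xhat <- xc * inv
  list(out = addBias(xhat * rep(g, each = nrow(X)), b), xhat = xhat, inv = inv)
}

layerNormBwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  rm1 <- rowMeans(dxhat)
  rm2 <- rowMeans(dxhat * xhat)
  list(dX = (dxhat - rm1 - xhat * rm2) * cache$inv,
       dg = colSums(dY * xhat), db = colSums(dY))
}

dropoutMask <- function(nr, nc, p) {
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

#' Single attention head
#'
#' Computes \code{softmax(M Wq (M Wk)^T / sqrt(d_k)) M Wv} with padding key
#' positions excluded before the softmax, so every weight row over the real
#' keys sums to 1.
#'
#' @param M token embedding matrix, one row per position.
#' @param Wq,Wk,Wv projection weight matrices.
#' @param mask binary vector marking real positions (1) vs padding (0).
#' @return list with \code{values} (the attended value matrix) and
#'   \code{weights} (the row-stochastic attention matrix).
#' @export
attentionHead <- function(M, Wq, Wk, Wv, mask = rep(1L, nrow(M))) {
  if (!any(mask == 1L)) stop("attentionHead: all positions are masked")
  Q <- M %*% Wq; K <- M %*% Wk; V <- M %*% Wv
  S <- Q %*% t(K) / sqrt(ncol(Wk))
  S[, mask == 0L] <- -1e30
  P <- softmaxRows(S)
  list(values = P %*% V, weights = P)
}

#' Multi-head self-attention
#'
#' Concatenates the per-head attended values and applies the output
#' projection: \code{Concat(head_1, ..., head_h) Wo}.
#'
#' @param M token embedding matrix.
#' @param heads list of per-head lists with elements \code{Wq}, \code{Wk},
#'   \code{Wv}.
#' @param Wo output projection; rows must equal the summed head widths.
#' @param mask binary vector marking real positions.
#' @return matrix with the shape of \code{M} (when \code{Wo} is square).
#' @export
multiHeadAttention <- function(M, heads, Wo, mask = rep(1L, nrow(M))) {
  vals <- lapply(heads, function(h)
    attentionHead(M, h$Wq, h$Wk, h$Wv, mask)$values)
  concat <- do.call(cbind, vals)
  if (ncol(concat) != nrow(Wo))
    stop("multiHeadAttention: concatenated head width does not match Wo")
  concat %*% Wo
}

# Batched encoder forward pass.
#
# ids, mask: B x L integer matrices; real tokens must form a prefix of each
# row. Rows are flattened example-major (row (b-1)*L + t holds token t of
# example b). Returns probabilities, and caches for the backward pass when
# train = TRUE, attention arrays when collectAttention = TRUE.
tfForward <- function(model, ids, mask, train = FALSE,
                      collectAttention = FALSE) {
  cfg <- model@config; par <- model@params
  B <- nrow(ids); L <- ncol(ids)
  if (L > cfg$max_positions)
    stop("tfForward: sequence length exceeds max_positions")
  H <- cfg$n_heads; dk <- cfg$d_head; d <- cfg$d_hidden
  nReal <- rowSums(mask == 1L)
  if (any(nReal == 0L)) stop("tfForward: an example has no real tokens")
  drop <- if (train && cfg$dropout > 0) cfg$dropout else 0
  idsVec <- as.vector(t(ids))
  posVec <- rep(seq_len(L), B)
  E <- par$tok_emb[idsVec, , drop = FALSE] +
    par$pos_emb[posVec, , drop = FALSE]
  lnE <- layerNormFwd(E, par$emb_g, par$emb_b)
  X <- lnE$out
  embDrop <- NULL
  if (drop > 0) { embDrop <- dropoutMask(nrow(X), d, drop); X <- X * embDrop }
  caches <- vector("list", cfg$n_layers)
  attn <- if (collectAttention) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    lay <- par$layers[[l]]
    Ain <- X
    Q <- addBias(Ain %*% lay$Wq, lay$bq)
    K <- addBias(Ain %*% lay$Wk, lay$bk)
    V <- addBias(Ain %*% lay$Wv, lay$bv)
    Ctx <- matrix(0, B * L, d)
    P <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      nr <- nReal[b]
      Pb <- array(0, c(L, L, H))
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dk)
        if (nr < L) S[, (nr + 1L):L] <- -1e30
        Ph <- softmaxRows(S)
        Pb[, , h] <- Ph
        Ctx[rows, cols] <- Ph %*% V[rows, cols, drop = FALSE]
      }
      P[[b]] <- Pb
    }
    AttnOut <- addBias(Ctx %*% lay$Wo, lay$bo)
    attnDrop <- NULL
    if (drop > 0) {
      attnDrop <- dropoutMask(nrow(AttnOut), d, drop)
      AttnOut <- AttnOut * attnDrop
    }
    ln1 <- layerNormFwd(Ain + AttnOut, lay$ln1_g, lay$ln1_b)
    H1 <- ln1$out
    Aff <- addBias(H1 %*% lay$W1, lay$b1)
    G <- gelu(Aff)
    Fout <- addBias(G %*% lay$W2, lay$b2)
    ffDrop <- NULL
    if (drop > 0) {
      ffDrop <- dropoutMask(nrow(Fout), d, drop)
      Fout <- Fout * ffDrop
    }
    ln2 <- layerNormFwd(H1 + Fout, lay$ln2_g, lay$ln2_b)
    X <- ln2$out
    caches[[l]] <- list(Ain = Ain, Q = Q, K = K, V = V, P = P, Ctx = Ctx,
                        ln1 = ln1, H1 = H1, Aff = Aff, G = G, ln2 = ln2,
                        attnDrop = attnDrop, ffDrop = ffDrop)
    if (collectAttention) attn[[l]] <- P
  }
  clsRows <- (seq_len(B) - 1L) * L + 1L
  hCls <- X[clsRows, , drop = FALSE]
  pooled <- tanh(addBias(hCls %*% par$pool_W, par$pool_b))
  logits <- addBias(pooled %*% par$cls_W, par$cls_b)
  probs <- softmaxRows(logits)
  cache <- NULL
  if (train)
    cache <- list(ids = ids, mask = mask, idsVec = idsVec, posVec = posVec,
                  lnE = lnE, embDrop = embDrop, layers = caches, hCls = hCls,
                  pooled = pooled, probs = probs, B = B, L = L, nReal = nReal)
  list(probs = probs, logits = logits, cache = cache, attention = attn,
       nReal = nReal)
}

# Backward pass for the mean cross-entropy loss over the batch; returns
# gradients with the same structure as model@params.
tfBackward <- function(model, cache, labels) {
  cfg <- model@config; par <- model@params
  B <- cache$B; L <- cache$L; d <- cfg$d_hidden
  H <- cfg$n_heads; dk <- cfg$d_head
  Y <- matrix(0, B, cfg$n_classes)
  Y[cbind(seq_len(B), labels + 1L)] <- 1
  dLogits <- (cache$probs - Y) / B
  g <- list(cls_W = crossprod(cache$pooled, dLogits), cls_b = colSums(dLogits))
  dPooled <- dLogits %*% t(par$cls_W)
  dPre <- dPooled * (1 - cache$pooled^2)
  g$pool_W <- crossprod(cache$hCls, dPre)
  g$pool_b <- colSums(dPre)
  dHcls <- dPre %*% t(par$pool_W)
  dX <- matrix(0, B * L, d)
  clsRows <- (seq_len(B) - 1L) * L + 1L
  dX[clsRows, ] <- dHcls
  g$layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lay <- par$layers[[l]]; ca <- cache$layers[[l]]
    l2 <- layerNormBwd(dX, ca$ln2, lay$ln2_g)
    dRes2 <- l2$dX
    dFout <- if (is.null(ca$ffDrop)) dRes2 else dRes2 * ca$ffDrop
    dG <- dFout %*% t(lay$W2)
    gW2 <- crossprod(ca$G, dFout); gb2 <- colSums(dFout)
    dAff <- dG * geluGrad(ca$Aff)
    gW1 <- crossprod(ca$H1, dAff); gb1 <- colSums(dAff)
    dH1 <- dRes2 + dAff %*% t(lay$W1)
    l1 <- layerNormBwd(dH1, ca$ln1, lay$ln1_g)
    dRes1 <- l1$dX
    dAttnOut <- if (is.null(ca$attnDrop)) dRes1 else dRes1 * ca$attnDrop
    dCtx <- dAttnOut %*% t(lay$Wo)
    gWo <- crossprod(ca$Ctx, dAttnOut); gbo <- colSums(dAttnOut)
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d)
    dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        P <- cache$layers[[l]]$P[[b]][, , h]
        dCtxh <- dCtx[rows, cols, drop = FALSE]
        Vh <- ca$V[rows, cols, drop = FALSE]
        dP <- tcrossprod(dCtxh, Vh)
        dV[rows, cols] <- crossprod(P, dCtxh)
        dS <- P * (dP - rowSums(dP * P))
        dQ[rows, cols] <- dS %*% ca$K[rows, cols, drop = FALSE] / sqrt(dk)
        dK[rows, cols] <- crossprod(dS, ca$Q[rows, cols, drop = FALSE]) /
          sqrt(dk)
      }
    }
    gWq <- crossprod(ca$Ain, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(ca$Ain, dK); gbk <- colSums(dK)
    gWv <- crossprod(ca$Ain, dV); gbv <- colSums(dV)
    dX <- dRes1 + dQ %*% t(lay$Wq) + dK %*% t(lay$Wk) + dV %*% t(lay$Wv)
    g$layers[[l]] <- list(Wq = gWq, bq = gbq, Wk = gWk, bk = gbk, Wv = gWv,
                          bv = gbv, Wo = gWo, bo = gbo,
                          ln1_g = l1$dg, ln1_b = l1$db, W1 = gW1, b1 = gb1,
                          W2 = gW2, b2 = gb2, ln2_g = l2$dg, ln2_b = l2$db)
  }
  if (!is.null(cache$embDrop)) dX <- dX * cache$embDrop
  lE <- layerNormBwd(dX, cache$lnE, par$emb_g)
  g$emb_g <- lE$dg; g$emb_b <- lE$db
  dE <- lE$dX
  gTok <- matrix(0, cfg$vocab_size, d)
  rs <- rowsum(dE, cache$idsVec)
  gTok[as.integer(rownames(rs)), ] <- rs
  g$tok_emb <- gTok
  gPos <- matrix(0, cfg$max_positions, d)
  rsP <- rowsum(dE, cache$posVec)
  gPos[as.integer(rownames(rsP)), ] <- rsP
  g$pos_emb <- gPos
  g
}

#' Classify one encoded token sequence
#'
#' Runs the encoder in evaluation mode on a single padded token sequence and
#' returns the class probabilities. The sequence must be padded to the model's
#' \code{max_positions}; padding positions carry no weight (the output is
#' invariant to their embedding values).
#'
#' @param model a [TransformerModel].
#' @param tokens encoded token list from [encodeTokens()] with
#'   \code{length(ids) == max_positions}.
#' @return numeric vector \code{c(p_neg, p_pos)} summing to 1.
#' @export
classify <- function(model, tokens) {
  stopifnot(is(model, "TransformerModel"))
  if (length(tokens$ids) != model@config$max_positions)
    stop(sprintf("classify: token length %d != max_positions %d",
                 length(tokens$ids), model@config$max_positions))
  nr <- tokens$n_real
  fw <- tfForward(model, matrix(tokens$ids[seq_len(nr)], 1L),
                  matrix(1L, 1L, nr))
  p <- as.numeric(fw$probs)
  names(p) <- c("p_neg", "p_pos")
  p
}

#' Per-layer attention maps for one sequence
#'
#' Runs the encoder in evaluation mode on the real (non-padding) tokens and
#' returns, for every layer, the per-head attention weight matrices. Each row
#' is a query position and sums to 1.
#'
#' @param model a [TransformerModel].
#' @param tokens encoded token list from [encodeTokens()].
#' @return list with one element per layer: \code{list(layer = l, weights =
#'   array(n_real, n_real, n_heads))}.
#' @export
getAttentionMaps <- function(model, tokens) {
  nr <- tokens$n_real
  fw <- tfForward(model, matrix(tokens$ids[seq_len(nr)], 1L),
                  matrix(1L, 1L, nr), collectAttention = TRUE)
  lapply(seq_along(fw$attention), function(l)
    list(layer = l, weights = fw$attention[[l]][[1L]]))
}

# Tokenize and score many sequences; returns p_pos in input order. Sequences
# are bucketed by token count so each forward batch is padded only to its own
# maximum.
classifySeqs <- function(model, seqs, batchSize = 16L) {
  cfg <- model@config
  idsList <- lapply(seqs, function(s)
    c(1L, kmerIds(kmerize(s, cfg$k, cfg$stride), model@vocab), 2L))
  lens <- lengths(idsList)
  if (any(lens > cfg$max_positions))
    stop("classifySeqs: an encoded sequence exceeds max_positions")
  ord <- order(lens)
  pPos <- numeric(length(seqs))
  padId <- specialId(model@vocab, "[PAD]")
  for (chunk in split(ord, ceiling(seq_along(ord) / batchSize))) {
    Lc <- max(lens[chunk])
    ids <- t(vapply(chunk, function(i)
      c(idsList[[i]], rep(padId, Lc - lens[i])), integer(Lc)))
    mask <- t(vapply(chunk, function(i)
      c(rep(1L, lens[i]), rep(0L, Lc - lens[i])), integer(Lc)))
    fw <- tfForward(model, ids, mask)
    pPos[chunk] <- fw$probs[, 2L]
  }
  pPos
}

#' Save / load a model
#'
#' The configuration and vocabulary are embedded in the checkpoint.
#'
#' @param model a [TransformerModel].
#' @param path checkpoint file path.
#' @return `saveModel()` returns `path` invisibly; `loadModel()` the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               k = model@vocab@k, tokens = model@vocab@tokens), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("TransformerModel", config = x$config, params = x$params,
      vocab = new("KmerVocab", k = x$k, tokens = x$tokens))
}
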