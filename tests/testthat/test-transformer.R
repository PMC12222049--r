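test_that("a single attention head matches the dense formula oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:6, 1L); d <- 8L; dk <- 4L
    M <- matrix(rnorm(n * d), n, d)
    Wq <- matrix(rnorm(d * dk), d, dk)
    Wk <- matrix(rnorm(d * dk), d, dk)
    Wv <- matrix(rnorm(d * dk), d, dk)
    got <- attentionHead(M, Wq, Wk, Wv)
    want <- denseHeadOracle(M, Wq, Wk, Wv)
    expect_lt(max(abs(got$weights - want$weights)), 1e-5)
    expect_lt(max(abs(got$values - want$values)), 1e-5)
  }
})

test_that("attention degenerate cases behave as softmax dictates", {
  d <- 6L
  W <- diag(d)[, 1:3]
  one <- attentionHead(matrix(rnorm(d), 1L, d), W, W, W)
  expect_equal(one$weights, matrix(1, 1L, 1L))
  # identical embeddings at all positions -> uniform attention rows
  M <- matrix(rep(rnorm(d), each = 5L), 5L, d)
  uni <- attentionHead(M, W, W, W)
  expect_equal(uni$weights, matrix(1 / 5, 5L, 5L), tolerance = 1e-12)
  expect_error(attentionHead(M, W, W, W, mask = rep(0L, 5L)), "masked")
})

test_that("attention masking zeroes padding keys and renormalizes rows", {
  set.seed(9)
  M <- matrix(rnorm(6 * 8), 6L, 8L)
  W <- matrix(rnorm(8 * 4), 8L, 4L)
  mask <- c(1L, 1L, 1L, 1L, 0L, 0L)
  got <- attentionHead(M, W, W, W, mask)
  expect_true(all(got$weights[, 5:6] < 1e-12))
  expect_equal(rowSums(got$weights), rep(1, 6L), tolerance = 1e-10)
  # equals the dense oracle run on the real positions only
  want <- denseHeadOracle(M[1:4, ], W, W, W)
  expect_lt(max(abs(got$weights[1:4, 1:4] - want$weights)), 1e-10)
})

test_that("multi-head attention equals the concat-then-project oracle", {
  set.seed(12)
  d <- 8L; dk <- 2L
  M <- matrix(rnorm(5 * d), 5L, d)
  heads <- lapply(1:4, function(h) list(Wq = matrix(rnorm(d * dk), d, dk),
                                        Wk = matrix(rnorm(d * dk), d, dk),
                                        Wv = matrix(rnorm(d * dk), d, dk)))
  Wo <- matrix(rnorm(d * d), d, d)
  got <- multiHeadAttention(M, heads, Wo)
  concat <- do.call(cbind, lapply(heads, function(h)
    denseHeadOracle(M, h$Wq, h$Wk, h$Wv)$values))
  expect_lt(max(abs(got - concat %*% Wo)), 1e-8)
  expect_identical(dim(got), dim(M))
  # one head with identity output projection returns the head values
  one <- multiHeadAttention(M, heads[1], diag(dk))
  h1 <- denseHeadOracle(M, heads[[1]]$Wq, heads[[1]]$Wk, heads[[1]]$Wv)
  expect_equal(one, h1$values, tolerance = 1e-8)
  # zero value projections give a zero output
  zheads <- lapply(heads, function(h) { h$Wv <- h$Wv * 0; h })
  expect_equal(max(abs(multiHeadAttention(M, zheads, Wo))), 0)
  expect_error(multiHeadAttention(M, heads, matrix(0, 3L, 3L)), "match")
})

test_that("classification head is symmetric at zero and deterministic", {
  m <- tinyModel()
  # zeroed classifier weights -> symmetric logits -> (0.5, 0.5)
  m@params$cls_W[] <- 0
  m@params$cls_b[] <- 0
  enc <- encodeTokens(kmerize("ACGTAGAC", 2L, 1L), vocab2(), 12L)
  p <- classify(m, enc)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-12)
  # softmax closed form: logits (2, 0) -> p_pos for the class with logit 2
  expect_equal(bactgene:::softmaxVec(c(0, 2))[2], 0.880797, tolerance = 1e-6)
  # determinism and normalization
  m2 <- tinyModel()
  p1 <- classify(m2, enc); p2 <- classify(m2, enc)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_error(classify(m2, encodeTokens(kmerize("ACGTA", 2L, 1L),
                                         vocab2(), 8L)),
               "max_positions")
})

test_that("classification is invariant to padding-position embeddings", {
  m <- tinyModel()
  enc <- encodeTokens(kmerize("ACGTAGAC", 2L, 1L), vocab2(), 12L)
  base <- classify(m, enc)
  mPerturbed <- m
  padId <- match("[PAD]", vocab2()@tokens)
  mPerturbed@params$tok_emb[padId, ] <-
    mPerturbed@params$tok_emb[padId, ] + 100
  expect_equal(classify(mPerturbed, enc), base, tolerance = 1e-5)
  # batched scoring with mixed lengths equals per-sequence scoring
  seqs <- c("ACGTAGAC", "ACGT", "ACGTACGTAC")
  batch <- bactgene:::classifySeqs(m, seqs, batchSize = 3L)
  solo <- vapply(seqs, function(s) {
    enc <- encodeTokens(kmerize(s, 2L, 1L), vocab2(), 12L)
    unname(classify(m, enc)["p_pos"])
  }, numeric(1))
  expect_equal(batch, unname(solo), tolerance = 1e-10)
})

test_that("attention maps are row-stochastic, stable and sized to the input", {
  tis <- tisShapeModel()
  w <- randomGenomeSeq(60L, 77L)
  enc <- encodeTokens(kmerize(w, 6L, 1L), vocab6(), 57L)
  maps <- getAttentionMaps(tis, enc)
  expect_length(maps, tis@config$n_layers)
  for (m in maps) {
    expect_identical(dim(m$weights), c(57L, 57L, tis@config$n_heads))
    for (h in seq_len(dim(m$weights)[3]))
      expect_equal(rowSums(m$weights[, , h]), rep(1, 57L), tolerance = 1e-5)
  }
  maps2 <- getAttentionMaps(tis, enc)
  expect_identical(maps, maps2)
})

test_that("analytic gradients match finite differences", {
  m <- tinyModel(maxPositions = 7L)
  set.seed(7)
  ids <- matrix(sample(5:20, 21L, replace = TRUE), 3L, 7L)
  ids[, 1] <- 1L
  mask <- rbind(rep(1L, 7L), c(rep(1L, 5L), 0L, 0L), c(rep(1L, 3L), rep(0L, 4L)))
  ids[mask == 0L] <- 3L
  labels <- c(1L, 0L, 1L)
  fw <- bactgene:::tfForward(m, ids, mask, train = TRUE)
  gr <- bactgene:::tfBackward(m, fw$cache, labels)
  lossAt <- function(P) {
    mm <- m; mm@params <- P
    bactgene:::crossEntropy(bactgene:::tfForward(mm, ids, mask)$probs, labels)
  }
  eps <- 1e-5
  checkEntries <- function(get, set, n = 3L) {
    gAll <- get(gr)
    idx <- sample(length(gAll), min(n, length(gAll)))
    for (i in idx) {
      P1 <- m@params; x <- get(P1); x[i] <- x[i] + eps; P1 <- set(P1, x)
      P2 <- m@params; x <- get(P2); x[i] <- x[i] - eps; P2 <- set(P2, x)
      num <- (lossAt(P1) - lossAt(P2)) / (2 * eps)
      expect_lt(abs(num - gAll[i]) / max(1e-6, abs(num) + abs(gAll[i])), 1e-3)
    }
  }
  set.seed(99)
  checkEntries(function(P) P$tok_emb, function(P, x) { P$tok_emb <- x; P })
  checkEntries(function(P) P$pos_emb, function(P, x) { P$pos_emb <- x; P })
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "ln1_g", "ln2_b", "bq")) {
    local({
      n2 <- nm
      checkEntries(function(P) P$layers[[1]][[n2]],
                   function(P, x) { P$layers[[1]][[n2]] <- x; P })
      checkEntries(function(P) P$layers[[2]][[n2]],
                   function(P, x) { P$layers[[2]][[n2]] <- x; P })
    })
  }
  checkEntries(function(P) P$pool_W, function(P, x) { P$pool_W <- x; P })
  checkEntries(function(P) P$cls_W, function(P, x) { P$cls_W <- x; P })
})

test_that("models save and load losslessly with embedded config", {
  m <- tinyModel()
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(m2@config, m@config)
  expect_identical(m2@params, m@params)
  enc <- encodeTokens(kmerize("ACGTAGAC", 2L, 1L), vocab2(), 12L)
  expect_identical(classify(m, enc), classify(m2, enc))
})
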