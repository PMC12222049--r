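test_that("TIS selection is an argmax with 5'-most tie-breaking", {
  sc <- data.frame(candidate_start = c(10L, 40L), orf_start = c(10L, 40L),
                   orf_end = c(100L, 100L), p_tis = c(0.2, 0.9))
  expect_equal(selectTis(sc), 2L)
  tie <- data.frame(candidate_start = c(10L, 40L), orf_start = c(10L, 40L),
                    orf_end = c(100L, 100L), p_tis = c(0.7, 0.7))
  expect_equal(selectTis(tie), 1L)   # longest ORF wins ties
  expect_error(selectTis(sc[0, ]), "no scored")
  # max-scan oracle over random score lists
  set.seed(14)
  for (i in 1:100) {
    n <- sample(1:8, 1L)
    sc <- data.frame(candidate_start = seq_len(n) * 3L,
                     orf_start = seq_len(n) * 3L, orf_end = 300L,
                     p_tis = round(runif(n), 2))
    sel <- selectTis(sc)
    best <- max(sc$p_tis)
    oracle <- min(which(sc$p_tis == best))  # rows are 5'- to 3'-ordered
    expect_equal(sel, oracle)
  }
})

test_that("TIS candidate scoring composes window building with classify", {
  g <- smallCorpus()[[1]]
  groups <- groupOrfs(extractOrfs(g$seq, g$id, 90L))
  big <- groups[[which.max(vapply(groups, nrow, integer(1)))]]
  tis <- tisShapeModel()
  scored <- predictTis(big, g$seq, tis, flank = 30L)
  expect_equal(nrow(scored), nrow(big))
  # upstream-to-downstream order = decreasing ORF length
  lens <- scored$orf_end - scored$orf_start
  expect_true(all(diff(lens) <= 0))
  # probabilities equal classify() applied window-wise
  for (i in seq_len(min(3L, nrow(scored)))) {
    w <- if (big$strand[1] == "+")
      substr(g$seq, scored$candidate_start[i] - 29L,
             scored$candidate_start[i] + 30L)
    else
      bactgene:::revcompChr(substr(g$seq, scored$candidate_start[i] - 29L,
                                   scored$candidate_start[i] + 30L))
    enc <- encodeTokens(kmerize(w, 6L, 1L), tis@vocab, 57L)
    expect_equal(scored$p_tis[i], unname(classify(tis, enc)["p_pos"]),
                 tolerance = 1e-10)
  }
})

test_that("group CDS scoring is independent of group order", {
  g <- smallCorpus()[[3]]
  sub <- substr(g$seq, 1L, 4000L)
  cds <- tisShapeModel()  # any scorer works for the invariance check
  cdsModel <- newTransformer(
    transformerConfig(nLayers = 1L, dHidden = 16L, nHeads = 2L,
                      maxPositions = 512L, vocabSize = 4100L, k = 6L,
                      stride = 3L), vocab6(), seed = 5L)
  r1 <- predictCds(sub, g$id, cdsModel)
  expect_equal(nrow(r1$scores), length(r1$groups))
  # rescoring the same groups in reverse order yields identical values
  revScores <- bactgene:::classifySeqs(
    cdsModel, rev(vapply(r1$groups, function(x) substr(x$seq[1], 1, 510),
                         character(1))))
  expect_equal(rev(revScores), unname(r1$scores$p_cds), tolerance = 1e-10)
})

test_that("annotation output respects pipeline invariants", {
  g <- smallCorpus()[[1]]
  cdsModel <- newTransformer(
    transformerConfig(nLayers = 1L, dHidden = 16L, nHeads = 2L,
                      maxPositions = 512L, vocabSize = 4100L, k = 6L,
                      stride = 3L), vocab6(), seed = 5L)
  tis <- tisShapeModel()
  sub <- substr(g$seq, 1L, 3000L)
  # untrained scores hover near 0.5; a low threshold exercises both stages
  anno <- annotateGenome(sub, g$id, cdsModel, tis, threshold = 0.45)
  p <- predictions(anno)
  expect_s4_class(anno, "GenePredictionSet")
  expect_true(validObject(anno))
  expect_gt(nrow(p), 0L)
  expect_true(all(p$prediction_max_likelihood %in% c(0L, 1L)))
  expect_true(all((p$end - p$start) %% 3L == 0L))
  # the selected TIS is a member of its group's candidate starts
  orfs <- extractOrfs(sub, g$id, 90L)
  keys <- paste(orfs$strand, orfs$start, orfs$end)
  expect_true(all(paste(p$strand, p$start, p$end) %in% keys))
  # determinism
  anno2 <- annotateGenome(sub, g$id, cdsModel, tis, threshold = 0.45)
  expect_identical(predictions(anno2), p)
  # threshold above every score -> no predictions
  none <- annotateGenome(sub, g$id, cdsModel, tis, threshold = 1.0)
  expect_true(nrow(predictions(none)) == 0L ||
                all(predictions(none)$p_cds >= 1.0))
  # GFF output validates and round-trips coordinates
  f <- withr::local_tempfile(fileext = ".gff")
  writeAnnotation(anno, f, "gff")
  back <- readCdsAnnotations(f)
  expect_identical(sort(paste(back$strand, back$start, back$end)),
                   sort(paste(p$strand, p$start, p$end)))
})

test_that("an all-N genome yields an empty annotation set", {
  cdsModel <- newTransformer(
    transformerConfig(nLayers = 1L, dHidden = 16L, nHeads = 2L,
                      maxPositions = 512L, vocabSize = 4100L, k = 6L,
                      stride = 3L), vocab6(), seed = 5L)
  anno <- annotateGenome(strrep("N", 500L), "empty", cdsModel,
                         tisShapeModel())
  expect_equal(nrow(predictions(anno)), 0L)
  f <- withr::local_tempfile(fileext = ".gff")
  writeAnnotation(anno, f, "gff")
  expect_identical(readLines(f), "##gff-version 3")
})

test_that("mismatched tokenizer settings are rejected before inference", {
  cdsModel <- newTransformer(
    transformerConfig(nLayers = 1L, dHidden = 8L, nHeads = 2L,
                      maxPositions = 64L, vocabSize = 20L, k = 2L,
                      stride = 3L), vocab2(), seed = 1L)
  expect_error(annotateGenome("ACGT", "g", cdsModel, tisShapeModel()),
               "k-mer length")
})
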