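test_that("minimal and nested ORFs are extracted with retained nesting", {
  one <- extractOrfs("ATGTAA", "g", minLen = 6L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 0L)
  expect_equal(one$end, 6L)
  expect_equal(one$strand, "+")

  nested <- extractOrfs("ATGATGTTTTAA", "g", minLen = 6L)
  fwd <- nested[nested$strand == "+", ]
  expect_equal(sort(fwd$start), c(0L, 3L))
  expect_equal(unique(fwd$end), 12L)         # same stop codon
  expect_equal(unique(fwd$stop_key), 12L)
})

test_that("ORF extraction matches the brute-force enumeration oracle", {
  for (seed in c(7L, 21L, 35L)) {
    seq <- randomGenomeSeq(2000L, seed)
    got <- extractOrfs(seq, "g", minLen = 6L)
    want <- bruteForceOrfs(seq, minLen = 6L)
    expect_identical(orfKey(got), orfKey(want))
    # min-length filtering consistent with the oracle
    got90 <- extractOrfs(seq, "g", minLen = 90L)
    expect_identical(orfKey(got90),
                     orfKey(bruteForceOrfs(seq, minLen = 90L)))
  }
})

test_that("every extracted ORF obeys the candidate invariants", {
  seq <- randomGenomeSeq(3000L, 11L)
  orfs <- extractOrfs(seq, "g", minLen = 30L)
  expect_gt(nrow(orfs), 0L)
  expect_true(all((orfs$end - orfs$start) %% 3L == 0L))
  expect_true(all(substr(orfs$seq, 1L, 3L) %in% c("ATG", "TTG", "GTG", "CTG")))
  lens <- nchar(orfs$seq)
  expect_true(all(substr(orfs$seq, lens - 2L, lens) %in%
                    c("TAA", "TAG", "TGA")))
  # no internal in-frame stop codons
  noInternal <- vapply(orfs$seq, function(s) {
    starts <- seq(1L, nchar(s) - 5L, by = 3L)
    !any(substring(s, starts, starts + 2L) %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_true(all(noInternal))
  # minus-strand sequences are the reverse complement of the genome slice
  minus <- orfs[orfs$strand == "-", ][1L, ]
  expect_identical(
    minus$seq,
    bactgene:::revcompChr(substr(seq, minus$start + 1L, minus$end)))
})

test_that("grouping partitions ORFs by stop key with longest member first", {
  nested <- extractOrfs("ATGATGTTTTAA", "g", minLen = 6L)
  fwd <- nested[nested$strand == "+", ]
  groups <- groupOrfs(fwd)
  expect_length(groups, 1L)
  expect_equal(nrow(groups[[1]]), 2L)
  expect_equal(groups[[1]]$start, c(0L, 3L))  # longest first

  seq <- randomGenomeSeq(5000L, 13L)
  orfs <- extractOrfs(seq, "g", minLen = 30L)
  groups <- groupOrfs(orfs)
  # group count equals the number of distinct (strand, stop) keys
  expect_length(groups, length(unique(paste(orfs$strand, orfs$stop_key))))
  # members nested: identical strand and stop within each group
  expect_true(all(vapply(groups, function(g)
    length(unique(g$stop_key)) == 1L && length(unique(g$strand)) == 1L,
    logical(1))))
})

test_that("CDS labeling is stop-anchored and truncates to the maximum length", {
  g <- smallCorpus()[[1]]
  groups <- groupOrfs(extractOrfs(g$seq, g$id, 90L))
  ex <- labelCds(groups, g$cds, organismId = g$id)
  expect_equal(nrow(ex), length(groups))      # one example per group
  expect_equal(sum(ex$label), nrow(g$cds))    # every planted gene is positive
  expect_true(all(nchar(ex$seq) <= 510L))
  # positives sit exactly on annotated stops
  refk <- paste(g$cds$strand, ifelse(g$cds$strand == "+", g$cds$end,
                                     g$cds$start))
  gk <- vapply(groups, function(x) paste(x$strand[1], x$stop_key[1]),
               character(1))
  expect_setequal(which(ex$label == 1L), which(gk %in% refk))
  # a long matching ORF is truncated from the 5' side (start codon kept)
  long <- ex[nchar(ex$seq) == 510L, ]
  if (nrow(long) > 0L)
    expect_true(all(substr(long$seq, 1L, 3L) %in%
                      c("ATG", "TTG", "GTG", "CTG")))
})

test_that("TIS windows have fixed geometry and one positive per matched gene", {
  g <- smallCorpus()[[2]]
  groups <- groupOrfs(extractOrfs(g$seq, g$id, 90L))
  tw <- buildTisWindows(groups, g$cds, g$seq, flank = 30L, organismId = g$id)
  expect_true(all(nchar(tw$seq) == 60L))
  expect_true(all(substr(tw$seq, 31L, 33L) %in% c("ATG", "TTG", "GTG", "CTG")))
  # only reference-matched groups contribute, one true start each
  perGroup <- tapply(tw$label, tw$group_key, sum)
  expect_true(all(perGroup == 1L))
  expect_equal(sum(tw$label), nrow(g$cds))
})

test_that("TIS windows at contig boundaries are skipped with a count", {
  # plant a gene 10 bp from the contig start: its window cannot fit
  seq <- paste0(paste(rep("C", 10), collapse = ""),
                "ATGGCTGCTGCTGCTGCTGCTGCTGCTGCTTAA",
                paste(rep("C", 80), collapse = ""))
  cds <- data.frame(seqid = "g", start = 10L, end = 43L, strand = "+")
  groups <- groupOrfs(extractOrfs(seq, "g", minLen = 30L))
  expect_message(
    tw <- buildTisWindows(groups, cds, seq, flank = 30L),
    "skipped 1 window")
  expect_false(10L %in% tw$candidate_start)
})

test_that("length balancing caps negatives per bin at the positive count", {
  mk <- function(n, lens, label) data.frame(
    seq = strrep("A", 9L), label = label, organism_id = "o",
    group_key = paste0("k", seq_len(n), label), length = lens)
  pos <- mk(10L, rep(320L, 10L), 1L)
  neg <- mk(100L, rep(330L, 100L), 0L)
  bal <- lengthBalance(pos, neg, binWidth = 50L, seed = 4L)
  expect_equal(sum(bal$label == 0L), 10L)
  expect_equal(sum(bal$label == 1L), 10L)
  # deterministic under the seed
  bal2 <- lengthBalance(pos, neg, binWidth = 50L, seed = 4L)
  expect_identical(bal$group_key, bal2$group_key)
  # histogram oracle on mixed distributions: per-bin negatives = min(pos, neg)
  set.seed(8)
  pos <- mk(60L, sample(seq(90L, 600L, 3L), 60L, TRUE), 1L)
  neg <- mk(200L, sample(seq(90L, 300L, 3L), 200L, TRUE), 0L)
  bal <- suppressWarnings(lengthBalance(pos, neg, binWidth = 50L, seed = 9L))
  posBin <- table(pos$length %/% 50L)
  negBin <- table(neg$length %/% 50L)
  balNegBin <- table(bal$length[bal$label == 0L] %/% 50L)
  for (b in names(posBin)) {
    wantN <- min(posBin[[b]], if (b %in% names(negBin)) negBin[[b]] else 0L)
    gotN <- if (b %in% names(balNegBin)) balNegBin[[b]] else 0L
    expect_equal(gotN, wantN)
  }
  # a populated positive bin with no negatives warns
  expect_warning(lengthBalance(mk(3L, rep(900L, 3L), 1L), neg, 50L, 1L),
                 "no negatives")
})

test_that("undersampling equalizes classes and is an identity when balanced", {
  df <- data.frame(seq = "A", label = rep(c(0L, 1L), c(100L, 40L)),
                   organism_id = "o")
  bal <- undersample(df, seed = 2L)
  expect_equal(as.vector(table(bal$label)), c(40L, 40L))
  even <- data.frame(seq = "A", label = rep(c(0L, 1L), each = 5L))
  expect_identical(undersample(even, seed = 1L), even)
  expect_error(undersample(data.frame(label = rep(1L, 4L)), 1L),
               "both classes")
})

test_that("organism split partitions organisms disjointly and reproducibly", {
  df <- data.frame(label = 1L,
                   organism_id = rep(sprintf("org%02d", 1:10), each = 7L))
  sp <- splitByOrganism(df, c(0.6, 0.2, 0.2), seed = 5L)
  orgSets <- lapply(sp, function(x) unique(x$organism_id))
  expect_length(orgSets$train, 6L)
  expect_length(orgSets$test, 2L)
  expect_length(orgSets$eval, 2L)
  expect_length(intersect(orgSets$train, orgSets$test), 0L)
  expect_length(intersect(orgSets$train, orgSets$eval), 0L)
  expect_length(intersect(orgSets$test, orgSets$eval), 0L)
  expect_equal(sum(vapply(sp, nrow, integer(1))), nrow(df))
  sp2 <- splitByOrganism(df, c(0.6, 0.2, 0.2), seed = 5L)
  expect_identical(sp, sp2)
  expect_error(splitByOrganism(data.frame(organism_id = c("a", "b")),
                               seed = 1L), "at least")
})
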