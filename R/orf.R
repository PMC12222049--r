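#' Extract open reading frames from both strands
#'
#' Scans all three frames of the forward and reverse strands for ORFs that
#' begin with one of the start codons ATG, TTG, GTG or CTG and end at the next
#' in-frame stop codon (TAA, TAG or TGA). Nested overlapping ORFs sharing a
#' stop are all retained: every qualifying in-frame start codon upstream of a
#' stop contributes one candidate.
#'
#' @param seq genome nucleotide string (A/C/G/T/N, uppercase).
#' @param genomeId sequence identifier recorded on each candidate.
#' @param minLen minimum ORF length in bp including the stop codon; must be a
#'   multiple of 3 and at least 6.
#' @return data.frame with one row per ORF: \code{genome_id}, \code{strand},
#'   \code{start}, \code{end} (0-based half-open, forward-strand), \code{frame}
#'   (0-2 on the scanned strand), \code{stop_key} (forward-strand coordinate of
#'   the stop boundary: \code{end} on +, \code{start} on -), and \code{seq}
#'   (reading orientation, reverse-complemented for -).
#' @export
extractOrfs <- function(seq, genomeId = "genome", minLen = 90L) {
  stopifnot(minLen >= 6L, minLen %% 3L == 0L)
  n <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcompChr(seq)
    for (frame in 0:2) res <- orfsInFrame(s, frame, strand, n, minLen, res)
  }
  if (length(res) == 0L)
    return(data.frame(genome_id = character(), strand = character(),
                      start = integer(), end = integer(), frame = integer(),
                      stop_key = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out$genome_id <- genomeId
  out[, c("genome_id", "strand", "start", "end", "frame", "stop_key", "seq")]
}

# Scan one frame of one oriented strand; coordinates are mapped back to the
# forward strand for '-' ORFs. Appends rows to `acc` and returns it.
orfsInFrame <- function(s, frame, strand, n, minLen, acc) {
  nCodons <- (nchar(s) - frame) %/% 3L
  if (nCodons < 2L) return(acc)
  codonStart <- frame + 3L * (seq_len(nCodons) - 1L) + 1L   # 1-based
  codons <- substring(s, codonStart, codonStart + 2L)
  isStop  <- codons %in% STOP_CODONS
  isStart <- codons %in% START_CODONS
  if (!any(isStop) || !any(isStart)) return(acc)
  stopIdx <- which(isStop)
  # For each start codon, the next in-frame stop at or after it.
  startIdx <- which(isStart)
  nxt <- stopIdx[findInterval(startIdx, stopIdx, left.open = TRUE) + 1L]
  keep <- !is.na(nxt) & nxt > startIdx           # start strictly before stop
  startIdx <- startIdx[keep]; nxt <- nxt[keep]
  lenBp <- (nxt - startIdx + 1L) * 3L
  keep <- lenBp >= minLen
  if (!any(keep)) return(acc)
  startIdx <- startIdx[keep]; nxt <- nxt[keep]
  a <- codonStart[startIdx] - 1L                 # 0-based on scanned strand
  b <- codonStart[nxt] + 2L                      # half-open past the stop
  orfSeq <- substring(s, a + 1L, b)
  if (strand == "+") {
    fs <- a; fe <- b
  } else {
    fs <- n - b; fe <- n - a
  }
  acc[[length(acc) + 1L]] <- data.frame(
    strand = strand, start = fs, end = fe, frame = frame,
    stop_key = if (strand == "+") fe else fs, seq = orfSeq,
    stringsAsFactors = FALSE)
  acc
}

#' Group ORFs sharing a stop codon
#'
#' Partitions ORF candidates by (genome, strand, stop coordinate). All members
#' of a group are nested and end at the same stop codon; choosing the TIS
#' selects one member.
#'
#' @param orfs data.frame from [extractOrfs()].
#' @return named list of data.frames, members sorted by decreasing length;
#'   names are \code{"<genome_id>|<strand>|<stop_key>"}.
#' @export
groupOrfs <- function(orfs) {
  if (nrow(orfs) == 0L) return(list())
  key <- paste(orfs$genome_id, orfs$strand, orfs$stop_key, sep = "|")
  grp <- split(orfs, key)
  lapply(grp, function(g) g[order(g$end - g$start, decreasing = TRUE), ,
                            drop = FALSE])
}

# Stop-anchored match of ORF groups against reference CDS rows: a group is
# positive iff its (strand, stop boundary) equals a reference 3' end.
refStopKeys <- function(cds) {
  paste(cds$strand, ifelse(cds$strand == "+", cds$end, cds$start), sep = "|")
}
groupStopKeys <- function(groups) {
  vapply(groups, function(g) paste(g$strand[1], g$stop_key[1], sep = "|"),
         character(1))
}

#' Build coding/non-coding training examples from ORF groups
#'
#' One example per group, taken from its longest member. The label is 1 iff
#' the group's stop codon (strand + 3' coordinate) matches an annotated CDS 3'
#' end. Sequences longer than \code{maxLen} are truncated to the first
#' \code{maxLen} nt measured from the start codon in reading orientation.
#'
#' @param groups list from [groupOrfs()].
#' @param cds reference CDS data.frame (see [readCdsAnnotations()]).
#' @param maxLen maximum example length in nt.
#' @param organismId organism identifier carried on each example.
#' @return data.frame with columns \code{seq}, \code{label}, \code{organism_id},
#'   \code{group_key}, \code{length} (untruncated ORF length in bp).
#' @export
labelCds <- function(groups, cds, maxLen = 510L, organismId = "organism") {
  if (length(groups) == 0L)
    return(data.frame(seq = character(), label = integer(),
                      organism_id = character(), group_key = character(),
                      length = integer(), stringsAsFactors = FALSE))
  refKeys <- refStopKeys(cds)
  gKeys <- groupStopKeys(groups)
  seqs <- vapply(groups, function(g) g$seq[1], character(1))
  lens <- vapply(groups, function(g) g$end[1] - g$start[1], integer(1))
  long <- nchar(seqs) > maxLen
  seqs[long] <- substr(seqs[long], 1L, maxLen)
  data.frame(seq = unname(seqs), label = as.integer(gKeys %in% refKeys),
             organism_id = organismId, group_key = names(groups),
             length = unname(lens), stringsAsFactors = FALSE)
}

#' Build TIS candidate windows for reference-matched ORF groups
#'
#' Only groups whose stop matches a reference CDS 3' end contribute. For every
#' member ORF's start codon a window of \code{2 * flank} nt centered on the
#' codon boundary is cut in reading orientation
#' (\code{[start - flank, start + flank)}), so the start codon occupies window
#' offsets \code{flank .. flank+2}. The label is 1 iff the candidate start
#' equals the matched reference CDS 5' end. Windows that would extend past the
#' contig boundary are skipped; the skip count is reported with a message.
#'
#' @param groups list from [groupOrfs()].
#' @param cds reference CDS data.frame.
#' @param seq genome nucleotide string the groups were extracted from.
#' @param flank nt of context on each side of the start codon boundary.
#' @param organismId organism identifier carried on each window.
#' @return data.frame with columns \code{seq} (length \code{2*flank}),
#'   \code{label}, \code{organism_id}, \code{group_key}, \code{candidate_start}
#'   (forward-strand bp of the candidate start boundary), \code{orf_start},
#'   \code{orf_end}.
#' @export
buildTisWindows <- function(groups, cds, seq, flank = 30L,
                            organismId = "organism") {
  stopifnot(flank >= 0L)
  empty <- data.frame(seq = character(), label = integer(),
                      organism_id = character(), group_key = character(),
                      candidate_start = integer(), orf_start = integer(),
                      orf_end = integer(), stringsAsFactors = FALSE)
  if (length(groups) == 0L) return(empty)
  refKeys <- refStopKeys(cds)
  gKeys <- groupStopKeys(groups)
  matched <- which(gKeys %in% refKeys)
  if (length(matched) == 0L) return(empty)
  n <- nchar(seq)
  nSkipped <- 0L
  rows <- list()
  for (gi in matched) {
    g <- groups[[gi]]
    ref <- cds[refStopKeys(cds) == gKeys[gi], , drop = FALSE][1L, ]
    trueStart <- if (ref$strand == "+") ref$start else ref$end
    for (m in seq_len(nrow(g))) {
      if (g$strand[m] == "+") {
        cand <- g$start[m]; lo <- cand - flank; hi <- cand + flank
        if (lo < 0L || hi > n) { nSkipped <- nSkipped + 1L; next }
        w <- substr(seq, lo + 1L, hi)
      } else {
        cand <- g$end[m]; lo <- cand - flank; hi <- cand + flank
        if (lo < 0L || hi > n) { nSkipped <- nSkipped + 1L; next }
        w <- revcompChr(substr(seq, lo + 1L, hi))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq = w, label = as.integer(cand == trueStart),
        organism_id = organismId, group_key = names(groups)[gi],
        candidate_start = cand, orf_start = g$start[m], orf_end = g$end[m],
        stringsAsFactors = FALSE)
    }
  }
  if (nSkipped > 0L)
    message(sprintf("buildTisWindows: skipped %d window(s) at contig boundaries",
                    nSkipped))
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Length-matched downsampling of negative examples
#'
#' Bins examples by sequence length and samples negatives without replacement
#' within each bin so that no bin holds more negatives than positives. This
#' removes length as a trivially discriminative feature.
#'
#' @param pos,neg data.frames of positive/negative examples carrying a
#'   \code{length} column.
#' @param binWidth length bin width in bp.
#' @param seed RNG seed; the selection is deterministic given the seed.
#' @return data.frame of all positives plus the retained negatives.
#' @export
lengthBalance <- function(pos, neg, binWidth = 50L, seed = 1L) {
  stopifnot(binWidth > 0L)
  bin <- function(len) len %/% binWidth
  posBins <- table(bin(pos$length))
  negBin <- bin(neg$length)
  keep <- integer(0)
  withSeed(seed, {
    for (b in names(posBins)) {
      idx <- which(negBin == as.integer(b))
      want <- posBins[[b]]
      if (length(idx) == 0L) {
        warning(sprintf("lengthBalance: bin %s has %d positives but no negatives",
                        b, want))
        next
      }
      if (length(idx) > want) idx <- sort(sample(idx, want))
      keep <- c(keep, idx)
    }
  })
  rbind(pos, neg[keep, , drop = FALSE])
}

#' Random undersampling to equal class counts
#'
#' The majority class is sampled without replacement down to the minority
#' count. Used for the fixed-length TIS windows, where length balancing is
#' moot.
#'
#' @param examples data.frame with a \code{label} column in \{0,1\}.
#' @param seed RNG seed.
#' @return balanced data.frame with equal class counts.
#' @export
undersample <- function(examples, seed = 1L) {
  n1 <- sum(examples$label == 1L); n0 <- sum(examples$label == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undersample: both classes must be present")
  nKeep <- min(n0, n1)
  withSeed(seed, {
    keep0 <- sort(sample(which(examples$label == 0L), nKeep))
    keep1 <- sort(sample(which(examples$label == 1L), nKeep))
  })
  examples[sort(c(keep0, keep1)), , drop = FALSE]
}

#' Organism-held-out train/test/eval split
#'
#' Assigns whole organisms to partitions so that the organism sets of the
#' three partitions are pairwise disjoint; the test and evaluation sets then
#' contain only organisms absent from the training set.
#'
#' @param examples data.frame with an \code{organism_id} column.
#' @param fractions numeric length-3 vector (train, test, eval) summing to 1.
#' @param seed RNG seed.
#' @return list with elements \code{train}, \code{test}, \code{eval}.
#' @export
splitByOrganism <- function(examples, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  orgs <- unique(examples$organism_id)
  if (length(orgs) < 3L)
    stop("splitByOrganism: need at least as many organisms as partitions")
  withSeed(seed, perm <- sample(orgs))
  nTrain <- max(1L, round(fractions[1] * length(orgs)))
  nTest  <- max(1L, round(fractions[2] * length(orgs)))
  nTrain <- min(nTrain, length(orgs) - 2L)
  nTest  <- min(nTest, length(orgs) - nTrain - 1L)
  trainOrgs <- perm[seq_len(nTrain)]
  testOrgs  <- perm[nTrain + seq_len(nTest)]
  evalOrgs  <- perm[-seq_len(nTrain + nTest)]
  list(train = examples[examples$organism_id %in% trainOrgs, , drop = FALSE],
       test  = examples[examples$organism_id %in% testOrgs, , drop = FALSE],
       eval  = examples[examples$organism_id %in% evalOrgs, , drop = FALSE])
}
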