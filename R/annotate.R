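# Two-stage genome annotation: ORF groups are scored for coding potential via
# their longest member; within predicted-coding groups every candidate start
# is scored by the TIS model and the highest-probability site is retained
# (prediction_max_likelihood = 1).

#' Score ORF groups for coding potential
#'
#' Each group is represented by its longest member, truncated to \code{maxLen}
#' nt from the start codon, and scored with the CDS classifier.
#'
#' @param seq genome nucleotide string.
#' @param genomeId sequence identifier.
#' @param model CDS-task [TransformerModel] (stride-3 tokenization).
#' @param threshold groups with \code{p_cds >= threshold} are flagged coding.
#' @param minLen minimum ORF length passed to [extractOrfs()].
#' @param maxLen truncation length for the scored sequence.
#' @return list with \code{groups} (the full [groupOrfs()] list) and
#'   \code{scores}: a data.frame with \code{group_key}, \code{p_cds},
#'   \code{coding}.
#' @export
predictCds <- function(seq, genomeId, model, threshold = 0.5, minLen = 90L,
                       maxLen = 510L) {
  orfs <- extractOrfs(seq, genomeId, minLen)
  groups <- groupOrfs(orfs)
  if (length(groups) == 0L)
    return(list(groups = groups,
                scores = data.frame(group_key = character(),
                                    p_cds = numeric(), coding = logical(),
                                    stringsAsFactors = FALSE)))
  seqs <- vapply(groups, function(g) g$seq[1], character(1))
  long <- nchar(seqs) > maxLen
  seqs[long] <- substr(seqs[long], 1L, maxLen)
  pCds <- classifySeqs(model, unname(seqs))
  list(groups = groups,
       scores = data.frame(group_key = names(groups), p_cds = pCds,
                           coding = pCds >= threshold,
                           stringsAsFactors = FALSE))
}

#' Score candidate translation initiation sites within one ORF group
#'
#' Builds the fixed-length window around every member's start codon (in
#' reading orientation) and scores it with the TIS classifier. Windows that
#' would extend past the contig boundary are skipped.
#'
#' @param group one element of a [groupOrfs()] list.
#' @param seq genome nucleotide string.
#' @param model TIS-task [TransformerModel] (stride-1 tokenization).
#' @param flank context nt on each side of the start codon boundary.
#' @return data.frame with \code{candidate_start}, \code{orf_start},
#'   \code{orf_end}, \code{p_tis}, ordered upstream-to-downstream (decreasing
#'   ORF length); zero rows when every window hits a boundary.
#' @export
predictTis <- function(group, seq, model, flank = 30L) {
  n <- nchar(seq)
  rows <- list()
  for (m in seq_len(nrow(group))) {
    if (group$strand[m] == "+") {
      cand <- group$start[m]; lo <- cand - flank; hi <- cand + flank
      if (lo < 0L || hi > n) next
      w <- substr(seq, lo + 1L, hi)
    } else {
      cand <- group$end[m]; lo <- cand - flank; hi <- cand + flank
      if (lo < 0L || hi > n) next
      w <- revcompChr(substr(seq, lo + 1L, hi))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      candidate_start = cand, orf_start = group$start[m],
      orf_end = group$end[m], window = w, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(candidate_start = integer(), orf_start = integer(),
                      orf_end = integer(), p_tis = numeric(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$p_tis <- classifySeqs(model, df$window)
  df$window <- NULL
  df[order(df$orf_end - df$orf_start, decreasing = TRUE), , drop = FALSE]
}

#' Select the maximum-likelihood TIS
#'
#' Returns the row index of the candidate with the highest TIS probability;
#' ties are broken toward the 5'-most candidate (the longest ORF member).
#'
#' @param scored data.frame from [predictTis()] with columns \code{p_tis},
#'   \code{orf_start}, \code{orf_end}.
#' @return integer row index of the selected candidate.
#' @export
selectTis <- function(scored) {
  if (nrow(scored) == 0L) stop("selectTis: no scored candidates")
  len <- scored$orf_end - scored$orf_start
  ord <- order(-scored$p_tis, -len)
  ord[1L]
}

#' Annotate a genome with the two-stage pipeline
#'
#' Extracts ORFs, groups them by stop codon, flags coding groups with the CDS
#' model, scores candidate starts within coding groups with the TIS model and
#' retains the maximum-likelihood site per group. Groups whose every candidate
#' window hits a contig boundary fall back to the longest member's start with
#' \code{prediction_max_likelihood = 0}.
#'
#' @param seq genome nucleotide string (or a length-1 named vector from
#'   [readGenome()]).
#' @param genomeId sequence identifier (defaults to the name of \code{seq}).
#' @param cdsModel,tisModel trained [TransformerModel]s for the two stages.
#' @param threshold CDS probability threshold.
#' @param minLen minimum ORF length in bp.
#' @param flank TIS window flank in nt.
#' @return a [GenePredictionSet].
#' @export
annotateGenome <- function(seq, genomeId = NULL, cdsModel, tisModel,
                           threshold = 0.5, minLen = 90L, flank = 30L) {
  if (is.null(genomeId))
    genomeId <- if (!is.null(names(seq))) names(seq)[1] else "genome"
  seq <- unname(seq[[1]])
  if (cdsModel@config$k != tisModel@config$k)
    stop("annotateGenome: CDS and TIS models use different k-mer lengths")
  stage1 <- predictCds(seq, genomeId, cdsModel, threshold, minLen)
  coding <- which(stage1$scores$coding)
  rows <- list()
  nFallback <- 0L
  for (gi in coding) {
    g <- stage1$groups[[gi]]
    scored <- predictTis(g, seq, tisModel, flank)
    if (nrow(scored) == 0L) {
      # every window hit a boundary: keep the longest member, flag 0
      nFallback <- nFallback + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        strand = g$strand[1], start = g$start[1], end = g$end[1],
        p_cds = stage1$scores$p_cds[gi], p_tis = NA_real_,
        prediction_max_likelihood = 0L, stringsAsFactors = FALSE)
      next
    }
    sel <- selectTis(scored)
    rows[[length(rows) + 1L]] <- data.frame(
      strand = g$strand[1], start = scored$orf_start[sel],
      end = scored$orf_end[sel], p_cds = stage1$scores$p_cds[gi],
      p_tis = scored$p_tis[sel], prediction_max_likelihood = 1L,
      stringsAsFactors = FALSE)
  }
  if (nFallback > 0L)
    message(sprintf(
      "annotateGenome: %d group(s) fell back to the longest member (boundary windows)",
      nFallback))
  preds <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(strand = character(), start = integer(), end = integer(),
               p_cds = numeric(), p_tis = numeric(),
               prediction_max_likelihood = integer(), stringsAsFactors = FALSE)
  new("GenePredictionSet", genomeId = genomeId, predictions = preds,
      provenance = list(threshold = threshold, min_orf_len = minLen,
                        flank = flank,
                        cds_config = cdsModel@config,
                        tis_config = tisModel@config))
}
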