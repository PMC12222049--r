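# Matched-end benchmarking: a reference gene is 3'-matched when some
# prediction shares its strand and stop coordinate (gene identity), and
# 5'+3'-matched when the start coordinate also agrees (correct TIS).

#' Compare predictions against reference annotations
#'
#' @param predicted a [GenePredictionSet].
#' @param reference reference CDS data.frame (see [readCdsAnnotations()]),
#'   0-based half-open coordinates.
#' @return a [BenchmarkResult]. Each reference gene is counted at most once;
#'   percentages are \code{100 * count / nReference}.
#' @export
matchAnnotations <- function(predicted, reference) {
  stopifnot(is(predicted, "GenePredictionSet"))
  p <- predictions(predicted)
  pStop <- paste(p$strand, ifelse(p$strand == "+", p$end, p$start))
  if (anyDuplicated(pStop))
    stop("matchAnnotations: duplicate (strand, stop) among predictions")
  rStop <- paste(reference$strand,
                 ifelse(reference$strand == "+", reference$end,
                        reference$start))
  rBoth <- paste(reference$strand, reference$start, reference$end)
  pBoth <- paste(p$strand, p$start, p$end)
  m3 <- sum(rStop %in% pStop)
  m53 <- sum(rBoth %in% pBoth & rStop %in% pStop)
  nRef <- nrow(reference)
  new("BenchmarkResult", nReference = nRef, matched5p3p = as.integer(m53),
      matched3p = as.integer(m3), totalPredicted = nrow(p),
      pct5p3p = if (nRef > 0L) 100 * m53 / nRef else NA_real_,
      pct3p = if (nRef > 0L) 100 * m3 / nRef else NA_real_)
}

#' Length-stratified classification metrics
#'
#' Groups ORF-level predictions into length bins (half-open intervals
#' \code{[lo, hi)}; the outer bins are \code{< edges[1]} and
#' \code{>= edges[length(edges)]}) and computes precision, recall and accuracy
#' per bin. Empty bins report \code{NA} metrics rather than zeros.
#'
#' @param lengths ORF lengths in bp.
#' @param pPos predicted positive-class probabilities (thresholded at 0.5).
#' @param labels true labels in \{0,1\}.
#' @param edges increasing interior bin edges; the default gives the four bins
#'   \code{<300}, \code{[300,1000)}, \code{[1000,2000)}, \code{>=2000}.
#' @return data.frame with one row per bin: \code{bin}, \code{n_orfs},
#'   \code{precision}, \code{recall}, \code{accuracy}.
#' @export
lengthStratified <- function(lengths, pPos, labels,
                             edges = c(300L, 1000L, 2000L)) {
  stopifnot(length(lengths) == length(pPos),
            length(lengths) == length(labels), !is.unsorted(edges))
  breaks <- c(-Inf, edges, Inf)
  labs <- c(sprintf("<%d", edges[1]),
            if (length(edges) > 1L)
              sprintf("[%d,%d)", edges[-length(edges)], edges[-1L]),
            sprintf(">=%d", edges[length(edges)]))
  binIdx <- findInterval(lengths, breaks, left.open = FALSE)
  out <- lapply(seq_along(labs), function(i) {
    sel <- binIdx == i
    if (!any(sel))
      return(data.frame(bin = labs[i], n_orfs = 0L, precision = NA_real_,
                        recall = NA_real_, accuracy = NA_real_,
                        stringsAsFactors = FALSE))
    r <- metricReport(pPos[sel], labels[sel])
    data.frame(bin = labs[i], n_orfs = sum(sel), precision = r$precision,
               recall = r$recall, accuracy = r$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
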