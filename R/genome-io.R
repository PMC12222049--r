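#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside \{A,C,G,T,N\} (IUPAC
#' ambiguity codes, gaps) is replaced by \code{N}; the number of replacements
#' is reported with a message.
#'
#' @param path path to a FASTA file (multi-record allowed).
#' @return A named character vector of genome sequences, in file order.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  if (file.size(path) == 0L) stop("FASTA file is empty: ", path)
  firstLine <- readLines(path, n = 1L)
  if (!startsWith(firstLine, ">"))
    stop("malformed FASTA header at line 1: ", firstLine)
  dna <- Biostrings::readBStringSet(path)
  if (length(dna) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(dna))
  # FASTA headers: keep the first whitespace-delimited word as the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  nBad <- sum(vapply(seqs, function(s) {
    nchar(s) - sum(charToRaw(chartr("ACGTN", "\1\1\1\1\1", s)) == as.raw(1L))
  }, numeric(1)))
  if (nBad > 0) {
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
    message(sprintf("readGenome: replaced %d non-ACGTN character(s) with N", nBad))
  }
  seqs
}

#' Read CDS annotations from a GFF3 file
#'
#' Only rows with feature type \code{CDS} are consumed. GFF's 1-based
#' inclusive coordinates are converted to the package-internal 0-based
#' half-open convention on the forward strand; the strand is kept separately.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns \code{seqid}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand}. CDS rows whose span is not a multiple
#'   of 3 are kept but reported with a message.
#' @export
readCdsAnnotations <- function(path) {
  if (!file.exists(path)) stop("GFF file does not exist: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  strand <- as.character(BiocGenerics::strand(gr))
  if (length(gr) > 0L && !all(strand %in% c("+", "-")))
    stop("unknown strand symbol in CDS rows (must be '+' or '-')")
  out <- data.frame(
    seqid  = as.character(GenomicRanges::seqnames(gr)),
    start  = BiocGenerics::start(gr) - 1L,   # 1-based inclusive -> 0-based
    end    = BiocGenerics::end(gr),          # inclusive -> half-open
    strand = strand,
    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("CDS row with start > end")
  nFrame <- sum((out$end - out$start) %% 3L != 0L)
  if (nFrame > 0L)
    message(sprintf("readCdsAnnotations: %d CDS row(s) with length not a multiple of 3 (kept)", nFrame))
  out
}

# Coordinate conversions confined to the I/O boundary.
internalToGff <- function(start, end) list(start = start + 1L, end = end)
gffToInternal <- function(start, end) list(start = start - 1L, end = end)

# Format prediction rows as GFF3 CDS feature lines.
gffLines <- function(genomeId, p) {
  g <- internalToGff(p$start, p$end)
  attrs <- sprintf("ID=gene%d;p_cds=%.6g;p_tis=%.6g;prediction_max_likelihood=%d",
                   seq_len(nrow(p)), p$p_cds, p$p_tis,
                   p$prediction_max_likelihood)
  sprintf("%s\tbactgene\tCDS\t%d\t%d\t%.4g\t%s\t0\t%s",
          genomeId, g$start, g$end, p$p_cds, p$strand, attrs)
}

#' Write a prediction set to GFF3 or CSV
#'
#' GFF3 output uses 1-based inclusive coordinates, feature type \code{CDS} and
#' carries the probabilities and the \code{prediction_max_likelihood} flag in
#' the attributes column; re-reading it with [readCdsAnnotations()] restores
#' the internal coordinates exactly. CSV output has the fixed header
#' \code{seqid,strand,start,end,p_cds,p_tis,prediction_max_likelihood} with
#' internal (0-based half-open) coordinates.
#'
#' @param annotations a [GenePredictionSet].
#' @param path output file path.
#' @param format \code{"gff"} or \code{"csv"}.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotations, path, format = c("gff", "csv")) {
  stopifnot(is(annotations, "GenePredictionSet"))
  format <- match.arg(format)
  p <- predictions(annotations)
  if (format == "gff") {
    lines <- c("##gff-version 3",
               if (nrow(p) > 0L) gffLines(genomeId(annotations), p))
    tryCatch(writeLines(lines, path),
             error = function(e) stop("cannot write to ", path, ": ",
                                      conditionMessage(e)))
  } else {
    df <- data.frame(seqid = genomeId(annotations), p[, c(
      "strand", "start", "end", "p_cds", "p_tis",
      "prediction_max_likelihood")], stringsAsFactors = FALSE)
    tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
             error = function(e) stop("cannot write to ", path, ": ",
                                      conditionMessage(e)))
  }
  invisible(path)
}
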