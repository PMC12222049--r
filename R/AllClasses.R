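#' k-mer vocabulary
#'
#' Bijection between the \code{4^k} DNA k-mers over \{A,C,G,T\} plus the four
#' special tokens \code{[CLS]}, \code{[EOS]}, \code{[PAD]}, \code{[UNK]} and
#' dense integer token ids. Ids are 1-based; the serialized form (one token per
#' line) uses the line number as the id.
#'
#' @slot k k-mer length.
#' @slot tokens character vector of all tokens; position is the token id.
#' @export
setClass("KmerVocab", representation(k = "integer", tokens = "character"))

setValidity("KmerVocab", function(object) {
  if (length(object@tokens) != 4L^object@k + 4L)
    return(sprintf("vocabulary must hold 4^k + 4 = %d tokens", 4L^object@k + 4L))
  if (anyDuplicated(object@tokens)) return("token list contains duplicates")
  if (!all(c("[CLS]", "[EOS]", "[PAD]", "[UNK]") %in% object@tokens))
    return("special tokens [CLS], [EOS], [PAD], [UNK] are required")
  TRUE
})

#' Transformer sequence classifier
#'
#' A k-mer transformer encoder (token + learned absolute position embeddings,
#' multi-head self-attention blocks with residual connections and layer
#' normalization) topped by a \code{[CLS]}-pooled classification head
#' (linear + tanh pooler, linear logits, softmax).
#'
#' @slot config named list: \code{n_layers}, \code{d_hidden}, \code{n_heads},
#'   \code{d_head}, \code{d_ff}, \code{max_positions}, \code{vocab_size},
#'   \code{n_classes}, \code{dropout}, \code{k}, \code{stride}.
#' @slot params named list of weight matrices/vectors.
#' @slot vocab the [KmerVocab] the model was built against.
#' @export
setClass("TransformerModel",
         representation(config = "list", params = "list", vocab = "KmerVocab"))

setValidity("TransformerModel", function(object) {
  cfg <- object@config
  if (cfg$d_hidden %% cfg$n_heads != 0L)
    return("d_hidden must be divisible by n_heads")
  if (cfg$max_positions < 3L) return("max_positions must be >= 3")
  if (nrow(object@params$tok_emb) != cfg$vocab_size)
    return("token embedding rows must equal vocab_size")
  TRUE
})

#' Predicted gene models for one genome
#'
#' One row per predicted gene: the selected translation initiation site
#' (\code{start}), the stop-codon boundary (\code{end}; 0-based half-open
#' forward-strand coordinates), the coding probability \code{p_cds}, the TIS
#' probability \code{p_tis} of the retained site and the
#' \code{prediction_max_likelihood} flag (1 when the site was chosen as the
#' within-group argmax, 0 for boundary fallbacks).
#'
#' @slot genomeId sequence identifier the coordinates refer to.
#' @slot predictions data.frame with columns \code{strand}, \code{start},
#'   \code{end}, \code{p_cds}, \code{p_tis}, \code{prediction_max_likelihood}.
#' @slot provenance named list (configuration, model fingerprints).
#' @export
setClass("GenePredictionSet",
         representation(genomeId = "character", predictions = "data.frame",
                        provenance = "list"))

setValidity("GenePredictionSet", function(object) {
  p <- object@predictions
  need <- c("strand", "start", "end", "p_cds", "p_tis",
            "prediction_max_likelihood")
  if (!all(need %in% names(p)))
    return(paste("predictions must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  if (!all(p$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (any(p$start >= p$end)) return("start must be < end")
  if (any((p$end - p$start) %% 3L != 0L))
    return("gene length must be a multiple of 3")
  stopKey <- ifelse(p$strand == "+", p$end, p$start)
  if (anyDuplicated(paste(p$strand, stopKey)))
    return("two predictions share a (strand, stop) key")
  if (!all(p$prediction_max_likelihood %in% c(0L, 1L)))
    return("prediction_max_likelihood must be 0 or 1")
  TRUE
})

#' Matched-end benchmarking result
#'
#' Counts of reference genes recovered by a prediction set: \code{matched3p}
#' (same strand and stop coordinate: gene identity) and \code{matched5p3p}
#' (additionally the same start: correct TIS), with percentages relative to
#' the number of reference genes.
#'
#' @slot nReference number of reference genes.
#' @slot matched5p3p count of reference genes matched at both ends.
#' @slot matched3p count of reference genes matched at the 3' end.
#' @slot totalPredicted number of predicted genes.
#' @slot pct5p3p,pct3p percentages (100 * count / nReference).
#' @export
setClass("BenchmarkResult",
         representation(nReference = "integer", matched5p3p = "integer",
                        matched3p = "integer", totalPredicted = "integer",
                        pct5p3p = "numeric", pct3p = "numeric"))

setValidity("BenchmarkResult", function(object) {
  if (object@matched5p3p > object@matched3p)
    return("matched 5'+3' count cannot exceed matched 3' count")
  if (object@matched3p > min(object@nReference, object@totalPredicted))
    return("matched 3' count cannot exceed reference or predicted totals")
  TRUE
})

setMethod("show", "KmerVocab", function(object) {
  cat(sprintf("KmerVocab: k = %d, %d tokens (%d k-mers + 4 specials)\n",
              object@k, length(object@tokens), 4L^object@k))
})

setMethod("show", "TransformerModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "TransformerModel: %d layer(s), d_hidden %d, %d head(s), max_positions %d\n",
    cfg$n_layers, cfg$d_hidden, cfg$n_heads, cfg$max_positions))
  cat(sprintf("  vocab: k = %d (%d tokens); classes: %d; parameters: %s\n",
              object@vocab@k, cfg$vocab_size, cfg$n_classes,
              format(nParameters(object), big.mark = ",")))
})

setMethod("show", "GenePredictionSet", function(object) {
  cat(sprintf("GenePredictionSet for '%s': %d predicted gene(s)\n",
              object@genomeId, nrow(object@predictions)))
  if (nrow(object@predictions) > 0L)
    print(utils::head(object@predictions, 5L))
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf(
    "BenchmarkResult: %d reference genes, %d predicted\n  matched 5'+3': %d (%.1f%%)\n  matched 3'  : %d (%.1f%%)\n",
    object@nReference, object@totalPredicted, object@matched5p3p,
    object@pct5p3p, object@matched3p, object@pct3p))
})

#' Accessors for annotation and benchmark containers
#'
#' @param object a [GenePredictionSet] or [BenchmarkResult].
#' @return `predictions()` the prediction data.frame; `genomeId()` the genome
#'   identifier; `provenance()` the provenance list; `nParameters()` the total
#'   trainable parameter count of a [TransformerModel].
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' @rdname predictions
#' @export
setMethod("predictions", "GenePredictionSet", function(object) object@predictions)

#' @rdname predictions
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))

#' @rdname predictions
#' @export
setMethod("genomeId", "GenePredictionSet", function(object) object@genomeId)

#' @rdname predictions
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname predictions
#' @export
setMethod("provenance", "GenePredictionSet", function(object) object@provenance)

#' @rdname predictions
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname predictions
#' @export
setMethod("nParameters", "TransformerModel", function(object) {
  count <- function(x) {
    if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  }
  count(object@params)
})
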