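#' Training configuration
#'
#' @param lrPeak peak learning rate reached at the end of warm-up (default
#'   3e-5, the published fine-tuning rate).
#' @param warmupFraction fraction of total steps spent in linear warm-up.
#' @param batchSize examples per optimizer step.
#' @param epochs maximum epochs; training may stop earlier when the eval F1
#'   plateaus (gain < 1e-3 between epochs).
#' @param seed RNG seed controlling shuffling (and dropout, if enabled).
#' @param weightDecay AdamW decoupled weight decay, applied to weight matrices
#'   only (not biases or layer-norm parameters).
#' @return named list of training settings.
#' @export
trainConfig <- function(lrPeak = 3e-5, warmupFraction = 0.1, batchSize = 16L,
                        epochs = 3L, seed = 1L, weightDecay = 0.01) {
  stopifnot(lrPeak > 0, warmupFraction >= 0, warmupFraction < 1)
  list(lr_peak = lrPeak, warmup_fraction = warmupFraction,
       batch_size = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed), weight_decay = weightDecay)
}

#' Mean cross-entropy loss
#'
#' \code{-sum(y' * log(y))} per example, averaged over the batch. Zero
#' probability at the true class is clamped at \code{1e-12} and reported with
#' a message.
#'
#' @param probs matrix of predicted class probabilities (rows sum to 1).
#' @param labels integer class labels in \code{0 .. ncol(probs)-1}.
#' @return non-negative scalar loss.
#' @export
crossEntropy <- function(probs, labels) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  if (any(p < 1e-12)) {
    message(sprintf("crossEntropy: clamped %d zero probability value(s)",
                    sum(p < 1e-12)))
    p <- pmax(p, 1e-12)
  }
  mean(-log(p))
}

#' Linear warm-up / linear decay learning-rate schedule
#'
#' The rate rises linearly from 0 to \code{lr_peak} over the warm-up steps,
#' then decays linearly to 0 at \code{totalSteps}.
#'
#' @param step current step (0-based, \code{0 <= step <= totalSteps}).
#' @param totalSteps total optimizer steps in the run.
#' @param cfg a [trainConfig()] list.
#' @return learning rate for this step.
#' @export
lrSchedule <- function(step, totalSteps, cfg) {
  if (totalSteps == 0L) stop("lrSchedule: totalSteps must be positive")
  warm <- cfg$warmup_fraction * totalSteps
  if (warm > 0 && step < warm) return(cfg$lr_peak * step / warm)
  if (totalSteps == warm) return(cfg$lr_peak)
  cfg$lr_peak * (totalSteps - step) / (totalSteps - warm)
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall and F1 from threshold-0.5 predictions:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = harmonic mean of precision and recall. A zero
#' denominator yields 0 with \code{degenerate = TRUE}.
#'
#' @param pPos predicted positive-class probabilities.
#' @param labels true labels in \{0,1\}.
#' @param loss optional mean loss to carry in the report.
#' @return list with \code{loss}, \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1}, \code{confusion} (TP, TN, FP, FN) and
#'   \code{degenerate}.
#' @export
metricReport <- function(pPos, labels, loss = NA_real_) {
  if (length(labels) == 0L) stop("metricReport: empty dataset")
  pred <- as.integer(pPos >= 0.5)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  degenerate <- (tp + fp) == 0L || (tp + fn) == 0L
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  list(loss = loss, accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1,
       confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
       degenerate = degenerate)
}

#' Evaluate a model on a labeled dataset
#'
#' Scores every sequence and computes the confusion-matrix metrics at a 0.5
#' threshold on the positive-class probability.
#'
#' @param model a [TransformerModel].
#' @param data data.frame with columns \code{seq} and \code{label}.
#' @param batchSize inference batch size.
#' @return a metric report list (see [metricReport()]).
#' @export
evaluateModel <- function(model, data, batchSize = 32L) {
  if (nrow(data) == 0L) stop("evaluateModel: empty dataset")
  pPos <- classifySeqs(model, data$seq, batchSize)
  probs <- cbind(1 - pPos, pPos)
  metricReport(pPos, data$label, loss = crossEntropy(probs, data$label))
}

# AdamW update, recursive over the nested parameter/gradient lists. Decoupled
# weight decay is applied to matrices only. Updates `params` and the moment
# state in place (environments avoided; returns both).
adamwStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0.01, t = 1L) {
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]   # align by name, not position
      out <- Map(step, p, g, m %||% vector("list", length(p)),
                 v %||% vector("list", length(p)))
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    if (is.matrix(p)) p <- p - lr * weightDecay * p
    list(p = p, m = m, v = v)
  }
  step(params, grads, state$m, state$v)
}

# Deterministic length-bucketed batch order: sort by token count, chunk, then
# shuffle chunk order. Reduces padding waste without changing semantics.
batchOrder <- function(lens, batchSize) {
  ord <- order(lens)
  chunks <- split(ord, ceiling(seq_along(ord) / batchSize))
  chunks[sample(length(chunks))]
}

#' Fine-tune a transformer classifier
#'
#' AdamW with the linear warm-up / linear decay schedule of [lrSchedule()] and
#' mean cross-entropy loss. Batches are length-bucketed and padded to the
#' batch maximum; the run is deterministic given \code{cfg$seed}. Training
#' stops early when the evaluation F1 gain between epochs falls below 1e-3,
#' and aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param model a [TransformerModel].
#' @param trainData data.frame with columns \code{seq}, \code{label}.
#' @param evalData data.frame evaluated after each epoch (per-epoch metric
#'   reports are returned; pass \code{NULL} to skip).
#' @param cfg a [trainConfig()] list.
#' @param checkpointDir optional directory; when given, a checkpoint is written
#'   after each epoch.
#' @return list with \code{model} (trained), \code{history} (per-epoch list of
#'   metric reports with \code{train_loss}) and \code{epochs_run}.
#' @export
trainModel <- function(model, trainData, evalData = NULL, cfg = trainConfig(),
                       checkpointDir = NULL) {
  stopifnot(nrow(trainData) > 0L)
  mcfg <- model@config
  idsList <- lapply(trainData$seq, function(s)
    c(specialId(model@vocab, "[CLS]"),
      kmerIds(kmerize(s, mcfg$k, mcfg$stride), model@vocab),
      specialId(model@vocab, "[EOS]")))
  lens <- lengths(idsList)
  if (any(lens > mcfg$max_positions))
    stop("trainModel: an encoded training sequence exceeds max_positions")
  labels <- as.integer(trainData$label)
  padId <- specialId(model@vocab, "[PAD]")
  nBatches <- ceiling(nrow(trainData) / cfg$batch_size)
  totalSteps <- nBatches * cfg$epochs
  params <- model@params
  state <- list(m = NULL, v = NULL)
  history <- list()
  globalStep <- 0L
  prevF1 <- -Inf
  epochsRun <- 0L
  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      chunks <- batchOrder(lens, cfg$batch_size)
      epochLoss <- 0
      for (chunk in chunks) {
        Lc <- max(lens[chunk])
        ids <- t(vapply(chunk, function(i)
          c(idsList[[i]], rep(padId, Lc - lens[i])), integer(Lc)))
        mask <- t(vapply(chunk, function(i)
          c(rep(1L, lens[i]), rep(0L, Lc - lens[i])), integer(Lc)))
        model@params <- params
        fw <- tfForward(model, ids, mask, train = TRUE)
        loss <- crossEntropy(fw$probs, labels[chunk])
        if (!is.finite(loss))
          stop(sprintf(
            "trainModel: loss diverged (NaN/Inf) at epoch %d step %d",
            epoch, globalStep))
        epochLoss <- epochLoss + loss * length(chunk)
        grads <- tfBackward(model, fw$cache, labels[chunk])
        lr <- lrSchedule(globalStep, totalSteps, cfg)
        upd <- adamwStep(params, grads, state, lr,
                         weightDecay = cfg$weight_decay, t = globalStep + 1L)
        params <- upd$p
        state <- list(m = upd$m, v = upd$v)
        globalStep <- globalStep + 1L
      }
      model@params <- params
      epochsRun <- epoch
      rep <- list(epoch = epoch,
                  train_loss = epochLoss / nrow(trainData))
      if (!is.null(evalData) && nrow(evalData) > 0L) {
        ev <- evaluateModel(model, evalData)
        rep <- c(rep, ev)
      }
      history[[epoch]] <- rep
      if (!is.null(checkpointDir)) {
        dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
        saveModel(model, file.path(checkpointDir,
                                   sprintf("epoch-%02d.rds", epoch)))
      }
      f1 <- rep$f1 %||% NA_real_
      if (!is.na(f1)) {
        if (f1 - prevF1 < 1e-3 && epoch > 1L) break
        prevF1 <- f1
      }
    }
  })
  model@params <- params
  list(model = model, history = history, epochs_run = epochsRun)
}
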