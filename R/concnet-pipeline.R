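#' Preprocess a raw EEG recording
#'
#' Trims 4 s of transient at each end, resamples to a uniform 250 Hz
#' (anti-aliased decimation for 500 Hz input) and low-pass filters at
#' 100 Hz with a 5th-order digital Butterworth filter, applied causally
#' (forward only) by default.
#'
#' @param rec a [RawRecording-class] at 250 or 500 Hz, longer than 8 s.
#' @param trim seconds removed at each end (default 4).
#' @param target_fs output sampling rate (default 250 Hz).
#' @param lowpass cutoff in Hz (default 100).
#' @param order Butterworth order (default 5).
#' @param zero_phase apply the filter forward-backward
#'   ([signal::filtfilt()]) instead of causally.
#' @return A preprocessed [RawRecording-class] at `target_fs`.
#' @export
preprocessRecording <- function(rec, trim = 4, target_fs = 250,
                                lowpass = 100, order = 5L,
                                zero_phase = FALSE) {
  stopifnot(methods::is(rec, "RawRecording"))
  fs <- samplingRate(rec)
  if (!fs %in% c(250, 500))
    stop("unsupported sampling rate ", fs, " Hz; allowed: 250, 500")
  sig <- signalValues(rec)
  n_trim <- round(trim * fs)
  if (ncol(sig) <= 2 * n_trim)
    stop("recording too short: ", ncol(sig) / fs, " s leaves nothing after ",
         "trimming ", trim, " s at each end")
  sig <- sig[, (n_trim + 1):(ncol(sig) - n_trim), drop = FALSE]

  if (fs != target_fs) {
    fac <- fs / target_fs
    if (fac != round(fac)) stop("non-integer decimation factor")
    sig <- t(apply(sig, 1, function(x)
      signal::decimate(x, q = as.integer(fac), ftype = "iir")))
    fs <- target_fs
  }

  bf <- signal::butter(order, lowpass / (fs / 2), type = "low")
  filt1 <- if (zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  sig <- t(apply(sig, 1, filt1))
  RawRecording(sig, fs = fs, participantId = participantId(rec),
               label = recordingLabel(rec))
}

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping contiguous 10 s windows from the start of the
#' (preprocessed, 250 Hz) recording; a trailing partial window is
#' discarded. Segmenting a 5-minute recording yields the nominal
#' 30-fold increase in sample count.
#'
#' @param rec a [RawRecording-class] at 250 Hz.
#' @param epoch_s epoch length in seconds (default 10).
#' @return list of epochs, each a list with `segment`
#'   (channels x samples), `participant_id`, `label`. Empty (with a
#'   warning) when the recording is shorter than one epoch.
#' @export
segmentEpochs <- function(rec, epoch_s = 10) {
  stopifnot(methods::is(rec, "RawRecording"))
  sig <- signalValues(rec)
  len <- round(epoch_s * samplingRate(rec))
  n_ep <- floor(ncol(sig) / len)
  if (n_ep < 1L) {
    warning("recording shorter than one ", epoch_s, " s epoch; no segments")
    return(list())
  }
  lapply(seq_len(n_ep), function(e) {
    list(segment = sig[, ((e - 1) * len + 1):(e * len), drop = FALSE],
         participant_id = participantId(rec), label = recordingLabel(rec))
  })
}

#' Subject-wise ensemble cross-validation plan
#'
#' Builds `repeats` independent rounds of `folds`-fold cross-validation
#' at the participant level. Within each repeat, each class is shuffled
#' and partitioned into `folds` test cores; each fold then draws one
#' validation participant per class, a class-balanced training set of
#' equal size per class, and assigns every remaining participant to the
#' test set. For a 15 + 11 cohort with 6 folds this reproduces the
#' train 8+8 / validation 1+1 / test 6+2 layout, every participant is
#' tested at least once per repeat, and no participant ever appears on
#' both sides of a train/test divide.
#'
#' @param labels named character vector: participant id -> class label
#'   (`"concussed"`/`"non-concussed"`).
#' @param repeats number of shuffled repeats (default 5).
#' @param folds folds per repeat (default 6).
#' @param seed integer seed.
#' @return list of class `"FoldPlan"`: `folds` — a list of realizations,
#'   each with `repeat_`, `fold`, `train`, `validation`, `test` id
#'   vectors — plus `repeats`, `n_folds`, `seed`.
#' @export
makeFolds <- function(labels, repeats = 5L, folds = 6L, seed = 1L) {
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes required")
  ids <- split(names(labels), labels)
  if (any(lengths(ids) < 3L))
    stop("cohort too small: need >= 3 participants per class ",
         "(1 validation + 1 train + 1 test)")
  n_min <- min(lengths(ids))
  if (folds > n_min * 2L)
    stop("too many folds (", folds, ") for the smaller class (", n_min, ")")
  set.seed(as.integer(seed))
  plan <- list()
  for (rep_i in seq_len(repeats)) {
    shuffled <- lapply(ids, sample)
    # cyclic test cores of ceil(n/folds): when folds * core size exceeds
    # the class, early participants are tested twice within the repeat
    cores <- lapply(shuffled, function(v) {
      cs <- ceiling(length(v) / folds)
      slots <- rep(v, length.out = folds * cs)
      split(slots, rep(seq_len(folds), each = cs))
    })
    for (f in seq_len(folds)) {
      test <- character(); val <- character(); train <- character()
      remain <- list()
      for (cl in classes) {
        core <- cores[[cl]][[f]]
        rest <- setdiff(shuffled[[cl]], core)
        val <- c(val, rest[1])
        remain[[cl]] <- rest[-1]
        test <- c(test, core)
      }
      n_train <- min(lengths(remain))
      for (cl in classes) {
        train <- c(train, remain[[cl]][seq_len(n_train)])
        extra <- remain[[cl]][-seq_len(n_train)]
        test <- c(test, extra)  # leftover large-class members are tested
      }
      stopifnot(length(intersect(train, test)) == 0L,
                length(intersect(val, test)) == 0L,
                length(intersect(train, val)) == 0L)
      plan[[length(plan) + 1L]] <- list(repeat_ = rep_i, fold = f,
                                        train = train, validation = val,
                                        test = test)
    }
  }
  structure(list(folds = plan, repeats = as.integer(repeats),
                 n_folds = as.integer(folds), seed = as.integer(seed)),
            class = "FoldPlan")
}

#' Confusion-matrix and ROC metrics
#'
#' Computes the confusion counts (positive class = concussed), the five
#' ratio metrics as percentages, a threshold-sweep ROC and its
#' trapezoidal AUC.
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels (same length).
#' @param scores optional numeric scores (`p_conc`) for the ROC/AUC.
#' @return list of class `"ClassifierMetrics"`: `tp`, `fn`, `fp`, `tn`,
#'   `accuracy`, `recall`, `specificity`, `precision`, `f1`
#'   (percentages), `roc` (data.frame `fpr`, `tpr`), `auc` (`NA` with
#'   flag `auc_defined = FALSE` for single-class truth).
#' @export
evaluateMetrics <- function(truth, predicted, scores = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and prediction lengths differ")
  pos <- "concussed"
  tp <- sum(truth == pos & predicted == pos)
  fn <- sum(truth == pos & predicted != pos)
  fp <- sum(truth != pos & predicted == pos)
  tn <- sum(truth != pos & predicted != pos)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- pct(tp, tp + fp)
  recall <- pct(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  roc <- NULL; auc <- NA_real_; auc_defined <- FALSE
  if (!is.null(scores) && length(unique(truth)) == 2L) {
    roc <- rocCurve(truth == pos, scores)
    auc <- trapezoidAUC(roc$fpr, roc$tpr)
    auc_defined <- TRUE
  }
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 accuracy = pct(tp + tn, tp + tn + fp + fn),
                 recall = recall, specificity = pct(tn, tn + fp),
                 precision = precision, f1 = f1,
                 roc = roc, auc = auc, auc_defined = auc_defined),
            class = "ClassifierMetrics")
}

# Threshold sweep over the observed scores (plus sentinels), one
# (FPR, TPR) point per threshold, ordered for trapezoidal integration.
rocCurve <- function(is_pos, scores) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  P <- sum(is_pos); N <- sum(!is_pos)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_pos) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_pos) / N, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoidAUC <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) + utils::tail(tpr[ord], -1)) / 2)
}

#' Pointwise median ROC across repeats
#'
#' Interpolates each repeat's ROC onto a common FPR grid and takes the
#' pointwise median TPR.
#'
#' @param rocs list of ROC data.frames (`fpr`, `tpr`).
#' @param grid FPR grid (default 101 points on \[0, 1\]).
#' @return data.frame `fpr`, `tpr_median`.
#' @export
medianROC <- function(rocs, grid = seq(0, 1, length.out = 101L)) {
  tprs <- vapply(rocs, function(rc) {
    ord <- order(rc$fpr, rc$tpr)
    stats::approx(rc$fpr[ord], rc$tpr[ord], xout = grid, ties = max,
                  rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr_median = apply(as.matrix(tprs), 1, stats::median))
}

#' Run the full subject-wise ensemble classification
#'
#' Segments every recording, builds the fold plan, trains one network
#' per realization and evaluates participant-level predictions (median
#' rule). Metrics are aggregated over all realizations with mean and
#' normal-approximation 95% CI; a per-participant misclassification
#' table records how often each participant was tested and erred.
#'
#' @param cohort a `"RawEEGCohort"` (see [genRawEEGCohort()]) or a list
#'   of [RawRecording-class].
#' @param config a [concNetConfig()].
#' @param repeats,folds cross-validation structure (defaults 5 and 6).
#' @param seed integer master seed (fold shuffling and per-realization
#'   training seeds derive from it).
#' @param preprocess apply [preprocessRecording()] first (default TRUE).
#' @param threshold participant decision threshold.
#' @param verbose print one line per realization.
#' @return list of class `"EnsembleResult"`: `per_realization`
#'   (data.frame of per-fold metrics), `summary` (mean and CI per
#'   metric), `mean_cm`, `rocs`, `median_roc`, `auc_mean`, `auc_ci`,
#'   `misclassification` (per-participant times tested/misclassified),
#'   `plan`.
#' @export
runEnsemble <- function(cohort, config = concNetConfig(), repeats = 5L,
                        folds = 6L, seed = 1L, preprocess = TRUE,
                        threshold = 0.5, verbose = FALSE) {
  recs <- if (inherits(cohort, "RawEEGCohort")) cohort$recordings else cohort
  if (preprocess) recs <- lapply(recs, preprocessRecording)
  epochs_by_id <- lapply(recs, segmentEpochs)
  names(epochs_by_id) <- vapply(recs, participantId, character(1))
  labels <- vapply(recs, recordingLabel, character(1))
  names(labels) <- names(epochs_by_id)
  plan <- makeFolds(labels, repeats = repeats, folds = folds, seed = seed)

  per <- list(); rocs_by_repeat <- vector("list", repeats)
  tested <- setNames(integer(length(labels)), names(labels))
  wrong <- tested
  scores_all <- list()
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    train_ep <- unlist(lapply(fold$train, function(id) epochs_by_id[[id]]),
                       recursive = FALSE)
    val_ep <- unlist(lapply(fold$validation, function(id) epochs_by_id[[id]]),
                     recursive = FALSE)
    cfg <- config
    cfg$seed <- config$seed + 1000L * fi
    set.seed(cfg$seed)
    model <- trainConcNet(train_ep, val_ep, cfg)
    preds <- lapply(fold$test, function(id)
      predictParticipant(model, epochs_by_id[[id]], threshold = threshold))
    truth <- unname(labels[fold$test])
    predicted <- vapply(preds, `[[`, character(1), "label")
    scores <- vapply(preds, `[[`, numeric(1), "p_conc")
    met <- evaluateMetrics(truth, predicted, scores)
    per[[fi]] <- data.frame(repeat_ = fold$repeat_, fold = fold$fold,
                            tp = met$tp, fn = met$fn, fp = met$fp,
                            tn = met$tn, accuracy = met$accuracy,
                            recall = met$recall,
                            specificity = met$specificity,
                            precision = met$precision, f1 = met$f1,
                            auc = met$auc)
    tested[fold$test] <- tested[fold$test] + 1L
    wrong[fold$test] <- wrong[fold$test] + (predicted != truth)
    scores_all[[fi]] <- data.frame(repeat_ = fold$repeat_, truth = truth,
                                   score = scores)
    if (verbose)
      message(sprintf("realization %d/%d (repeat %d fold %d): acc %.1f%%",
                      fi, length(plan$folds), fold$repeat_, fold$fold,
                      met$accuracy))
  }
  per <- do.call(rbind, per)
  scores_all <- do.call(rbind, scores_all)

  # repeat-level ROC from pooled participant scores of that repeat
  rocs <- lapply(seq_len(repeats), function(r) {
    d <- scores_all[scores_all$repeat_ == r, ]
    if (length(unique(d$truth)) < 2L) return(NULL)
    rocCurve(d$truth == "concussed", d$score)
  })
  rocs <- Filter(Negate(is.null), rocs)

  ci <- function(x) {
    x <- x[is.finite(x)]
    se <- stats::sd(x) / sqrt(length(x))
    c(mean = mean(x), lo = mean(x) - 1.96 * se, hi = mean(x) + 1.96 * se)
  }
  metrics <- c("accuracy", "recall", "specificity", "precision", "f1", "auc")
  summary <- t(vapply(metrics, function(m) ci(per[[m]]), numeric(3)))

  structure(list(
    per_realization = per,
    summary = as.data.frame(summary),
    mean_cm = c(tp = mean(per$tp), fn = mean(per$fn), fp = mean(per$fp),
                tn = mean(per$tn)),
    rocs = rocs,
    median_roc = if (length(rocs)) medianROC(rocs) else NULL,
    auc_mean = mean(per$auc[is.finite(per$auc)]),
    auc_ci = unname(ci(per$auc)[2:3]),
    misclassification = data.frame(participant = names(tested),
                                   label = unname(labels[names(tested)]),
                                   times_tested = unname(tested),
                                   times_misclassified = unname(wrong),
                                   row.names = NULL),
    plan = plan
  ), class = "EnsembleResult")
}
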