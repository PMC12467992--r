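test_that("preprocessing trims, resamples and filters to the expected geometry", {
  set.seed(31)
  rec500 <- RawRecording(matrix(rnorm(4 * 500 * 20), 4), fs = 500)
  out <- preprocessRecording(rec500)
  expect_equal(samplingRate(out), 250)
  expect_identical(ncol(signalValues(out)), as.integer((20 - 8) * 250))

  rec250 <- RawRecording(matrix(rnorm(4 * 250 * 20), 4), fs = 250)
  out250 <- preprocessRecording(rec250)
  expect_equal(samplingRate(out250), 250)
  expect_identical(ncol(signalValues(out250)), as.integer((20 - 8) * 250))

  short <- RawRecording(matrix(rnorm(4 * 250 * 7), 4), fs = 250)
  expect_error(preprocessRecording(short), "too short")
  odd <- RawRecording(matrix(rnorm(4 * 100), 4), fs = 100)
  expect_error(preprocessRecording(odd), "unsupported sampling rate")
})

test_that("the low-pass attenuates tones by the analytic digital Butterworth amount", {
  # closed-form magnitude of an order-n digital Butterworth designed by
  # bilinear transform: |H(f)|^2 = 1 / (1 + (tan(pi f/fs)/tan(pi fc/fs))^(2n))
  warped_att_db <- function(f, fc, fs, n = 5)
    10 * log10(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * n))
  fs <- 250; dur <- 20
  t <- seq_len(fs * dur) / fs
  tone <- function(f) sin(2 * pi * f * t)
  measure <- function(f, fc) {
    rec <- RawRecording(rbind(tone(f), tone(f)), fs = fs)
    out <- signalValues(preprocessRecording(rec, lowpass = fc))
    tail_idx <- seq(ncol(out) - 2000, ncol(out)) # steady state
    10 * log10(mean(tone(f)[tail_idx]^2) / mean(out[1, tail_idx]^2))
  }
  # 1.2x the 100 Hz cutoff sits near Nyquist, where frequency warping
  # sharpens the analog prototype's ~8.6 dB to ~71 dB
  expect_equal(measure(120, 100), warped_att_db(120, 100, fs),
               tolerance = 0.02)
  expect_equal(measure(36, 30), warped_att_db(36, 30, fs),
               tolerance = 0.02)
  # passband tone essentially untouched
  expect_lt(abs(measure(10, 100)), 0.1)
})

test_that("segmentation yields floor(duration/10) contiguous epochs", {
  mk <- function(secs) RawRecording(matrix(rnorm(2 * 250 * secs), 2), fs = 250)
  expect_length(segmentEpochs(mk(300)), 30L)
  expect_length(segmentEpochs(mk(292)), 29L)
  expect_warning(e <- segmentEpochs(mk(9)), "shorter than one")
  expect_length(e, 0L)
  eps <- segmentEpochs(mk(25))
  expect_identical(dim(eps[[1]]$segment), c(2L, 2500L))
  # contiguity: second epoch starts where the first ends
  rec <- mk(25)
  eps <- segmentEpochs(rec)
  expect_identical(eps[[2]]$segment[, 1], signalValues(rec)[, 2501])
})

test_that("fold plans reproduce the 8+8/1+1/6+2 layout and never leak participants", {
  labs <- setNames(c(rep("non-concussed", 15), rep("concussed", 11)),
                   c(paste0("HC_", 1:15), paste0("CC_", 1:11)))
  plan <- makeFolds(labs, repeats = 5, folds = 6, seed = 3)
  expect_length(plan$folds, 30L)
  for (f in plan$folds) {
    expect_identical(length(f$train), 16L)
    expect_identical(sum(grepl("^CC", f$train)), 8L)
    expect_identical(length(f$validation), 2L)
    expect_identical(length(f$test), 8L)
    expect_identical(sum(grepl("^CC", f$test)), 2L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$validation, f$test), 0L)
    expect_length(intersect(f$train, f$validation), 0L)
  }
  for (r in 1:5) {
    tested <- unique(unlist(lapply(
      Filter(function(f) f$repeat_ == r, plan$folds), `[[`, "test")))
    expect_setequal(tested, names(labs))
  }
  expect_error(makeFolds(setNames(rep(c("a", "b"), 2), paste0("P", 1:4))),
               "cohort too small")
})

test_that("the network has the published trainable parameter count", {
  # closed form: 2 x 4H(D + H + 1) per bidirectional layer + dense head
  H <- 24; D <- 64; F <- 8
  expected <- 2 * 4 * H * (D + H + 1) + 2 * 4 * H * (2 * H + H + 1) +
    (2 * H * F + F) + (F * 2 + 2)
  expect_identical(expected, 31514)
  expect_identical(countParams(initConcNet(64L, concNetConfig())), 31514L)
})

test_that("output probabilities sum to one for arbitrary inputs", {
  set.seed(32)
  params <- initConcNet(3L, concNetConfig(lstm_units = 5L, seed = 1))
  for (i in 1:10) {
    p <- flowconn:::cn_predict_cpp(params, matrix(rnorm(3 * 40), 3))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(33)
  cfg <- concNetConfig(lstm_units = 3L, fc_hidden = 4L, seed = 7)
  params <- initConcNet(2L, cfg)
  Xs <- list(matrix(rnorm(2 * 6), 2), matrix(rnorm(2 * 6), 2))
  ys <- c(1L, 0L)
  g <- flowconn:::cn_grad_batch_cpp(params, Xs, ys, 0.0)
  h <- 1e-5
  for (k in names(params)) {
    for (idx in sample(length(params[[k]]), min(4, length(params[[k]])))) {
      pp <- params; pp[[k]][idx] <- pp[[k]][idx] + h
      pm <- params; pm[[k]][idx] <- pm[[k]][idx] - h
      num <- (flowconn:::cn_grad_batch_cpp(pp, Xs, ys, 0.0)$loss -
              flowconn:::cn_grad_batch_cpp(pm, Xs, ys, 0.0)$loss) / (2 * h)
      expect_equal(g$grads[[k]][idx], num, tolerance = 1e-5)
    }
  }
})

test_that("a tiny separable set is fit to 100% training accuracy", {
  set.seed(34)
  eps <- makeToyEpochs(4, d = 4, len = 100)
  cfg <- concNetConfig(lr = 0.003, epochs = 50L, seed = 5)
  model <- trainConcNet(eps, config = cfg)
  p <- predictEpochs(model, eps)
  truth <- vapply(eps, function(e) e$label == "concussed", logical(1))
  expect_identical(unname(p > 0.5), unname(truth))
})

test_that("training is reproducible under the config seed", {
  set.seed(35)
  eps <- makeToyEpochs(2, d = 3, len = 50)
  cfg <- concNetConfig(lstm_units = 4L, epochs = 2L, seed = 9)
  m1 <- trainConcNet(eps, config = cfg)
  m2 <- trainConcNet(eps, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("the participant median rule applies a strict threshold", {
  eps <- makeToyEpochs(1, d = 2, len = 30, sep = FALSE)
  cfg <- concNetConfig(lstm_units = 2L, epochs = 1L, seed = 2)
  m <- trainConcNet(eps, config = cfg)
  pred <- predictParticipant(m, eps[1], threshold = 1) # p <= 1 always
  expect_identical(pred$label, "non-concussed")
  pred2 <- predictParticipant(m, eps[1], threshold = 0) # p > 0 always
  expect_identical(pred2$label, "concussed")
})

test_that("confusion-matrix metrics reproduce their defining formulas", {
  truth <- c(rep("concussed", 10), rep("non-concussed", 10))
  pred <- c(rep("concussed", 9), "non-concussed",
            rep("non-concussed", 8), rep("concussed", 2))
  met <- evaluateMetrics(truth, pred)
  expect_identical(c(met$tp, met$fn, met$fp, met$tn), c(9L, 1L, 2L, 8L))
  expect_equal(met$accuracy, 85)
  expect_equal(met$recall, 90)
  expect_equal(met$specificity, 80)
  expect_equal(met$precision, 100 * 9 / 11, tolerance = 1e-10)
  expect_equal(met$f1, 2 * met$precision * met$recall /
                 (met$precision + met$recall))
})

test_that("AUC is one for perfect separation, halves for label-free scores, and is rank-invariant", {
  truth <- rep(c("concussed", "non-concussed"), each = 20)
  perfect <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  met <- evaluateMetrics(truth, ifelse(perfect > 0.5, "concussed",
                                       "non-concussed"), perfect)
  expect_equal(met$auc, 1)
  set.seed(36)
  rnd <- runif(40)
  aucs <- replicate(200, {
    s <- runif(40)
    evaluateMetrics(truth, rep("concussed", 40), s)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # strictly monotone transform leaves the AUC unchanged
  met_a <- evaluateMetrics(truth, rep("concussed", 40), rnd)
  met_b <- evaluateMetrics(truth, rep("concussed", 40), plogis(5 * rnd - 2))
  expect_equal(met_a$auc, met_b$auc)
  one_class <- evaluateMetrics(rep("concussed", 5), rep("concussed", 5),
                               runif(5))
  expect_false(one_class$auc_defined)
})

test_that("the trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  truth <- sample(rep(c("concussed", "non-concussed"), each = 15))
  scores <- rnorm(30) + (truth == "concussed")
  met <- evaluateMetrics(truth, rep("concussed", 30), scores)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("non-concussed",
                                                     "concussed"),
    direction = "<", quiet = TRUE)))
  expect_equal(met$auc, ref, tolerance = 1e-10)
})

test_that("a miniature ensemble run keeps exact misclassification bookkeeping", {
  set.seed(38)
  coh <- genRawEEGCohort(4, fs = 250, duration = 30,
                         class_effect_size = 4, seed = 40)
  cfg <- concNetConfig(lstm_units = 4L, epochs = 1L, seed = 3)
  res <- runEnsemble(coh, config = cfg, repeats = 1L, folds = 2L, seed = 3)
  expect_identical(nrow(res$per_realization), 2L)
  errors_from_cm <- sum(res$per_realization$fn + res$per_realization$fp)
  expect_identical(sum(res$misclassification$times_misclassified),
                   as.integer(errors_from_cm))
  expect_identical(sum(res$misclassification$times_tested),
                   sum(res$per_realization$tp + res$per_realization$fn +
                       res$per_realization$fp + res$per_realization$tn))
  expect_true(all(c("accuracy", "auc") %in% rownames(res$summary)))
})
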