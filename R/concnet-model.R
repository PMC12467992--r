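#' ConcNet model configuration
#'
#' Hyperparameters of the bidirectional-LSTM classifier: two stacked
#' bidirectional LSTM layers of 24 units per direction (the first
#' sequence-to-sequence, the second emitting its concatenated final
#' hidden states), dropout 0.32 after each recurrent layer and after
#' the 8-unit ReLU dense layer, a 2-unit softmax output, cross-entropy
#' loss, Adam at learning rate 0.03, minibatches of 12, 5 training
#' epochs.
#'
#' @param lstm_units recurrent units per direction.
#' @param fc_hidden dense hidden units.
#' @param dropout dropout probability in (0, 1).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param standardize z-score each epoch per channel before input
#'   (recommended for stable training on raw-amplitude EEG; disable for
#'   strict raw input).
#' @param seed integer seed controlling weight initialization, dropout
#'   and shuffling.
#' @return list of class `"ConcNetConfig"`.
#' @export
concNetConfig <- function(lstm_units = 24L, fc_hidden = 8L, dropout = 0.32,
                          lr = 0.03, batch_size = 12L, epochs = 5L,
                          standardize = TRUE, seed = 1L) {
  stopifnot(dropout > 0, dropout < 1, lstm_units >= 1, fc_hidden >= 1,
            batch_size >= 1, epochs >= 1, lr > 0)
  structure(list(lstm_units = as.integer(lstm_units),
                 fc_hidden = as.integer(fc_hidden), dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), standardize = standardize,
                 seed = as.integer(seed)),
            class = "ConcNetConfig")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize ConcNet parameters
#'
#' Glorot-uniform weights, zero biases except the LSTM forget-gate
#' biases which start at 1 (standard practice for gradient flow through
#' long sequences). Gate row layout within each `4H`-row block:
#' input, forget, candidate, output.
#'
#' @param n_input input features per time step (channels; 64 for the
#'   standard montage).
#' @param config a [concNetConfig()].
#' @return Named list of parameter matrices/vectors.
#' @export
initConcNet <- function(n_input = 64L, config = concNetConfig()) {
  H <- config$lstm_units
  lstm_init <- function(din) {
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1
    list(W = glorot(4 * H, din), U = glorot(4 * H, H), b = b)
  }
  set.seed(config$seed)
  l1f <- lstm_init(n_input); l1b <- lstm_init(n_input)
  l2f <- lstm_init(2 * H); l2b <- lstm_init(2 * H)
  F <- config$fc_hidden
  list(W1f = l1f$W, U1f = l1f$U, b1f = l1f$b,
       W1b = l1b$W, U1b = l1b$U, b1b = l1b$b,
       W2f = l2f$W, U2f = l2f$U, b2f = l2f$b,
       W2b = l2b$W, U2b = l2b$U, b2b = l2b$b,
       Wd1 = glorot(F, 2 * H), bd1 = rep(0, F),
       Wd2 = glorot(2L, F), bd2 = rep(0, 2))
}

#' Number of trainable parameters
#'
#' @param params parameter list from [initConcNet()] (or a trained
#'   model's `$params`).
#' @return Total count of trainable scalars.
#' @export
countParams <- function(params) {
  if (inherits(params, "ConcNetModel")) params <- params$params
  sum(vapply(params, length, integer(1)))
}

standardizeEpoch <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2))
  s[s == 0] <- 1
  (x - mu) / s
}

#' Train a ConcNet model
#'
#' Minibatch gradient descent with Adam on the cross-entropy loss.
#' Training order is reshuffled each epoch; dropout masks and shuffling
#' draw from R's RNG, so results are reproducible under the config
#' seed. The validation set, when given, is only monitored (loss
#' reported per epoch at `verbose = TRUE`); training always runs the
#' configured number of epochs.
#'
#' @param train_epochs list of epochs, each a list with `segment`
#'   (channels x samples matrix) and `label`
#'   (`"concussed"`/`"non-concussed"`); see [segmentEpochs()].
#' @param val_epochs optional validation epochs, same format.
#' @param config a [concNetConfig()].
#' @param verbose print per-epoch losses.
#' @return list of class `"ConcNetModel"`: `params`, `config`,
#'   `history` (per-epoch mean training loss).
#' @export
trainConcNet <- function(train_epochs, val_epochs = NULL,
                         config = concNetConfig(), verbose = FALSE) {
  if (!length(train_epochs)) stop("empty training set")
  ys <- vapply(train_epochs, function(e) as.integer(e$label == "concussed"),
               integer(1))
  if (length(unique(ys)) < 2L)
    stop("training set must contain both classes")
  Xs <- lapply(train_epochs, function(e) {
    x <- e$segment
    if (config$standardize) standardizeEpoch(x) else x
  })
  n_input <- nrow(Xs[[1]])
  params <- initConcNet(n_input, config)  # seeds the RNG too
  adam <- list(m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0), t = 0L)
  history <- numeric(config$epochs)
  n <- length(Xs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      res <- cn_grad_batch_cpp(params, Xs[idx], ys[idx], config$dropout)
      g <- lapply(res$grads, function(x) x / length(idx))
      adam$t <- adam$t + 1L
      upd <- adamStep(params, g, adam, config$lr)
      params <- upd$params; adam <- upd$adam
      tot <- tot + res$loss
    }
    history[ep] <- tot / n
    if (verbose) {
      msg <- sprintf("epoch %d/%d: train loss %.4f", ep, config$epochs,
                     history[ep])
      if (!is.null(val_epochs) && length(val_epochs)) {
        vp <- predictEpochs(list(params = params, config = config),
                            val_epochs)
        vy <- vapply(val_epochs,
                     function(e) as.integer(e$label == "concussed"),
                     integer(1))
        vl <- -mean(log(pmax(ifelse(vy == 1, vp, 1 - vp), 1e-12)))
        msg <- paste0(msg, sprintf(", val loss %.4f", vl))
      }
      message(msg)
    }
  }
  structure(list(params = params, config = config, history = history),
            class = "ConcNetModel")
}

adamStep <- function(params, grads, adam, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  t <- adam$t
  for (k in names(params)) {
    adam$m[[k]] <- beta1 * adam$m[[k]] + (1 - beta1) * grads[[k]]
    adam$v[[k]] <- beta2 * adam$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- adam$m[[k]] / (1 - beta1^t)
    vhat <- adam$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, adam = adam)
}

#' Per-epoch class probabilities
#'
#' @param model a `"ConcNetModel"`.
#' @param epochs list of epochs (see [trainConcNet()]).
#' @return Numeric vector of `p_conc`, the probability of the positive
#'   (concussed) class, one per epoch; `p_hlth = 1 - p_conc`.
#' @export
predictEpochs <- function(model, epochs) {
  cfg <- model$config
  vapply(epochs, function(e) {
    x <- e$segment
    if (cfg$standardize) x <- standardizeEpoch(x)
    cn_predict_cpp(model$params, x)[1]
  }, numeric(1))
}

#' Participant-level prediction by the median rule
#'
#' Aggregates one participant's per-epoch probabilities as their
#' median; the participant is labelled concussed iff the median is
#' strictly above the threshold.
#'
#' @param model a `"ConcNetModel"`.
#' @param epochs all epochs of one participant.
#' @param threshold decision threshold (default 0.5).
#' @return list `p_conc` (median probability) and `label`.
#' @export
predictParticipant <- function(model, epochs, threshold = 0.5) {
  if (!length(epochs)) stop("no epochs for participant")
  p <- stats::median(predictEpochs(model, epochs))
  list(p_conc = p,
       label = if (p > threshold) "concussed" else "non-concussed")
}
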