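#' Stationary covariance of a linear stochastic system
#'
#' Solves the continuous-time Lyapunov equation
#' \eqn{A \Sigma + \Sigma A^\top + Q = 0} for the stationary covariance
#' \eqn{\Sigma} of \eqn{dX = A X\,dt + dW}, \eqn{Q = \mathrm{diag}(\sigma^2)},
#' by vectorization. Used as the analytic oracle for planted information
#' flows.
#'
#' @param drift square drift matrix `A`; all eigenvalues must have
#'   negative real part.
#' @param noise_sd per-node noise standard deviations (recycled).
#' @return The stationary covariance matrix.
#' @export
lyapunovCov <- function(drift, noise_sd) {
  drift <- as.matrix(drift)
  d <- nrow(drift)
  assertStableDrift(drift)
  noise_sd <- rep_len(noise_sd, d)
  Q <- diag(noise_sd^2, d)
  I <- diag(d)
  K <- kronecker(I, drift) + kronecker(drift, I)
  Sigma <- matrix(solve(K, -as.vector(Q)), d, d)
  (Sigma + t(Sigma)) / 2
}

assertStableDrift <- function(drift) {
  ev <- eigen(drift, only.values = TRUE)$values
  worst <- ev[which.max(Re(ev))]
  if (max(Re(ev)) >= 0)
    stop("unstable drift matrix: eigenvalue ", format(worst),
         " has non-negative real part; no stationary distribution exists")
  invisible(ev)
}

#' Simulate a linear stochastic system (Euler-Maruyama)
#'
#' Discretizes \eqn{dX = A X\,dt + \mathrm{diag}(\sigma)\,dW} with the
#' forward-Euler scheme \eqn{X_{n+1} = X_n + A X_n\,dt + \sigma\sqrt{dt}\,\epsilon_n},
#' matching the forward-difference convention of the flow estimator.
#' Paths start from the origin; a burn-in is discarded so the retained
#' samples are approximately stationary.
#'
#' @inheritParams lyapunovCov
#' @param dt time step in seconds.
#' @param n number of retained samples.
#' @param burn_in discarded initial steps (default 2000).
#' @return numeric matrix, `nrow(drift)` rows by `n` columns.
#' @export
simulateOU <- function(drift, noise_sd, dt, n, burn_in = 2000L) {
  drift <- as.matrix(drift)
  assertStableDrift(drift)
  if (n < 1L) stop("'n' must be positive")
  noise_sd <- rep_len(noise_sd, nrow(drift))
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0")
  ou_simulate_cpp(drift, noise_sd, dt, as.integer(n), as.integer(burn_in))
}

#' Two-node linear pair with a planted directed coupling
#'
#' Generates one discretized path of the two-node system
#' \deqn{dX_1 = (a_{11} X_1 + a_{12} X_2)\,dt + \sigma\,dW_1, \quad
#'       dX_2 = a_{22} X_2\,dt + \sigma\,dW_2,}
#' so information flows only from node 2 to node 1 (coupling
#' \eqn{a_{12}}). The analytic stationary flow rate is
#' \eqn{T_{2 \to 1} = a_{12}\,\sigma_{12}/\sigma_{11}} with \eqn{\sigma}
#' the Lyapunov stationary covariance — the closed-form oracle against
#' which the sample estimator is validated.
#'
#' @param a11,a22 self-feedback coefficients (must be negative).
#' @param a12 coupling from node 2 into node 1.
#' @param noise_sd noise standard deviation (both nodes).
#' @param dt time step in seconds.
#' @param n number of samples (>= 1000).
#' @param seed integer seed; same seed, same path, bit for bit.
#' @return A list with `x1`, `x2` (numeric vectors), `true_T` (analytic
#'   flow 2 -> 1 in nats per unit time), `drift` and `Sigma`.
#' @examples
#' p <- genLinearPair(seed = 1)
#' p$true_T
#' @export
genLinearPair <- function(a11 = -1, a12 = 0.5, a22 = -1, noise_sd = 1,
                          dt = 0.01, n = 10000L, seed = 1L) {
  if (a11 >= 0 || a22 >= 0) stop("self-feedback a11, a22 must be negative")
  if (n < 1000L) stop("'n' must be at least 1000")
  drift <- matrix(c(a11, 0, a12, a22), 2, 2) # column-major: [a11 a12; 0 a22]
  assertStableDrift(drift)
  Sigma <- lyapunovCov(drift, noise_sd)
  true_T <- a12 * Sigma[1, 2] / Sigma[1, 1]
  set.seed(as.integer(seed))
  path <- simulateOU(drift, noise_sd, dt, n)
  list(x1 = path[1, ], x2 = path[2, ], true_T = true_T,
       drift = drift, Sigma = Sigma)
}

#' Default ten-node drift with three planted directed edges
#'
#' Self-feedback \eqn{-1} on the diagonal and three planted couplings of
#' the given strength: RC -> LC, LO -> LC and RP -> LP (receiver row,
#' transmitter column), echoing hub patterns typical of resting-state
#' source networks and making top-k edge recovery checkable.
#'
#' @param coupling planted edge strength (default 0.5).
#' @param self self-feedback (default -1).
#' @return 10 x 10 drift matrix with [ROI_LABELS] dimnames.
#' @export
defaultDrift <- function(coupling = 0.5, self = -1) {
  R <- length(ROI_LABELS)
  A <- diag(self, R)
  dimnames(A) <- list(ROI_LABELS, ROI_LABELS)
  edges <- defaultTruthEdges()
  for (k in seq_len(nrow(edges)))
    A[edges$receiver[k], edges$transmitter[k]] <- coupling
  A
}

#' @rdname defaultDrift
#' @export
defaultTruthEdges <- function() {
  data.frame(transmitter = c("RC", "LO", "RP"),
             receiver = c("LC", "LC", "LP"),
             stringsAsFactors = FALSE)
}

#' Generate a two-group cohort of coupled ROI dynamics
#'
#' Produces `2 * n_per_group` participants of ten-node (by default)
#' linear stochastic dynamics. The concussed-like group's off-diagonal
#' drift entries are scaled by `group_gain`, planting a group-level
#' magnitude effect on every true coupling while controls keep the base
#' drift — emulating a cohort whose flow magnitudes are stochastically
#' larger in one group.
#'
#' @param n_per_group participants per group.
#' @param drift base drift matrix (default [defaultDrift()]).
#' @param noise_sd per-node noise standard deviation.
#' @param dt sampling interval in seconds (default 1/250, i.e. 250 Hz).
#' @param n_samples samples per participant (default 75000 = 5 min at
#'   250 Hz, the study-length recording).
#' @param group_gain multiplier (>= 1) on off-diagonal drift entries for
#'   the concussed-like group.
#' @param seed integer seed.
#' @return A [SyntheticCohort-class]; `truth` holds each participant's
#'   drift and the planted edge list.
#' @export
genVarCohort <- function(n_per_group, drift = defaultDrift(),
                         noise_sd = 1, dt = 1 / 250, n_samples = 75000L,
                         group_gain = 1.5, seed = 1L) {
  drift <- as.matrix(drift)
  if (n_samples < 100L) stop("'n_samples' must be at least 100")
  if (group_gain < 1) stop("'group_gain' must be >= 1")
  assertStableDrift(drift)
  gained <- drift
  off <- row(gained) != col(gained)
  gained[off] <- gained[off] * group_gain
  ev <- tryCatch(assertStableDrift(gained), error = function(e)
    stop("drift becomes unstable after applying group_gain = ", group_gain,
         ": ", conditionMessage(e)))
  labels <- if (!is.null(rownames(drift))) rownames(drift)
    else if (nrow(drift) == length(ROI_LABELS)) ROI_LABELS
    else paste0("ROI", seq_len(nrow(drift)))

  set.seed(as.integer(seed))
  parts <- list(); grp <- character(); truth <- list()
  idx <- 0L
  for (g in c("control-like", "concussed-like")) {
    A <- if (g == "concussed-like") gained else drift
    for (p in seq_len(n_per_group)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", if (g == "control-like") "HC" else "CC", p)
      path <- simulateOU(A, noise_sd, dt, n_samples)
      parts[[idx]] <- ROITimeSeries(path, roiLabels = labels, dt = dt,
                                    participantId = id)
      grp[idx] <- g
      truth[[idx]] <- list(drift = A, noise_sd = noise_sd, dt = dt,
                           edges = defaultTruthEdges())
    }
  }
  methods::new("SyntheticCohort", participants = parts, groupLabel = grp,
               truth = truth)
}

#' Generate a raw multichannel EEG-like cohort
#'
#' Each recording is a fixed random near-orthonormal mixture of latent
#' sources into 64 channels: one 8-12 Hz band-limited oscillation
#' (alpha-like), several 1/f-shaped noise sources and white sensor
#' noise. One class ("concussed") has its oscillation amplitude scaled
#' by `1 + class_effect_size`, giving a band-power/connectivity class
#' signature; at `class_effect_size = 0` the labels carry no signal.
#'
#' @param n_per_class recordings per class.
#' @param fs sampling rate, 250 or 500 Hz (study hardware rates).
#' @param duration recording length in seconds (>= 30; the study used
#'   5-minute recordings).
#' @param class_effect_size amplitude scaling of the oscillatory source
#'   for the concussed class (0 = null generator).
#' @param n_channels number of sensors (64, the study montage).
#' @param seed integer seed; the mixing matrix is drawn once from the
#'   seed and shared by all recordings.
#' @return A list of class `"RawEEGCohort"`: `recordings` (list of
#'   [RawRecording-class]) and `class_effect` (description string).
#' @export
genRawEEGCohort <- function(n_per_class, fs = 250, duration = 60,
                            class_effect_size = 0, n_channels = 64L,
                            seed = 1L) {
  if (!fs %in% c(250, 500))
    stop("unsupported sampling rate ", fs, " Hz; allowed: 250, 500")
  if (duration < 30) stop("'duration' must be at least 30 s")
  set.seed(as.integer(seed))
  n <- round(duration * fs)
  n_src <- 8L
  mix <- qr.Q(qr(matrix(rnorm(n_channels * n_src), n_channels, n_src)))

  make_sources <- function(alpha_gain) {
    S <- matrix(0, n_src, n)
    S[1, ] <- alpha_gain * bandOscillation(n, fs, 8, 12)
    for (s in 2:n_src) S[s, ] <- pinkNoise(n)
    S
  }

  recs <- list(); idx <- 0L
  for (cls in c("non-concussed", "concussed")) {
    gain <- if (cls == "concussed") 1 + class_effect_size else 1
    for (p in seq_len(n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", if (cls == "concussed") "CC" else "HC", p)
      sig <- mix %*% make_sources(gain) + 0.1 * matrix(rnorm(n_channels * n),
                                                       n_channels, n)
      recs[[idx]] <- RawRecording(sig, fs = fs, participantId = id,
                                  label = cls)
    }
  }
  structure(list(
    recordings = recs,
    class_effect = sprintf("alpha (8-12 Hz) amplitude x %g for concussed",
                           1 + class_effect_size)
  ), class = "RawEEGCohort")
}

# Band-limited oscillation: white noise band-passed to [lo, hi] Hz via
# FFT masking, unit variance.
bandOscillation <- function(n, fs, lo, hi) {
  w <- rnorm(n)
  sp <- stats::fft(w)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)
  keep <- freqs >= lo & freqs <= hi
  sp[!keep] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# 1/f-shaped noise via spectral shaping, unit variance.
pinkNoise <- function(n) {
  w <- rnorm(n)
  sp <- stats::fft(w)
  freqs <- (seq_len(n) - 1) / n
  freqs <- pmin(freqs, 1 - freqs)
  shape <- 1 / sqrt(pmax(freqs, 1 / n))
  shape[1] <- 0
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Mean band power of a recording
#'
#' Average periodogram power in a frequency band, across channels.
#' Used to verify the planted spectral class effect.
#'
#' @param rec a [RawRecording-class].
#' @param lo,hi band edges in Hz.
#' @return Mean power in the band (periodogram units).
#' @export
bandPower <- function(rec, lo = 8, hi = 12) {
  sig <- signalValues(rec)
  fs <- samplingRate(rec)
  n <- ncol(sig)
  freqs <- (seq_len(n) - 1) / n * fs
  keep <- freqs >= lo & freqs <= hi
  pw <- apply(sig, 1, function(x) {
    sp <- Mod(stats::fft(x - mean(x)))^2 / n
    mean(sp[keep])
  })
  mean(pw)
}
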