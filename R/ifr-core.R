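#' Sample cross-covariance (population normalization)
#'
#' Mean of elementwise products minus the product of the means,
#' \eqn{\overline{xy} - \bar x \, \bar y}, i.e. the covariance with the
#' divide-by-N normalization. All moment estimates in the flow-rate
#' pipeline use this form so that the correlation ratios are unaffected
#' by the normalization constant.
#'
#' @param x,y numeric vectors of equal length (>= 2), finite.
#' @return A single number.
#' @examples
#' sampleCrossCovariance(1:4, 1:4) # 1.25
#' @export
sampleCrossCovariance <- function(x, y) {
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y))
  if (length(x) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input series")
  mean(x * y) - mean(x) * mean(y)
}

#' Pearson correlation from population covariances
#'
#' @param x,y numeric vectors of equal length, both non-constant.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
pearsonCorrelation <- function(x, y) {
  sx <- sqrt(sampleCrossCovariance(x, x))
  sy <- sqrt(sampleCrossCovariance(y, y))
  if (sx == 0 || sy == 0)
    stop("degenerate input: zero variance series")
  r <- sampleCrossCovariance(x, y) / (sx * sy)
  max(-1, min(1, r))
}

#' Forward-difference derivative estimate
#'
#' First-order forward Euler difference \eqn{(x_{n+k} - x_n)/(k\,dt)},
#' the standard derivative estimator in the information-flow literature.
#'
#' @param x numeric vector, length > k.
#' @param dt sampling interval in seconds.
#' @param k difference step (1 by default; 2 selects the two-step form).
#' @return numeric vector of length `length(x) - k`.
#' @export
forwardDifference <- function(x, dt, k = 1L) {
  if (dt <= 0) stop("'dt' must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be a positive integer")
  n <- length(x)
  if (n <= k) stop("series too short for a k-step difference")
  (x[(1L + k):n] - x[1L:(n - k)]) / (k * dt)
}

#' Pairwise covariance/correlation statistics for one ordered ROI pair
#'
#' Computes every moment entering the Liang-Kleeman flow rate from
#' transmitter `x_i` to receiver `x_j`: the population cross-covariances
#' \eqn{C_{ij}, C_{ii}, C_{jj}}, the covariances of each series with the
#' receiver's forward-difference derivative
#' (\eqn{C_{i,dj}, C_{j,dj}}), and the correlation ratios
#' \eqn{r_{ij} = C_{ij}/(\sigma_i\sigma_j)},
#' \eqn{r_{i,dj} = C_{i,dj}/(\sigma_i\sigma_j)},
#' \eqn{r_{j,dj} = C_{j,dj}/\sigma_j^2}.
#'
#' All statistics are computed on the first \eqn{N - k} samples of each
#' series, aligned with the derivative sample at the same index, so that
#' every moment estimate shares one common index set.
#'
#' @param x_i transmitter series.
#' @param x_j receiver series (same length, >= 3 samples).
#' @param dt sampling interval in seconds.
#' @param k derivative difference step, see [forwardDifference()].
#' @param deriv_sd if `TRUE`, normalize \eqn{r_{i,dj}} and
#'   \eqn{r_{j,dj}} by the derivative's own standard deviation instead
#'   of the receiver's (alternative convention; off by default).
#' @return A list of class `"PairStats"` with fields `C_ij`, `C_ii`,
#'   `C_jj`, `C_i_dj`, `C_j_dj`, `C_djdj`, `sigma_i`, `sigma_j`,
#'   `r_ij`, `r_i_dj`, `r_j_dj`, `dt`, `n`.
#' @export
pairStats <- function(x_i, x_j, dt, k = 1L, deriv_sd = FALSE) {
  if (length(x_i) != length(x_j))
    stop("series lengths differ: ", length(x_i), " vs ", length(x_j))
  n <- length(x_i)
  if (n < 3L) stop("need at least 3 samples")
  dxj <- forwardDifference(x_j, dt, k = k)
  m <- n - as.integer(k)
  xi <- x_i[seq_len(m)]
  xj <- x_j[seq_len(m)]

  C_ij <- sampleCrossCovariance(xi, xj)
  C_ii <- sampleCrossCovariance(xi, xi)
  C_jj <- sampleCrossCovariance(xj, xj)
  C_i_dj <- sampleCrossCovariance(xi, dxj)
  C_j_dj <- sampleCrossCovariance(xj, dxj)
  C_djdj <- sampleCrossCovariance(dxj, dxj)
  sigma_i <- sqrt(C_ii)
  sigma_j <- sqrt(C_jj)
  if (sigma_i == 0 || sigma_j == 0)
    stop("degenerate input: zero variance series")

  denom_d <- if (deriv_sd) {
    if (C_djdj == 0) stop("degenerate input: constant derivative with deriv_sd normalization")
    sqrt(C_djdj)
  } else sigma_j

  structure(list(
    C_ij = C_ij, C_ii = C_ii, C_jj = C_jj,
    C_i_dj = C_i_dj, C_j_dj = C_j_dj, C_djdj = C_djdj,
    sigma_i = sigma_i, sigma_j = sigma_j,
    r_ij = C_ij / (sigma_i * sigma_j),
    r_i_dj = C_i_dj / (sigma_i * denom_d),
    r_j_dj = C_j_dj / (sigma_j * denom_d),
    dt = dt, n = m
  ), class = "PairStats")
}

#' Liang-Kleeman information flow rate from pair statistics
#'
#' \deqn{T_{i \to j} = \frac{r_{ij}}{1 - r_{ij}^2}
#'   \left(r_{i,dj} - r_{ij}\, r_{j,dj}\right)}
#' in nats per unit time. With the default normalization of
#' [pairStats()] this equals the covariance form
#' \eqn{(C_{jj} C_{ij} C_{i,dj} - C_{ij}^2 C_{j,dj}) /
#'      (C_{jj}^2 C_{ii} - C_{jj} C_{ij}^2)}.
#'
#' @param stats a `"PairStats"` list from [pairStats()].
#' @param eps collinearity guard: an error is raised when
#'   \eqn{|r_{ij}| \ge 1 - } `eps`.
#' @return The flow rate \eqn{T_{i \to j}} (nats per unit time).
#' @export
liangT <- function(stats, eps = 1e-10) {
  r <- stats$r_ij
  if (abs(r) >= 1 - eps)
    stop("degenerate collinearity: |r_ij| = ", format(abs(r)),
         " >= 1 - ", format(eps))
  (r / (1 - r^2)) * (stats$r_i_dj - r * stats$r_j_dj)
}

#' Normalized flow rate tau and its entropy-budget components
#'
#' Normalizes \eqn{T_{i \to j}} by the magnitude of the receiver's total
#' entropy-rate budget. The receiver's derivative is fitted by least
#' squares on (receiver, transmitter) using the same population
#' covariances; the fitted self-feedback coefficient is the own-dynamics
#' term, and the residual noise intensity \eqn{g_j = dt \cdot}MSE gives
#' the noise term \eqn{g_j / (2 C_{jj})}. Then
#' \deqn{Z = |T| + |\mathrm{self}| + |\mathrm{noise}|, \qquad
#'       \tau = T / Z,}
#' so \eqn{|\tau| \le 1} by construction and
#' \eqn{\mathrm{sign}(\tau) = \mathrm{sign}(T)} whenever \eqn{Z > 0}.
#'
#' @param stats a `"PairStats"` list from [pairStats()].
#' @param T flow rate from [liangT()] (computed when missing).
#' @return A list of class `"FlowEstimate"` with fields `T`, `Z`,
#'   `self_term`, `noise_term`, `tau`, `abs_tau` and `degenerate`
#'   (`TRUE` when `Z == 0` and `tau` was set to 0).
#' @export
normalizeTau <- function(stats, T = NULL) {
  if (is.null(T)) T <- liangT(stats)
  stopifnot(is.finite(T))
  det <- stats$C_ii * stats$C_jj - stats$C_ij^2
  a_jj <- (stats$C_ii * stats$C_j_dj - stats$C_ij * stats$C_i_dj) / det
  a_ij <- (stats$C_jj * stats$C_i_dj - stats$C_ij * stats$C_j_dj) / det
  mse <- stats$C_djdj - a_jj * stats$C_j_dj - a_ij * stats$C_i_dj
  mse <- max(mse, 0) # guard tiny negative round-off
  g_j <- stats$dt * mse
  noise_term <- g_j / (2 * stats$C_jj)
  Z <- abs(T) + abs(a_jj) + abs(noise_term)
  degenerate <- Z == 0
  tau <- if (degenerate) 0 else T / Z
  structure(list(
    T = T, Z = Z, self_term = a_jj, noise_term = noise_term,
    tau = tau, abs_tau = abs(tau), degenerate = degenerate
  ), class = "FlowEstimate")
}

#' Normalized flow rate for one ordered pair of series
#'
#' Convenience wrapper chaining [pairStats()], [liangT()] and
#' [normalizeTau()].
#'
#' @inheritParams pairStats
#' @inheritParams liangT
#' @return A `"FlowEstimate"` list, see [normalizeTau()].
#' @export
pairFlow <- function(x_i, x_j, dt, k = 1L, deriv_sd = FALSE, eps = 1e-10) {
  st <- pairStats(x_i, x_j, dt, k = k, deriv_sd = deriv_sd)
  normalizeTau(st, T = liangT(st, eps = eps))
}

#' Full directed flow matrix for one participant
#'
#' Computes \eqn{\tau_{i \to j}} for every ordered ROI pair
#' (\eqn{R(R-1)} pairs for \eqn{R} ROIs; 90 for the canonical ten). The
#' diagonal is masked. Degenerate pairs (zero variance or collinear
#' series) are masked with `NA` and reported in one warning rather than
#' aborting the participant.
#'
#' @param ts an [ROITimeSeries-class].
#' @inheritParams pairStats
#' @inheritParams liangT
#' @return A [FlowMatrix-class].
#' @examples
#' set.seed(1)
#' ts <- ROITimeSeries(matrix(rnorm(10 * 500), nrow = 10), dt = 0.004)
#' fm <- ifrMatrix(ts)
#' sum(!is.na(tauMatrix(fm))) # 90 ordered pairs
#' @export
ifrMatrix <- function(ts, k = 1L, deriv_sd = FALSE, eps = 1e-10) {
  stopifnot(methods::is(ts, "ROITimeSeries"))
  v <- ts@values
  R <- nrow(v)
  dt <- ts@dt
  tau <- matrix(NA_real_, R, R)
  bad <- character()
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (i == j) next
      est <- tryCatch(
        pairFlow(v[i, ], v[j, ], dt, k = k, deriv_sd = deriv_sd, eps = eps),
        error = function(e) NULL
      )
      if (is.null(est)) {
        bad <- c(bad, sprintf("%s->%s", ts@roiLabels[i], ts@roiLabels[j]))
      } else {
        tau[i, j] <- est$tau
      }
    }
  }
  if (length(bad))
    warning("masked ", length(bad), " degenerate pair(s): ",
            paste(bad, collapse = ", "))
  FlowMatrix(tau, roiLabels = ts@roiLabels, participantId = ts@participantId)
}
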