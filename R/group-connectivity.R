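#' Group-mean absolute flow matrix
#'
#' Elementwise mean of \eqn{|\tau|} across a group's participants.
#' Masked (NA) entries are excluded pairwise, so one degenerate
#' participant does not mask a connection for the whole group.
#'
#' @param matrices non-empty list of [FlowMatrix-class] sharing node
#'   count and ordering.
#' @param group_name optional name recorded as the result's participant
#'   id.
#' @return A [FlowMatrix-class] of mean \eqn{|\tau|} values.
#' @export
meanGroupMatrix <- function(matrices, group_name = "group") {
  checkGroup(matrices)
  R <- nROI(matrices[[1]])
  acc <- matrix(0, R, R)
  cnt <- matrix(0L, R, R)
  for (m in matrices) {
    a <- absTau(m)
    ok <- !is.na(a)
    acc[ok] <- acc[ok] + a[ok]
    cnt <- cnt + ok
  }
  mean_m <- ifelse(cnt > 0, acc / cnt, NA_real_)
  FlowMatrix(mean_m, roiLabels = roiLabels(matrices[[1]]),
             participantId = group_name)
}

checkGroup <- function(matrices) {
  if (length(matrices) == 0L) stop("empty group")
  ok <- vapply(matrices, methods::is, logical(1), "FlowMatrix")
  if (!all(ok)) stop("all group members must be FlowMatrix objects")
  rr <- vapply(matrices, nROI, integer(1))
  if (length(unique(rr)) != 1L) stop("group matrices differ in node count")
  labs <- vapply(matrices, function(m) paste(roiLabels(m), collapse = ","),
                 character(1))
  if (length(unique(labs)) != 1L) stop("group matrices differ in ROI ordering")
  invisible(TRUE)
}

#' Active connections of a mean flow matrix
#'
#' Ordered pairs whose mean \eqn{|\tau|} exceeds the activity threshold
#' (0.05 by default, the conventional cut for a meaningful directed
#' influence).
#'
#' @param mean_matrix a [FlowMatrix-class] of mean \eqn{|\tau|}.
#' @param threshold activity threshold (default 0.05).
#' @return data.frame with columns `transmitter`, `receiver`,
#'   `mean_abs_tau`, sorted by descending magnitude.
#' @export
activeConnections <- function(mean_matrix, threshold = 0.05) {
  edges <- flowEdges(mean_matrix)
  out <- edges[!is.na(edges$mean_abs_tau) & edges$mean_abs_tau > threshold, ]
  rownames(out) <- NULL
  out
}

#' Top-k strongest connections
#'
#' The `k` largest off-diagonal mean \eqn{|\tau|} entries with their ROI
#' pair labels, in descending order. Ties are broken by (transmitter,
#' receiver) position in the fixed ROI ordering, so ranking is
#' deterministic. Requests beyond the available \eqn{R(R-1)} pairs
#' return all pairs, ranked.
#'
#' @param mean_matrix a [FlowMatrix-class].
#' @param k number of connections (default 10).
#' @return data.frame `transmitter`, `receiver`, `mean_abs_tau`.
#' @export
topConnections <- function(mean_matrix, k = 10L) {
  if (k < 1L) stop("'k' must be >= 1")
  edges <- flowEdges(mean_matrix)
  edges <- edges[!is.na(edges$mean_abs_tau), ]
  utils::head(edges, n = k)
}

# Off-diagonal entries as a deterministic, rank-ordered edge table.
flowEdges <- function(mean_matrix) {
  stopifnot(methods::is(mean_matrix, "FlowMatrix"))
  a <- absTau(mean_matrix)
  labs <- roiLabels(mean_matrix)
  R <- nrow(a)
  ij <- which(row(a) != col(a), arr.ind = TRUE)
  df <- data.frame(
    transmitter = labs[ij[, 1]],
    receiver = labs[ij[, 2]],
    mean_abs_tau = a[ij],
    stringsAsFactors = FALSE
  )
  ord <- order(-df$mean_abs_tau, ij[, 1], ij[, 2], na.last = TRUE)
  df <- df[ord, ]
  rownames(df) <- NULL
  df
}

#' Permutation null distribution of |tau| for one group
#'
#' For every participant, connection and permutation the transmitter's
#' samples are shuffled uniformly at random (the receiver untouched),
#' destroying all temporal structure, and \eqn{|\tau|} recomputed. All
#' permuted values are pooled across participants and connections into
#' one group-level null; its 5th and 95th percentiles are reported and
#' the 95th is the significance threshold for mean connections.
#'
#' @param group list of [ROITimeSeries-class] (one group).
#' @param n_perm permutations per connection (default 100).
#' @param seed integer seed.
#' @param k derivative step, see [pairStats()].
#' @return list of class `"NullDistribution"`: `values` (pooled permuted
#'   \eqn{|\tau|}, length `n_participants * R(R-1) * n_perm`), `p5`,
#'   `p95`, `n_perm`, `seed`.
#' @export
permutationNull <- function(group, n_perm = 100L, seed = 1L, k = 1L) {
  if (length(group) < 1L) stop("need at least one participant")
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  set.seed(as.integer(seed))
  vals <- lapply(group, function(ts) permTauParticipant(ts, n_perm, k = k))
  pooled <- unlist(vals, use.names = FALSE)
  qs <- stats::quantile(pooled, c(0.05, 0.95), names = FALSE, na.rm = TRUE)
  structure(list(values = pooled, p5 = qs[1], p95 = qs[2],
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "NullDistribution")
}

# Permuted |tau| values for all ordered pairs of one participant.
# The receiver-side moments are permutation-invariant, so only the
# transmitter-dependent covariances are recomputed per shuffle, with
# the n_perm shuffles of one pair batched through one crossprod.
permTauParticipant <- function(ts, n_perm, k = 1L) {
  v <- signalValues(ts)
  R <- nrow(v); n <- ncol(v); dt <- samplingInterval(ts)
  m <- n - as.integer(k)
  out <- numeric(0)
  for (j in seq_len(R)) {
    xj_full <- v[j, ]
    dxj <- forwardDifference(xj_full, dt, k = k)
    xj <- xj_full[seq_len(m)]
    C_jj <- sampleCrossCovariance(xj, xj)
    C_j_dj <- sampleCrossCovariance(xj, dxj)
    C_djdj <- sampleCrossCovariance(dxj, dxj)
    mdx <- mean(dxj); mxj <- mean(xj)
    recv <- cbind(xj, dxj)
    for (i in seq_len(R)) {
      if (i == j) next
      xi_full <- v[i, ]
      # shuffle the full transmitter series, then truncate/align
      P <- matrix(0, m, n_perm)
      for (p in seq_len(n_perm)) {
        P[, p] <- xi_full[sample.int(n)][seq_len(m)]
      }
      cp <- crossprod(P, recv) / m          # n_perm x 2
      mi <- colMeans(P)
      C_ij <- cp[, 1] - mi * mxj
      C_i_dj <- cp[, 2] - mi * mdx
      C_ii <- colMeans(P^2) - mi^2
      tau_p <- vapply(seq_len(n_perm), function(p) {
        st <- structure(list(
          C_ij = C_ij[p], C_ii = C_ii[p], C_jj = C_jj,
          C_i_dj = C_i_dj[p], C_j_dj = C_j_dj, C_djdj = C_djdj,
          sigma_i = sqrt(C_ii[p]), sigma_j = sqrt(C_jj),
          r_ij = C_ij[p] / sqrt(C_ii[p] * C_jj),
          r_i_dj = C_i_dj[p] / sqrt(C_ii[p] * C_jj),
          r_j_dj = C_j_dj / C_jj,
          dt = dt, n = m), class = "PairStats")
        est <- tryCatch(normalizeTau(st), error = function(e) NULL)
        if (is.null(est)) NA_real_ else est$abs_tau
      }, numeric(1))
      out <- c(out, tau_p)
    }
  }
  out[!is.na(out)]
}

#' Pool a group's |tau| values into one distribution
#'
#' Concatenates every participant's off-diagonal \eqn{|\tau|} values
#' (90 per participant for ten ROIs) and computes descriptive and shape
#' statistics: mean, median, SD, coefficient of variation (SD/mean),
#' skewness and kurtosis.
#'
#' @param matrices list of [FlowMatrix-class].
#' @param group_name label stored with the result.
#' @param excess_kurtosis report excess (Fisher) kurtosis instead of raw
#'   (Pearson, normal = 3); raw is the default convention here.
#' @return list of class `"PooledDistribution"`: `values` and `stats`
#'   (named vector `mean`, `median`, `sd`, `cov`, `skewness`,
#'   `kurtosis`).
#' @export
poolGroupValues <- function(matrices, group_name = "group",
                            excess_kurtosis = FALSE) {
  checkGroup(matrices)
  vals <- unlist(lapply(matrices, function(m) {
    a <- absTau(m)
    a[row(a) != col(a)]
  }), use.names = FALSE)
  vals <- vals[!is.na(vals)]
  kurt <- e1071::kurtosis(vals, type = 1)   # excess, moment form
  if (!excess_kurtosis) kurt <- kurt + 3
  stats <- c(
    mean = mean(vals), median = stats::median(vals), sd = popSd(vals),
    cov = popSd(vals) / mean(vals),
    skewness = e1071::skewness(vals, type = 1),
    kurtosis = kurt
  )
  structure(list(values = vals, stats = stats, group_name = group_name),
            class = "PooledDistribution")
}

popSd <- function(x) sqrt(mean((x - mean(x))^2) * length(x) / (length(x) - 1))

#' Compare two pooled |tau| distributions
#'
#' Two-sample Kolmogorov-Smirnov test (shape), Kruskal-Wallis test
#' (central tendency) and Cohen's d with pooled SD (effect size).
#'
#' @param a,b `"PooledDistribution"` objects (or bare numeric vectors).
#' @return list of class `"GroupComparison"`: `ks_stat`, `ks_p`,
#'   `kw_stat`, `kw_p`, `cohens_d`.
#' @export
compareGroups <- function(a, b) {
  va <- if (inherits(a, "PooledDistribution")) a$values else as.numeric(a)
  vb <- if (inherits(b, "PooledDistribution")) b$values else as.numeric(b)
  if (!length(va) || !length(vb)) stop("empty distribution")
  ks <- suppressWarnings(stats::ks.test(va, vb))
  kw <- stats::kruskal.test(list(va, vb))
  structure(list(
    ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    kw_stat = unname(kw$statistic), kw_p = kw$p.value,
    cohens_d = cohensD(va, vb)
  ), class = "GroupComparison")
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric samples.
#' @return \eqn{(\bar x - \bar y)/s_p} with
#'   \eqn{s_p^2 = ((n_x-1)s_x^2 + (n_y-1)s_y^2)/(n_x+n_y-2)}.
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Shape features of random participant subsamples
#'
#' For each repetition, `k` participants are drawn without replacement,
#' their \eqn{|\tau|} values pooled, and the (COV, skewness, kurtosis)
#' triplet recorded — producing the cloud of shape features whose
#' separation between groups visualizes distributional differences.
#' Pooled moments are combined from per-participant raw-moment sums, so
#' the default 100,000 repetitions reduce to one matrix product.
#'
#' @param matrices list of [FlowMatrix-class] (one group).
#' @param k participants per subsample (default 6).
#' @param reps number of subsamples (default 100000).
#' @param seed integer seed.
#' @param excess_kurtosis as in [poolGroupValues()].
#' @return list of class `"SubsampleFeatures"`: `features` (reps x 3
#'   matrix, columns `cov`, `skewness`, `kurtosis`), `k`, `reps`,
#'   `seed`.
#' @export
subsampleShapeFeatures <- function(matrices, k = 6L, reps = 100000L,
                                   seed = 1L, excess_kurtosis = FALSE) {
  checkGroup(matrices)
  G <- length(matrices)
  if (k > G) stop("'k' (", k, ") exceeds group size (", G, ")")
  # per-participant raw moment sums: n, Sx, Sx2, Sx3, Sx4
  sums <- t(vapply(matrices, function(m) {
    a <- absTau(m); v <- a[row(a) != col(a)]; v <- v[!is.na(v)]
    c(length(v), sum(v), sum(v^2), sum(v^3), sum(v^4))
  }, numeric(5)))
  set.seed(as.integer(seed))
  pick <- matrix(0L, reps, G)
  for (r in seq_len(reps)) pick[r, sample.int(G, k)] <- 1L
  agg <- pick %*% sums                    # reps x 5 pooled raw sums
  n <- agg[, 1]; m1 <- agg[, 2] / n
  m2 <- agg[, 3] / n - m1^2               # population central moments
  m3 <- agg[, 4] / n - 3 * m1 * agg[, 3] / n + 2 * m1^3
  m4 <- agg[, 5] / n - 4 * m1 * agg[, 4] / n + 6 * m1^2 * agg[, 3] / n - 3 * m1^4
  sdv <- sqrt(m2 * n / (n - 1))
  skew <- m3 / m2^1.5
  kurt <- m4 / m2^2
  if (excess_kurtosis) kurt <- kurt - 3
  feat <- cbind(cov = sdv / m1, skewness = skew, kurtosis = kurt)
  structure(list(features = feat, k = as.integer(k),
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "SubsampleFeatures")
}
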