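# Independent brute-force oracles: literal explicit-loop transcriptions
# of the estimator definitions, kept deliberately free of the package's
# vectorized code paths.

# all pairwise statistics, flow rate T, normalizer components and tau
# for transmitter xi -> receiver xj, by direct summation
bfPairFlow <- function(xi, xj, dt, k = 1L) {
  n <- length(xj)
  m <- n - k
  dx <- numeric(m)
  for (t in seq_len(m)) dx[t] <- (xj[t + k] - xj[t]) / (k * dt)
  xi <- xi[seq_len(m)]
  xj <- xj[seq_len(m)]
  mn <- function(v) {
    s <- 0
    for (t in seq_len(m)) s <- s + v[t]
    s / m
  }
  cv <- function(a, b) {
    ma <- mn(a); mb <- mn(b)
    s <- 0
    for (t in seq_len(m)) s <- s + (a[t] - ma) * (b[t] - mb)
    s / m
  }
  C_ij <- cv(xi, xj); C_ii <- cv(xi, xi); C_jj <- cv(xj, xj)
  C_i_dj <- cv(xi, dx); C_j_dj <- cv(xj, dx); C_djdj <- cv(dx, dx)
  si <- sqrt(C_ii); sj <- sqrt(C_jj)
  r_ij <- C_ij / (si * sj)
  r_i_dj <- C_i_dj / (si * sj)
  r_j_dj <- C_j_dj / (sj * sj)
  T <- r_ij / (1 - r_ij^2) * (r_i_dj - r_ij * r_j_dj)
  det <- C_ii * C_jj - C_ij^2
  a_jj <- (C_ii * C_j_dj - C_ij * C_i_dj) / det
  a_ij <- (C_jj * C_i_dj - C_ij * C_j_dj) / det
  mse <- C_djdj - a_jj * C_j_dj - a_ij * C_i_dj
  noise <- dt * max(mse, 0) / (2 * C_jj)
  Z <- abs(T) + abs(a_jj) + abs(noise)
  list(C_ij = C_ij, C_ii = C_ii, C_jj = C_jj,
       C_i_dj = C_i_dj, C_j_dj = C_j_dj, C_djdj = C_djdj,
       sigma_i = si, sigma_j = sj,
       r_ij = r_ij, r_i_dj = r_i_dj, r_j_dj = r_j_dj,
       T = T, self_term = a_jj, noise_term = noise, Z = Z,
       tau = if (Z > 0) T / Z else 0)
}

# weighted directed assortativity by explicit edge enumeration and
# loop-computed weighted Pearson correlation
bfAssortativity <- function(tau_mat, variant = "out-in") {
  a <- abs(tau_mat)
  diag(a) <- 0
  a[is.na(a)] <- 0
  R <- nrow(a)
  outd <- ind <- numeric(R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    outd[i] <- outd[i] + a[i, j]
    ind[j] <- ind[j] + a[i, j]
  }
  xs <- ys <- ws <- numeric(0)
  ends <- strsplit(variant, "-")[[1]]
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j && a[i, j] > 0) {
      xs <- c(xs, if (ends[1] == "out") outd[i] else ind[i])
      ys <- c(ys, if (ends[2] == "out") outd[j] else ind[j])
      ws <- c(ws, a[i, j])
    }
  }
  if (length(ws) < 2) return(NA_real_)
  sw <- sum(ws)
  mx <- sum(ws * xs) / sw; my <- sum(ws * ys) / sw
  vx <- sum(ws * (xs - mx)^2) / sw
  vy <- sum(ws * (ys - my)^2) / sw
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(ws * (xs - mx) * (ys - my)) / sw / sqrt(vx * vy)
}

# closed-form stationary covariance of the 2x2 upper-triangular drift
# [[a11, a12], [0, a22]] with noise variances q (both nodes), solved by
# hand from the Lyapunov equations rather than the kron-solve the
# package uses
bfLinearPairT <- function(a11, a12, a22, q) {
  s22 <- q / (-2 * a22)
  s12 <- a12 * s22 / (-(a11 + a22))
  s11 <- (q + 2 * a12 * s12) / (-2 * a11)
  a12 * s12 / s11
}

# random non-degenerate series pair for property tests
randomSeriesPair <- function(n = 60) {
  kind <- sample(3, 1)
  xi <- switch(kind,
               rnorm(n),
               cumsum(rnorm(n)),
               sin(seq_len(n) / 3) + 0.5 * rnorm(n))
  rho <- runif(1, -0.8, 0.8)
  xj <- rho * xi + sqrt(1 - rho^2) * rnorm(n)
  list(xi = xi, xj = xj, dt = runif(1, 0.002, 0.1))
}

# small random weighted digraph tau matrix (possibly sparse)
randomTauMatrix <- function(R = sample(3:7, 1), p_edge = 0.6) {
  m <- matrix(0, R, R)
  for (i in seq_len(R)) for (j in seq_len(R))
    if (i != j && runif(1) < p_edge) m[i, j] <- runif(1, 0.01, 1)
  diag(m) <- NA
  m
}

# quick epoch list builder for classifier tests
makeToyEpochs <- function(n_per_class, d = 4L, len = 250L, sep = TRUE,
                          id_prefix = "P") {
  out <- list()
  idx <- 0
  for (cls in c("concussed", "non-concussed")) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1
      base <- matrix(rnorm(d * len, sd = 0.3), d, len)
      if (sep && cls == "concussed")
        base <- base + matrix(rep(sin(2 * pi * 10 * seq_len(len) / 250),
                                  each = d), d, len)
      out[[idx]] <- list(segment = base,
                         participant_id = paste0(id_prefix, idx),
                         label = cls)
    }
  }
  out
}
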