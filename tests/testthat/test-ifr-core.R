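test_that("sample cross-covariance matches hand-computable cases", {
  expect_equal(sampleCrossCovariance(1:4, 1:4), 1.25)
  expect_equal(sampleCrossCovariance(rep(2, 5), rnorm(5)), 0)
  expect_equal(sampleCrossCovariance(1:4, 4:1), -1.25)
  expect_error(sampleCrossCovariance(1:3, 1:4), "lengths differ")
  expect_error(sampleCrossCovariance(c(1, NA, 2), c(1, 2, 3)), "non-finite")
})

test_that("pearson correlation handles identity, antisymmetry, orthogonality", {
  x <- rnorm(20)
  expect_equal(pearsonCorrelation(x, x), 1)
  expect_equal(pearsonCorrelation(x, -x), -1)
  expect_equal(pearsonCorrelation(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("forward difference is the scaled one-step slope", {
  expect_equal(forwardDifference(c(0, 1, 2, 3), dt = 1), c(1, 1, 1))
  expect_equal(forwardDifference(rep(3, 6), dt = 0.1), rep(0, 5))
  expect_equal(forwardDifference(c(0, 0.004), dt = 0.004), 1)
  expect_equal(forwardDifference(c(0, 1, 2, 4), dt = 1, k = 2), c(1, 1.5))
  expect_error(forwardDifference(1:5, dt = 0), "positive")
})

test_that("pair statistics agree with the brute-force transcription on the printed six-point fixture", {
  x_i <- c(0.2, -0.1, 0.4, 0.0, -0.3, 0.1)
  x_j <- c(0.0, 0.3, -0.2, 0.1, 0.2, -0.1)
  st <- pairStats(x_i, x_j, dt = 1)
  bf <- bfPairFlow(x_i, x_j, dt = 1)
  for (f in c("C_ij", "C_ii", "C_jj", "C_i_dj", "C_j_dj", "sigma_i",
              "sigma_j", "r_ij", "r_i_dj", "r_j_dj"))
    expect_equal(st[[f]], bf[[f]], tolerance = 1e-12, info = f)
})

test_that("a ramp receiver has constant derivative, hence zero derivative covariance", {
  x_j <- seq(0, 5, length.out = 50)
  x_i <- rnorm(50)
  st <- pairStats(x_i, x_j, dt = 0.01)
  expect_equal(st$C_i_dj, 0, tolerance = 1e-9)
  expect_equal(st$r_i_dj, 0, tolerance = 1e-9)
})

test_that("normalized quantities are amplitude-scale invariant", {
  set.seed(11)
  p <- randomSeriesPair(100)
  s1 <- pairStats(p$xi, p$xj, p$dt)
  s2 <- pairStats(5 * p$xi, p$xj, p$dt)
  s3 <- pairStats(p$xi, 3 * p$xj, p$dt)
  expect_equal(s1$r_ij, s2$r_ij, tolerance = 1e-12)
  expect_equal(s1$r_i_dj, s2$r_i_dj, tolerance = 1e-12)
  t1 <- normalizeTau(s1); t2 <- normalizeTau(s2); t3 <- normalizeTau(s3)
  expect_equal(t1$tau, t2$tau, tolerance = 1e-10)
  expect_equal(t1$tau, t3$tau, tolerance = 1e-10)
})

test_that("flow rate is zero when series are uncorrelated and errors on collinearity", {
  st <- list(r_ij = 0, r_i_dj = 0.4, r_j_dj = -0.2)
  expect_equal(liangT(structure(st, class = "PairStats")), 0)
  x <- rnorm(50)
  expect_error(liangT(pairStats(x, x, dt = 0.01)), "collinearity")
})

test_that("estimator fields match the explicit-loop oracle on random inputs", {
  set.seed(202)
  for (rep in seq_len(250)) {
    p <- randomSeriesPair(sample(20:120, 1))
    st <- pairStats(p$xi, p$xj, p$dt)
    bf <- bfPairFlow(p$xi, p$xj, p$dt)
    if (abs(bf$r_ij) >= 1 - 1e-10) next
    est <- normalizeTau(st)
    for (f in c("C_ij", "C_i_dj", "r_ij", "r_i_dj", "r_j_dj"))
      expect_equal(st[[f]], bf[[f]], tolerance = 1e-10)
    expect_equal(est$T, bf$T, tolerance = 1e-10)
    expect_equal(est$Z, bf$Z, tolerance = 1e-10)
    expect_equal(est$tau, bf$tau, tolerance = 1e-10)
  }
})

test_that("tau is bounded by one with the sign of T, and Z decomposes exactly", {
  set.seed(77)
  for (rep in seq_len(200)) {
    p <- randomSeriesPair(60)
    st <- pairStats(p$xi, p$xj, p$dt)
    if (abs(st$r_ij) >= 1 - 1e-10) next
    est <- normalizeTau(st)
    expect_lte(abs(est$tau), 1)
    expect_equal(est$Z, abs(est$T) + abs(est$self_term) + abs(est$noise_term))
    if (est$Z > 0 && est$T != 0)
      expect_equal(sign(est$tau), sign(est$T))
  }
})

test_that("alternative derivative normalization rescales but preserves zero crossings", {
  set.seed(5)
  p <- randomSeriesPair(200)
  st_def <- pairStats(p$xi, p$xj, p$dt)
  st_alt <- pairStats(p$xi, p$xj, p$dt, deriv_sd = TRUE)
  ratio <- st_alt$r_i_dj / st_def$r_i_dj
  expect_equal(st_alt$r_j_dj / st_def$r_j_dj, ratio, tolerance = 1e-10)
  expect_equal(ratio, st_def$sigma_j / sqrt(st_def$C_djdj), tolerance = 1e-10)
})

test_that("a ten-ROI series yields exactly 90 ordered-pair estimates", {
  set.seed(9)
  ts <- ROITimeSeries(matrix(rnorm(10 * 400), nrow = 10), dt = 1 / 250)
  fm <- ifrMatrix(ts)
  expect_true(all(is.na(diag(tauMatrix(fm)))))
  expect_identical(sum(!is.na(tauMatrix(fm))), 90L)
  expect_identical(absTau(fm), abs(tauMatrix(fm)))
})

test_that("relabeling ROIs permutes the flow matrix by conjugation", {
  set.seed(10)
  v <- matrix(rnorm(5 * 300), nrow = 5)
  ts <- ROITimeSeries(v, roiLabels = paste0("R", 1:5), dt = 0.004)
  fm <- ifrMatrix(ts)
  perm <- c(3, 1, 5, 2, 4)
  ts_p <- ROITimeSeries(v[perm, ], roiLabels = paste0("R", 1:5)[perm],
                        dt = 0.004)
  fm_p <- ifrMatrix(ts_p)
  expect_equal(tauMatrix(fm_p), tauMatrix(fm)[perm, perm],
               ignore_attr = TRUE)
})

test_that("degenerate ROIs are masked with a warning, not fatal", {
  set.seed(12)
  v <- matrix(rnorm(4 * 200), nrow = 4)
  v[2, ] <- 1 # constant row
  ts <- ROITimeSeries(v, roiLabels = paste0("R", 1:4), dt = 0.01)
  expect_warning(fm <- ifrMatrix(ts), "degenerate")
  expect_true(all(is.na(tauMatrix(fm)[2, ])))
  expect_true(all(is.na(tauMatrix(fm)[, 2])))
  expect_true(all(!is.na(tauMatrix(fm)[c(1, 3, 4), c(1, 3, 4)][
    row(diag(3)) != col(diag(3))])))
})

test_that("independent white-noise ROIs produce uniformly small |tau|", {
  set.seed(13)
  ts <- ROITimeSeries(matrix(rnorm(10 * 10000), nrow = 10), dt = 1 / 250)
  fm <- ifrMatrix(ts)
  off <- absTau(fm)[row(tauMatrix(fm)) != col(tauMatrix(fm))]
  expect_lte(mean(off > 0.05), 0.10)
})
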