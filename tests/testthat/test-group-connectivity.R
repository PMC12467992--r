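# Published group-mean |tau| magnitudes for the ten strongest
# connections of each group (transmitter, receiver, mean |tau|),
# used as fixed worked-example inputs.
CONTROL_TOP10 <- data.frame(
  transmitter = c("RC", "LT", "LP", "RP", "RP", "LC", "RT", "RO", "RO", "RT"),
  receiver    = c("LC", "LC", "LC", "LC", "LP", "LT", "LP", "RT", "RP", "RP"),
  value = c(6.54e-2, 4.83e-2, 4.61e-2, 4.58e-2, 4.58e-2, 4.44e-2, 4.24e-2,
            4.10e-2, 4.05e-2, 4.01e-2))
CONCUSSED_TOP10 <- data.frame(
  transmitter = c("LO", "RO", "LT", "LP", "LT", "RP", "LP", "RO", "RP", "RC"),
  receiver    = c("LC", "LP", "LP", "LO", "LO", "LP", "RO", "LC", "LC", "LC"),
  value = c(7.63e-2, 7.25e-2, 7.24e-2, 7.12e-2, 7.07e-2, 6.96e-2, 6.82e-2,
            6.69e-2, 6.35e-2, 6.10e-2))

embedTop10 <- function(tab, fill = 0.001) {
  m <- matrix(fill, 10, 10, dimnames = list(ROI_LABELS, ROI_LABELS))
  for (r in seq_len(nrow(tab)))
    m[tab$transmitter[r], tab$receiver[r]] <- tab$value[r]
  FlowMatrix(m)
}

test_that("group averaging is the pairwise-complete elementwise mean", {
  m1 <- FlowMatrix(matrix(c(NA, 0.02, 0.1, NA), 2, 2), paste0("R", 1:2))
  m2 <- FlowMatrix(matrix(c(NA, 0.04, NA, NA), 2, 2), paste0("R", 1:2))
  avg <- meanGroupMatrix(list(m1, m2))
  expect_equal(tauMatrix(avg)[2, 1], 0.03)
  expect_equal(tauMatrix(avg)[1, 2], 0.1) # masked entry excluded pairwise
  single <- meanGroupMatrix(list(m1))
  expect_equal(tauMatrix(single), abs(tauMatrix(m1)), ignore_attr = TRUE)
  expect_error(meanGroupMatrix(list()), "empty")

  set.seed(2)
  ms <- lapply(1:4, function(i) FlowMatrix(matrix(runif(25), 5, 5)))
  avg <- meanGroupMatrix(ms)
  for (idx in which(row(diag(5)) != col(diag(5)))) {
    vals <- vapply(ms, function(m) absTau(m)[idx], numeric(1))
    expect_gte(tauMatrix(avg)[idx], min(vals))
    expect_lte(tauMatrix(avg)[idx], max(vals))
  }
})

test_that("published control magnitudes leave one active connection, concussed all ten", {
  ctl <- embedTop10(CONTROL_TOP10)
  act <- activeConnections(ctl, threshold = 0.05)
  expect_identical(nrow(act), 1L)
  expect_identical(act$transmitter, "RC")
  expect_identical(act$receiver, "LC")
  conc <- embedTop10(CONCUSSED_TOP10)
  expect_identical(nrow(activeConnections(conc, 0.05)), 10L)
  zero <- FlowMatrix(matrix(0, 10, 10))
  expect_identical(nrow(activeConnections(zero)), 0L)
})

test_that("top-k ranking reproduces the published order and caps at 90 pairs", {
  ctl <- embedTop10(CONTROL_TOP10)
  top <- topConnections(ctl, 10)
  expect_identical(top$transmitter[1], "RC")
  expect_identical(top$receiver[1], "LC")
  expect_equal(top$mean_abs_tau[1], 6.54e-2)
  expect_identical(paste(top$transmitter, top$receiver),
                   paste(CONTROL_TOP10$transmitter, CONTROL_TOP10$receiver))
  conc <- embedTop10(CONCUSSED_TOP10)
  expect_identical(topConnections(conc, 1)$transmitter, "LO")
  expect_identical(topConnections(conc, 1)$receiver, "LC")
  expect_identical(nrow(topConnections(ctl, 200)), 90L)
  expect_true(all(diff(topConnections(ctl, 90)$mean_abs_tau) <= 0))
})

test_that("ranking ties break deterministically by ROI order", {
  m <- matrix(0, 3, 3, dimnames = NULL)
  m[1, 2] <- 0.5; m[2, 1] <- 0.5; m[3, 1] <- 0.5
  fm <- FlowMatrix(m, paste0("R", 1:3))
  top <- topConnections(fm, 3)
  expect_identical(top$transmitter, c("R1", "R2", "R3"))
})

test_that("pooled distributions have one value per participant and pair", {
  set.seed(3)
  mk <- function(n) lapply(seq_len(n), function(i)
    FlowMatrix(matrix(abs(rnorm(100, 0.03, 0.02)), 10, 10)))
  expect_length(poolGroupValues(mk(15))$values, 1350L)
  expect_length(poolGroupValues(mk(11))$values, 11L * 90L)
  p1 <- poolGroupValues(mk(1))
  expect_length(p1$values, 90L)
  expect_true(all(p1$values >= 0))
  expect_equal(unname(p1$stats["cov"]),
               unname(p1$stats["sd"] / p1$stats["mean"]))
  # raw vs excess kurtosis differ by exactly 3
  g2 <- mk(2)
  p_raw <- poolGroupValues(g2)
  p_exc <- poolGroupValues(g2, excess_kurtosis = TRUE)
  expect_equal(unname(p_raw$stats["kurtosis"] - p_exc$stats["kurtosis"]), 3)
})

test_that("identical distributions compare as indistinguishable", {
  set.seed(4)
  v <- abs(rnorm(500, 0.05, 0.03))
  cmp <- compareGroups(v, v)
  expect_equal(cmp$ks_stat, 0)
  expect_equal(cmp$cohens_d, 0)
  expect_true(cmp$ks_p >= 0 && cmp$ks_p <= 1)
})

test_that("Cohen's d recovers a known standardized shift", {
  set.seed(5)
  ds <- replicate(20, cohensD(rnorm(1000, 0.5), rnorm(1000)))
  expect_lt(abs(mean(ds) - 0.5), 0.1)
})

test_that("K-S p-values are approximately uniform under the iid null", {
  set.seed(6)
  ps <- replicate(400, {
    suppressWarnings(stats::ks.test(rgamma(150, 2, 40),
                                    rgamma(150, 2, 40))$p.value)
  })
  # two-sample K-S p-values are mildly discrete at n = 150, so check
  # uniformity through bin frequencies rather than a K-S-on-K-S test
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.08)
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("permutation nulls pool the expected count and are seed-stable", {
  set.seed(7)
  grp <- lapply(1:2, function(i)
    ROITimeSeries(matrix(rnorm(4 * 300), 4), roiLabels = paste0("R", 1:4),
                  dt = 0.01, participantId = paste0("P", i)))
  n1 <- permutationNull(grp, n_perm = 10, seed = 99)
  expect_length(n1$values, 2 * 4 * 3 * 10)
  expect_lte(n1$p5, n1$p95)
  n2 <- permutationNull(grp, n_perm = 10, seed = 99)
  expect_identical(n1$p95, n2$p95)
  expect_identical(n1$values, n2$values)
})

test_that("subsample features have one row per repetition and degenerate to the full-group stats", {
  set.seed(8)
  ms <- lapply(1:5, function(i)
    FlowMatrix(matrix(abs(rnorm(36, 0.04, 0.02)), 6, 6)))
  sub <- subsampleShapeFeatures(ms, k = 3, reps = 50, seed = 1)
  expect_identical(dim(sub$features), c(50L, 3L))
  full <- poolGroupValues(ms)
  deg <- subsampleShapeFeatures(ms, k = 5, reps = 4, seed = 2)
  for (r in 1:4) {
    expect_equal(unname(deg$features[r, "cov"]), unname(full$stats["cov"]),
                 tolerance = 1e-12)
    expect_equal(unname(deg$features[r, "skewness"]),
                 unname(full$stats["skewness"]), tolerance = 1e-12)
    expect_equal(unname(deg$features[r, "kurtosis"]),
                 unname(full$stats["kurtosis"]), tolerance = 1e-12)
  }
  expect_error(subsampleShapeFeatures(ms, k = 6), "exceeds group size")
})

test_that("groups with different tail weight separate in shape-feature space", {
  set.seed(9)
  light <- lapply(1:6, function(i)
    FlowMatrix(matrix(abs(rnorm(49, 0.05, 0.01)), 7, 7)))
  heavy <- lapply(1:6, function(i)
    FlowMatrix(matrix(rgamma(49, shape = 0.6, rate = 12), 7, 7)))
  fl <- subsampleShapeFeatures(light, k = 4, reps = 200, seed = 3)$features
  fh <- subsampleShapeFeatures(heavy, k = 4, reps = 200, seed = 3)$features
  centroid_gap <- sqrt(sum((colMeans(fl) - colMeans(fh))^2))
  spread <- mean(c(apply(fl, 2, sd), apply(fh, 2, sd)))
  expect_gt(centroid_gap, spread)
})
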