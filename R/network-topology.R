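#' Weighted in/out degrees of a flow network
#'
#' Node strengths of the directed \eqn{|\tau|} network: out-degree =
#' row sums (total transmitted weight), in-degree = column sums (total
#' received weight). Masked cells contribute zero, so total in-degree
#' always equals total out-degree (both equal the total edge weight).
#'
#' @param m a [FlowMatrix-class].
#' @return data.frame with columns `node`, `in_degree`, `out_degree`.
#' @export
weightedDegrees <- function(m) {
  stopifnot(methods::is(m, "FlowMatrix"))
  a <- absTau(m)
  a[is.na(a)] <- 0
  data.frame(node = roiLabels(m),
             in_degree = colSums(a),
             out_degree = rowSums(a),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted directed degree assortativity
#'
#' Weighted Pearson correlation, across directed edges, between the
#' degree of the edge's source node and the degree of its target node,
#' each edge weighted by its \eqn{|\tau|}. Degrees are the weighted
#' strengths of [weightedDegrees()]; the `variant` picks which strength
#' enters at each end (default: source out-degree vs target in-degree).
#' \eqn{r_w \in [-1, 1]}: positive when similar-degree nodes connect
#' preferentially, negative when hubs feed low-degree nodes. When the
#' endpoint degree lists have zero weighted variance the coefficient is
#' undefined and flagged.
#'
#' @param m a [FlowMatrix-class].
#' @param variant one of `"out-in"`, `"in-out"`, `"out-out"`, `"in-in"`:
#'   degree type at the source and target end respectively.
#' @return list of class `"AssortativityResult"`: `r_w` (or `NA`),
#'   `defined`, `variant`, `participant_id`, `n_edges`.
#' @export
degreeAssortativity <- function(m, variant = c("out-in", "in-out",
                                               "out-out", "in-in")) {
  variant <- match.arg(variant)
  deg <- weightedDegrees(m)
  a <- absTau(m)
  a[is.na(a)] <- 0
  ij <- which(a > 0 & row(a) != col(a), arr.ind = TRUE)
  w <- a[ij]
  ends <- strsplit(variant, "-")[[1]]
  degOf <- function(kind, idx)
    if (kind == "out") deg$out_degree[idx] else deg$in_degree[idx]
  ds <- degOf(ends[1], ij[, 1])
  dtg <- degOf(ends[2], ij[, 2])
  r_w <- if (length(w) < 2L) NA_real_ else weightedPearson(ds, dtg, w)
  structure(list(r_w = r_w, defined = is.finite(r_w), variant = variant,
                 participant_id = participantId(m), n_edges = length(w)),
            class = "AssortativityResult")
}

#' Weighted Pearson correlation
#'
#' @param x,y numeric vectors.
#' @param w non-negative weights.
#' @return Weighted correlation; `NA` when either weighted variance is
#'   zero.
#' @export
weightedPearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cxy <- sum(w * (x - mx) * (y - my)) / sw
  max(-1, min(1, cxy / sqrt(vx * vy)))
}

#' Compare assortativity between two groups
#'
#' Welch's unequal-variance two-sample t-test on per-participant
#' \eqn{r_w}, with Welch-Satterthwaite degrees of freedom, the mean
#' difference with SE and 95% CI, and Cohen's d with a
#' normal-approximation 95% CI. Undefined \eqn{r_w} values are excluded
#' with a message.
#'
#' @param a,b lists of `"AssortativityResult"` (or numeric vectors of
#'   \eqn{r_w}).
#' @return list of class `"GroupAssortativityComparison"`: `mean_a`,
#'   `mean_b`, `t_stat`, `df`, `p`, `mean_diff`, `se`, `ci` (length 2),
#'   `cohens_d`, `d_ci`, `n_excluded`.
#' @export
compareAssortativity <- function(a, b) {
  xa <- rwValues(a); xb <- rwValues(b)
  n_excl <- attr(xa, "excluded") + attr(xb, "excluded")
  if (n_excl > 0)
    message("excluded ", n_excl, " undefined r_w value(s)")
  if (!length(xa) || !length(xb)) stop("a group has no defined r_w values")
  tt <- stats::t.test(xa, xb, var.equal = FALSE)
  d <- cohensD(xa, xb)
  na <- length(xa); nb <- length(xb)
  se_d <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb)))
  structure(list(
    mean_a = mean(xa), mean_b = mean(xb),
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    mean_diff = mean(xa) - mean(xb),
    se = unname(tt$stderr),
    ci = unname(tt$conf.int),
    cohens_d = d, d_ci = c(d - 1.96 * se_d, d + 1.96 * se_d),
    n_excluded = n_excl
  ), class = "GroupAssortativityComparison")
}

rwValues <- function(g) {
  if (is.numeric(g)) {
    v <- g
  } else {
    v <- vapply(g, function(r) {
      if (inherits(r, "AssortativityResult")) r$r_w else as.numeric(r)
    }, numeric(1))
  }
  keep <- is.finite(v)
  structure(v[keep], excluded = sum(!keep))
}
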