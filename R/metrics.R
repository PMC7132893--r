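#' Embed an expression profile on the probability simplex
#'
#' Shifts the profile to be strictly positive (by `-min(x) + delta`, with
#' `delta = 1e-8 * range(x)`, or `1e-8` for a constant profile) and divides
#' by the sum. A constant profile maps to the uniform point.
#'
#' @param x finite numeric vector (log2-CPM profile of one gene over the
#'   samples of one condition).
#' @return non-negative vector summing to 1.
#' @export
to_simplex <- function(x) {
  if (any(!is.finite(x))) stop("profile must be finite")
  rng <- max(x) - min(x)
  delta <- if (rng > 0) 1e-8 * rng else 1e-8
  p <- x - min(x) + delta
  p / sum(p)
}

#' Fisher information metric on the simplex
#'
#' Geodesic distance under the Fisher-Rao geometry of the multinomial
#' simplex: `arccos` of the Bhattacharyya coefficient,
#' `d(p, q) = arccos(sum_i sqrt(p_i q_i))`, with the argument clipped to
#' `[-1, 1]`. The convention without the leading factor 2 is used, so the
#' range is `[0, pi/2]`; the factor only rescales distances and cancels in
#' [distance_to_association()].
#'
#' @param p,q simplex points of equal length (see [to_simplex()]).
#' @return distance in `[0, pi/2]`.
#' @export
fisher_distance <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  ## Bhattacharyya coefficient in Hellinger form: exact 1 (hence distance
  ## exactly 0) for p == q, no cancellation near the minimum
  bc <- 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)
  acos(min(1, max(-1, bc)))
}

## circular first difference: w[j+1] - w[j] with wraparound
.circ_diff <- function(w) w[c(seq_along(w)[-1L], 1L)] - w

#' Sobolev metric between simplex points
#'
#' With `w = p - q`, the order-k Sobolev distance combines the values of
#' `w` and its circular finite differences:
#' `d^2 = sum_{j=0}^{k} ||D^j w||^2`, where `D` is the circular first
#' difference. `k = 0` is the Euclidean norm; the default `k = 1` adds the
#' first-derivative term. The circular boundary makes the finite-difference
#' form exactly Parseval-equivalent to its discrete-Fourier evaluation.
#' Note the metric depends on coordinate order: profiles must use one fixed
#' sample order (the count-matrix order) in both conditions.
#'
#' @param p,q simplex points of equal length.
#' @param order_k non-negative integer order (default 1).
#' @return non-negative distance.
#' @export
sobolev_distance <- function(p, q, order_k = 1L) {
  if (length(p) != length(q)) stop("length mismatch")
  stopifnot(order_k >= 0, order_k == round(order_k))
  w <- p - q
  ss <- sum(w^2)
  for (j in seq_len(order_k)) {
    w <- .circ_diff(w)
    ss <- ss + sum(w^2)
  }
  sqrt(ss)
}

#' Pearson or Spearman correlation of two expression profiles
#'
#' Spearman is Pearson on mid-ranks (average ranks for ties). A
#' zero-variance profile yields a defined association of 0, with a warning.
#'
#' @param x,y numeric profiles of equal length >= 3.
#' @param which `"pearson"` or `"spearman"`.
#' @return correlation in `[-1, 1]`.
#' @export
statistical_correlation <- function(x, y, which = c("pearson", "spearman")) {
  which <- match.arg(which)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("profiles need length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance profile; correlation defined as 0")
    return(0)
  }
  stats::cor(x, y, method = which)
}

#' Map a geometric distance to an association score
#'
#' `a = 1 - d / d_max`, strictly decreasing in `d`, giving 1 at distance 0
#' and 0 at the maximal distance. For the Fisher metric `d_max = pi/2` (the
#' theoretical maximum); for the Sobolev metric `d_max` is the largest
#' distance observed across all regulator-gene pairs in both conditions of
#' the current run (recorded in the association set for reproducibility).
#'
#' @param d distance(s), each `<= d_max + 1e-9`.
#' @param d_max positive normalization constant.
#' @return association value(s) in `[0, 1]`.
#' @export
distance_to_association <- function(d, d_max = pi / 2) {
  stopifnot(d_max > 0)
  if (any(d > d_max + 1e-9)) stop("distance exceeds d_max")
  a <- 1 - d / d_max
  a[a < 0] <- 0
  a[a > 1] <- 1
  a
}

## rows of x mapped through to_simplex (genes x samples -> genes x samples)
.simplex_rows <- function(x) {
  out <- t(apply(x, 1L, to_simplex))
  dimnames(out) <- dimnames(x)
  out
}

## pairwise Fisher distances between rows of sp_a and rows of sp_b
.fisher_cross <- function(sp_a, sp_b) {
  bc <- sqrt(sp_a) %*% t(sqrt(sp_b))
  bc[bc > 1] <- 1
  bc[bc < -1] <- -1
  acos(bc)
}

## Sobolev feature map: stack w, Dw, ..., D^k w so that the Sobolev
## distance is the Euclidean distance between feature vectors
.sobolev_features <- function(sp, order_k) {
  feats <- sp
  d <- sp
  for (j in seq_len(order_k)) {
    d <- t(apply(d, 1L, .circ_diff))
    feats <- cbind(feats, d)
  }
  feats
}

.euclid_cross <- function(a, b) {
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}

## Pearson/Spearman cross-correlation with zero-variance columns mapped to 0
.stat_cross <- function(xr, xg, method) {
  bad_r <- apply(xr, 1L, stats::sd) == 0
  bad_g <- apply(xg, 1L, stats::sd) == 0
  if (any(bad_r) || any(bad_g))
    warning("zero-variance profile(s); associations defined as 0")
  r <- suppressWarnings(stats::cor(t(xr), t(xg), method = method))
  r[bad_r, ] <- 0
  r[, bad_g] <- 0
  r[is.na(r)] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Condition-wise regulator x DE-gene association matrices
#'
#' Fills `r1` (condition-1 samples) and `r2` (condition-2 samples) pairwise
#' for every regulator in the catalog present in the expression matrix and
#' every DE gene. Statistical metrics use sample correlation of log2-CPM
#' profiles; geometric metrics route each profile through [to_simplex()],
#' compute pairwise distances, and map them to `[0, 1]` associations with a
#' single `d_max` shared across both conditions. Regulators that are
#' themselves DE stay on the regulator axis.
#'
#' @param nm a `normalized_matrix` from [log_cpm()].
#' @param de a `de_result` from [select_de()] (must contain >= 1 DE gene).
#' @param cat a [regulator_catalog()]; regulators absent from the matrix
#'   are dropped with a warning.
#' @param metric one of `"pearson"`, `"spearman"`, `"fisher"`, `"sobolev"`.
#' @param sobolev_order Sobolev derivative order (default 1).
#' @param signed_geometric multiply geometric associations by the sign of
#'   the pairwise Pearson correlation (default FALSE: unsigned, in
#'   `[0, 1]`).
#' @return object of class `association_set`: list with `metric`, `r1`,
#'   `r2` (regulators x DE genes), `d_max`, `regulators`, `de_genes`.
#' @export
association_matrices <- function(nm, de, cat,
                                 metric = c("pearson", "spearman", "fisher", "sobolev"),
                                 sobolev_order = 1L, signed_geometric = FALSE) {
  metric <- match.arg(metric)
  de_genes <- de$gene[de$is_de]
  if (!length(de_genes)) stop("empty DE set")
  regs <- names(cat$classes_of)
  present <- regs %in% rownames(nm$log_expr)
  if (any(!present))
    warning(sum(!present), " regulator(s) absent from the expression matrix, dropped")
  regs <- regs[present]
  if (!length(regs)) stop("no regulators present in the expression matrix")

  in1 <- nm$condition == nm$condition_levels[1L]
  x1 <- nm$log_expr[, in1, drop = FALSE]
  x2 <- nm$log_expr[, !in1, drop = FALSE]
  d_max <- NA_real_

  if (metric %in% c("pearson", "spearman")) {
    r1 <- .stat_cross(x1[regs, , drop = FALSE], x1[de_genes, , drop = FALSE], metric)
    r2 <- .stat_cross(x2[regs, , drop = FALSE], x2[de_genes, , drop = FALSE], metric)
  } else {
    ids <- unique(c(regs, de_genes))
    s1 <- .simplex_rows(x1[ids, , drop = FALSE])
    s2 <- .simplex_rows(x2[ids, , drop = FALSE])
    if (metric == "fisher") {
      d1 <- .fisher_cross(s1[regs, , drop = FALSE], s1[de_genes, , drop = FALSE])
      d2 <- .fisher_cross(s2[regs, , drop = FALSE], s2[de_genes, , drop = FALSE])
      d_max <- pi / 2
    } else {
      f1r <- .sobolev_features(s1[regs, , drop = FALSE], sobolev_order)
      f1g <- .sobolev_features(s1[de_genes, , drop = FALSE], sobolev_order)
      f2r <- .sobolev_features(s2[regs, , drop = FALSE], sobolev_order)
      f2g <- .sobolev_features(s2[de_genes, , drop = FALSE], sobolev_order)
      d1 <- .euclid_cross(f1r, f1g)
      d2 <- .euclid_cross(f2r, f2g)
      d_max <- max(d1, d2, .Machine$double.eps)
    }
    r1 <- distance_to_association(d1, d_max)
    r2 <- distance_to_association(d2, d_max)
    if (signed_geometric) {
      r1 <- r1 * sign(.stat_cross(x1[regs, , drop = FALSE],
                                  x1[de_genes, , drop = FALSE], "pearson"))
      r2 <- r2 * sign(.stat_cross(x2[regs, , drop = FALSE],
                                  x2[de_genes, , drop = FALSE], "pearson"))
    }
  }
  dimnames(r1) <- dimnames(r2) <- list(regs, de_genes)
  structure(list(metric = metric, r1 = r1, r2 = r2, d_max = d_max,
                 sobolev_order = sobolev_order,
                 regulators = regs, de_genes = de_genes),
            class = "association_set")
}
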