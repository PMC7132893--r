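#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`:
#' the correlation between x and y after removing the linear effect of z.
#' Vectorized over its arguments.
#'
#' @param r_xy,r_xz,r_yz pairwise correlations with `|r_xz| < 1`,
#'   `|r_yz| < 1`.
#' @return partial correlation(s).
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  den2 <- (1 - r_xz^2) * (1 - r_yz^2)
  if (any(den2 < 1e-12)) stop("degenerate conditioning")
  (r_xy - r_xz * r_yz) / sqrt(den2)
}

#' PCIT edge filter on a correlation matrix
#'
#' Partial Correlation and Information Theory filtering: for every pair
#' (x, y) and every third node z, the three first-order partial
#' correlations of the trio are computed, and a trio-specific tolerance
#' `eps_z` is taken as the mean of the absolute ratios
#' `|partial / direct|` over the trio's pairs (terms with
#' `|direct| < 1e-12` are skipped). The edge (x, y) is eliminated if some z
#' satisfies both `|r_xy| <= eps_z * |r_xz|` and `|r_xy| <= eps_z * |r_yz|`
#' — i.e. z explains the x-y correlation; otherwise it survives. Trios with
#' degenerate conditioning (a squared correlation within 1e-12 of 1) are
#' skipped as eliminators.
#'
#' @param corr symmetric correlation matrix with unit diagonal, >= 3 nodes.
#' @return logical matrix `survived`, symmetric with FALSE diagonal.
#' @export
pcit_filter <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) stop("square matrix required")
  n <- nrow(corr)
  if (n < 3L) stop("PCIT needs >= 3 nodes")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("diagonal must be 1")

  A <- corr
  sA2 <- 1 - A^2
  elim <- matrix(FALSE, n, n)
  for (z in seq_len(n)) {
    rz <- A[, z]
    sz2 <- 1 - rz^2
    ok_z <- sz2 >= 1e-12                  # conditioning on z defined for this node
    X <- matrix(rz, n, n)                 # X[x, y] = r_xz
    Y <- t(X)                             # Y[x, y] = r_yz
    p_xy <- (A - X * Y) / sqrt(outer(sz2, sz2))
    p_xz <- (X - A * Y) / sqrt(sA2 * (1 - Y^2))
    p_yz <- (Y - A * X) / sqrt(sA2 * (1 - X^2))

    t1 <- abs(p_xy / A); t1[abs(A) < 1e-12] <- NA
    t2 <- abs(p_xz / X); t2[abs(X) < 1e-12] <- NA
    t3 <- abs(p_yz / Y); t3[abs(Y) < 1e-12] <- NA
    terms <- (!is.na(t1)) + (!is.na(t2)) + (!is.na(t3))
    t1[is.na(t1)] <- 0; t2[is.na(t2)] <- 0; t3[is.na(t3)] <- 0
    eps <- (t1 + t2 + t3) / terms         # NaN where no usable term

    cond <- (abs(A) <= eps * abs(X)) & (abs(A) <= eps * abs(Y))
    cond[!is.finite(eps)] <- FALSE
    cond[!ok_z, ] <- FALSE; cond[, !ok_z] <- FALSE  # |r_xz| or |r_yz| ~ 1
    cond[sA2 < 1e-12] <- FALSE            # |r_xy| ~ 1: trio partials undefined
    cond[z, ] <- FALSE; cond[, z] <- FALSE
    diag(cond) <- FALSE
    cond[is.na(cond)] <- FALSE
    elim <- elim | cond
  }
  survived <- !elim
  diag(survived) <- FALSE
  dimnames(survived) <- dimnames(corr)
  survived
}

## minimum |first-order partial| over all conditioning nodes, per pair
.min_abs_partial <- function(corr) {
  n <- nrow(corr)
  out <- matrix(Inf, n, n)
  for (z in seq_len(n)) {
    rz <- corr[, z]
    sz2 <- 1 - rz^2
    if (any(sz2 < 1e-12)) next
    p <- abs((corr - outer(rz, rz)) / sqrt(outer(sz2, sz2)))
    p[z, ] <- Inf; p[, z] <- Inf
    out <- pmin(out, p)
  }
  diag(out) <- Inf
  out
}

#' Build the significant-regulator interaction network
#'
#' Direct correlations between the selected regulators are pooled-sample
#' Pearson correlations of log2-CPM over both conditions (the scale PCIT is
#' defined on, regardless of the RIF association metric). The PCIT filter
#' is applied, and edges are retained when they (a) survive PCIT and (b)
#' have `|direct r| >= edge_threshold`. Isolated nodes stay in the node
#' table. With fewer than 3 selected regulators the PCIT stage is skipped
#' with a warning and only the threshold applies.
#'
#' @param table a `rif_table` for one metric (its `selected` column defines
#'   the node set).
#' @param nm a `normalized_matrix` from [log_cpm()].
#' @param edge_threshold minimum |direct correlation| (default 0.90).
#' @param min_partial optional stricter rule: additionally require the
#'   minimum |partial correlation| over all conditioning nodes to be at
#'   least this value.
#' @return a [regulator_network()].
#' @export
build_network <- function(table, nm, edge_threshold = 0.90, min_partial = NULL) {
  metric <- unique(table$metric)
  if (length(metric) != 1L) stop("one metric per network")
  sel <- table$regulator[table$selected]
  sel <- sel[sel %in% rownames(nm$log_expr)]
  sel <- sort(unique(sel))
  classes <- stats::setNames(table$classes, table$regulator)
  nodes <- data.frame(node = sel, classes = unname(classes[sel]),
                      metrics_found_by = metric, stringsAsFactors = FALSE)
  empty_edges <- data.frame(node_a = character(0), node_b = character(0),
                            direct_correlation = numeric(0), metric = character(0),
                            stringsAsFactors = FALSE)
  if (length(sel) < 2L)
    return(regulator_network(nodes, empty_edges))
  C <- stats::cor(t(nm$log_expr[sel, , drop = FALSE]))
  if (length(sel) < 3L) {
    warning("fewer than 3 selected regulators; PCIT stage skipped")
    survived <- matrix(TRUE, length(sel), length(sel), dimnames = dimnames(C))
    diag(survived) <- FALSE
  } else {
    survived <- pcit_filter(C)
  }
  keep <- survived & abs(C) >= edge_threshold
  if (!is.null(min_partial) && length(sel) >= 3L)
    keep <- keep & .min_abs_partial(C) >= min_partial
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- if (nrow(idx)) data.frame(node_a = sel[idx[, 1L]],
                                     node_b = sel[idx[, 2L]],
                                     direct_correlation = C[idx],
                                     metric = metric,
                                     stringsAsFactors = FALSE) else empty_edges
  regulator_network(nodes, edges)
}
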