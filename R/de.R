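#' Trimmed-mean-of-M-values normalization factors
#'
#' Scaling factors for sequencing-depth/composition normalization. For each
#' sample, a weighted mean of the log2 expression ratios (M-values) against
#' a reference sample is taken after trimming 30% of M-values and 5% of
#' A-values from each tail; weights are the inverse asymptotic (delta
#' method) variance of M. Factors are rescaled to geometric mean 1. The
#' reference defaults to the sample whose 75th count percentile (on the
#' depth-normalized scale) is closest to the across-sample mean.
#'
#' @param m a [count_matrix()].
#' @param ref_sample optional sample ID to use as the reference.
#' @param logratio_trim fraction of M-values trimmed from each tail (0.30).
#' @param abs_expr_trim fraction of A-values trimmed from each tail (0.05).
#' @return named vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(m, ref_sample = NULL,
                        logratio_trim = 0.30, abs_expr_trim = 0.05) {
  counts <- m$counts
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(ref_sample)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample: ", ref_sample)
  }
  f <- vapply(seq_len(ncol(counts)), function(s)
    .tmm_pair(counts[, s], counts[, ref], lib[s], lib[ref],
              logratio_trim, abs_expr_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, lr_trim, ae_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * lr_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * ae_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Log2 counts-per-million on effective library sizes
#'
#' `log_expr[g, s] = log2((count + pseudocount) / (lib_size * factor) * 1e6)`.
#' This is the expression scale used by every downstream stage (condition
#' means feeding PIF/RIF, co-expression profiles for all four metrics).
#'
#' @param m a [count_matrix()].
#' @param factors per-sample normalization factors, e.g. from
#'   [tmm_factors()].
#' @param pseudocount positive offset avoiding log of zero (default 0.5).
#' @return object of class `normalized_matrix`: list with `log_expr`,
#'   `norm_factors`, `lib_sizes`, plus the sample condition labels carried
#'   over from `m`.
#' @export
log_cpm <- function(m, factors = tmm_factors(m), pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  factors <- factors[colnames(m$counts)]
  if (any(is.na(factors) | factors <= 0)) stop("factors must be positive, one per sample")
  lib <- colSums(m$counts)
  eff <- lib * factors
  le <- log2(sweep(m$counts + pseudocount, 2, eff, "/") * 1e6)
  structure(list(log_expr = le, norm_factors = factors, lib_sizes = lib,
                 condition = m$condition, condition_levels = m$condition_levels),
            class = "normalized_matrix")
}

## rescale counts to a common effective library (geometric mean), rounding
## half to even, so the conditional NB arguments are exchangeable
.equalize_counts <- function(counts, eff_lib) {
  target <- exp(mean(log(eff_lib)))
  round(sweep(counts, 2, target / eff_lib, "*"))
}

## NB conditional log-likelihood of a sample group given its total, summed
## over genes: log P(y_1..y_n | sum) for iid NB(size = 1/alpha); the mean
## parameter cancels, leaving a function of alpha alone.
.cond_loglik <- function(alpha, y, grp, levels) {
  r <- 1 / alpha
  total <- 0
  for (lev in levels) {
    yk <- y[, grp == lev, drop = FALSE]
    nk <- ncol(yk)
    z <- rowSums(yk)
    total <- total + sum(lgamma(yk + r)) - nrow(yk) * nk * lgamma(r) -
      sum(lgamma(z + nk * r)) + nrow(yk) * lgamma(nk * r)
  }
  total
}

#' Estimate the negative-binomial dispersion
#'
#' Assumes the mean-variance law `v = mu + alpha * mu^2`. The common
#' dispersion maximizes the conditional NB log-likelihood (given per-group
#' totals, which removes the mean parameter) summed over genes, on counts
#' rescaled to a common effective library size; the maximization is 1-D on
#' `alpha` in `[1e-6, 10]` with tolerance 1e-6. Tagwise values shrink the
#' per-gene conditional-ML estimates toward the common value with a fixed
#' prior weight: `alpha_g = (w * alpha_common + n_g * alpha_hat_g) / (w + n_g)`
#' where `n_g` is the number of samples.
#'
#' @param m a [count_matrix()] (each condition must have >= 2 samples).
#' @param factors per-sample normalization factors.
#' @param prior_weight shrinkage weight `w` in pseudo-samples (default 10).
#' @param tagwise compute per-gene estimates as well (default TRUE; with
#'   FALSE, `alpha_tagwise` is the common value for every gene).
#' @return object of class `dispersion_estimate`: list with `alpha_common`,
#'   `alpha_tagwise` (named per gene), `prior_weight`.
#' @export
estimate_common_dispersion <- function(m, factors, prior_weight = 10,
                                       tagwise = TRUE) {
  grp <- m$condition
  levels <- m$condition_levels
  if (min(table(grp)) < 2L) stop("each condition needs >= 2 samples")
  y <- .equalize_counts(m$counts, colSums(m$counts) * factors[colnames(m$counts)])
  alpha_common <- stats::optimize(.cond_loglik, c(1e-6, 10), maximum = TRUE,
                                  tol = 1e-6, y = y, grp = grp,
                                  levels = levels)$maximum
  n_s <- ncol(y)
  if (tagwise) {
    alpha_ml <- vapply(seq_len(nrow(y)), function(g) {
      yg <- y[g, , drop = FALSE]
      if (sum(yg) == 0) return(alpha_common)
      stats::optimize(.cond_loglik, c(1e-6, 10), maximum = TRUE, tol = 1e-4,
                      y = yg, grp = grp, levels = levels)$maximum
    }, numeric(1))
    alpha_tag <- (prior_weight * alpha_common + n_s * alpha_ml) / (prior_weight + n_s)
  } else {
    alpha_tag <- rep(alpha_common, nrow(y))
  }
  structure(list(alpha_common = alpha_common,
                 alpha_tagwise = stats::setNames(alpha_tag, rownames(y)),
                 prior_weight = prior_weight),
            class = "dispersion_estimate")
}

## two-sided conditional exact p for one gene: distribution of the group-1
## total given the grand total, sums of NB samples treated as NB with
## dispersion alpha/n_k; outcomes at most as probable as the observed split
## are accumulated.
.exact_p <- function(s1, s2, n1, n2, alpha) {
  s <- s1 + s2
  if (s == 0) return(1)
  k <- 0:s
  if (alpha < 1e-10) {
    lp <- stats::dbinom(k, s, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- s / (n1 + n2)
    lp <- stats::dnbinom(k, size = n1 / alpha, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(s - k, size = n2 / alpha, mu = n2 * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[s1 + 1] * (1 + 1e-10)]))
}

#' Simplified negative-binomial exact test
#'
#' Per gene, counts are rescaled to a common effective library size
#' (rounded half to even), and the two-sided conditional probability of the
#' observed split of the grand total between the two conditions is computed
#' under equal means, with the total over `n_k` samples modelled as NB with
#' dispersion `alpha_g / n_k`. With `alpha = 0` this reduces to the exact
#' binomial conditional of two Poisson totals. Genes with zero total count
#' get p = 1.
#'
#' @param m a [count_matrix()].
#' @param factors per-sample normalization factors.
#' @param disp a [estimate_common_dispersion()] result.
#' @param dispersion use the per-gene shrunken dispersions (`"tagwise"`,
#'   default) or the single common value (`"common"`).
#' @return named per-gene p-value vector in `[0, 1]`.
#' @export
nb_exact_test <- function(m, factors, disp,
                          dispersion = c("tagwise", "common")) {
  dispersion <- match.arg(dispersion)
  grp <- m$condition
  l1 <- m$condition_levels[1L]
  y <- .equalize_counts(m$counts, colSums(m$counts) * factors[colnames(m$counts)])
  in1 <- grp == l1
  n1 <- sum(in1); n2 <- sum(!in1)
  s1 <- rowSums(y[, in1, drop = FALSE])
  s2 <- rowSums(y[, !in1, drop = FALSE])
  alpha <- if (dispersion == "common") rep(disp$alpha_common, nrow(y))
           else disp$alpha_tagwise[rownames(y)]
  pv <- vapply(seq_len(nrow(y)), function(g)
    .exact_p(s1[g], s2[g], n1, n2, alpha[g]), numeric(1))
  stats::setNames(pv, rownames(y))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues numeric vector in `[0, 1]` (values outside error out).
#' @return adjusted values, monotone and capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Assemble the differential-expression result table
#'
#' Per-condition mean log2-CPM (`e1`, `e2`), `logFC = e1 - e2`, the exact
#' test p-value, its BH adjustment, and the DE call `fdr < fdr_cutoff`
#' (strict: a gene sitting exactly at the cutoff is not DE). Regulator
#' genes receive no special treatment and may themselves be DE.
#'
#' @param m a [count_matrix()].
#' @param factors per-sample normalization factors.
#' @param pvals per-gene p-values from [nb_exact_test()].
#' @param fdr_cutoff FDR threshold in (0, 1), default 0.05.
#' @param pseudocount log-CPM pseudocount (default 0.5).
#' @return a `de_result` data frame with columns gene, e1, e2, logFC,
#'   pvalue, fdr, is_de.
#' @export
select_de <- function(m, factors, pvals, fdr_cutoff = 0.05, pseudocount = 0.5) {
  stopifnot(fdr_cutoff > 0, fdr_cutoff < 1)
  nm <- log_cpm(m, factors, pseudocount)
  in1 <- nm$condition == nm$condition_levels[1L]
  e1 <- rowMeans(nm$log_expr[, in1, drop = FALSE])
  e2 <- rowMeans(nm$log_expr[, !in1, drop = FALSE])
  pvals <- pvals[rownames(m$counts)]
  fdr <- bh_adjust(pvals)
  out <- data.frame(gene = rownames(m$counts), e1 = e1, e2 = e2,
                    logFC = e1 - e2, pvalue = unname(pvals),
                    fdr = unname(fdr), is_de = unname(fdr < fdr_cutoff),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Drop genes with zero counts in every sample
#'
#' Applied before all downstream stages; the number of dropped genes is
#' reported via `message()`.
#'
#' @param m a [count_matrix()].
#' @return a [count_matrix()] without all-zero genes.
#' @export
drop_zero_genes <- function(m) {
  keep <- rowSums(m$counts) > 0
  if (!all(keep)) {
    message(sum(!keep), " gene(s) with all-zero counts dropped")
    m <- count_matrix(m$counts[keep, , drop = FALSE], m$condition,
                      pair = m$pair, condition_levels = m$condition_levels)
  }
  m
}
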