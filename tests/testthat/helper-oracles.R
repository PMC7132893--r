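# Independent brute-force oracles and fixture builders shared across tests.
# Every oracle is written directly from the defining formula, independently
# of the package code paths it checks.

random_count_matrix <- function(seed, n_genes = 30, n_per_cond = 4,
                                mu = 100, alpha = 0.2) {
  set.seed(seed)
  n <- 2 * n_per_cond
  counts <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / alpha), n_genes, n)
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(n)))
  cond <- setNames(rep(c("A", "B"), each = n_per_cond), colnames(counts))
  count_matrix(counts, cond)
}

random_simplex <- function(n) {
  x <- rexp(n)
  x / sum(x)
}

# BH step-up from the definition: sort, multiply by n/i, enforce
# monotonicity from the largest p downwards, cap at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in rev(seq_len(n - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# textbook Pearson correlation
pearson_oracle <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# TMM factor for one sample against a reference, applying the trim/weight
# definition directly with sort-based (not rank-based) trimming
tmm_pair_oracle <- function(obs, ref, lr_trim = 0.30, ae_trim = 0.05) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  # mid-rank of each value computed from first principles (ties share the
  # average of the positions they occupy)
  midrank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rM <- midrank(M); rA <- midrank(A)
  lo_M <- floor(n * lr_trim) + 1; hi_M <- n + 1 - lo_M
  lo_A <- floor(n * ae_trim) + 1; hi_A <- n + 1 - lo_A
  keep <- rM >= lo_M & rM <= hi_M & rA >= lo_A & rA <= hi_A
  2^(sum(M[keep] * w[keep]) / sum(w[keep]))
}

# exact conditional two-sided p in the Poisson limit by direct binomial
# enumeration
binom_exact_oracle <- function(s1, s2, n1, n2) {
  s <- s1 + s2
  if (s == 0) return(1)
  pr <- dbinom(0:s, s, n1 / (n1 + n2))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[s1 + 1] * (1 + 1e-10)]))
}

# RIF1/RIF2 by explicit double loops
rif1_oracle <- function(pif, dw) {
  out <- numeric(nrow(dw))
  for (j in seq_len(nrow(dw))) {
    acc <- 0
    for (i in seq_len(ncol(dw))) acc <- acc + pif[i] * dw[j, i]^2
    out[j] <- acc / ncol(dw)
  }
  out
}

rif2_oracle <- function(e1, e2, r1, r2) {
  out <- numeric(nrow(r1))
  for (j in seq_len(nrow(r1))) {
    acc <- 0
    for (i in seq_len(ncol(r1)))
      acc <- acc + (e1[i] * r1[j, i])^2 - (e2[i] * r2[j, i])^2
    out[j] <- acc / ncol(r1)
  }
  out
}

# partial correlation via inversion of the 3x3 correlation matrix:
# r_xy.z = -P_xy / sqrt(P_xx P_yy) with P the precision matrix
partial_corr_precision_oracle <- function(r_xy, r_xz, r_yz) {
  C <- matrix(c(1, r_xy, r_xz,
                r_xy, 1, r_yz,
                r_xz, r_yz, 1), 3, 3)
  P <- solve(C)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# PCIT elimination by scalar triple loops, straight from the definition
pcit_oracle <- function(corr) {
  n <- nrow(corr)
  pc <- function(rxy, rxz, ryz) (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  elim <- matrix(FALSE, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) for (z in seq_len(n)) {
    if (x == y || x == z || y == z) next
    rxy <- corr[x, y]; rxz <- corr[x, z]; ryz <- corr[y, z]
    if ((1 - rxz^2) < 1e-12 || (1 - ryz^2) < 1e-12 || (1 - rxy^2) < 1e-12) next
    p_xy <- pc(rxy, rxz, ryz)
    p_xz <- pc(rxz, rxy, ryz)
    p_yz <- pc(ryz, rxy, rxz)
    ratios <- c()
    if (abs(rxy) >= 1e-12) ratios <- c(ratios, abs(p_xy / rxy))
    if (abs(rxz) >= 1e-12) ratios <- c(ratios, abs(p_xz / rxz))
    if (abs(ryz) >= 1e-12) ratios <- c(ratios, abs(p_yz / ryz))
    if (!length(ratios)) next
    eps <- mean(ratios)
    if (abs(rxy) <= eps * abs(rxz) && abs(rxy) <= eps * abs(ryz))
      elim[x, y] <- TRUE
  }
  surv <- !elim
  diag(surv) <- FALSE
  surv
}

# a random positive-definite correlation matrix from random data
random_corr <- function(seed, n_nodes = 8, n_obs = 15) {
  set.seed(seed)
  cor(matrix(rnorm(n_obs * n_nodes), n_obs, n_nodes))
}

# Sobolev distance (order 1) via the discrete Fourier transform:
# d^2 = (1/n) * sum_t (1 + |1 - e^{2 pi i t / n}|^2) |what_t|^2
sobolev_spectral_oracle <- function(p, q) {
  w <- p - q
  n <- length(w)
  wh <- fft(w)
  lam <- abs(1 - exp(2i * pi * (seq_len(n) - 1) / n))^2
  sqrt(sum((1 + lam) * Mod(wh)^2) / n)
}
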