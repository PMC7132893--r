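test_that("TMM factors match the trim/weight definition and edgeR", {
  # identical columns: all factors exactly 1
  counts <- matrix(rep(c(10L, 50L, 200L, 1000L), 4), 4, 4,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  m <- count_matrix(counts, setNames(c("A", "A", "B", "B"), paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(m)), rep(1, 4))

  # doubling a column changes only the library size, not the ratios
  m2 <- random_count_matrix(7, n_genes = 200, n_per_cond = 2)
  doubled <- m2$counts
  doubled[, 2] <- 2 * doubled[, 1]
  md <- count_matrix(doubled, m2$condition)
  f <- tmm_factors(md, ref_sample = "s01")
  expect_equal(f[["s01"]], f[["s02"]], tolerance = 1e-12)

  # random fixtures vs the sort-based oracle applied per sample
  for (seed in 1:10) {
    mr <- random_count_matrix(seed, n_genes = 300, n_per_cond = 3)
    f <- tmm_factors(mr, ref_sample = "s01")
    raw <- vapply(seq_len(ncol(mr$counts)), function(s)
      tmm_pair_oracle(mr$counts[, s], mr$counts[, 1]), numeric(1))
    expect_equal(unname(f), raw / exp(mean(log(raw))), tolerance = 1e-9)
  }

  # cross-check against edgeR's TMM on the same reference column
  library(edgeR)
  for (seed in 1:5) {
    mr <- random_count_matrix(seed, n_genes = 400, n_per_cond = 4)
    f_pkg <- tmm_factors(mr, ref_sample = "s03")
    f_edger <- edgeR::calcNormFactors(mr$counts, method = "TMM", refColumn = 3)
    expect_equal(unname(f_pkg), unname(f_edger), tolerance = 1e-9)
  }

  zero <- matrix(c(1L, 2L, 0L, 0L, 3L, 4L, 5L, 6L), 2, 4,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  mz <- count_matrix(zero, setNames(c("A", "A", "B", "B"), paste0("s", 1:4)))
  expect_error(tmm_factors(mz), "all-zero")
})

test_that("log-CPM follows the stated formula and is monotone in counts", {
  counts <- matrix(c(0L, 1000000L, 500L, 999500L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  # library sizes hit 1e6 exactly; with unit factors the zero-count entry
  # evaluates to log2(pseudocount)
  cond <- setNames(c("A", "B"), c("s1", "s2"))
  expect_error(count_matrix(counts, cond), "at least 2")  # 1-per-condition guard
  counts4 <- cbind(counts, counts)
  colnames(counts4) <- paste0("s", 1:4)
  m <- count_matrix(counts4, setNames(c("A", "B", "A", "B"), paste0("s", 1:4)))
  nm <- log_cpm(m, factors = setNames(rep(1, 4), paste0("s", 1:4)), pseudocount = 0.5)
  expect_equal(nm$log_expr["g1", "s1"], log2(0.5), tolerance = 1e-12)

  # doubling counts and libraries with a scaled pseudocount is exact
  mr <- random_count_matrix(3, n_genes = 50)
  f1 <- setNames(rep(1, ncol(mr$counts)), colnames(mr$counts))
  m2 <- count_matrix(2L * mr$counts, mr$condition)
  a <- log_cpm(mr, f1, pseudocount = 0.5)$log_expr
  b <- log_cpm(m2, f1, pseudocount = 1.0)$log_expr
  expect_equal(a, b, tolerance = 1e-12)

  # monotone within a sample
  x <- mr$counts[, 1]
  le <- log_cpm(mr, f1)$log_expr[, 1]
  expect_true(all(diff(le[order(x)]) >= 0))

  # TMM factors feeding log_cpm have geometric mean 1
  f <- tmm_factors(mr)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("dispersion estimation recovers Poisson and shrinkage limits", {
  p0 <- synth_params(n_genes = 2000, n_per_condition = 5, dispersion = 0)
  m <- generate_null(p0, seed = 11)
  f <- tmm_factors(m)
  d <- estimate_common_dispersion(m, f, tagwise = FALSE)
  expect_lt(d$alpha_common, 0.05)

  # prior weight -> Inf collapses tagwise estimates onto the common value
  p <- synth_params(n_genes = 100, n_per_condition = 4, dispersion = 0.3)
  m <- generate_null(p, seed = 5)
  f <- tmm_factors(m)
  d_inf <- estimate_common_dispersion(m, f, prior_weight = 1e12)
  expect_equal(unname(d_inf$alpha_tagwise),
               rep(d_inf$alpha_common, 100), tolerance = 1e-6)
})

test_that("exact test matches binomial enumeration in the Poisson limit", {
  # modal split with equal group sizes: p = 1
  expect_equal(georif:::.exact_p(10, 10, 4, 4, 0.2), 1)
  expect_equal(georif:::.exact_p(0, 0, 4, 4, 0.2), 1)

  set.seed(9)
  for (rep in 1:200) {
    s <- sample(0:30, 1)
    s1 <- if (s > 0) sample(0:s, 1) else 0
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    expect_equal(georif:::.exact_p(s1, s - s1, n1, n2, 0),
                 binom_exact_oracle(s1, s - s1, n1, n2), tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the step-up oracle and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(31)
  for (rep in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DE call respects the strict cutoff and label-swap symmetry", {
  m <- generate_null(synth_params(n_genes = 200, n_per_condition = 5,
                                  dispersion = 0.2), seed = 21)
  m <- suppressMessages(drop_zero_genes(m))
  f <- tmm_factors(m)
  disp <- estimate_common_dispersion(m, f, tagwise = FALSE)
  pv <- nb_exact_test(m, f, disp, dispersion = "common")
  de <- select_de(m, f, pv, fdr_cutoff = 0.05)
  expect_true(all(de$fdr >= de$pvalue - 1e-12))
  expect_identical(de$is_de, de$fdr < 0.05)
  # a gene exactly at the cutoff is not DE (strict <)
  pv_fixed <- setNames(seq(0.0001, 0.9, length.out = nrow(m$counts)),
                       rownames(m$counts))
  de_at <- select_de(m, f, pv_fixed,
                     fdr_cutoff = min(bh_adjust(pv_fixed)))
  expect_false(de_at$is_de[which.min(de_at$fdr)])

  # swapping condition labels preserves p-values and negates logFC
  m_sw <- count_matrix(m$counts, m$condition, pair = m$pair,
                       condition_levels = rev(m$condition_levels))
  pv_sw <- nb_exact_test(m_sw, f, disp, dispersion = "common")
  expect_equal(pv_sw, pv, tolerance = 1e-12)
  de_sw <- select_de(m_sw, f, pv_sw)
  expect_equal(de_sw$logFC, -de$logFC, tolerance = 1e-12)
})
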