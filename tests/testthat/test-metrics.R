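test_that("simplex embedding normalizes and handles constants", {
  expect_equal(to_simplex(c(1, 1, 1)), rep(1 / 3, 3), tolerance = 1e-9)
  p <- to_simplex(c(0, 1))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_lt(p[1], 1e-7)
  set.seed(2)
  for (rep in 1:1000) {
    p <- to_simplex(rnorm(sample(3:30, 1), sd = 10))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("Fisher and Sobolev spot values match hand evaluation", {
  expect_equal(fisher_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(fisher_distance(c(1, 0), c(0, 1)), pi / 2, tolerance = 1e-12)
  expect_equal(fisher_distance(c(0.5, 0.5), c(0.9, 0.1)),
               acos(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)
  expect_equal(acos(sqrt(0.45) + sqrt(0.05)), 0.4636, tolerance = 2e-4)

  expect_equal(sobolev_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  # w = (-0.4, 0.4); ||w||^2 = 0.32; circular diffs (0.8, -0.8) add 1.28
  expect_equal(sobolev_distance(c(0.5, 0.5), c(0.9, 0.1), order_k = 1),
               sqrt(1.6), tolerance = 1e-12)
  expect_equal(sqrt(1.6), 1.2649, tolerance = 1e-4)

  expect_error(fisher_distance(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(sobolev_distance(c(0.5, 0.5), c(1, 0, 0)), "length")
})

test_that("metric axioms hold on random simplex pairs and triples", {
  set.seed(11)
  for (rep in 1:1000) {
    n <- sample(3:20, 1)
    p <- random_simplex(n); q <- random_simplex(n); r <- random_simplex(n)
    for (dist_fn in list(fisher_distance, sobolev_distance)) {
      dpq <- dist_fn(p, q)
      expect_gte(dpq, 0)
      expect_equal(dist_fn(p, p), 0, tolerance = 1e-9)
      expect_equal(dist_fn(q, p), dpq, tolerance = 1e-12)
      expect_lte(dpq, dist_fn(p, r) + dist_fn(r, q) + 1e-9)
    }
    expect_lte(fisher_distance(p, q), pi / 2)
  }
})

test_that("order-0 Sobolev is Euclidean; order-1 matches the spectral form", {
  set.seed(4)
  for (rep in 1:1000) {
    n <- sample(3:16, 1)
    p <- random_simplex(n); q <- random_simplex(n)
    expect_equal(sobolev_distance(p, q, order_k = 0),
                 sqrt(sum((p - q)^2)), tolerance = 1e-12)
  }
  for (n in c(4, 8, 16, 64)) {
    for (rep in 1:25) {
      p <- random_simplex(n); q <- random_simplex(n)
      expect_equal(sobolev_distance(p, q, order_k = 1),
                   sobolev_spectral_oracle(p, q), tolerance = 1e-10)
    }
  }
})

test_that("statistical correlations behave and degenerate inputs warn", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(statistical_correlation(x, x, "pearson"), 1)
  expect_equal(statistical_correlation(x, -x, "pearson"), -1)
  expect_equal(statistical_correlation(c(1, 2, 3), c(2, 4, 7), "spearman"), 1)
  expect_warning(z <- statistical_correlation(c(1, 1, 1), x[1:3], "pearson"),
                 "zero-variance")
  expect_equal(z, 0)
  expect_error(statistical_correlation(1:3, 1:4), "length")
  set.seed(6)
  for (rep in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(statistical_correlation(x, y, "pearson"),
                 pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("distance-to-association maps [0, d_max] onto [1, 0] decreasingly", {
  expect_equal(distance_to_association(0, d_max = 2), 1)
  expect_equal(distance_to_association(2, d_max = 2), 0)
  expect_equal(distance_to_association(0.4636, d_max = pi / 2), 0.7048,
               tolerance = 1e-4)
  d <- seq(0, 1.5, length.out = 50)
  a <- distance_to_association(d, d_max = 1.5)
  expect_true(all(diff(a) < 0))
  expect_error(distance_to_association(2.1, d_max = 2), "exceeds")
})

test_that("association matrices have the right shape, range and content", {
  p <- synth_params(n_genes = 60, n_per_condition = 6, dispersion = 0.1,
                    n_tf = 5, n_ef = 0, n_tf_ef_overlap = 0, n_lncrna = 0)
  truth <- synthetic_truth(p, seed = 8, n_de = 10, n_targets = 3)
  fx <- generate_wired(p, truth)
  m <- fx$matrix
  f <- tmm_factors(m)
  nm <- log_cpm(m, f)
  pv <- setNames(rep(1, nrow(m$counts)), rownames(m$counts))
  pv[names(truth$de_genes)] <- 1e-8
  de <- select_de(m, f, pv)

  for (met in c("pearson", "spearman", "fisher", "sobolev")) {
    a <- association_matrices(nm, de, fx$catalog, metric = met)
    expect_identical(dim(a$r1), c(5L, 10L))
    expect_identical(dim(a$r1), dim(a$r2))
    lo <- if (met %in% c("fisher", "sobolev")) 0 else -1
    expect_true(all(a$r1 >= lo - 1e-9 & a$r1 <= 1 + 1e-9))
    expect_true(all(a$r2 >= lo - 1e-9 & a$r2 <= 1 + 1e-9))
  }

  # pearson entries equal the textbook formula pairwise
  a <- association_matrices(nm, de, fx$catalog, metric = "pearson")
  in1 <- nm$condition == nm$condition_levels[1]
  for (j in a$regulators[1:3]) for (i in a$de_genes[1:5]) {
    expect_equal(a$r1[j, i],
                 pearson_oracle(nm$log_expr[j, in1], nm$log_expr[i, in1]),
                 tolerance = 1e-12)
  }

  # geometric entries factor through to_simplex + distance + normalization
  a <- association_matrices(nm, de, fx$catalog, metric = "fisher")
  j <- a$regulators[1]; i <- a$de_genes[1]
  d_hand <- fisher_distance(to_simplex(nm$log_expr[j, in1]),
                            to_simplex(nm$log_expr[i, in1]))
  expect_equal(a$r1[j, i], 1 - d_hand / (pi / 2), tolerance = 1e-12)
  a <- association_matrices(nm, de, fx$catalog, metric = "sobolev")
  d_hand <- sobolev_distance(to_simplex(nm$log_expr[j, in1]),
                             to_simplex(nm$log_expr[i, in1]))
  expect_equal(a$r1[j, i], 1 - d_hand / a$d_max, tolerance = 1e-12)

  # error and warning contracts
  de_none <- de; de_none$is_de[] <- FALSE
  expect_error(association_matrices(nm, de_none, fx$catalog), "empty DE set")
  cat_extra <- merge_catalogs(fx$catalog,
                              regulator_catalog(list(ghost = "TF")))
  expect_warning(association_matrices(nm, de, cat_extra, metric = "pearson"),
                 "absent")
})
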