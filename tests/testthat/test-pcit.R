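test_that("partial correlation matches hand values and precision-matrix oracle", {
  # perfect chain x-z-y: conditioning on z removes the x-y correlation
  expect_equal(partial_correlation(0.81, 0.9, 0.9), 0, tolerance = 1e-12)
  expect_equal(partial_correlation(0.5, 0, 0), 0.5)
  expect_equal(partial_correlation(0.9, 0.9, 0.81),
               0.171 / sqrt(0.19 * 0.3439), tolerance = 1e-10)
  expect_error(partial_correlation(0.5, 1, 0.3), "degenerate")

  set.seed(12)
  for (rep in 1:100) {
    C <- random_corr(rep, n_nodes = 3, n_obs = 10)
    expect_equal(partial_correlation(C[1, 2], C[1, 3], C[2, 3]),
                 partial_corr_precision_oracle(C[1, 2], C[1, 3], C[2, 3]),
                 tolerance = 1e-10)
  }
})

test_that("PCIT eliminates weak explained edges and keeps strong ones", {
  # perfect strong chain: the x-y partial vanishes, which drags the trio
  # tolerance eps = mean(0, 0.743, 0.743) = 0.496 down, so the elimination
  # condition 0.81 <= 0.496 * 0.9 fails and the strong edge is KEPT; the
  # filter prunes edges that are weak relative to the trio, not every
  # perfectly mediated one (hand evaluation of the definition)
  chain <- matrix(c(1, 0.81, 0.9,
                    0.81, 1, 0.9,
                    0.9, 0.9, 1), 3, 3)
  surv <- pcit_filter(chain)
  expect_true(surv[1, 2])
  expect_true(surv[1, 3])
  expect_true(surv[2, 3])

  # weak mediated edge: with r_xz = r_yz = c = 0.5 and r_xy = c^2 = 0.25,
  # eps = (2/3)/sqrt(1 + c^2) = 0.596, and 0.25 <= 0.596 * 0.5 = 0.298
  # holds for both links, so x-y is eliminated while the links to the
  # mediator survive
  weak <- matrix(c(1, 0.25, 0.5,
                   0.25, 1, 0.5,
                   0.5, 0.5, 1), 3, 3)
  surv <- pcit_filter(weak)
  expect_false(surv[1, 2])
  expect_true(surv[1, 3])
  expect_true(surv[2, 3])

  # uncorrelated conditioners cannot eliminate
  indep <- matrix(c(1, 0.7, 0,
                    0.7, 1, 0,
                    0, 0, 1), 3, 3)
  surv <- pcit_filter(indep)
  expect_true(surv[1, 2])

  expect_error(pcit_filter(matrix(c(1, 0.2, 0.5, 1), 2, 2)), ">= 3")
  bad <- chain; bad[1, 2] <- 0.5
  expect_error(pcit_filter(bad), "symmetric")
})

test_that("PCIT agrees with the triple-loop oracle on random matrices", {
  for (seed in 1:50) {
    C <- random_corr(seed, n_nodes = 8, n_obs = 15)
    surv <- pcit_filter(C)
    expect_identical(unname(surv), pcit_oracle(C))
    # structural invariants: symmetry, empty diagonal
    expect_identical(surv, t(surv))
    expect_false(any(diag(surv)))
  }
})

test_that("removing an uninvolved node never flips a surviving edge", {
  for (seed in 1:20) {
    C <- random_corr(seed + 300, n_nodes = 6, n_obs = 12)
    surv_full <- pcit_filter(C)
    # find, per surviving edge, whether dropping each non-eliminating node
    # keeps it alive (its eliminators are still present)
    for (drop_node in seq_len(6)) {
      keep <- setdiff(seq_len(6), drop_node)
      surv_sub <- pcit_filter(C[keep, keep])
      for (i in seq_along(keep)) for (j in seq_along(keep)) {
        if (i >= j) next
        if (surv_full[keep[i], keep[j]]) expect_true(surv_sub[i, j])
      }
    }
  }
})

test_that("mediated correlations are eliminated in simulation", {
  # y is a pure function of z plus noise; x correlates with y only through
  # z; noise is large enough that the mediated x-y correlation (~ 0.1) is
  # weak relative to the x-z and y-z links (~ 0.32), the regime in which
  # the trio tolerance rule fires
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed + 1000)
    n <- 200
    z <- rnorm(n)
    x <- z + 3 * rnorm(n)
    y <- z + 3 * rnorm(n)
    surv <- pcit_filter(cor(cbind(x, y, z)))
    if (!surv["x", "y"]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("build_network applies PCIT plus the direct-correlation threshold", {
  # three co-regulated genes plus unrelated ones, measured profiles
  set.seed(99)
  n <- 40
  base <- rnorm(n)
  prof <- rbind(a = base + 0.2 * rnorm(n),
                b = base + 0.2 * rnorm(n),
                c = base + 0.2 * rnorm(n),
                d = rnorm(n),
                e = rnorm(n))
  nm <- structure(list(log_expr = prof,
                       condition = setNames(rep(c("T", "N"), each = n / 2),
                                            paste0("s", 1:n)),
                       condition_levels = c("T", "N")),
                  class = "normalized_matrix")
  colnames(nm$log_expr) <- paste0("s", 1:n)
  tab <- data.frame(regulator = c("a", "b", "c", "d", "e"), classes = "TF",
                    metric = "pearson", rif1_raw = 1, rif2_raw = 1,
                    rif1_z = 0, rif2_z = 0, rank1 = 1L, rank2 = 1L,
                    selected = TRUE, stringsAsFactors = FALSE)
  C <- cor(t(prof))
  surv <- pcit_filter(C)

  net <- build_network(tab, nm, edge_threshold = 0.90)
  expect_setequal(net$nodes$node, c("a", "b", "c", "d", "e"))
  expected <- sum(surv & abs(C) >= 0.90 & upper.tri(C))
  expect_equal(nrow(net$edges), expected)
  expect_true(all(abs(net$edges$direct_correlation) >= 0.90))

  # threshold 1: no edges, nodes preserved
  net_hi <- build_network(tab, nm, edge_threshold = 1 + 1e-9)
  expect_equal(nrow(net_hi$edges), 0)
  expect_equal(nrow(net_hi$nodes), 5)

  # threshold 0: PCIT survivors only
  net0 <- build_network(tab, nm, edge_threshold = 0)
  expect_equal(nrow(net0$edges), sum(surv & upper.tri(surv)))

  # fewer than 3 selected: PCIT skipped with a warning
  tab2 <- tab[1:2, ]
  expect_warning(net2 <- build_network(tab2, nm, edge_threshold = 0.5),
                 "PCIT stage skipped")
  expect_equal(nrow(net2$edges), 1)
})
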