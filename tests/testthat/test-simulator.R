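test_that("space configuration validates its invariants", {
  cfg <- space_config(10, 7, p_fs = 0.02, seed = 1)
  expect_s3_class(cfg, "space_config")
  expect_identical(cfg$A_t, 6L)
  expect_error(space_config(1, 7, 0.1, 1), ">= 2")
  expect_error(space_config(10, 1, 0.1, 1), ">= 2")
  expect_error(space_config(10, 7, 1.2, 1), "\\[0, 1\\]")
  expect_error(space_config(40, 20, 0.1, 1), "too large")
  expect_error(space_config(10, 7, 0.1, 1, transition = "restricted",
                            A_t = 6), "\\[1, A - 2\\]")
  # odd transition count needs the self-paired half-turn offset: even A only
  expect_error(space_config(10, 7, 0.1, 1, transition = "restricted",
                            A_t = 3), "symmetric")
  cfg8 <- space_config(10, 8, 0.1, 1, transition = "restricted", A_t = 3)
  expect_setequal(cfg8$offsets, c(1L, -1L, 4L))
})

test_that("neighbour enumeration is complete, regular and symmetric", {
  cfg <- space_config(10, 7, p_fs = 0.5, seed = 4)
  nb <- neighbors(cfg, start_sequence(cfg))
  expect_identical(nrow(nb), 60L)
  expect_identical(nrow(unique(nb)), 60L)
  expect_true(all(rowSums(nb != rep(1L, 10)[col(nb)]) == 1))

  cfgR <- space_config(10, 7, p_fs = 0.5, seed = 4,
                       transition = "restricted", A_t = 2)
  nbR <- neighbors(cfgR, c(1:7, 1:3))
  expect_identical(nrow(nbR), 20L)

  # symmetry: u in N(v) <=> v in N(u), sampled over random sequences
  set.seed(5)
  for (cf in list(cfg, cfgR)) {
    for (i in 1:30) {
      v <- sample.int(7, 10, replace = TRUE)
      for (j in sample(nrow(neighbors(cf, v)), 5)) {
        u <- neighbors(cf, v)[j, ]
        back <- neighbors(cf, u)
        expect_true(any(colSums(t(back) != v) == 0))
      }
    }
  }
})

test_that("functional assignment is deterministic, seeded and binomial", {
  cfg <- space_config(10, 7, p_fs = 0, seed = 3)
  expect_false(functional(cfg, c(2, rep(1, 9))))
  expect_true(functional(cfg, start_sequence(cfg))) # forced start
  cfg1 <- space_config(10, 7, p_fs = 1, seed = 3)
  expect_true(all(functional(cfg1, neighbors(cfg1, target_sequence(cfg1)))))

  # same (seed, sequence) always yields the same deviate
  cfg2 <- space_config(10, 7, p_fs = 0.02, seed = 77)
  seqs <- index_codes(cfg2, c(0, 1, 7^5, 7^10 - 1))
  expect_identical(seq_uniform(cfg2, seqs), seq_uniform(cfg2, seqs))

  # empirical functional fraction over 1e5 distinct sequences
  set.seed(8)
  idx <- sample(0:(7^10 - 1), 1e5)
  u <- seq_uniform(cfg2, index_codes(cfg2, idx))
  expect_lt(abs(mean(u < 0.02) - 0.02), 4 * sqrt(0.02 * 0.98 / 1e5))
  expect_error(functional(cfg2, rep(1, 3)), "codes")
})

test_that("cluster search matches the explicit-graph oracle exactly", {
  skip_if_not_installed("igraph")
  set.seed(13)
  grids <- list(c(3, 3), c(4, 3), c(3, 5), c(4, 4))
  trial <- 0
  for (g in grids) {
    for (r in 1:25) {
      trial <- trial + 1
      cfg <- space_config(g[1], g[2], p_fs = runif(1, 0.1, 0.9),
                          seed = 1000 + trial)
      out <- cluster_from_start(cfg, cap = 1e4, collect = TRUE)
      members <- oracle_cluster_members(cfg)
      expect_equal(out$size, length(members))
      expect_equal(sort(seqspace:::codes_to_index(cfg, out$members)),
                   as.numeric(members))
      tol <- sample(0:g[1], 1)
      expect_identical(connect_to_target(cfg, tol = tol),
                       oracle_connect(cfg, tol))
    }
  }
})

test_that("cluster outcomes are deterministic and respect the cap", {
  cfg <- space_config(10, 7, p_fs = 0.021, seed = 19)
  a <- cluster_from_start(cfg, cap = 5000)
  b <- cluster_from_start(cfg, cap = 5000)
  expect_identical(a$size, b$size)
  expect_identical(a$capped, b$capped)
  expect_true(!a$capped || a$size == 5000)
  expect_identical(a$is_large, a$capped)

  empty <- cluster_from_start(space_config(5, 4, p_fs = 0, seed = 2))
  expect_identical(empty$size, 1) # forced-functional start
  expect_false(empty$is_large)
  expect_error(cluster_from_start(cfg, cap = 0), "at least 1")
})

test_that("connectivity handles the trivial regimes", {
  full <- space_config(4, 4, p_fs = 1, seed = 6)
  expect_true(connect_to_target(full, tol = 0))
  some <- space_config(4, 4, p_fs = 0.5, seed = 6)
  expect_true(connect_to_target(some, tol = 4)) # start within tolerance
  set.seed(10)
  expect_identical(attempts_until_connected(full, tol = 2)$attempts, 1L)
  none <- space_config(4, 4, p_fs = 0, seed = 6,
                       force_start_functional = FALSE)
  out <- attempts_until_connected(none, tol = 0, max_attempts = 50)
  expect_false(out$success)
  expect_identical(out$attempts, 50L)
  expect_error(connect_to_target(full, tol = 9), "\\[0, L\\]")
})

test_that("large-cluster fraction hits its bounds and vanishes below threshold", {
  expect_identical(large_cluster_fraction(
    space_config(10, 7, p_fs = 0, seed = 1), reps = 5), 0)
  expect_identical(large_cluster_fraction(
    space_config(6, 4, p_fs = 1, seed = 1), reps = 3, cap = 500), 1)
  # subcritical: no large clusters in 100 replicate spaces
  expect_identical(large_cluster_fraction(
    space_config(10, 7, p_fs = 0.016, seed = 1), reps = 100), 0)
})

test_that("sweep couples replicates monotonically and finds the transition", {
  cfg <- space_config(10, 7, p_fs = 0, seed = 42)
  expect_error(sweep_transition(cfg, c(0.02, 0.01), reps = 10), "ascending")
  sw <- sweep_transition(cfg, c(0.005, 0.012, 0.019, 0.022), reps = 12,
                         cap = 2000)
  # per-seed monotone coupling, asserted exactly
  expect_true(all(apply(sw$sizes, 1, function(s) all(diff(s) >= 0))))
  expect_true(all(apply(sw$large, 1, function(l) all(diff(l) >= 0))))
  expect_true(all(diff(sw$grid$large_fraction) >= 0))
  zero <- sweep_transition(cfg, c(0.001, 0.002), reps = 10)
  expect_true(is.na(zero$critical_p_fs))
})

test_that("cluster-size samples feed the power-law fit", {
  sizes0 <- cluster_size_distribution(
    space_config(8, 4, p_fs = 0, seed = 7), reps = 5)
  expect_true(all(sizes0$size == 1))
  expect_error(cluster_size_distribution(
    space_config(8, 4, p_fs = 0, seed = 7), reps = 0), "at least 1")
  # per-seed agreement with the oracle on exhaustive spaces
  skip_if_not_installed("igraph")
  cfg <- space_config(3, 3, p_fs = 0.5, seed = 33)
  dist <- cluster_size_distribution(cfg, reps = 10, cap = 100)
  manual <- vapply(seq_len(10), function(r) {
    c2 <- cfg; c2$seed <- cfg$seed + 1e6 * r
    length(oracle_cluster_members(c2))
  }, numeric(1))
  expect_equal(dist$size, manual)
})

test_that("power-law exponent is recovered from synthetic samples", {
  set.seed(42)
  f2 <- fit_power_law_tau(sample_power_law(1e4, 2, 5), s_min = 5)
  expect_gt(f2$tau, 1.9); expect_lt(f2$tau, 2.1)
  f3 <- fit_power_law_tau(sample_power_law(1e4, 3, 5), s_min = 5)
  expect_gt(f3$tau, 2.85); expect_lt(f3$tau, 3.15)
  expect_error(fit_power_law_tau(rep(7, 100)), "degenerate")
  expect_error(fit_power_law_tau(1:10), "at least 20")
})
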