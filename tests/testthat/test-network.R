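test_that("coupling input sums over the other units", {
  cfg <- network_config(2, weights = 0.1, column_scales = 1, r_im_base = 0,
                        grid_shape = c(1, 2))
  expect_equal(coupling_input(c(1, 3), 1, cfg, eps_i = 0), 0.3)
  expect_equal(coupling_input(c(0, 0), 1, cfg, eps_i = 0.5), 0.5)
})

test_that("global feedback adds v * M to the no-feedback value", {
  set.seed(1)
  m <- runif(16, 0, 10)
  v <- 0.00001
  w <- sample_weights(16, seed = 2)
  cfg0 <- network_config(16, weights = w, r_im_base = 0)
  cfgv <- network_config(16, weights = w, feedback_v = v, r_im_base = 0)
  for (i in c(1, 7, 16)) {
    base <- coupling_input(m, i, cfg0, eps_i = 0.001)
    withf <- coupling_input(m, i, cfgv, eps_i = 0.001)
    expect_equal(withf, base + v * sum(m), tolerance = 1e-14)
    # independent summation oracle
    expect_equal(base, sum(w[-i] * m[-i]) + 0.001, tolerance = 1e-14)
  }
})

test_that("baseline input is part of the coupling contract", {
  cfg <- network_config(2, weights = 0.1, column_scales = 1,
                        r_im_base = 0.01, grid_shape = c(1, 2))
  expect_equal(coupling_input(c(1, 3), 1, cfg), 0.31)
})

test_that("perturbation draws are reproducible and column-identical", {
  cfg <- network_config(16, weights = 0.0002)
  sched <- perturbation_schedule("uniform", seed = 11)
  a <- draw_perturbation(sched, 5, 3, cfg)
  b <- draw_perturbation(sched, 5, 3, cfg)
  expect_identical(a, b)
  # units 1..4 share column 1; their values differ only via weights (equal
  # here), so the epoch's draw is identical within the column
  cols <- unit_columns(cfg)
  em <- perturbation_matrix(sched, cfg, 10)
  for (cc in unique(cols)) {
    vals <- em[4, cols == cc]
    expect_true(all(abs(vals - vals[1]) < 1e-15))
  }
})

test_that("uniform epoch draws recover the scaled uniform distribution", {
  cfg <- network_config(16, weights = 0.0002)
  sched <- perturbation_schedule("uniform", seed = 21)
  em <- perturbation_matrix(sched, cfg, 1e4)
  s <- perturbation_scales(cfg)[5]
  draws <- em[, 5]
  expect_lt(max(abs(draws)), s + 1e-12)
  ks <- suppressWarnings(stats::ks.test(draws, "punif", -s, s))
  expect_gt(ks$p.value, 0.01)
})

test_that("gaussian mode draws independent per-unit values", {
  cfg <- network_config(8, weights = 0.0002,
                        column_scales = sample_unit_scales(8, 1))
  sched <- perturbation_schedule("gaussian", seed = 3)
  em <- perturbation_matrix(sched, cfg, 2000)
  expect_false(any(duplicated(em[1, ])))
  z <- em[, 2] / perturbation_scales(cfg)[2] / sched$gaussian_norm
  expect_equal(mean(z), sched$gaussian_mean, tolerance = 0.15)
  expect_equal(sd(z), sqrt(sched$gaussian_variance), tolerance = 0.1)
  expect_error(draw_perturbation(
    structure(list(distribution = "weird"), class = "perturbation_schedule"),
    1, 1, cfg))
})

test_that("CN stencil input is exact on constant, fixed-point and random fields", {
  cfg <- network_config(16, weights = 0.0003,
                        coupling_mode = "crank_nicholson", r_im_base = 0)
  m_const <- rep(2, 16)
  vals <- vapply(1:16, function(i) cn_coupling_input(m_const, i, cfg),
                 numeric(1))
  expect_equal(vals, rep(4 * 0.0003 * 0.5 * (2 + 2), 16))
  # previous equal to current: temporal averaging is a no-op
  set.seed(5)
  m <- runif(16, 0, 10)
  expect_equal(cn_coupling_input(m, 6, cfg, m_prev = m),
               cn_coupling_input(m, 6, cfg))
  # hand-computed stencil on a 4x4 grid
  m_prev <- runif(16, 0, 10)
  rows <- 4; cols <- 4
  for (i in c(1, 6, 16)) {
    c0 <- (i - 1) %/% rows; r0 <- (i - 1) %% rows
    idx <- c()
    for (dc in 0:1) for (dr in 0:1) {
      rr <- (r0 + dr) %% rows; ccol <- (c0 + dc) %% cols
      idx <- c(idx, ccol * rows + rr + 1)
    }
    hand <- sum(cfg$weights[idx] * 0.5 * (m[idx] + m_prev[idx]))
    expect_equal(cn_coupling_input(m, i, cfg, m_prev = m_prev), hand,
                 tolerance = 1e-14)
  }
})

test_that("global observables are exact sums", {
  expect_equal(global_observables(matrix(0, 3, 4)), c(M = 0, F = 0))
  expect_equal(global_observables(oscillator_state(2, 3, 1, 1)),
               c(M = 2, F = 3))
  set.seed(9)
  st <- matrix(runif(64), 16, 4)
  expect_equal(global_observables(st),
               c(M = sum(st[, 1]), F = sum(st[, 2])))
})

test_that("relabelling units with their weights and scales leaves M and F invariant", {
  n <- 8
  w <- sample_weights(n, seed = 4)
  scales <- c(5, 1, 7, 2, 3, 8, 6, 4)
  sched <- perturbation_schedule(redraw_interval = 500L, seed = 4)
  spec <- integrator_spec(dt = 1, record_stride = 5L)
  cfg1 <- network_config(n, weights = w, column_scales = scales,
                         grid_shape = c(1, n))
  s0 <- network_initial_state(cfg1, seed = 4)
  eps <- perturbation_matrix(sched, cfg1, 3)
  tr1 <- integrate_epochs(cfg1, sched, spec, n_epochs = 3, state0 = s0,
                          eps_matrix = eps)
  perm <- c(3, 1, 4, 2, 8, 5, 7, 6)
  cfg2 <- network_config(n, weights = w[perm], column_scales = scales[perm],
                         grid_shape = c(1, n))
  s0p <- as.vector(matrix(s0, n, 4)[perm, ])
  tr2 <- integrate_epochs(cfg2, sched, spec, n_epochs = 3, state0 = s0p,
                          eps_matrix = eps[, perm, drop = FALSE])
  expect_equal(tr2$M, tr1$M, tolerance = 1e-12)
  expect_equal(tr2$F, tr1$F, tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(16, weights = 0.0001, feedback_v = 0.0002),
               "v_k")
  expect_error(network_config(15, grid_shape = c(4, 4)))
  w <- sample_weights(100, seed = 1)
  expect_true(all(w %in% c(0.00011, 0.00012, 0.00025)))
  sc <- sample_unit_scales(64, seed = 1)
  expect_true(all(sc %in% 1:10))
  cfg <- network_config(16, weights = 1e-4)
  wm <- ramp_weights(cfg, 20)
  expect_equal(dim(wm), c(20L, 16L))
  expect_equal(wm[1, 1:4], c(1e-4, 1e-4, 1e-4, 1e-4))
  expect_equal(wm[6, ] - wm[1, ], rep(0.00005, 16))
  expect_equal(wm[20, ] - wm[1, ], rep(3 * 0.00005, 16))
})
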