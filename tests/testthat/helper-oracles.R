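# Independent reference implementations used as oracles.  These are coded
# directly from the model equations, separately from the package internals.

# uncontrolled Berry vector field, independent transcription
oracle_berry_deriv <- function(s, r_im, sigma_p = 1, sigma_g = 1) {
  m <- s[[1]]; f <- s[[2]]; p <- s[[3]]; g <- s[[4]]
  gamma <- 0.026; beta <- 0.00075; K_R <- 4.5; K_S <- 1; K_G <- 0.1
  K_deg <- 1.1; k_g <- 0.05; k_deg <- 0.05; k_a <- k_deg / K_deg
  c(k_g * f * g / (K_G + f) - m * p / (1 + m) + r_im,
    -k_g * f * g / (K_G + f) + m * p / (1 + m) - f * p / (1 + f),
    sigma_p * gamma * f^4 / (K_R^4 + f^4) - k_a * p^2,
    sigma_g * beta * f^4 / (K_S^4 + f^4) - k_deg * g * p / (K_deg + g))
}

# naive full-network RK4 step (independent of the compiled path)
oracle_network_step <- function(y, cfg, eps, dt) {
  n <- cfg$n_units
  deriv <- function(y) {
    m <- y[1:n]; f <- y[n + 1:n]; p <- y[2 * n + 1:n]; g <- y[3 * n + 1:n]
    M <- sum(m)
    d <- matrix(0, 4, n)
    for (i in 1:n) {
      rim <- cfg$r_im_base + sum(cfg$weights[-i] * m[-i]) + eps[i]
      if (cfg$feedback_v[i] != 0) rim <- rim + cfg$feedback_v[i] * M
      q <- f[i] / (f[i] + cfg$rcc$mu_f)
      sp <- if (cfg$rcc$enabled) cfg$rcc$f_p * exp(cfg$rcc$xi_p * q) else cfg$rcc$f_p
      sg <- if (cfg$rcc$enabled) cfg$rcc$f_g * exp(cfg$rcc$xi_g * q) else cfg$rcc$f_g
      d[, i] <- oracle_berry_deriv(c(m[i], f[i], p[i], g[i]), rim, sp, sg)
    }
    c(d[1, ], d[2, ], d[3, ], d[4, ])
  }
  k1 <- deriv(y)
  k2 <- deriv(y + dt / 2 * k1)
  k3 <- deriv(y + dt / 2 * k2)
  k4 <- deriv(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# two-trajectory divergence estimate of the largest Lyapunov exponent of a
# single Berry unit (independent of the tangent-space estimator it checks)
oracle_lyapunov_divergence <- function(r_im, rcc, s0, n_steps = 6e4,
                                       d0 = 1e-8, chunk = 2000L, dt = 1) {
  spec <- integrator_spec(dt = dt, record_stride = 0L)
  x1 <- s0
  x2 <- s0 + c(d0, 0, 0, 0)
  lam <- 0; total_t <- 0
  for (s in seq_len(n_steps %/% chunk)) {
    x1 <- simulate_single(r_im, rcc, n_steps = chunk, state0 = x1,
                          spec = spec)$state
    x2 <- simulate_single(r_im, rcc, n_steps = chunk, state0 = x2,
                          spec = spec)$state
    d <- sqrt(sum((x2 - x1)^2))
    lam <- lam + log(d / d0)
    total_t <- total_t + chunk * dt
    x2 <- x1 + (x2 - x1) * d0 / d
  }
  lam / total_t
}

# small standard network for integration tests
tiny_network <- function(n = 4, seed = 1, ...) {
  network_config(n, weights = sample_weights(n, seed = seed),
                 grid_shape = c(min(n, 4L), n %/% min(n, 4L)), ...)
}

# minimal hand-built trajectory object for analysis tests
fake_trajectory <- function(M, epoch, eps_matrix,
                            F = M / 10, record_stride = 1L) {
  structure(list(time = seq_along(M), epoch = as.integer(epoch), M = M,
                 F = F, eps_matrix = eps_matrix,
                 schedule = list(redraw_interval = sum(epoch == epoch[1]) *
                                   record_stride),
                 spec = list(record_stride = record_stride)),
            class = "socrcc_trajectory")
}
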