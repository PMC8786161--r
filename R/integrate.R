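#' Fixed-step integrator specification
#'
#' The network is integrated with classical explicit Runge-Kutta schemes in
#' fixed-step mode (no adaptive error control); the embedded pairs
#' (Fehlberg, Prince-Dormand) use their higher-order solution only.
#'
#' @param method \code{"rk4"}, \code{"rk_fehlberg"} or
#'   \code{"rk_prince_dormand"}.
#' @param dt time step (model time units; default 1, validated by
#'   step-halving against the controlled oscillation -- see the methods
#'   vignette; the kinetic rates are all below 0.05 per time unit).
#' @param record_stride integration steps between recorded samples.
#' @return Object of class \code{integrator_spec}.
#' @export
integrator_spec <- function(method = c("rk4", "rk_fehlberg",
                                       "rk_prince_dormand"),
                            dt = 1, record_stride = 10L) {
  method <- match.arg(method)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(method = method, dt = dt,
                 record_stride = as.integer(record_stride)),
            class = "integrator_spec")
}

.method_code <- function(method) {
  match(method, c("rk4", "rk_fehlberg", "rk_prince_dormand")) - 1L
}

#' Butcher tableau of a supported explicit scheme
#'
#' @param method scheme name as in [integrator_spec()].
#' @return List with stage matrix \code{A}, weights \code{b} (higher-order
#'   solution for the embedded pairs) and nodes \code{c}.
#' @export
rk_tableau <- function(method = c("rk4", "rk_fehlberg", "rk_prince_dormand")) {
  method <- match.arg(method)
  if (method == "rk4") {
    A <- matrix(0, 4, 4)
    A[2, 1] <- 0.5; A[3, 2] <- 0.5; A[4, 3] <- 1
    list(A = A, b = c(1, 2, 2, 1) / 6, c = c(0, 0.5, 0.5, 1))
  } else if (method == "rk_fehlberg") {
    A <- matrix(0, 6, 6)
    A[2, 1] <- 1 / 4
    A[3, 1:2] <- c(3 / 32, 9 / 32)
    A[4, 1:3] <- c(1932 / 2197, -7200 / 2197, 7296 / 2197)
    A[5, 1:4] <- c(439 / 216, -8, 3680 / 513, -845 / 4104)
    A[6, 1:5] <- c(-8 / 27, 2, -3544 / 2565, 1859 / 4104, -11 / 40)
    list(A = A,
         b = c(16 / 135, 0, 6656 / 12825, 28561 / 56430, -9 / 50, 2 / 55),
         c = c(0, 1 / 4, 3 / 8, 12 / 13, 1, 1 / 2))
  } else {
    A <- matrix(0, 7, 7)
    A[2, 1] <- 1 / 5
    A[3, 1:2] <- c(3 / 40, 9 / 40)
    A[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
    A[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
    A[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
                   -5103 / 18656)
    A[7, 1:6] <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
    list(A = A,
         b = c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0),
         c = c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1))
  }
}

#' One explicit Runge-Kutta step
#'
#' Advances an arbitrary ODE system by one fixed step of the selected
#' tableau.  The derivative function is re-evaluated at every stage, so any
#' state-dependent coupling or instantaneous global observable it computes
#' is stage-fresh.
#'
#' @param deriv function \code{(t, state) -> derivative vector}.
#' @param state current state vector (finite).
#' @param t current time.
#' @param dt step size.
#' @param method scheme name.
#' @return The state after one step.  A non-finite result signals
#'   divergence via an error of class \code{socrcc_divergence}.
#' @export
rk_step <- function(deriv, state, t, dt, method = "rk4") {
  tb <- rk_tableau(method)
  ns <- length(tb$b)
  K <- matrix(0, ns, length(state))
  for (s in seq_len(ns)) {
    ys <- if (s == 1) state
          else state + dt * drop(tb$A[s, 1:(s - 1), drop = FALSE] %*%
                                 K[1:(s - 1), , drop = FALSE])
    K[s, ] <- deriv(t + tb$c[s] * dt, ys)
  }
  out <- state + dt * drop(tb$b %*% K)
  if (any(!is.finite(out)))
    stop(structure(class = c("socrcc_divergence", "error", "condition"),
                   list(message = "non-finite state after RK step",
                        call = sys.call())))
  out
}

#' Integrate a network over a perturbation schedule
#'
#' Simulates the coupled system epoch by epoch: the perturbation is held
#' constant within each epoch of \code{schedule$redraw_interval} steps and
#' redrawn at epoch boundaries (synchronously for all units).  Global
#' feedback, when configured, uses the instantaneous summed matrix M
#' recomputed at every RK stage.  Deterministic given (config, schedule
#' seed, spec, initial state).
#'
#' @param cfg a [network_config()].
#' @param schedule a [perturbation_schedule()].
#' @param spec an [integrator_spec()].
#' @param n_epochs number of perturbation epochs to run.
#' @param state0 initial state vector (length \code{4 * n_units}, layout
#'   m..., f..., p..., g...); defaults to seeded uniform (0, 1] values using
#'   the schedule seed.
#' @param weight_matrix optional per-epoch weight matrix (epochs x units),
#'   e.g. from [ramp_weights()]; defaults to constant \code{cfg$weights}.
#' @param eps_matrix optional explicit perturbation matrix overriding the
#'   schedule draws.
#' @param record_units logical; also record per-unit m and f series.
#' @param ceiling divergence ceiling on any state component (default 1e7);
#'   exceeding it truncates the trajectory and flags the offending epoch.
#' @param stale_feedback diagnostic flag: use the step-start value of M for
#'   the feedback term instead of the stage-level value (violates the
#'   instantaneous-feedback contract; for testing only).
#' @return Object of class \code{socrcc_trajectory}: a list with \code{time},
#'   \code{epoch}, \code{M}, \code{F} (recorded series), \code{state} (final
#'   state), divergence flags, the applied \code{eps_matrix} and the
#'   generating configuration.
#' @export
integrate_epochs <- function(cfg, schedule, spec = integrator_spec(),
                             n_epochs = 100L, state0 = NULL,
                             weight_matrix = NULL, eps_matrix = NULL,
                             record_units = FALSE, ceiling = 1e7,
                             stale_feedback = FALSE) {
  n_epochs <- as.integer(n_epochs)
  n <- cfg$n_units
  if (n_epochs <= 0) {
    return(structure(list(time = numeric(0), epoch = integer(0),
                          M = numeric(0), F = numeric(0),
                          state = state0 %||% rep(0, 4 * n),
                          diverged = FALSE, diverge_epoch = NA_integer_,
                          eps_matrix = matrix(0, 0, n), cfg = cfg,
                          schedule = schedule, spec = spec),
                     class = "socrcc_trajectory"))
  }
  if (is.null(eps_matrix)) eps_matrix <- perturbation_matrix(schedule, cfg, n_epochs)
  if (is.null(weight_matrix))
    weight_matrix <- matrix(rep(cfg$weights, each = n_epochs), n_epochs, n)
  if (is.null(state0)) {
    state0 <- if (n == 1L) random_initial_state(1L, seed = schedule$seed)
              else network_initial_state(cfg, seed = schedule$seed)
  }
  stopifnot(length(state0) == 4 * n, nrow(eps_matrix) == n_epochs,
            ncol(eps_matrix) == n, all(dim(weight_matrix) == dim(eps_matrix)))
  feedback <- any(cfg$feedback_v != 0)
  res <- .sim_network_cpp(
    n, weight_matrix, eps_matrix + cfg$r_im_base, cfg$feedback_v, feedback,
    switch(cfg$coupling_mode, all_to_all = 0L, crank_nicholson = 1L,
           grid = 2L),
    cfg$grid_shape[1], cfg$grid_shape[2],
    unlist(cfg$bp[c("gamma", "beta", "K_R", "K_S", "K_G", "K_deg", "k_g",
                    "k_deg", "k_a", "hill_n", "hill_l")], use.names = FALSE),
    c(cfg$rcc$mu_f, cfg$rcc$xi_p, cfg$rcc$xi_g, cfg$rcc$f_p, cfg$rcc$f_g,
      as.numeric(cfg$rcc$enabled)),
    state0, spec$dt, schedule$redraw_interval, spec$record_stride,
    .method_code(spec$method), ceiling, record_units, stale_feedback)
  res$eps_matrix <- eps_matrix
  res$cfg <- cfg
  res$schedule <- schedule
  res$spec <- spec
  if (res$diverged)
    warning("trajectory diverged in epoch ", res$diverge_epoch,
            " (step ", res$diverge_step, "); output truncated")
  neg <- res$state < 0
  if (any(neg) && !res$diverged)
    warning("final state has ", sum(neg),
            " negative component(s): integration error may have left the ",
            "physical domain (trajectory-quality warning, not clamped)")
  structure(res, class = "socrcc_trajectory")
}

#' Default initial state for a coupled network
#'
#' The coupled network is bistable: besides the active chaotic/controlled
#' regime it has a dead low-concentration state from which the weak coupling
#' cannot bootstrap the dynamics (and whose neighbourhood contains the model
#' poles at \code{f = -K_G} and \code{m = -1}).  Network runs therefore start
#' each unit from the settled single-unit controlled attractor at the
#' chaotic input preset, de-phased along the orbit: each unit's state is
#' taken from a different (seeded, random) point of the settled trajectory,
#' so the summed input to every unit starts near its time-averaged value
#' rather than swinging coherently.  Epoch transients are discarded by the
#' analysis pipeline.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the phase draws and jitter.
#' @param jitter relative jitter amplitude (default 0.02: each component is
#'   additionally scaled by a U[1 - jitter, 1 + jitter] factor).
#' @param settle_steps steps of the single-unit settling run.
#' @return Numeric vector of length \code{4 * n_units}.
#' @export
network_initial_state <- function(cfg, seed = 1L, jitter = 0.02,
                                  settle_steps = 2e5) {
  fp <- .self_consistent_unit(cfg, settle_steps)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  n <- cfg$n_units
  spec <- integrator_spec(dt = 1, record_stride = 0L)
  states <- matrix(0, 4, n)
  s <- fp$state
  # walk along the attractor: random-phase offsets between consecutive units
  offsets <- sample(200:5000, n, replace = TRUE)
  for (i in seq_len(n)) {
    s <- simulate_single(fp$r_im, rcc = cfg$rcc, n_steps = offsets[i],
                         state0 = s, spec = spec, bp = cfg$bp)$state
    states[, i] <- s
  }
  s0 <- as.vector(t(states))           # layout m..., f..., p..., g...
  s0 * (1 + jitter * stats::runif(4 * n, -1, 1))
}

.settle_cache <- new.env(parent = emptyenv())

# Locate the network's mean-field operating point: the input r* at which one
# controlled unit's time-averaged m, fed back through the coupling weights,
# reproduces r*.  Damped fixed-point iteration from the chaotic preset.
.self_consistent_unit <- function(cfg, settle_steps = 2e5) {
  n <- cfg$n_units
  Sw <- switch(cfg$coupling_mode,
    all_to_all = mean(vapply(seq_len(n),
      function(i) sum(cfg$weights[-i]), numeric(1))),
    # grid modes: 8 (Moore) / 4 (2x2 stencil) neighbour weights on average
    grid = mean(cfg$weights) * min(8L, n - 1L),
    crank_nicholson = mean(cfg$weights) * min(4L, n))
  key <- paste(c(unlist(cfg$bp), unlist(cfg$rcc), signif(Sw, 6),
                 cfg$r_im_base, settle_steps), collapse = "|")
  if (!is.null(.settle_cache[[key]])) return(.settle_cache[[key]])
  spec <- integrator_spec(dt = 1, record_stride = 10L)
  r <- cfg$r_im_base + Sw * 5      # crude first guess at the operating point
  s <- c(1, 1, 0.1, 0.1)
  for (iter in 1:6) {
    tr <- simulate_single(r, rcc = cfg$rcc, n_steps = settle_steps,
                          state0 = s, spec = spec, bp = cfg$bp)
    s <- tr$state
    m_bar <- mean(tr$M[tr$time > settle_steps / 2])
    r_new <- cfg$r_im_base + Sw * m_bar
    if (!is.finite(r_new) || r_new <= 0) break
    if (abs(r_new - r) < 0.02 * r) { r <- r_new; break }
    r <- (r + r_new) / 2
  }
  out <- list(r_im = r, state = s)
  .settle_cache[[key]] <- out
  out
}

#' Single-oscillator run with a fixed external input
#'
#' Convenience wrapper: one Berry unit, no coupling, constant \code{r_im}
#' as its external input.  Used for the isolated chaotic / controlled runs.
#'
#' @param r_im external input rate.
#' @param rcc [rcc_params()] (set \code{enabled = FALSE} for the
#'   uncontrolled model).
#' @param n_steps integration steps.
#' @param state0 initial 4-vector (m, f, p, g); default seeded from
#'   \code{seed}.
#' @param spec an [integrator_spec()].
#' @param bp [berry_params()].
#' @param seed seed for the default initial state.
#' @param record_units unused for n = 1 (kept for interface symmetry).
#' @return A \code{socrcc_trajectory} (M and F are the unit's m and f).
#' @export
simulate_single <- function(r_im, rcc = rcc_params(), n_steps = 2e5,
                            state0 = NULL, spec = integrator_spec(),
                            bp = berry_params(), seed = 1L,
                            record_units = FALSE) {
  cfg <- network_config(1, weights = 0, column_scales = 1, r_im_base = 0,
                        bp = bp, rcc = rcc, grid_shape = c(1, 1))
  sched <- perturbation_schedule(redraw_interval = as.integer(n_steps),
                                 seed = seed)
  integrate_epochs(cfg, sched, spec, n_epochs = 1L, state0 = state0,
                   eps_matrix = matrix(r_im, 1, 1))
}

#' @export
print.socrcc_trajectory <- function(x, ...) {
  cat("<socrcc_trajectory>\n")
  cat("  units:", x$cfg$n_units, " epochs:", nrow(x$eps_matrix),
      " samples:", length(x$M), "\n")
  cat("  method:", x$spec$method, " dt:", x$spec$dt, "\n")
  if (isTRUE(x$diverged))
    cat("  DIVERGED in epoch", x$diverge_epoch, "\n")
  else if (length(x$M))
    cat(sprintf("  M range: [%.4g, %.4g]\n", min(x$M), max(x$M)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
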