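#' Configuration of a coupled oscillator network
#'
#' Describes N identical RCC-controlled Berry oscillators coupled through
#' their external input: each unit receives the weighted sum of all other
#' units' matrix concentrations plus a random perturbation, and optionally a
#' signed global-feedback term proportional to the instantaneous total M.
#'
#' @param n_units number of oscillators.
#' @param weights per-unit connectivity strengths \code{w_k} (recycled to
#'   length \code{n_units}).  The weight indexes the *source* unit: unit i
#'   receives \code{sum_{k != i} w_k m_k}.
#' @param column_scales per-column perturbation multipliers (e.g.
#'   \code{c(7.5, 1, 8, 3.25)}); length must divide the grid columns.
#' @param feedback_v signed per-unit global feedback strength \code{v_k}
#'   (positive boosts, negative damps); 0 disables feedback.  Must satisfy
#'   \code{|v_k| < w_k} when non-zero.
#' @param coupling_mode \code{"grid"} (finite-difference connections: the
#'   weighted sum over the unit's Moore neighbourhood on the grid, periodic
#'   wrap; the default), \code{"all_to_all"} (the weighted sum over all
#'   other units) or \code{"crank_nicholson"} (2x2 grid-stencil averaging of
#'   current and previous-step neighbour states, the linearising control).
#' @param r_im_base constant baseline external input shared by all units,
#'   keeping each oscillator inside the chaotic domain regardless of the
#'   instantaneous coupling; coupling and perturbation are increments on it.
#'   Defaults to [r_im_chaotic()].
#' @param bp,rcc model and control parameter objects.
#' @param grid_shape integer c(rows, cols); units are assigned to columns
#'   column-major.  Defaults to 4 rows and \code{n_units / 4} columns when
#'   \code{n_units} is a multiple of 4, else a single row.
#' @return Object of class \code{network_config}.
#' @export
network_config <- function(n_units, weights = 0.00012,
                           column_scales = c(7.5, 1, 8, 3.25),
                           feedback_v = 0,
                           coupling_mode = c("all_to_all", "grid",
                                             "crank_nicholson"),
                           r_im_base = r_im_chaotic(),
                           bp = berry_params(), rcc = rcc_params(),
                           grid_shape = NULL) {
  coupling_mode <- match.arg(coupling_mode)
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 1)
  weights <- rep_len(weights, n_units)
  feedback_v <- rep_len(feedback_v, n_units)
  if (any(feedback_v != 0 & abs(feedback_v) >= weights))
    stop("global feedback requires |v_k| < w_k for every unit")
  if (is.null(grid_shape)) {
    grid_shape <- if (n_units %% 4L == 0L) c(4L, n_units %/% 4L)
                  else c(1L, n_units)
  }
  grid_shape <- as.integer(grid_shape)
  if (prod(grid_shape) != n_units)
    stop("grid_shape rows * cols must equal n_units")
  structure(list(n_units = n_units, weights = weights,
                 column_scales = column_scales, feedback_v = feedback_v,
                 coupling_mode = coupling_mode, r_im_base = r_im_base,
                 bp = bp, rcc = rcc, grid_shape = grid_shape),
            class = "network_config")
}

#' Column index of each unit
#'
#' Units fill the grid column-major: unit 1 is (row 1, col 1), unit
#' \code{rows + 1} is (row 1, col 2), and so on.
#' @param cfg a [network_config()].
#' @return Integer vector of column indices, length \code{n_units}.
#' @export
unit_columns <- function(cfg) {
  rep(seq_len(cfg$grid_shape[2]), each = cfg$grid_shape[1])
}

#' Random perturbation schedule
#'
#' The external perturbation is piecewise constant: it is redrawn every
#' \code{redraw_interval} integration steps (one draw per epoch).  In
#' \code{"uniform"} mode a single U[-1, 1] draw is shared by all units of an
#' epoch and scaled per unit by its connectivity strength and its column's
#' scale, so units in the same column receive identical values.  In
#' \code{"gaussian"} mode each unit receives an independent draw from
#' N(mean, variance) rescaled by \code{gaussian_norm} (draw value =
#' \code{gaussian_norm * rnorm(mean, sd)} times the unit scale).  The
#' default normalisation standardises the draw (divides by the standard
#' deviation), which puts the per-unit magnitudes on the same order as the
#' uniform mode's U[-1, 1] draws.
#'
#' @param distribution \code{"uniform"} or \code{"gaussian"}.
#' @param redraw_interval integration steps between redraws (> 0).
#' @param seed integer seed making all draws reproducible.
#' @param gaussian_mean,gaussian_variance parameters of the gaussian mode
#'   (defaults mean 0.00005, variance 10).
#' @param gaussian_norm rescaling constant applied to gaussian draws.
#' @return Object of class \code{perturbation_schedule}.
#' @export
perturbation_schedule <- function(distribution = c("uniform", "gaussian"),
                                  redraw_interval = 20000L, seed = 1L,
                                  gaussian_mean = 0.00005,
                                  gaussian_variance = 10,
                                  gaussian_norm = 1 / sqrt(gaussian_variance)) {
  distribution <- match.arg(distribution)
  redraw_interval <- as.integer(redraw_interval)
  if (redraw_interval <= 0) stop("redraw_interval must be > 0")
  structure(list(distribution = distribution,
                 redraw_interval = redraw_interval, seed = as.integer(seed),
                 gaussian_mean = gaussian_mean,
                 gaussian_variance = gaussian_variance,
                 gaussian_norm = gaussian_norm),
            class = "perturbation_schedule")
}

#' Per-unit perturbation scale factors
#'
#' Uniform mode scales each unit by its connectivity strength times its
#' column's scale.  Gaussian (64-unit) mode uses the per-unit unique scales
#' stored in \code{cfg$column_scales} when their length equals
#' \code{n_units}, otherwise the column mapping.
#' @param cfg a [network_config()].
#' @return Numeric vector of length \code{n_units}.
#' @export
perturbation_scales <- function(cfg) {
  if (length(cfg$column_scales) == cfg$n_units) {
    cfg$weights * cfg$column_scales
  } else {
    cs <- rep_len(cfg$column_scales, cfg$grid_shape[2])
    cfg$weights * cs[unit_columns(cfg)]
  }
}

#' Full perturbation matrix for a run
#'
#' Generates the epoch-by-unit matrix of perturbation values \code{eps}
#' applied to the coupling input, deterministically from the schedule seed.
#' Epoch boundaries are synchronous across units.
#'
#' @param schedule a [perturbation_schedule()].
#' @param cfg a [network_config()].
#' @param n_epochs number of epochs to draw.
#' @return Numeric matrix, \code{n_epochs} rows by \code{n_units} columns.
#' @export
perturbation_matrix <- function(schedule, cfg, n_epochs) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(schedule$seed)
  scales <- perturbation_scales(cfg)
  n <- cfg$n_units
  if (schedule$distribution == "uniform") {
    base <- stats::runif(n_epochs, -1, 1)          # one shared draw per epoch
    outer(base, scales)
  } else {
    draws <- matrix(stats::rnorm(n_epochs * n, mean = schedule$gaussian_mean,
                                 sd = sqrt(schedule$gaussian_variance)),
                    n_epochs, n)
    sweep(draws * schedule$gaussian_norm, 2, scales, `*`)
  }
}

#' Perturbation value for one (epoch, unit) pair
#'
#' Reproducible point query into the schedule: the same (epoch, unit) always
#' returns the same value for a given seed and configuration.
#'
#' @param schedule a [perturbation_schedule()].
#' @param epoch epoch index (1-based).
#' @param unit unit index (1-based).
#' @param cfg a [network_config()].
#' @return A single perturbation value.
#' @export
draw_perturbation <- function(schedule, epoch, unit, cfg) {
  if (!(schedule$distribution %in% c("uniform", "gaussian")))
    stop("unknown distribution: ", schedule$distribution)
  perturbation_matrix(schedule, cfg, epoch)[epoch, unit]
}

#' Coupling input to one unit (all-to-all form)
#'
#' \code{r_im_i = r_base + sum_{k != i} w_k m_k + eps_i}, plus
#' \code{v_i * M} when global feedback is on (\code{M} the instantaneous
#' summed matrix).  \code{r_base} is the constant chaotic-domain baseline
#' from the configuration.
#'
#' @param m_all per-unit matrix concentrations.
#' @param i receiving unit index (1-based).
#' @param cfg a [network_config()].
#' @param eps_i perturbation applied to unit i.
#' @param M instantaneous global matrix sum; defaults to \code{sum(m_all)}.
#' @return The external input rate for unit i.
#' @export
coupling_input <- function(m_all, i, cfg, eps_i = 0, M = sum(m_all)) {
  val <- cfg$r_im_base + sum(cfg$weights[-i] * m_all[-i]) + eps_i
  if (cfg$feedback_v[i] != 0) val <- val + cfg$feedback_v[i] * M
  val
}

#' Coupling input under the Crank-Nicolson stencil
#'
#' Linearised grid-local coupling: the unit's 2x2 stencil neighbourhood
#' (its own cell plus right, down and diagonal neighbours, periodic wrap)
#' is summed with weights \code{w_k}, averaging current and previous-step
#' values with equal (1/2, 1/2) temporal weights, per the standard
#' Crank-Nicolson template.  On the first step (no previous state) current
#' values are used for both.
#'
#' @param m_grid current per-unit matrix concentrations (column-major grid).
#' @param i receiving unit index (1-based).
#' @param cfg a [network_config()] with a declared grid.
#' @param eps_i perturbation applied to unit i.
#' @param m_prev previous-step matrix concentrations (defaults to current).
#' @return The external input rate for unit i.
#' @export
cn_coupling_input <- function(m_grid, i, cfg, eps_i = 0, m_prev = m_grid) {
  rows <- cfg$grid_shape[1]; cols <- cfg$grid_shape[2]
  c0 <- (i - 1) %/% rows; r0 <- (i - 1) %% rows
  r1 <- (r0 + 1) %% rows; c1 <- (c0 + 1) %% cols
  idx <- c(c0 * rows + r0, c0 * rows + r1, c1 * rows + r0, c1 * rows + r1) + 1
  cfg$r_im_base + sum(cfg$weights[idx] * 0.5 * (m_grid[idx] + m_prev[idx])) +
    eps_i
}

#' Global observables M and F
#'
#' The unweighted sums of matrix and filament over all oscillators -- what a
#' remote observer of the pooled output sees.  When feedback is on the
#' simulator recomputes M inside every derivative evaluation (stage-level,
#' not the previous step's value).
#'
#' @param states numeric matrix with columns (m, f, p, g), one row per unit,
#'   or a single [oscillator_state()].
#' @return Named vector \code{c(M = sum(m), F = sum(f))}.
#' @export
global_observables <- function(states) {
  if (is.null(dim(states))) states <- matrix(unclass(states), nrow = 1)
  c(M = sum(states[, 1]), F = sum(states[, 2]))
}

#' Seeded draw of connectivity strengths from the standard set
#'
#' Each unit's \code{w_k} is one of the three chaotic-domain values
#' 0.00011, 0.00012, 0.00025, assigned at random.
#'
#' @param n number of units.
#' @param seed integer seed.
#' @return Numeric vector of weights.
#' @export
sample_weights <- function(n, seed = 1L) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  sample(c(0.00011, 0.00012, 0.00025), n, replace = TRUE)
}

#' Seeded per-unit scales for the 64-oscillator experiment
#'
#' Each unit receives a randomly assigned value between 1 and 10 as its
#' perturbation scale (uniform integer draw with repetition across units).
#'
#' @param n number of units.
#' @param seed integer seed.
#' @return Numeric vector of scales in 1..10.
#' @export
sample_unit_scales <- function(n, seed = 1L) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  sample(1:10, n, replace = TRUE)
}

#' Stepwise connectivity ramp
#'
#' Per-epoch weight matrix implementing the ramp protocol: columns start at
#' \code{start} (one value per grid column) and every \code{every} epochs all
#' weights increase by \code{increment}.
#'
#' @param cfg a [network_config()].
#' @param n_epochs total epochs.
#' @param start starting weights per column
#'   (default \code{c(0.0001, 0.0002, 0.0003, 0.0004)}).
#' @param increment weight increment (default 0.00005).
#' @param every epochs between increments (default 5, i.e. every 1e5 steps
#'   at the standard 2e4-step epoch).
#' @return Matrix \code{n_epochs} x \code{n_units} of weights.
#' @export
ramp_weights <- function(cfg, n_epochs, start = c(1e-4, 2e-4, 3e-4, 4e-4),
                         increment = 0.00005, every = 5L) {
  cs <- rep_len(start, cfg$grid_shape[2])
  w0 <- cs[unit_columns(cfg)]
  steps <- (seq_len(n_epochs) - 1L) %/% every
  matrix(rep(w0, each = n_epochs), n_epochs, cfg$n_units) + steps * increment
}
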