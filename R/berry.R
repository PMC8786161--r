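#' Parameters of the Berry bienzymatic matrix-remodelling model
#'
#' Kinetic constants of the four-variable model of extracellular-matrix
#' remodelling: matrix \code{m} is formed from soluble filament \code{f} by
#' transglutaminase \code{g} and degraded back to filament by proteinase
#' \code{p}; both enzymes are produced under Hill-type activation by \code{f}
#' and decay in \code{p}-proportional catalytic steps.
#'
#' @param gamma maximal proteinase production rate.
#' @param beta maximal transglutaminase production rate.
#' @param K_R Hill constant of proteinase production.
#' @param K_S Hill constant of transglutaminase production.
#' @param K_G Michaelis constant of matrix formation from filament.
#' @param K_deg Michaelis constant of transglutaminase degradation.
#' @param k_g rate constant of matrix formation.
#' @param k_deg rate constant of transglutaminase degradation.
#' @param k_a proteinase self-inactivation rate; defaults to the exact
#'   quotient \code{k_deg / K_deg} (0.04545..., commonly rounded to 0.0455).
#' @param hill_n,hill_l Hill exponents (integers, >= 1) of the two enzyme
#'   production terms.
#'
#' @return An object of class \code{berry_params} (named list).
#' @seealso [rcc_params()], [berry_derivatives()]
#' @export
berry_params <- function(gamma = 0.026, beta = 0.00075, K_R = 4.5, K_S = 1,
                         K_G = 0.1, K_deg = 1.1, k_g = 0.05, k_deg = 0.05,
                         k_a = k_deg / K_deg, hill_n = 4L, hill_l = 4L) {
  vals <- c(gamma = gamma, beta = beta, K_R = K_R, K_S = K_S, K_G = K_G,
            K_deg = K_deg, k_g = k_g, k_deg = k_deg, k_a = k_a)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Berry rate constants must be finite and strictly positive")
  if (hill_n < 1 || hill_l < 1) stop("Hill exponents must be >= 1")
  structure(list(gamma = gamma, beta = beta, K_R = K_R, K_S = K_S, K_G = K_G,
                 K_deg = K_deg, k_g = k_g, k_deg = k_deg, k_a = k_a,
                 hill_n = as.integer(hill_n), hill_l = as.integer(hill_l)),
            class = "berry_params")
}

#' Rate-Control-of-Chaos (RCC) control parameters
#'
#' RCC multiplies selected production terms by \eqn{\sigma = f_s e^{\xi q}}
#' where \eqn{q = f/(f + \mu_f)} is a bounded rate quotient of the local
#' filament concentration.  With \code{enabled = FALSE} the control factors
#' reduce to the constant scales \code{f_p}, \code{f_g} (both 1 by default),
#' recovering the uncontrolled model.
#'
#' @param mu_f half-saturation of the rate quotient (default 2).
#' @param xi_p,xi_g control exponents on the proteinase and transglutaminase
#'   production terms; -1 for the standard perturbation experiments, -3 for
#'   the enhanced control used with global feedback.
#' @param f_p,f_g control scale factors (default 1).
#' @param enabled logical; turn the control on or off.
#'
#' @return An object of class \code{rcc_params}.
#' @export
rcc_params <- function(mu_f = 2, xi_p = -1, xi_g = -1, f_p = 1, f_g = 1,
                       enabled = TRUE) {
  if (!is.finite(mu_f) || mu_f <= 0) stop("mu_f must be finite and > 0")
  structure(list(mu_f = mu_f, xi_p = xi_p, xi_g = xi_g, f_p = f_p, f_g = f_g,
                 enabled = isTRUE(enabled)),
            class = "rcc_params")
}

#' State of one Berry oscillator
#'
#' @param m,f,p,g matrix, filament, proteinase and transglutaminase
#'   concentrations (finite; non-negative for physically valid states).
#' @return Named numeric vector of class \code{oscillator_state}.
#' @export
oscillator_state <- function(m, f, p, g) {
  s <- c(m = m, f = f, p = p, g = g)
  if (any(!is.finite(s))) stop("oscillator state must be finite")
  structure(s, class = "oscillator_state")
}

#' Bounded rate quotient of the RCC control
#'
#' \code{q = f / (f + mu_f)}, the proportional measure of filament
#' concentration against its control scale; strictly within [0, 1).
#'
#' @param f filament concentration (>= 0).
#' @param mu_f control half-saturation (> 0).
#' @return Dimensionless quotient in [0, 1).
#' @export
rate_quotient <- function(f, mu_f = 2) {
  if (any(!is.finite(f)) || any(f < 0)) stop("f must be finite and >= 0")
  if (any(!is.finite(mu_f)) || any(mu_f <= 0)) stop("mu_f must be > 0")
  f / (f + mu_f)
}

#' RCC exponential control function
#'
#' \code{sigma = f_scale * exp(xi * q)}.  For \code{xi < 0} this is monotone
#' decreasing in \code{q} and bounded in \code{[f_scale * exp(xi), f_scale]}
#' on \code{q} in [0, 1]; at \code{q = 0} it equals \code{f_scale}.
#'
#' @param q rate quotient in [0, 1).
#' @param f_scale control scale factor.
#' @param xi control exponent (negative slows the controlled production).
#' @return Strictly positive control multiplier.
#' @export
control_sigma <- function(q, f_scale = 1, xi = -1) {
  if (any(!is.finite(q)) || any(!is.finite(f_scale)) || any(!is.finite(xi)))
    stop("non-finite input to control_sigma")
  f_scale * exp(xi * q)
}

#' Vector field of one RCC-controlled Berry oscillator
#'
#' Time derivatives of (m, f, p, g) with external matrix input \code{r_im}.
#' The RCC factors \code{sigma_p(q_f)} and \code{sigma_g(q_f)} multiply the
#' production terms of proteinase and transglutaminase; with control disabled
#' they reduce to the constant scales \code{f_p}, \code{f_g}.
#'
#' @param state an [oscillator_state()] or numeric vector (m, f, p, g).
#' @param bp [berry_params()].
#' @param rcc [rcc_params()].
#' @param r_im external matrix input rate (the bifurcation parameter; in a
#'   network this is the coupling input).
#' @return Named numeric derivative vector (dm, df, dp, dg).
#' @export
berry_derivatives <- function(state, bp = berry_params(), rcc = rcc_params(),
                              r_im = 0) {
  s <- unclass(state)
  if (length(s) != 4 || any(!is.finite(s)) || !is.finite(r_im))
    stop("state and r_im must be finite; state has 4 components")
  m <- s[[1]]; f <- s[[2]]; p <- s[[3]]; g <- s[[4]]
  if (rcc$enabled) {
    q <- f / (f + rcc$mu_f)
    sp <- rcc$f_p * exp(rcc$xi_p * q)
    sg <- rcc$f_g * exp(rcc$xi_g * q)
  } else {
    sp <- rcc$f_p
    sg <- rcc$f_g
  }
  flux_gf <- bp$k_g * f * g / (bp$K_G + f)
  flux_mp <- m * p / (1 + m)
  fn <- f^bp$hill_n
  fl <- f^bp$hill_l
  c(m = flux_gf - flux_mp + r_im,
    f = -flux_gf + flux_mp - f * p / (1 + f),
    p = sp * bp$gamma * fn / (bp$K_R^bp$hill_n + fn) - bp$k_a * p^2,
    g = sg * bp$beta * fl / (bp$K_S^bp$hill_l + fl) -
      bp$k_deg * g * p / (bp$K_deg + g))
}

#' Chaotic external-input preset for the isolated oscillator
#'
#' A fixed \code{r_im} inside the chaotic domain of the uncontrolled model,
#' located by scanning the largest Lyapunov exponent over the input range
#' (see the methods vignette).  Used as the default for single-oscillator
#' stabilisation runs.
#'
#' @format A single number.
#' @export
r_im_chaotic <- function() 0.01

#' Seedable random initial conditions
#'
#' Initial concentrations are not part of the model definition; transients
#' are discarded by the analysis pipeline.  Draws all 4n components uniformly
#' from (0, 1].
#'
#' @param n number of oscillators.
#' @param seed optional integer seed.
#' @return Numeric vector of length \code{4 * n}, layout
#'   \code{(m_1..m_n, f_1..f_n, p_1..p_n, g_1..g_n)}.
#' @export
random_initial_state <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  1 - stats::runif(4 * n)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
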