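#' Remove the leading transient of a series
#'
#' Drops the leading fraction (default 25%) or a fixed number of samples
#' from an epoch's recorded observable, so that per-epoch statistics are
#' computed on the stabilised oscillation only.
#'
#' @param series numeric vector (non-empty).
#' @param fraction fraction of samples to drop from the front.
#' @param steps fixed number of samples to drop instead (overrides
#'   \code{fraction} when not \code{NULL}).
#' @return The trimmed series.  Trimming the whole series is an error.
#' @export
remove_transient <- function(series, fraction = 0.25, steps = NULL) {
  n <- length(series)
  if (n == 0) stop("empty series")
  k <- if (!is.null(steps)) as.integer(steps) else floor(n * fraction)
  if (k >= n) stop("transient trim (", k, ") >= series length (", n, ")")
  if (k <= 0) series else series[-seq_len(k)]
}

#' Per-epoch peak summaries of a trajectory
#'
#' For every perturbation epoch: removes the transient, takes the maximum of
#' the recorded global observables M and F, classifies the orbit period from
#' the post-transient M peaks, and records the epoch's perturbation (summed
#' absolute value by default -- the scalar used on the x-axis of the
#' perturbation-response plots -- plus the signed sum).
#'
#' @param traj a \code{socrcc_trajectory} from [integrate_epochs()].
#' @param fraction transient fraction per epoch (default 0.25).
#' @param eps_summary how to reduce the per-unit perturbation vector to the
#'   scalar \code{eps}: \code{"sum_abs"} (default) or \code{"sum"}.
#' @param tol relative tolerance of the orbit-level clustering.
#' @param stability_tol relative tolerance of the stability check: an epoch
#'   is stable when the maxima (and minima) of the first and second halves
#'   of its post-transient window agree within this fraction of the
#'   oscillation amplitude.  Stability does not require strict periodicity:
#'   the controlled orbits remain weakly chaotic, so \code{orbit_period}
#'   can be NA for a stable epoch.
#' @return A data.frame of class \code{epoch_summaries}: one row per epoch
#'   with \code{epoch}, \code{eps}, \code{eps_signed}, \code{max_M},
#'   \code{max_F}, \code{orbit_period} (NA when aperiodic/undetermined) and
#'   \code{stable}.  Epochs whose post-transient window is empty (e.g.
#'   truncated by divergence) are flagged unstable and carry NA maxima.
#' @export
epoch_peaks <- function(traj, fraction = 0.25,
                        eps_summary = c("sum_abs", "sum"), tol = 0.01,
                        stability_tol = 0.05) {
  eps_summary <- match.arg(eps_summary)
  n_epochs <- nrow(traj$eps_matrix)
  out <- data.frame(epoch = seq_len(n_epochs),
                    eps = if (eps_summary == "sum_abs")
                            rowSums(abs(traj$eps_matrix))
                          else rowSums(traj$eps_matrix),
                    eps_signed = rowSums(traj$eps_matrix),
                    max_M = NA_real_, max_F = NA_real_,
                    orbit_period = NA_integer_, stable = FALSE)
  for (e in seq_len(n_epochs)) {
    sel <- traj$epoch == e
    if (!any(sel)) next
    M <- traj$M[sel]
    k <- floor(length(M) * fraction)
    full <- traj$schedule$redraw_interval %/% max(1L, traj$spec$record_stride)
    if (length(M) - k < max(2, 0.5 * (full - floor(full * fraction)))) next
    Mp <- if (k > 0) M[-seq_len(k)] else M
    Fp <- traj$F[sel]
    Fp <- if (k > 0) Fp[-seq_len(k)] else Fp
    out$max_M[e] <- max(Mp)
    out$max_F[e] <- max(Fp)
    per <- tryCatch(classify_orbit(Mp, tol = tol), error = function(err) NA)
    out$orbit_period[e] <- if (is.na(per)) NA_integer_ else as.integer(per)
    # stationary envelope: halves of the settled window agree
    h <- length(Mp) %/% 2
    amp <- max(max(Mp) - min(Mp), abs(max(Mp)) * 1e-9)
    a1 <- Mp[seq_len(h)]; a2 <- Mp[(h + 1):length(Mp)]
    settled <- abs(max(a1) - max(a2)) <= stability_tol * amp &&
               abs(min(a1) - min(a2)) <= stability_tol * amp
    out$stable[e] <- is.finite(out$max_M[e]) && settled
  }
  class(out) <- c("epoch_summaries", "data.frame")
  out
}

#' Orbit period from peak-level clustering
#'
#' Detects local maxima of a (post-transient) oscillatory series, clusters
#' their heights at a relative tolerance, and returns the number of distinct
#' alternating peak levels: 1 for a simple limit cycle, 2 for a
#' period-doubled two-orbit, and so on.  A peak sequence that does not
#' repeat with the period implied by the number of levels is aperiodic
#' (returns \code{NA}).
#'
#' @param series numeric vector containing at least 4 local maxima.
#' @param tol relative tolerance (fraction of the peak amplitude range)
#'   within which two peak heights belong to the same level; default 1%.
#' @return Integer period count, or \code{NA} for aperiodic structure.
#' @export
classify_orbit <- function(series, tol = 0.01) {
  pk_idx <- which(diff(sign(diff(series))) == -2) + 1L
  if (length(pk_idx) < 4)
    stop("fewer than 4 local maxima: orbit period undetermined")
  pk <- series[pk_idx]
  rng <- max(pk) - min(pk)
  # tolerance is relative to the oscillation amplitude of the series itself
  amp <- max(max(series) - min(series), abs(max(series)) * 1e-9,
             .Machine$double.eps)
  if (rng <= tol * amp)
    return(1L)                      # all peaks at one level
  # cluster peak heights: split sorted heights at gaps larger than tol*amp
  s <- sort(pk)
  breaks <- which(diff(s) > tol * amp)
  n_levels <- length(breaks) + 1L
  bounds <- c(-Inf, (s[breaks] + s[breaks + 1]) / 2, Inf)
  labels <- findInterval(pk, bounds)
  # periodic iff the label sequence repeats with period n_levels
  if (n_levels > 1 && n_levels <= length(pk) / 2) {
    lag <- labels[-seq_len(n_levels)] == labels[seq_len(length(labels) - n_levels)]
    if (all(lag)) return(as.integer(n_levels))
    return(NA_integer_)
  }
  if (n_levels == 1L) return(1L)
  NA_integer_
}

#' Local largest-Lyapunov-exponent estimates along a trajectory
#'
#' Propagates a tangent vector along a sampled trajectory through the
#' linearised flow (Jacobian by central finite differences, refreshed every
#' step), renormalising every \code{window} steps; each window's logarithmic
#' growth rate is one local estimate of the largest Lyapunov exponent.
#'
#' @param deriv function \code{(t, state) -> derivative} of the system.
#' @param trajectory matrix of states (rows = samples at spacing \code{dt}).
#' @param dt time between consecutive trajectory rows.
#' @param window steps between renormalisations (one estimate per window).
#' @return Numeric vector of window-local exponents (per unit time).  A
#'   degenerate (fixed-point) trajectory yields non-positive estimates with
#'   a warning.
#' @export
lyapunov_local <- function(deriv, trajectory, dt, window = 50L) {
  trajectory <- as.matrix(trajectory)
  n_steps <- nrow(trajectory) - 1L
  d <- ncol(trajectory)
  if (n_steps < window) stop("trajectory shorter than one window")
  u <- rep(1 / sqrt(d), d)
  eps_fd <- 1e-6
  jac <- function(t, x) {
    J <- matrix(0, d, d)
    for (j in seq_len(d)) {
      h <- eps_fd * max(1, abs(x[j]))
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      J[, j] <- (deriv(t, xp) - deriv(t, xm)) / (2 * h)
    }
    J
  }
  out <- numeric(0)
  acc <- 0
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    J <- jac(t, trajectory[s, ])
    # RK4 on the linearised system u' = J u (J frozen over the step)
    k1 <- J %*% u
    k2 <- J %*% (u + dt / 2 * k1)
    k3 <- J %*% (u + dt / 2 * k2)
    k4 <- J %*% (u + dt * k3)
    u <- u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    u <- as.vector(u)
    if (s %% window == 0L) {
      nrm <- sqrt(sum(u^2))
      out <- c(out, log(nrm) / (window * dt))
      u <- u / nrm
    }
  }
  traj_spread <- max(apply(trajectory, 2, function(col) diff(range(col))))
  if (traj_spread < 1e-10 && all(out <= 0))
    warning("degenerate (fixed-point) trajectory: all local estimates <= 0")
  out
}

#' Hurwitz zeta function
#'
#' \eqn{\zeta(s, a) = \sum_{k \ge 0} (a + k)^{-s}} for \eqn{s > 1},
#' \eqn{a > 0}, by Euler-Maclaurin summation.  Used by the discrete
#' power-law likelihood.
#'
#' @param s exponent (> 1).
#' @param a offset (> 0).
#' @param N direct-summation cutoff before the tail correction.
#' @return The zeta value.
#' @export
hurwitz_zeta <- function(s, a, N = 25L) {
  stopifnot(s > 1, a > 0)
  k <- 0:(N - 1)
  direct <- sum((a + k)^(-s))
  aN <- a + N
  tail <- aN^(1 - s) / (s - 1) + 0.5 * aN^(-s)
  # Bernoulli corrections B2 = 1/6, B4 = -1/30
  t1 <- s * aN^(-s - 1) / 12
  t2 <- -s * (s + 1) * (s + 2) * aN^(-s - 3) / 720
  direct + tail + t1 + t2
}

#' Maximum-likelihood power-law fit with KS-selected cutoff
#'
#' Fits the tail of a positive sample to a power law
#' \eqn{p(x) \propto x^{-\alpha}} for \eqn{x \ge x_{min}}: for every
#' candidate cutoff taken from the observed values, the exponent is
#' estimated by maximum likelihood (continuous form: the closed expression
#' \eqn{\hat\alpha = 1 + n / \sum \ln(x_i / x_{min})}; discrete form:
#' numerical maximisation of
#' \eqn{L(\alpha) = -n \ln \zeta(\alpha, x_{min}) - \alpha \sum \ln x_i}
#' with the Hurwitz zeta), the Kolmogorov-Smirnov distance between the
#' empirical and fitted tail CDFs is computed, and the fit with minimal KS
#' distance is returned.
#'
#' @param x positive sample (at least 5 values).
#' @param discrete logical; use the discrete (zeta) likelihood.  Continuous
#'   is the default: oscillation amplitudes are continuous quantities.
#' @param x_min_candidates optional explicit candidate cutoffs; defaults to
#'   the unique observed values that leave at least 2 tail samples.
#' @return Object of class \code{powerlaw_fit}: list with \code{alpha},
#'   \code{x_min}, \code{ks_distance}, \code{log_likelihood}, \code{n_tail},
#'   and \code{discrete}.
#' @export
powerlaw_mle <- function(x, discrete = FALSE, x_min_candidates = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 positive samples")
  if (any(x <= 0)) stop("samples must be strictly positive")
  if (diff(range(x)) == 0) stop("degenerate sample: all values equal")
  cand <- sort(unique(if (is.null(x_min_candidates)) x else x_min_candidates))
  cand <- cand[vapply(cand, function(xm) sum(x >= xm) >= 2, logical(1))]
  if (!length(cand)) stop("no candidate x_min leaves a tail of size >= 2")
  best <- NULL
  for (xm in cand) {
    tail_x <- x[x >= xm]
    n <- length(tail_x)
    slog <- sum(log(tail_x / xm))
    if (slog <= 0) next
    if (!discrete) {
      alpha <- 1 + n / slog
      ll <- n * log(alpha - 1) - n * log(xm) - alpha * slog
      # KS distance, continuous tail CDF 1 - (x/xm)^(1-alpha)
      xs <- sort(tail_x)
      emp_hi <- seq_len(n) / n
      emp_lo <- (seq_len(n) - 1) / n
      fit_cdf <- 1 - (xs / xm)^(1 - alpha)
      ks <- max(pmax(abs(emp_hi - fit_cdf), abs(emp_lo - fit_cdf)))
    } else {
      nll <- function(a) n * log(hurwitz_zeta(a, xm)) + a * sum(log(tail_x))
      opt <- stats::optimize(nll, c(1.0001, 20))
      alpha <- opt$minimum
      ll <- -opt$objective
      xs <- sort(unique(round(tail_x)))
      xs <- xs[xs >= xm]
      if (length(xs) < 2) next
      zx <- hurwitz_zeta(alpha, xm)
      pmf <- vapply(xs, function(v) v^(-alpha) / zx, numeric(1))
      fit_cdf <- cumsum(pmf)
      emp_cdf <- vapply(xs, function(v) mean(round(tail_x) <= v), numeric(1))
      ks <- max(abs(emp_cdf - fit_cdf))
    }
    if (is.null(best) || ks < best$ks_distance)
      best <- list(alpha = alpha, x_min = xm, ks_distance = ks,
                   log_likelihood = ll, n_tail = n, discrete = discrete)
  }
  if (is.null(best)) stop("power-law fit failed on all candidate cutoffs")
  class(best) <- "powerlaw_fit"
  best
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha=%.4g x_min=%.4g KS=%.4g n_tail=%d (%s)\n",
              x$alpha, x$x_min, x$ks_distance, x$n_tail,
              if (x$discrete) "discrete" else "continuous"))
  invisible(x)
}

#' Least-squares power or exponential curve fit
#'
#' Fits \code{y = a * x^b} (power) or \code{y = a * exp(b * x)}
#' (exponential) by linear regression on the log scale, refined by
#' nonlinear least squares on the original scale; reports the coefficients,
#' the mean squared error on the original scale, and AIC/BIC from the MSE
#' (see [information_criteria()]).  The log-log slope of the initial linear
#' fit is reported alongside (\code{loglog_slope}) since tail-estimation
#' slopes are quoted in both conventions in the literature.
#'
#' @param x predictor (strictly positive for the power form).
#' @param y response.
#' @param form \code{"power"} or \code{"exponential"}.
#' @return Object of class \code{curve_fit}: list with \code{form},
#'   \code{a}, \code{b}, \code{mse}, \code{aic}, \code{bic}, \code{n},
#'   \code{k} (= 2), \code{loglog_slope}, and \code{fitted}.
#' @export
fit_curve <- function(x, y, form = c("power", "exponential")) {
  form <- match.arg(form)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (form == "power" && any(x <= 0)) stop("power form requires x > 0")
  k <- 2L
  n <- length(x)
  if (all(y > 0)) {
    lf <- if (form == "power") stats::lm(log(y) ~ log(x))
          else stats::lm(log(y) ~ x)
    a0 <- exp(coef(lf)[[1]]); b0 <- coef(lf)[[2]]
  } else {
    # log-transform unavailable: crude direct start
    a0 <- max(abs(y)); b0 <- if (form == "power") -0.5 else -0.1
    lf <- NULL
  }
  predfun <- if (form == "power") function(a, b) a * x^b
             else function(a, b) a * exp(b * x)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ predfun(a, b), start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    a <- coef(fit)[["a"]]; b <- coef(fit)[["b"]]
  } else {
    a <- a0; b <- b0
  }
  yhat <- predfun(a, b)
  mse <- mean((y - yhat)^2)
  ic <- if (mse > 0) information_criteria(mse, n, k)
        else c(aic = NA_real_, bic = NA_real_)
  structure(list(form = form, a = a, b = b, mse = mse,
                 aic = ic[["aic"]], bic = ic[["bic"]], n = n, k = k,
                 loglog_slope = if (!is.null(lf)) coef(lf)[[2]] else NA_real_,
                 fitted = yhat),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit %s> a=%.4g b=%.4g mse=%.4g aic=%.4g bic=%.4g\n",
              x$form, x$a, x$b, x$mse, x$aic, x$bic))
  invisible(x)
}

#' MSE-based information criteria
#'
#' \code{aic = -n*log(mse) + 2k} and \code{bic = -n*log(mse) + k*log(n)}.
#' Note the sign of the \code{n*log(mse)} term: this (default) convention
#' makes the criteria *larger* for better fits, the opposite of the
#' textbook \code{n*log(mse) + 2k} form, which is available with
#' \code{conventional = TRUE}.
#'
#' @param mse mean squared error (> 0; a perfect fit has no defined value).
#' @param n sample size (> k).
#' @param k number of fitted parameters.
#' @param conventional logical; use the textbook sign convention.
#' @return Named vector \code{c(aic = , bic = )}.
#' @export
information_criteria <- function(mse, n, k = 2L, conventional = FALSE) {
  if (!is.finite(mse) || mse <= 0)
    stop("mse must be > 0 (a perfect fit has undefined criteria here)")
  if (n <= k) stop("need n > k")
  term <- n * log(mse)
  if (conventional) c(aic = term + 2 * k, bic = term + k * log(n))
  else c(aic = -term + 2 * k, bic = -term + k * log(n))
}

#' Changepoint of the perturbation-response relation
#'
#' Locates the perturbation level that best splits the (eps, max M) relation
#' into two power-law domains: every candidate split (quantile grid) fits a
#' power curve to each side on the log scale, and the split minimising the
#' pooled log-scale residual sum of squares is returned.
#'
#' @param eps positive perturbation magnitudes.
#' @param max_M corresponding per-epoch maxima.
#' @param min_frac smallest fraction of points allowed on either side.
#' @param n_grid number of candidate splits.
#' @return List with \code{split} (the eps value), \code{lower} and
#'   \code{upper} (the two [fit_curve()] power fits).
#' @export
detect_domain_split <- function(eps, max_M, min_frac = 0.2, n_grid = 25L) {
  ok <- is.finite(eps) & is.finite(max_M) & eps > 0 & max_M > 0
  eps <- eps[ok]; max_M <- max_M[ok]
  n <- length(eps)
  if (n < 10) stop("need at least 10 points for a domain split")
  cand <- stats::quantile(eps, probs = seq(min_frac, 1 - min_frac,
                                           length.out = n_grid))
  best <- NULL
  for (sp in unique(cand)) {
    lo <- eps <= sp
    if (sum(lo) < 5 || sum(!lo) < 5) next
    sse <- function(sel) {
      f <- stats::lm(log(max_M[sel]) ~ log(eps[sel]))
      sum(stats::resid(f)^2)
    }
    tot <- sse(lo) + sse(!lo)
    if (is.null(best) || tot < best$sse) best <- list(split = sp, sse = tot)
  }
  if (is.null(best)) stop("no admissible split found")
  lo <- eps <= best$split
  list(split = unname(best$split),
       lower = fit_curve(eps[lo], max_M[lo], "power"),
       upper = fit_curve(eps[!lo], max_M[!lo], "power"))
}
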