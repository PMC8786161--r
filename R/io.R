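#' Serialise a network configuration (with schedule and integrator) to YAML
#'
#' Flat config layout: \code{model} (Berry parameters), \code{control}
#' (RCC), \code{network}, \code{schedule}, \code{integrator}.  The named
#' preset \code{"berry-2022"} carries the standard parameter set.
#'
#' @param cfg a [network_config()].
#' @param schedule a [perturbation_schedule()].
#' @param spec an [integrator_spec()].
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, schedule, spec, path) {
  obj <- list(
    preset = "berry-2022",
    model = cfg$bp[names(cfg$bp)],
    control = cfg$rcc[names(cfg$rcc)],
    network = list(n_units = cfg$n_units, weights = cfg$weights,
                   column_scales = cfg$column_scales,
                   feedback_v = cfg$feedback_v,
                   coupling_mode = cfg$coupling_mode,
                   r_im_base = cfg$r_im_base,
                   grid_shape = cfg$grid_shape),
    schedule = schedule[names(schedule)],
    integrator = spec[names(spec)])
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a YAML configuration written by [write_config()]
#'
#' @param path config file.
#' @return List with \code{cfg}, \code{schedule}, \code{spec}.
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  bp <- do.call(berry_params, obj$model)
  rcc <- do.call(rcc_params, obj$control)
  nw <- obj$network
  cfg <- network_config(nw$n_units, weights = nw$weights,
                        column_scales = nw$column_scales,
                        feedback_v = nw$feedback_v,
                        coupling_mode = nw$coupling_mode,
                        r_im_base = nw$r_im_base,
                        bp = bp, rcc = rcc, grid_shape = nw$grid_shape)
  sched <- do.call(perturbation_schedule, obj$schedule)
  spec <- do.call(integrator_spec, obj$integrator)
  list(cfg = cfg, schedule = sched, spec = spec)
}

#' Write a trajectory as tidy CSV
#'
#' Long format: one row per recorded sample with \code{t}, \code{epoch},
#' \code{M}, \code{F}, and (when per-unit series were recorded) one row per
#' unit with \code{unit}, \code{m}, \code{f}.
#'
#' @param traj a \code{socrcc_trajectory}.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!is.null(traj$m_units)) {
    n <- ncol(traj$m_units)
    df <- data.frame(
      t = rep(traj$time, n),
      epoch = rep(traj$epoch, n),
      unit = rep(seq_len(n), each = length(traj$time)),
      m = as.vector(traj$m_units),
      f = as.vector(traj$f_units))
  } else {
    df <- data.frame(t = traj$time, epoch = traj$epoch,
                     M = traj$M, F = traj$F)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment result bundle (CSV summaries + JSON report)
#'
#' @param res an \code{experiment_result} from [run_experiment()].
#' @param out_dir output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res$summaries),
                   file.path(out_dir, "epoch_summaries.csv"),
                   row.names = FALSE)
  write_trajectory_csv(res$trajectory,
                       file.path(out_dir, "trajectory.csv"))
  fit_json <- function(f) if (is.null(f)) NULL else
    f[c("form", "a", "b", "mse", "aic", "bic", "loglog_slope")]
  report <- list(
    preset = res$preset$name,
    n_epochs = nrow(res$summaries),
    n_stable = sum(res$summaries$stable),
    diverged = res$diverged,
    singularity = res$singularity,
    power_fit = fit_json(res$power_fit),
    exponential_fit = fit_json(res$exp_fit),
    power_fit_conventional_ic = if (!is.null(res$power_fit) &&
                                    res$power_fit$mse > 0)
      as.list(information_criteria(res$power_fit$mse, res$power_fit$n,
                                   res$power_fit$k, conventional = TRUE)),
    tail_mle = if (!is.null(res$tail_fit))
      res$tail_fit[c("alpha", "x_min", "ks_distance", "log_likelihood",
                     "n_tail")])
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
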