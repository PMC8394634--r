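#' Configuration for a phantom reconstruction experiment
#'
#' Assembles and validates the configuration driving
#' [run_ct_experiment()] and [run_parameter_sweep()]. Defaults reproduce
#' the packaged numerical-phantom study: 128 x 128 modified Shepp-Logan
#' phantom, 180 views x 184 bins over 180 degrees, 200 iterations with
#' `h = 1`, checkpoints at 50/100/200, and (for the noisy study) white
#' Gaussian noise at 30 dB SNR. One master `seed` drives noise generation;
#' reconstruction itself is deterministic.
#'
#' @param image_size,n_views,n_bins geometry of the study.
#' @param snr_db noise level in dB or `NULL` for noise-free projections.
#' @param seed master seed for the noise realization.
#' @param param_sets named list of `c(gamma, alpha)` pairs to reconstruct
#'   with; MLEM `(1, 1)` is always included under the name `"MLEM"`.
#' @param h relaxation parameter (default 1).
#' @param n_iter iteration count (default 200).
#' @param checkpoints iteration numbers reported in the summary tables.
#' @param z0 initial constant (`NULL` for the scaled flat start).
#' @return a validated config list of class `ct_experiment_config`.
#' @export
ct_experiment_config <- function(image_size = 128L, n_views = 180L,
                                 n_bins = 184L, snr_db = 30, seed = 1L,
                                 param_sets = list(
                                   "PDEM(0.8,1.2)" = c(0.8, 1.2),
                                   "PDEM(0.5,1.2)" = c(0.5, 1.2),
                                   "PDEM(0.3,1.2)" = c(0.3, 1.2)),
                                 h = 1, n_iter = 200L,
                                 checkpoints = c(50L, 100L, 200L),
                                 z0 = NULL) {
  if (!is.null(snr_db) && (!is.numeric(snr_db) || !is.finite(snr_db)))
    stop("config field 'snr_db' must be a finite number or NULL", call. = FALSE)
  if (!is.list(param_sets) || (length(param_sets) && is.null(names(param_sets))))
    stop("config field 'param_sets' must be a named list of c(gamma, alpha)",
         call. = FALSE)
  for (nm in names(param_sets)) {
    p <- param_sets[[nm]]
    if (!is.numeric(p) || length(p) != 2L)
      stop(sprintf("config field 'param_sets$%s' must be c(gamma, alpha)", nm),
           call. = FALSE)
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  n_iter <- max(as.integer(n_iter), checkpoints)
  if (any(checkpoints < 0L))
    stop("config field 'checkpoints' must be nonnegative", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size), n_views = as.integer(n_views),
    n_bins = as.integer(n_bins), snr_db = snr_db, seed = as.integer(seed),
    param_sets = param_sets, h = h, n_iter = n_iter,
    checkpoints = checkpoints, z0 = z0
  ), class = "ct_experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Accepts the keys of [ct_experiment_config()]; `param_sets` is a mapping
#' from algorithm label to a two-element `[gamma, alpha]` sequence.
#'
#' @param path YAML file path.
#' @return a `ct_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ct_experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (!is.null(raw$param_sets))
    raw$param_sets <- lapply(raw$param_sets, as.numeric)
  do.call(ct_experiment_config, raw)
}

#' Run a phantom reconstruction experiment
#'
#' Generates the phantom and sinogram(s) defined by the config, reconstructs
#' with MLEM and every configured PDEM parameter set, and summarizes the
#' evaluation function `E` and SSIM at the configured checkpoints. Fully
#' reproducible from the config (the only stochastic element is the noise
#' realization, driven by `config$seed`).
#'
#' @param config a [ct_experiment_config()] (or a YAML path understood by
#'   [read_experiment_config()]).
#' @param system optional precomputed system matrix for the config geometry,
#'   reused across calls (e.g. across noise seeds).
#' @param out_dir optional directory; when given, metric logs
#'   (`metrics_<label>.csv` with columns `n,E,V,SSIM`), the summary table
#'   (`summary.csv`) and a provenance YAML are written there.
#' @return list with `traces` (named list of `pdem_trace`), `summary`
#'   (data.frame: label, gamma, alpha, checkpoint `N`, `E`, `SSIM`),
#'   `phantom`, `y`, `system`, `config`.
#' @export
run_ct_experiment <- function(config, system = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (!inherits(config, "ct_experiment_config"))
    stop("'config' must be a ct_experiment_config or a YAML path", call. = FALSE)
  geom <- ct_geometry(config$n_views, config$n_bins, config$image_size)
  sim <- simulate_ct_data(geom, snr_db = config$snr_db, seed = config$seed,
                          system = system)

  algos <- c(list(MLEM = c(1, 1)), config$param_sets)
  algos <- algos[!duplicated(names(algos))]
  traces <- list()
  rows <- list()
  for (nm in names(algos)) {
    pr <- epdm_params(algos[[nm]][1], algos[[nm]][2], config$h)
    tr <- pdem_reconstruct(sim$system, sim$y, pr, n_iter = config$n_iter,
                           z0 = config$z0, ground_truth = sim$phantom,
                           keep_iterates = config$checkpoints)
    traces[[nm]] <- tr
    ck <- tr$metrics[tr$metrics$n %in% config$checkpoints, ]
    rows[[nm]] <- data.frame(label = nm, gamma = pr$gamma, alpha = pr$alpha,
                             N = ck$n, E = ck$E, SSIM = ck$SSIM,
                             row.names = NULL)
  }
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  res <- list(traces = traces, summary = summary, phantom = sim$phantom,
              y = sim$y, system = sim$system, config = config)
  if (!is.null(out_dir)) write_experiment_outputs(res, out_dir)
  res
}

write_experiment_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$traces)) {
    m <- res$traces[[nm]]$metrics[, c("n", "E", "V", "SSIM")]
    utils::write.csv(m, file.path(out_dir, paste0(
      "metrics_", gsub("[^A-Za-z0-9._-]", "_", nm), ".csv")),
      row.names = FALSE)
  }
  utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  cfg <- res$config
  yaml::write_yaml(list(
    image_size = cfg$image_size, n_views = cfg$n_views, n_bins = cfg$n_bins,
    snr_db = if (is.null(cfg$snr_db)) "noise-free" else cfg$snr_db,
    seed = cfg$seed, h = cfg$h, n_iter = cfg$n_iter,
    checkpoints = cfg$checkpoints,
    param_sets = lapply(res$config$param_sets, as.numeric)
  ), file.path(out_dir, "provenance.yaml"))
  invisible(res)
}

#' Sweep the (gamma, alpha) parameter plane
#'
#' Reconstructs the configured study once per grid point and records
#' `log10(E(z(N)))` at each checkpoint `N`. A single system matrix and a
#' single sinogram (one shared noise realization, when `snr_db` is set) are
#' reused across the whole grid. Grid points whose reconstruction fails are
#' recorded as `NA` with the error message, and the sweep continues.
#'
#' @param config a [ct_experiment_config()]; its `param_sets` are ignored.
#' @param gamma_grid,alpha_grid sampled parameter values.
#' @param system optional precomputed system matrix.
#' @return object of class `ct_sweep`: list with `gamma_grid`, `alpha_grid`,
#'   `checkpoints`, `log10_E` (3-d array gamma x alpha x checkpoint),
#'   `E` (same shape, raw values), `failures` (data.frame, possibly empty),
#'   and `mlem_point` (the `(1, 1)` grid location, or `NA`s if absent).
#' @export
run_parameter_sweep <- function(config,
                                gamma_grid = seq(0.1, 1.5, by = 0.1),
                                alpha_grid = seq(0, 1.4, by = 0.1),
                                system = NULL) {
  if (!inherits(config, "ct_experiment_config"))
    stop("'config' must be a ct_experiment_config", call. = FALSE)
  if (!length(gamma_grid) || !length(alpha_grid))
    stop("parameter grids must be nonempty", call. = FALSE)
  geom <- ct_geometry(config$n_views, config$n_bins, config$image_size)
  sim <- simulate_ct_data(geom, snr_db = config$snr_db, seed = config$seed,
                          system = system)
  cps <- config$checkpoints
  E <- array(NA_real_, dim = c(length(gamma_grid), length(alpha_grid),
                               length(cps)),
             dimnames = list(gamma = gamma_grid, alpha = alpha_grid, N = cps))
  fails <- list()
  for (gi in seq_along(gamma_grid)) for (ai in seq_along(alpha_grid)) {
    pr <- epdm_params(gamma_grid[gi], alpha_grid[ai], config$h)
    tr <- tryCatch(
      pdem_reconstruct(sim$system, sim$y, pr, n_iter = config$n_iter,
                       z0 = config$z0, ground_truth = sim$phantom),
      error = function(e) e)
    if (inherits(tr, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        gamma = gamma_grid[gi], alpha = alpha_grid[ai],
        message = conditionMessage(tr))
      next
    }
    E[gi, ai, ] <- tr$metrics$E[match(cps, tr$metrics$n)]
  }
  structure(list(
    gamma_grid = gamma_grid, alpha_grid = alpha_grid, checkpoints = cps,
    E = E, log10_E = log10(E),
    failures = if (length(fails)) do.call(rbind, fails)
               else data.frame(gamma = numeric(), alpha = numeric(),
                               message = character()),
    mlem_point = c(gamma = if (any(gamma_grid == 1)) 1 else NA_real_,
                   alpha = if (any(alpha_grid == 1)) 1 else NA_real_)
  ), class = "ct_sweep")
}

#' Minimizing grid point of a parameter sweep
#'
#' @param sweep a [run_parameter_sweep()] result.
#' @param checkpoint one of the sweep's checkpoints.
#' @return named vector `c(gamma, alpha, E)` at the grid minimum of
#'   `E(z(checkpoint))`.
#' @export
sweep_argmin <- function(sweep, checkpoint) {
  ci <- match(checkpoint, sweep$checkpoints)
  if (is.na(ci)) stop("'checkpoint' not in sweep", call. = FALSE)
  M <- sweep$E[, , ci]
  idx <- which(M == min(M, na.rm = TRUE), arr.ind = TRUE)[1, ]
  c(gamma = sweep$gamma_grid[idx[1]], alpha = sweep$alpha_grid[idx[2]],
    E = M[idx[1], idx[2]])
}

#' Contour plot of a sweep checkpoint
#'
#' Draws `log10(E(z(N)))` over the `(gamma, alpha)` plane, marking the MLEM
#' point `(1, 1)` with a white dot when it lies on the grid.
#'
#' @inheritParams sweep_argmin
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot_sweep <- function(sweep, checkpoint, ...) {
  ci <- match(checkpoint, sweep$checkpoints)
  if (is.na(ci)) stop("'checkpoint' not in sweep", call. = FALSE)
  graphics::filled.contour(
    sweep$gamma_grid, sweep$alpha_grid, sweep$log10_E[, , ci],
    xlab = expression(gamma), ylab = expression(alpha),
    main = sprintf("log10 E(z(%d))", checkpoint),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      if (!anyNA(sweep$mlem_point))
        graphics::points(sweep$mlem_point[1], sweep$mlem_point[2],
                         pch = 21, bg = "white")
    }, ...)
  invisible(sweep)
}
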