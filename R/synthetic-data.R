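#' Ground truth for synthetic data generation
#'
#' Bundles the generating model, true parameters, and the heterogeneity /
#' noise model used to emulate single-cell kinase-activity-reporter data.
#' Cell-to-cell variability is modeled as i.i.d. lognormal perturbation
#' factors (mean 1, coefficient of variation `cell_cv`) applied to every
#' kinetic parameter; measurement noise is additive Gaussian on the
#' normalized-activity scale.
#'
#' @param model a `signaling_model` (see [build_model()]).
#' @param theta_true true parameter vector; defaults to the model nominals.
#' @param cell_cv coefficient of variation of per-cell parameter
#'   perturbations (default 0.15).
#' @param noise_sd measurement noise standard deviation in normalized units
#'   (default 0.05 for trajectories; dose-response data conventionally uses
#'   0.1 -- see [generate_dose_response_data()]).
#' @param seed integer root seed; all per-cell random streams are derived
#'   deterministically from it.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(model, theta_true = model$params_nominal,
                            cell_cv = 0.15, noise_sd = 0.05, seed = 1L) {
  stopifnot(cell_cv >= 0, noise_sd >= 0)
  structure(list(model = model, theta_true = theta_true,
                 cell_cv = cell_cv, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Calibration dataset container
#'
#' @param design design points: times in minutes (`kind = "trajectory"`) or
#'   EGF doses in nM (`kind = "dose_response"`).
#' @param y observations (normalized, dimensionless).
#' @param sigma per-point standard deviations (all > 0).
#' @param kind `"trajectory"` or `"dose_response"`.
#' @param egf EGF dose in nM driving a trajectory dataset (ignored for
#'   dose-response data, whose doses are the design points).
#' @param rap1_inhibited if `TRUE`, the dataset was recorded under Rap1
#'   inhibition: model predictions for it must zero the total Rap1
#'   concentration.
#' @param location subcellular location label (e.g. `"CYTO"`, `"PM"`).
#' @return an object of class `calibration_data` with `n_train` points.
#' @export
calibration_data <- function(design, y, sigma,
                             kind = c("trajectory", "dose_response"),
                             egf = 0.1, rap1_inhibited = FALSE,
                             location = "CYTO") {
  kind <- match.arg(kind)
  stopifnot(length(design) == length(y), length(y) == length(sigma),
            all(sigma > 0))
  structure(list(design = as.numeric(design), y = as.numeric(y),
                 sigma = as.numeric(sigma), kind = kind,
                 n_train = length(y), egf = egf,
                 rap1_inhibited = isTRUE(rap1_inhibited),
                 location = location),
            class = "calibration_data")
}

#' @export
print.calibration_data <- function(x, ...) {
  cat(sprintf("<calibration_data: %s, %d points%s%s>\n", x$kind, x$n_train,
              if (x$kind == "trajectory") sprintf(", EGF %g nM", x$egf) else "",
              if (x$rap1_inhibited) ", Rap1-inhibited" else ""))
  invisible(x)
}

#' Default EGF dose levels for dose-response data
#'
#' Ten levels log-spaced over 0.001 to 0.106 nM.
#'
#' @param n number of levels.
#' @return numeric vector of doses (nM).
#' @export
default_egf_levels <- function(n = 10) {
  10^seq(log10(0.001), log10(0.106), length.out = n)
}

#' Generate a synthetic EGF-ERK dose-response dataset
#'
#' Computes the generating model's normalized steady-state dose-response
#' curve and adds i.i.d. mean-zero Gaussian noise.
#'
#' @param truth a [synthetic_truth()]; its `noise_sd` is used unless
#'   `noise_sd` is given (dose-response data conventionally uses 0.1).
#' @param egf_levels EGF doses in nM (default [default_egf_levels()]).
#' @param noise_sd measurement noise sd (default 0.1).
#' @param seed integer seed (default `truth$seed`).
#' @param settings a [solver_settings()].
#' @return a [calibration_data()] of kind `"dose_response"` with attribute
#'   `noiseless` holding the noise-free curve.
#' @export
generate_dose_response_data <- function(truth,
                                        egf_levels = default_egf_levels(),
                                        noise_sd = 0.1, seed = truth$seed,
                                        settings = solver_settings()) {
  curve <- dose_response(truth$model, truth$theta_true, egf_levels,
                         settings = settings)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  y <- as.numeric(curve) + stats::rnorm(length(curve), 0, noise_sd)
  out <- calibration_data(design = egf_levels, y = y,
                          sigma = rep(max(noise_sd, 1e-6), length(y)),
                          kind = "dose_response")
  attr(out, "noiseless") <- as.numeric(curve)
  out
}

#' Single-cell trajectory ensemble container
#'
#' @param times time points in minutes (increasing).
#' @param ratios matrix (cells x time) of emission-ratio-like responses.
#' @param condition condition label (`"EKAR4-only"` or `"+Rap1GAP"`).
#' @param location location label (`"CYTO"` or `"PM"`).
#' @return an object of class `cell_trajectories`.
#' @export
cell_trajectories <- function(times, ratios, condition = "EKAR4-only",
                              location = "CYTO") {
  ratios <- as.matrix(ratios)
  stopifnot(!is.unsorted(times, strictly = TRUE), nrow(ratios) >= 1,
            ncol(ratios) == length(times), all(is.finite(ratios)))
  structure(list(times = as.numeric(times), ratios = ratios,
                 condition = condition, location = location),
            class = "cell_trajectories")
}

#' @export
print.cell_trajectories <- function(x, ...) {
  cat(sprintf("<cell_trajectories: %d cells x %d times, %s, %s>\n",
              nrow(x$ratios), length(x$times), x$condition, x$location))
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng_state <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
.cell_seed <- function(root, i) (as.integer(root) + 7919L * i) %% 2147483587L

#' Generate a synthetic single-cell trajectory ensemble
#'
#' Emulates kinase-activity-reporter (EKAR4-style) emission-ratio data:
#' each cell is simulated at parameters `theta_true` perturbed by i.i.d.
#' lognormal factors of coefficient of variation `truth$cell_cv`, the
#' active-ERK trajectory is mapped to an emission-ratio scale
#' \eqn{R(t) = r_0 + span (aERK/ERK_{tot} + \epsilon)}, with additive
#' Gaussian readout noise \eqn{\epsilon} of sd `truth$noise_sd` (normalized
#' units).  The `"+Rap1GAP"` condition sets the total Rap1 concentration to
#' zero before simulating.  Each cell draws from its own deterministic
#' stream derived from `truth$seed`, so ensembles and their subsets are
#' reproducible.
#'
#' @param truth a [synthetic_truth()].
#' @param n_cells number of cells (default 76).
#' @param t_grid time grid in minutes (default 0 to 40 at 1-min spacing).
#' @param egf EGF dose in nM (default 0.1).
#' @param condition `"EKAR4-only"` or `"+Rap1GAP"`.
#' @param location label stored on the result.
#' @param baseline,span emission-ratio mapping constants.
#' @param settings a [solver_settings()].
#' @return a [cell_trajectories()] object.
#' @export
generate_single_cell_trajectories <- function(truth, n_cells = 76,
                                              t_grid = seq(0, 40, by = 1),
                                              egf = 0.1,
                                              condition = c("EKAR4-only",
                                                            "+Rap1GAP"),
                                              location = "CYTO",
                                              baseline = 1, span = 0.4,
                                              settings = solver_settings()) {
  condition <- match.arg(condition)
  stopifnot(n_cells >= 1)
  model <- truth$model
  theta0 <- truth$theta_true
  if (condition == "+Rap1GAP" && "Rap1_tot" %in% names(theta0))
    theta0[["Rap1_tot"]] <- 0
  erk_tot <- theta0[["ERK_tot"]]
  sdlog <- sqrt(log(1 + truth$cell_cv^2))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  ratios <- matrix(NA_real_, n_cells, length(t_grid))
  for (i in seq_len(n_cells)) {
    set.seed(.cell_seed(truth$seed, i))
    theta_i <- theta0
    if (truth$cell_cv > 0) {
      fac <- stats::rlnorm(length(theta0), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
      theta_i <- theta0 * fac
    }
    tr <- tryCatch(
      simulate_model(model, theta_i, t_grid, egf = egf, settings = settings),
      error = function(e)
        stop(sprintf("integration failure for cell %d: %s", i,
                     conditionMessage(e)), call. = FALSE))
    act <- active_erk(model, tr) / erk_tot
    eps <- stats::rnorm(length(t_grid), 0, truth$noise_sd)
    ratios[i, ] <- baseline + span * (act + eps)
  }
  cell_trajectories(t_grid, ratios, condition = condition,
                    location = location)
}

#' Min-max normalization of single-cell trajectories
#'
#' Maps each cell's trajectory to \[0, 1\] by removing the cell-wise minimum
#' and dividing by the difference between the cell-wise maximum and minimum.
#'
#' @param cells a [cell_trajectories()] object.
#' @return a new `cell_trajectories` with every row spanning \[0, 1\].
#' @export
normalize_min_max <- function(cells) {
  lo <- apply(cells$ratios, 1, min)
  hi <- apply(cells$ratios, 1, max)
  bad <- which(hi <= lo)
  if (length(bad))
    stop(sprintf("degenerate normalization: constant trajectory for cell %d",
                 bad[1]), call. = FALSE)
  out <- cells
  out$ratios <- (cells$ratios - lo) / (hi - lo)
  out
}

#' Mean-max normalization across conditions
#'
#' Divides every trajectory by a single scalar: the mean over all cells of
#' all supplied conditions of the cell-wise (in time) maximum emission
#' ratio.  Using one pooled divisor preserves relative differences between
#' conditions (e.g. with and without Rap1 inhibition).
#'
#' @param cells_by_condition list of [cell_trajectories()] objects.
#' @return list of normalized `cell_trajectories` in the same order.
#' @export
normalize_mean_max <- function(cells_by_condition) {
  stopifnot(length(cells_by_condition) >= 1)
  maxima <- unlist(lapply(cells_by_condition,
                          function(cc) apply(cc$ratios, 1, max)))
  divisor <- mean(maxima)
  if (divisor <= 0)
    stop("degenerate normalization: pooled mean of cell-wise maxima is zero",
         call. = FALSE)
  lapply(cells_by_condition, function(cc) {
    cc$ratios <- cc$ratios / divisor
    cc
  })
}

#' Aggregate single cells into a calibration dataset
#'
#' Computes the cell-wise mean and (sample) standard deviation at each time
#' point.  Setting `sd_halving = TRUE` halves the standard deviation, the
#' convention used for Rap1-inhibition data where normalization inflates the
#' spread.  Zero standard deviations are floored at `1e-6` to keep the
#' Gaussian likelihood proper.
#'
#' @param cells a [cell_trajectories()] with at least two cells.
#' @param sd_halving halve the standard deviation (default `FALSE`).
#' @param egf EGF dose recorded on the resulting dataset.
#' @return a [calibration_data()] of kind `"trajectory"`.
#' @export
aggregate_cells <- function(cells, sd_halving = FALSE, egf = 0.1) {
  if (nrow(cells$ratios) < 2)
    stop("aggregate_cells needs at least 2 cells", call. = FALSE)
  y <- colMeans(cells$ratios)
  s <- apply(cells$ratios, 2, stats::sd)
  if (sd_halving) s <- s / 2
  s <- pmax(s, 1e-6)
  calibration_data(design = cells$times, y = y, sigma = s,
                   kind = "trajectory", egf = egf,
                   rap1_inhibited = identical(cells$condition, "+Rap1GAP"),
                   location = cells$location)
}

#' Truncate a trajectory dataset in time
#'
#' @param data a [calibration_data()] of kind `"trajectory"`.
#' @param t_cut keep points with time at most `t_cut` minutes.
#' @return truncated `calibration_data`.
#' @export
truncate_data <- function(data, t_cut) {
  stopifnot(inherits(data, "calibration_data"))
  keep <- data$design <= t_cut
  if (!any(keep))
    stop("truncation removes every data point", call. = FALSE)
  calibration_data(design = data$design[keep], y = data$y[keep],
                   sigma = data$sigma[keep], kind = data$kind,
                   egf = data$egf, rap1_inhibited = data$rap1_inhibited,
                   location = data$location)
}

#' Draw random cell subsets
#'
#' Draws `n_replicates` independent subsets of `n_subset` cells, each
#' uniformly without replacement, reproducibly under `seed`.
#'
#' @param cells a [cell_trajectories()].
#' @param n_subset subset size (at most the number of cells).
#' @param n_replicates number of replicate subsets (default 40).
#' @param seed integer seed.
#' @return list of `cell_trajectories`, one per replicate.
#' @export
subsample_cells <- function(cells, n_subset, n_replicates = 40, seed = 1L) {
  n_cells <- nrow(cells$ratios)
  if (n_subset > n_cells)
    stop(sprintf("n_subset (%d) exceeds the number of cells (%d)",
                 n_subset, n_cells), call. = FALSE)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  lapply(seq_len(n_replicates), function(b) {
    idx <- sample.int(n_cells, n_subset)
    out <- cells
    out$ratios <- cells$ratios[idx, , drop = FALSE]
    out
  })
}

#' Write / read calibration data as CSV
#'
#' Columns: `design`, `y`, `sigma`, plus constant columns `kind`, `egf`,
#' `rap1_inhibited`, `location`.
#'
#' @param data a [calibration_data()].
#' @param path file path.
#' @return `read_calibration_csv` returns a `calibration_data`.
#' @export
write_calibration_csv <- function(data, path) {
  df <- data.frame(design = data$design, y = data$y, sigma = data$sigma,
                   kind = data$kind, egf = data$egf,
                   rap1_inhibited = data$rap1_inhibited,
                   location = data$location)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  calibration_data(design = df$design, y = df$y, sigma = df$sigma,
                   kind = df$kind[1], egf = df$egf[1],
                   rap1_inhibited = df$rap1_inhibited[1],
                   location = df$location[1])
}

#' Write / read a cell-trajectory ensemble as wide CSV
#'
#' First column `time`, then one column per cell.
#'
#' @param cells a [cell_trajectories()].
#' @param path file path.
#' @param condition,location labels applied on read.
#' @export
write_trajectories_csv <- function(cells, path) {
  df <- data.frame(time = cells$times, t(cells$ratios))
  names(df)[-1] <- paste0("cell_", seq_len(nrow(cells$ratios)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path, condition = "EKAR4-only",
                                  location = "CYTO") {
  df <- utils::read.csv(path)
  cell_trajectories(df$time, t(as.matrix(df[, -1, drop = FALSE])),
                    condition = condition, location = location)
}
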