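#' Full multimodel-inference run on one dataset
#'
#' Per model: SMC calibration, chain-averaged log marginal likelihood, and
#' PSIS-LOO ELPD.  Per weighting method: model weights, a mixture
#' prediction, and error/uncertainty metrics of the mixture against a
#' reference.  Single-model metrics are reported alongside.
#'
#' @param models named list of `signaling_model`s.
#' @param data a [calibration_data()].
#' @param smc an [smc_settings()].
#' @param methods subset of `c("BMA", "PSEUDO_BMA", "PSEUDO_BMA_BB",
#'   "STACKING")`.
#' @param reference vector to score predictions against (default: the
#'   training observations `data$y`).
#' @param n_mix mixture draws per method.
#' @param seed seed for mixture resampling and the Bayesian bootstrap.
#' @param out_dir optional directory; when given, weights, metrics and
#'   ensemble bundles are written there as CSV/JSON.
#' @param solver a [solver_settings()].
#' @return object of class `mmi_report`: `calibrations`, `elpds`,
#'   `log_ml`, `weights` (per method), `mixtures`, `metrics` (data frame),
#'   `model_metrics` (data frame).
#' @export
run_mmi <- function(models, data, smc = smc_settings(),
                    methods = c("BMA", "PSEUDO_BMA", "PSEUDO_BMA_BB",
                                "STACKING"),
                    reference = data$y, n_mix = 2000, seed = 1L,
                    out_dir = NULL, solver = solver_settings()) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "name")
  methods <- match.arg(methods, several.ok = TRUE)
  calibrations <- lapply(models, function(m)
    calibrate_model(m, data, settings = smc, solver = solver))
  report <- .mmi_weights_and_metrics(calibrations, data, methods, reference,
                                     n_mix, seed, solver)
  report$recomputed <- length(models)   # calibration cache accounting
  if (!is.null(out_dir)) .write_mmi_report(report, out_dir)
  report
}

# Weighting + mixture scoring from cached calibrations (no refitting).
.mmi_weights_and_metrics <- function(calibrations, data, methods, reference,
                                     n_mix, seed, solver) {
  model_names <- names(calibrations)
  elpds <- lapply(calibrations, function(ens) psis_loo(ens$pointwise_loglik))
  log_ml <- vapply(calibrations, average_log_ml, numeric(1))
  pushes <- lapply(calibrations, function(ens)
    push_forward(ens, data = data, kind = "push_forward_obs",
                 solver = solver))
  weights <- list()
  for (meth in methods) {
    weights[[meth]] <- switch(meth,
      BMA = bma_weights(log_ml, model_names = model_names),
      PSEUDO_BMA = pseudo_bma_weights(vapply(elpds, `[[`, numeric(1),
                                             "total"),
                                      model_names = model_names),
      PSEUDO_BMA_BB = pseudo_bma_bb_weights(elpds, seed = seed,
                                            model_names = model_names),
      STACKING = stacking_weights(elpds, model_names = model_names))
  }
  mixtures <- lapply(weights, function(w)
    mixture_sample(pushes, w, n_mix = n_mix, seed = seed))
  metrics <- do.call(rbind, lapply(names(mixtures), function(meth) {
    pm <- prediction_metrics(mixtures[[meth]], reference)
    data.frame(method = meth, rmse = pm$rmse,
               relative_error = pm$relative_error,
               mean_ci_width = pm$mean_ci_width)
  }))
  model_metrics <- do.call(rbind, lapply(model_names, function(nm) {
    pm <- prediction_metrics(pushes[[nm]], reference)
    data.frame(model = nm, elpd = elpds[[nm]]$total, log_ml = log_ml[[nm]],
               rmse = pm$rmse, relative_error = pm$relative_error,
               mean_ci_width = pm$mean_ci_width)
  }))
  structure(list(calibrations = calibrations, elpds = elpds,
                 log_ml = log_ml, weights = weights, mixtures = mixtures,
                 pushes = pushes, metrics = metrics,
                 model_metrics = model_metrics, data = data,
                 reference = reference, n_mix = n_mix, seed = seed),
            class = "mmi_report")
}

.write_mmi_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_weights(report$weights, file.path(out_dir, "weights"))
  utils::write.csv(report$metrics, file.path(out_dir, "mmi_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$model_metrics,
                   file.path(out_dir, "model_metrics.csv"),
                   row.names = FALSE)
  for (nm in names(report$calibrations))
    write_ensemble(report$calibrations[[nm]],
                   file.path(out_dir, paste0("ensemble_", nm)))
  invisible(out_dir)
}

#' @export
print.mmi_report <- function(x, ...) {
  cat(sprintf("<mmi_report: %d models, %d data points>\n",
              length(x$calibrations), x$data$n_train))
  print(x$metrics)
  invisible(x)
}

#' All model subsets of a given size
#'
#' @param models list (or vector of names) of models.
#' @param size subset size.
#' @return list of all unordered subsets, in deterministic
#'   (lexicographic-index) order.
#' @export
model_set_combinations <- function(models, size) {
  k <- length(models)
  stopifnot(size >= 1, size <= k)
  idx <- utils::combn(k, size, simplify = FALSE)
  lapply(idx, function(ii) models[ii])
}

#' Model-set perturbation experiment
#'
#' Recomputes weights and mixture metrics after dropping the best- or
#' worst-ELPD model, reusing the cached calibrations of a previous
#' [run_mmi()] report (no model is ever refit; `recomputed` stays 0).
#'
#' @param report an `mmi_report` from [run_mmi()].
#' @param drop `"best_elpd"`, `"worst_elpd"`, or `"none"`.
#' @param methods weighting methods (default: those in the report).
#' @return a new `mmi_report` over the reduced model set, with
#'   `dropped_model` recorded.
#' @export
perturb_model_set <- function(report,
                              drop = c("none", "best_elpd", "worst_elpd"),
                              methods = names(report$weights)) {
  drop <- match.arg(drop)
  totals <- vapply(report$elpds, `[[`, numeric(1), "total")
  keep <- names(report$calibrations)
  dropped <- NULL
  if (drop == "best_elpd") dropped <- names(which.max(totals))
  if (drop == "worst_elpd") dropped <- names(which.min(totals))
  if (!is.null(dropped)) keep <- setdiff(keep, dropped)
  out <- .mmi_weights_and_metrics(report$calibrations[keep], report$data,
                                  methods, report$reference, report$n_mix,
                                  report$seed, solver_settings())
  out$recomputed <- 0L
  out$dropped_model <- dropped
  out
}

#' Data-length robustness experiment
#'
#' For each truncation point, calibrates every model on the truncated
#' trajectory data, predicts the full time grid, and scores error and
#' uncertainty on the held-out test window (times beyond `test_after`).
#'
#' @param models named list of `signaling_model`s.
#' @param data full-length trajectory [calibration_data()].
#' @param cut_points truncation times in minutes (default `c(10, 20, 30)`).
#' @param test_after start of the evaluation window (default 30 min).
#' @param smc an [smc_settings()].
#' @param methods weighting methods.
#' @param reference full-grid reference (default `data$y`).
#' @param seed seed.
#' @return data frame: one row per (cut, method-or-model) with test-window
#'   relative error and mean credible-interval width.
#' @export
data_length_experiment <- function(models, data, cut_points = c(10, 20, 30),
                                   test_after = 30, smc = smc_settings(),
                                   methods = c("PSEUDO_BMA", "BMA",
                                               "STACKING"),
                                   reference = data$y, seed = 1L) {
  test_idx <- which(data$design > test_after)
  if (!length(test_idx)) stop("empty test window", call. = FALSE)
  rows <- list()
  for (tc in cut_points) {
    d_cut <- truncate_data(data, tc)
    calibs <- lapply(models, function(m)
      calibrate_model(m, d_cut, settings = smc))
    # predict on the FULL grid with the truncated-data posteriors
    pushes <- lapply(calibs, function(ens)
      push_forward(ens, data = data, kind = "push_forward_obs"))
    elpds <- lapply(calibs, function(ens) psis_loo(ens$pointwise_loglik))
    log_ml <- vapply(calibs, average_log_ml, numeric(1))
    wts <- list(
      PSEUDO_BMA = pseudo_bma_weights(vapply(elpds, `[[`, numeric(1),
                                             "total"),
                                      model_names = names(models)),
      BMA = bma_weights(log_ml, model_names = names(models)),
      STACKING = stacking_weights(elpds, model_names = names(models)))
    for (meth in methods) {
      mix <- mixture_sample(pushes, wts[[meth]], seed = seed)
      sub <- mix$samples[, test_idx, drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        cut = tc, predictor = meth, type = "mmi",
        relative_error = relative_error(colMeans(sub), reference[test_idx]),
        mean_ci_width = credible_interval_width(sub)$mean_width)
    }
    for (nm in names(models)) {
      sub <- pushes[[nm]]$samples[, test_idx, drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        cut = tc, predictor = nm, type = "single_model",
        relative_error = relative_error(colMeans(sub), reference[test_idx]),
        mean_ci_width = credible_interval_width(sub)$mean_width)
    }
  }
  do.call(rbind, rows)
}

#' Data-quality robustness experiment
#'
#' Emulates decreasing data quality by averaging random subsets of cells:
#' per replicate subset, aggregates, calibrates every model, and scores
#' predictions against the full-ensemble mean.
#'
#' @param models named list of `signaling_model`s.
#' @param cells a [cell_trajectories()] ensemble (the full recording).
#' @param subset_sizes cell counts (default `c(10, 20, 40, 60)`).
#' @param n_replicates replicate subsets per size (default 40).
#' @param smc an [smc_settings()].
#' @param methods weighting methods.
#' @param seed integer seed.
#' @return data frame with replicate-level metrics: one row per (size,
#'   replicate, predictor), including the raw-training-data error
#'   (`predictor = "raw_data"`).
#' @export
data_quality_experiment <- function(models, cells,
                                    subset_sizes = c(10, 20, 40, 60),
                                    n_replicates = 40,
                                    smc = smc_settings(),
                                    methods = c("PSEUDO_BMA", "BMA",
                                                "STACKING"),
                                    seed = 1L) {
  full <- aggregate_cells(cells)
  reference <- full$y
  rows <- list()
  for (sz in subset_sizes) {
    subsets <- subsample_cells(cells, sz, n_replicates,
                               seed = seed + sz)
    for (b in seq_along(subsets)) {
      d_sub <- aggregate_cells(subsets[[b]])
      rows[[length(rows) + 1]] <- data.frame(
        size = sz, replicate = b, predictor = "raw_data", type = "data",
        relative_error = relative_error(d_sub$y, reference),
        mean_ci_width = NA_real_)
      calibs <- lapply(models, function(m)
        calibrate_model(m, d_sub, settings = smc))
      pushes <- lapply(calibs, function(ens)
        push_forward(ens, data = full, kind = "push_forward_obs"))
      elpds <- lapply(calibs, function(ens) psis_loo(ens$pointwise_loglik))
      log_ml <- vapply(calibs, average_log_ml, numeric(1))
      wts <- list(
        PSEUDO_BMA = pseudo_bma_weights(vapply(elpds, `[[`, numeric(1),
                                               "total"),
                                        model_names = names(models)),
        BMA = bma_weights(log_ml, model_names = names(models)),
        STACKING = stacking_weights(elpds, model_names = names(models)))
      for (meth in methods) {
        mix <- mixture_sample(pushes, wts[[meth]], seed = seed + b)
        pm <- prediction_metrics(mix, reference)
        rows[[length(rows) + 1]] <- data.frame(
          size = sz, replicate = b, predictor = meth, type = "mmi",
          relative_error = pm$relative_error,
          mean_ci_width = pm$mean_ci_width)
      }
      for (nm in names(models)) {
        pm <- prediction_metrics(pushes[[nm]], reference)
        rows[[length(rows) + 1]] <- data.frame(
          size = sz, replicate = b, predictor = nm, type = "single_model",
          relative_error = pm$relative_error,
          mean_ci_width = pm$mean_ci_width)
      }
    }
  }
  do.call(rbind, rows)
}

#' Shared-vs-location-specific parameter hypothesis
#'
#' Declares, per parameter group of a model, whether the group's parameters
#' are shared across subcellular locations or estimated independently per
#' location.
#'
#' @param name hypothesis label (e.g. `"Rap1_diff"`).
#' @param archetype model archetype (see [build_model()]).
#' @param location_specific character vector of group names (from the
#'   model's `param_groups`) allowed to vary between locations; all other
#'   groups (and ungrouped parameters) are shared.
#' @return object of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(name, archetype = "RAP1_CASCADE",
                            location_specific = character()) {
  model <- build_model(archetype)
  unknown <- setdiff(location_specific, names(model$param_groups))
  if (length(unknown))
    stop(sprintf("unknown parameter group(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  structure(list(name = name, archetype = archetype,
                 location_specific = location_specific),
            class = "hypothesis_spec")
}

# Coordinate layout of a hypothesis fit: one sampling coordinate per shared
# free parameter, one per (location-specific free parameter, location).
.hypothesis_coords <- function(model, spec, locations) {
  free <- names(model$free_mask)[model$free_mask]
  loc_params <- unlist(model$param_groups[spec$location_specific],
                       use.names = FALSE)
  coords <- list()
  for (p in free) {
    if (p %in% loc_params) {
      for (loc in locations)
        coords[[paste0(p, "@", loc)]] <- list(param = p, location = loc)
    } else {
      coords[[p]] <- list(param = p, location = NA_character_)
    }
  }
  coords
}

#' Fit a parameter-sharing hypothesis jointly to multi-location data
#'
#' Shared groups contribute one sampling coordinate; location-specific
#' groups contribute one per location.  The joint likelihood sums
#' independent pointwise terms over all condition datasets; datasets with
#' `rap1_inhibited = TRUE` zero the total Rap1 concentration in their
#' predictions.
#'
#' Normalization follows the location-study convention: when a location
#' contributes several condition datasets (e.g. with and without Rap1
#' inhibition), the predicted active-ERK trajectories of that location are
#' divided by one shared scalar -- the mean over conditions of the
#' trajectory-wise maximum -- mirroring mean-max-normalized data and
#' preserving relative amplitudes between conditions (which carry the Rap1
#' inhibition signal).  A location with a single dataset falls back to
#' trajectory-max normalization.
#'
#' @param spec a [hypothesis_spec()].
#' @param datasets list of [calibration_data()]s carrying `location` labels.
#' @param smc an [smc_settings()].
#' @param solver a [solver_settings()].
#' @return a `posterior_ensemble` whose pointwise log-likelihood matrix
#'   concatenates all datasets' points (in input order); attribute
#'   `coords` documents the coordinate layout.
#' @export
fit_hypothesis <- function(spec, datasets, smc = smc_settings(),
                           solver = solver_settings()) {
  model <- build_model(spec$archetype)
  locs <- vapply(datasets, `[[`, character(1), "location")
  locations <- unique(locs)
  coords <- .hypothesis_coords(model, spec, locations)
  mu <- vapply(coords, function(cd)
    log(model$params_nominal[[cd$param]]), numeric(1))
  prior <- gaussian_prior(mu, rep(lognormal_prior_scale(), length(mu)),
                          names = names(coords))
  theta_full <- model$params_nominal
  assemble <- function(z, loc) {
    theta <- theta_full
    for (j in seq_along(coords)) {
      cd <- coords[[j]]
      if (is.na(cd$location) || cd$location == loc)
        theta[[cd$param]] <- exp(z[j])
    }
    theta
  }
  # active-ERK trajectory of one dataset at assembled parameters
  raw_traj <- function(theta, d) {
    if (d$rap1_inhibited && "Rap1_tot" %in% names(theta))
      theta[["Rap1_tot"]] <- 0
    tg <- d$design
    prepend <- tg[1] > 0
    if (prepend) tg <- c(0, tg)
    act <- active_erk(model, simulate_model(model, theta, tg, egf = d$egf,
                                            settings = solver))
    if (prepend) act <- act[-1]
    act
  }
  n_points <- vapply(datasets, `[[`, integer(1), "n_train")
  loglik_fn <- function(z) {
    pw <- tryCatch({
      trajs <- lapply(datasets, function(d) raw_traj(assemble(z, d$location),
                                                     d))
      out <- vector("list", length(datasets))
      for (loc in locations) {
        ii <- which(locs == loc)
        divisor <- mean(vapply(trajs[ii], max, numeric(1)))
        if (divisor <= 0) stop("all-zero prediction")
        for (i in ii)
          out[[i]] <- stats::dnorm(datasets[[i]]$y,
                                   trajs[[i]] / divisor,
                                   datasets[[i]]$sigma, log = TRUE)
      }
      unlist(out)
    }, error = function(e) rep(-Inf, sum(n_points)))
    list(total = sum(pw), pointwise = pw)
  }
  ens <- run_smc(loglik_fn, prior, smc)
  ens$model <- model
  ens$data <- datasets
  ens$spec <- spec
  attr(ens, "coords") <- coords
  ens
}

#' Compare parameter-sharing hypotheses by ELPD and MMI weights
#'
#' Fits each hypothesis jointly to all its condition datasets, estimates
#' PSIS-LOO ELPD over the pooled pointwise log-likelihoods, and weights
#' the hypotheses by pseudo-BMA, BMA and stacking.
#'
#' @param specs list of [hypothesis_spec()]s.
#' @param datasets list of [calibration_data()]s (shared by all specs).
#' @param smc an [smc_settings()].
#' @param seed seed for the Bayesian bootstrap.
#' @return object of class `hypothesis_report`: `fits`, `elpds`, `table`
#'   (ranked data frame), `weights` (per method).
#' @export
hypothesis_comparison <- function(specs, datasets, smc = smc_settings(),
                                  seed = 1L) {
  stopifnot(length(specs) >= 1)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  fits <- lapply(specs, fit_hypothesis, datasets = datasets, smc = smc)
  elpds <- lapply(fits, function(f) psis_loo(f$pointwise_loglik))
  log_ml <- vapply(fits, average_log_ml, numeric(1))
  totals <- vapply(elpds, `[[`, numeric(1), "total")
  weights <- list(
    PSEUDO_BMA = pseudo_bma_weights(totals, model_names = names(specs)),
    BMA = bma_weights(log_ml, model_names = names(specs)),
    STACKING = stacking_weights(elpds, model_names = names(specs)))
  if (length(specs) >= 2) {
    best <- names(which.max(totals))
    se_vs_best <- vapply(names(specs), function(nm)
      if (nm == best) 0 else elpd_diff_se(elpds[[nm]], elpds[[best]]),
      numeric(1))
  } else se_vs_best <- 0
  tab <- data.frame(hypothesis = names(specs), elpd = totals,
                    log_ml = log_ml,
                    elpd_diff = totals - max(totals),
                    elpd_diff_se = se_vs_best)
  tab <- tab[order(-tab$elpd), ]
  structure(list(fits = fits, elpds = elpds, table = tab,
                 weights = weights),
            class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("<hypothesis_report>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
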