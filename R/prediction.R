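#' Forward uncertainty propagation of a posterior ensemble
#'
#' Propagates every posterior draw through the model on an evaluation grid.
#' Kinds:
#' * `"push_forward_qoi"` -- raw active-ERK (quantity-of-interest)
#'   trajectories or steady-state curves;
#' * `"push_forward_obs"` -- normalized observables on the data scale (what
#'   [model_predict()] returns);
#' * `"posterior_predictive"` -- observables plus independent Gaussian
#'   measurement noise drawn per point from `data$sigma` (total predictive
#'   uncertainty).
#'
#' Draws whose solve fails are dropped with a recorded count; more than 10%
#' failures abort.
#'
#' @param ensemble a `posterior_ensemble` from [calibrate_model()].
#' @param model a `signaling_model` (default: the ensemble's).
#' @param data a [calibration_data()] defining the evaluation grid and
#'   noise scales (default: the ensemble's).
#' @param kind see above.
#' @param seed seed for the measurement-noise draws.
#' @param solver a [solver_settings()].
#' @return object of class `predictive_ensemble`: `samples` (S x T
#'   matrix), `design`, `kind`, `n_failed`.
#' @export
push_forward <- function(ensemble, model = ensemble$model,
                         data = if (inherits(ensemble$data, "calibration_data"))
                           ensemble$data else ensemble$data[[1]],
                         kind = c("push_forward_obs", "push_forward_qoi",
                                  "posterior_predictive"),
                         seed = 1L, solver = solver_settings()) {
  kind <- match.arg(kind)
  theta_draws <- ensemble$theta
  if (is.null(theta_draws))
    stop("ensemble lacks natural-scale draws; calibrate with calibrate_model()",
         call. = FALSE)
  s <- nrow(theta_draws)
  theta_full <- model$params_nominal
  rows <- vector("list", s)
  n_failed <- 0L
  for (j in seq_len(s)) {
    theta <- theta_full
    theta[colnames(theta_draws)] <- theta_draws[j, ]
    pred <- tryCatch({
      if (kind == "push_forward_qoi") {
        if (data$kind == "trajectory") {
          tg <- data$design
          prepend <- tg[1] > 0
          if (prepend) tg <- c(0, tg)
          if (data$rap1_inhibited && "Rap1_tot" %in% names(theta))
            theta[["Rap1_tot"]] <- 0
          act <- active_erk(model, simulate_model(model, theta, tg,
                                                  egf = data$egf,
                                                  settings = solver))
          if (prepend) act[-1] else act
        } else {
          st <- .steady_state_sweep(model, theta, data$design, solver)
          st[, model$obs_state]
        }
      } else {
        model_predict(model, theta, data, settings = solver)
      }
    }, error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      n_failed <- n_failed + 1L
      rows[[j]] <- NULL
    } else {
      rows[[j]] <- pred
    }
  }
  if (n_failed > 0.1 * s)
    stop(sprintf("propagation error: %d of %d draws failed", n_failed, s),
         call. = FALSE)
  samples <- do.call(rbind, rows)
  if (kind == "posterior_predictive") {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(samples), 0,
                                 rep(data$sigma, each = nrow(samples))),
                    nrow(samples))
    samples <- samples + noise
  }
  structure(list(samples = samples, design = data$design, kind = kind,
                 n_failed = n_failed),
            class = "predictive_ensemble")
}

#' Sample a mixture of per-model predictive ensembles
#'
#' Realizes the consensus density \eqn{\sum_k w_k p_k} by component
#' resampling: each mixture draw picks model k with probability
#' \eqn{w_k}, then a uniformly random row of that model's predictive
#' ensemble.
#'
#' @param ensembles list of `predictive_ensemble`s sharing the design grid.
#' @param weights an [mmi_weights()] of matching length.
#' @param n_mix number of mixture draws (default 2000).
#' @param seed integer seed.
#' @return object of class `mixture_prediction`: `samples` (n_mix x T),
#'   `component_ids`, `weights_used`, `design`.
#' @export
mixture_sample <- function(ensembles, weights, n_mix = 2000, seed = 1L) {
  k <- length(ensembles)
  stopifnot(k == length(weights$weights))
  design <- ensembles[[1]]$design
  for (e in ensembles)
    if (!isTRUE(all.equal(e$design, design)))
      stop("predictive ensembles must share the design grid", call. = FALSE)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  comp <- sample.int(k, n_mix, replace = TRUE, prob = weights$weights)
  samples <- matrix(NA_real_, n_mix, length(design))
  for (j in seq_len(n_mix)) {
    e <- ensembles[[comp[j]]]
    samples[j, ] <- e$samples[sample.int(nrow(e$samples), 1), ]
  }
  structure(list(samples = samples, component_ids = comp,
                 weights_used = weights, design = design),
            class = "mixture_prediction")
}

#' Root mean square error (as printed)
#'
#' Implements \eqn{RMSE = \sqrt{\sum_i (\hat y_i - y_i)^2} / N}: the square
#' root of the *sum* of squared residuals divided by N.  Note this differs
#' from the conventional \eqn{\sqrt{mean}}; see [rmse_conventional()].
#'
#' @param pred_mean,reference equal-length vectors.
#' @return scalar error.
#' @export
rmse <- function(pred_mean, reference) {
  if (length(pred_mean) != length(reference))
    stop("length mismatch", call. = FALSE)
  sqrt(sum((pred_mean - reference)^2)) / length(reference)
}

#' Conventional root mean square error
#'
#' \eqn{\sqrt{\frac{1}{N}\sum_i (\hat y_i - y_i)^2}}; provided for
#' comparison with [rmse()], which is used throughout the package.
#'
#' @inheritParams rmse
#' @return scalar error.
#' @export
rmse_conventional <- function(pred_mean, reference) {
  if (length(pred_mean) != length(reference))
    stop("length mismatch", call. = FALSE)
  sqrt(mean((pred_mean - reference)^2))
}

#' Relative error (ratio of Euclidean norms)
#'
#' \eqn{\|\hat y - y\|_2 / \|y\|_2}.
#'
#' @param pred,reference equal-length vectors; `reference` must be nonzero.
#' @return scalar relative error.
#' @export
relative_error <- function(pred, reference) {
  if (length(pred) != length(reference))
    stop("length mismatch", call. = FALSE)
  nref <- sqrt(sum(reference^2))
  if (nref == 0) stop("zero reference norm", call. = FALSE)
  sqrt(sum((pred - reference)^2)) / nref
}

#' 95% credible interval and its mean width
#'
#' Element-wise 2.5th and 97.5th percentiles of a sample matrix (linear
#' interpolation between order statistics) and the mean over the design
#' grid of the interval width.
#'
#' @param samples S x T matrix of predictive samples (S at least 2).
#' @return list with `lower`, `upper` (length T) and `mean_width`.
#' @export
credible_interval_width <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2)
    stop("credible interval needs at least 2 samples", call. = FALSE)
  lo <- apply(samples, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(samples, 2, stats::quantile, probs = 0.975, names = FALSE)
  list(lower = lo, upper = hi, mean_width = mean(hi - lo))
}

#' Summarize a predictive or mixture ensemble against a reference
#'
#' @param samples S x T matrix (or `predictive_ensemble` /
#'   `mixture_prediction`).
#' @param reference reference vector (length T), e.g. the data or the
#'   noiseless truth.
#' @return list with `mean`, `lower`, `upper`, `rmse`, `relative_error`,
#'   `mean_ci_width`.
#' @export
prediction_metrics <- function(samples, reference) {
  if (inherits(samples, c("predictive_ensemble", "mixture_prediction")))
    samples <- samples$samples
  m <- colMeans(samples)
  ci <- credible_interval_width(samples)
  list(mean = m, lower = ci$lower, upper = ci$upper,
       rmse = rmse(m, reference),
       relative_error = relative_error(m, reference),
       mean_ci_width = ci$mean_width)
}
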