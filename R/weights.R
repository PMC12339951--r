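#' Model-weight container
#'
#' @param weights nonnegative vector summing to 1.
#' @param method one of `"BMA"`, `"PSEUDO_BMA"`, `"PSEUDO_BMA_BB"`,
#'   `"STACKING"`.
#' @param model_names labels.
#' @param diagnostics method-specific extras (bootstrap spread, stacking
#'   objective value).
#' @return object of class `mmi_weights`.
#' @export
mmi_weights <- function(weights, method, model_names = NULL,
                        diagnostics = list()) {
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) <= 1e-12)
  if (is.null(model_names)) model_names <- paste0("model_", seq_along(weights))
  structure(list(weights = stats::setNames(as.numeric(weights), model_names),
                 method = method, model_names = model_names,
                 diagnostics = diagnostics),
            class = "mmi_weights")
}

#' @export
print.mmi_weights <- function(x, ...) {
  cat(sprintf("<mmi_weights %s: %s>\n", x$method,
              paste(sprintf("%s=%.3f", x$model_names, x$weights),
                    collapse = " ")))
  invisible(x)
}

.softmax_stable <- function(x) {
  w <- exp(x - log_sum_exp(x))
  w / sum(w)   # renormalize away rounding
}

#' Bayesian model averaging weights from log marginal likelihoods
#'
#' Posterior model probabilities
#' \eqn{w_k \propto p(d \mid M_k)\, p(M_k)} computed through the
#' log-sum-exp trick; by default each model is equally probable a priori.
#'
#' @param log_ml per-model (chain-averaged) log marginal likelihoods.
#' @param prior_probs prior model probabilities on the simplex (default
#'   uniform).
#' @param model_names labels.
#' @return an [mmi_weights()] with method `"BMA"`.
#' @export
bma_weights <- function(log_ml, prior_probs = NULL, model_names = NULL) {
  k <- length(log_ml)
  if (is.null(prior_probs)) prior_probs <- rep(1 / k, k)
  if (length(prior_probs) != k || any(prior_probs < 0) ||
      abs(sum(prior_probs) - 1) > 1e-8)
    stop("prior model probabilities must lie on the simplex", call. = FALSE)
  x <- log_ml + log(prior_probs)
  mmi_weights(.softmax_stable(x), "BMA", model_names)
}

#' Pseudo-BMA weights from ELPD estimates
#'
#' Softmax of the per-model ELPD values (log-sum-exp stabilized); invariant
#' to adding a constant to every ELPD.
#'
#' @param elpd per-model ELPD estimates (numeric) or a list of
#'   [elpd_estimate()]s.
#' @param model_names labels.
#' @return an [mmi_weights()] with method `"PSEUDO_BMA"`.
#' @export
pseudo_bma_weights <- function(elpd, model_names = NULL) {
  if (is.list(elpd)) elpd <- vapply(elpd, `[[`, numeric(1), "total")
  if (any(!is.finite(elpd)))
    stop("non-finite ELPD estimate", call. = FALSE)
  mmi_weights(.softmax_stable(elpd), "PSEUDO_BMA", model_names)
}

#' Pseudo-BMA weights with the Bayesian bootstrap
#'
#' Accounts for uncertainty in the ELPD estimates: per bootstrap replicate,
#' data-point weights \eqn{\alpha \sim Dirichlet(1, \ldots, 1)} rescale the
#' pointwise ELPD contributions (\eqn{z_{b,k} = N \sum_i \alpha_{b,i}
#' elpd_{k,i}}), a softmax over models is taken, and the final weights
#' average the replicates.
#'
#' @param pointwise_elpd K x N matrix of pointwise ELPD values (rows =
#'   models), or list of [elpd_estimate()]s.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param model_names labels.
#' @return an [mmi_weights()] with method `"PSEUDO_BMA_BB"`; diagnostics
#'   hold the per-model bootstrap standard deviation of the weights.
#' @export
pseudo_bma_bb_weights <- function(pointwise_elpd, n_boot = 1000, seed = 1L,
                                  model_names = NULL) {
  if (is.list(pointwise_elpd))
    pointwise_elpd <- do.call(rbind, lapply(pointwise_elpd, `[[`, "pointwise"))
  k <- nrow(pointwise_elpd)
  n <- ncol(pointwise_elpd)
  if (n < 2) stop("Bayesian bootstrap needs at least 2 data points",
                  call. = FALSE)
  stopifnot(n_boot >= 1)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  w_boot <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    g <- stats::rexp(n)
    alpha <- g / sum(g)                      # Dirichlet(1, ..., 1)
    z <- n * as.numeric(pointwise_elpd %*% alpha)
    w_boot[b, ] <- .softmax_stable(z)
  }
  w <- colMeans(w_boot)
  mmi_weights(w / sum(w), "PSEUDO_BMA_BB", model_names,
              diagnostics = list(bootstrap_sd = apply(w_boot, 2, stats::sd),
                                 n_boot = n_boot))
}

#' Stacking of predictive densities
#'
#' Maximizes the leave-one-out log score of the weighted mixture,
#' \eqn{\frac{1}{n}\sum_i \log \sum_k w_k\, p_{k,i}}, over the probability
#' simplex.  The objective is concave; the maximizer is found by the
#' EM-style fixed-point update
#' \eqn{w_k \leftarrow \frac{1}{n}\sum_i w_k p_{k,i} / \sum_l w_l p_{l,i}}
#' iterated from the uniform start until the relative objective change
#' drops below `tol`.  On flat objectives the uniform start returns the
#' symmetric solution.
#'
#' @param loo_pointwise_density K x N matrix of leave-one-out predictive
#'   densities (exponentiated pointwise ELPD values), all positive and
#'   finite; or a list of [elpd_estimate()]s (exponentiated internally,
#'   stabilized by a shared per-point shift which leaves the maximizer
#'   unchanged).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @param model_names labels.
#' @return an [mmi_weights()] with method `"STACKING"`; diagnostics hold
#'   the final objective value and iteration count.
#' @export
stacking_weights <- function(loo_pointwise_density, tol = 1e-10,
                             max_iter = 1e5, model_names = NULL) {
  if (is.list(loo_pointwise_density)) {
    lp <- do.call(rbind,
                  lapply(loo_pointwise_density, `[[`, "pointwise"))
    # common per-point shift: scales every model's density at point i by
    # the same factor, leaving the argmax over the simplex unchanged
    lp <- sweep(lp, 2, apply(lp, 2, max))
    loo_pointwise_density <- exp(lp)
  }
  dens <- as.matrix(loo_pointwise_density)
  if (any(!is.finite(dens)) || any(dens <= 0))
    stop("stacking needs positive finite predictive densities",
         call. = FALSE)
  k <- nrow(dens)
  n <- ncol(dens)
  if (k == 1)
    return(mmi_weights(1, "STACKING", model_names,
                       diagnostics = list(objective = mean(log(dens)),
                                          iterations = 0L)))
  w <- rep(1 / k, k)
  obj <- function(w) mean(log(colSums(w * dens)))
  o_prev <- obj(w)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mix <- colSums(w * dens)                # length n
    w <- as.numeric((dens / rep(mix, each = k)) %*% rep(1 / n, n)) * w
    w <- w / sum(w)
    o <- obj(w)
    if (iter >= max_iter ||
        abs(o - o_prev) <= tol * max(1, abs(o_prev))) break
    o_prev <- o
  }
  mmi_weights(w, "STACKING", model_names,
              diagnostics = list(objective = obj(w), iterations = iter))
}

#' Write a weights table as CSV and JSON
#'
#' @param weights_list list of [mmi_weights()] (e.g. one per method).
#' @param stem path stem; writes `<stem>.csv` and `<stem>.json`.
#' @export
write_weights <- function(weights_list, stem) {
  df <- do.call(rbind, lapply(weights_list, function(w)
    data.frame(model = w$model_names, method = w$method,
               weight = as.numeric(w$weights))))
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(df, dataframe = "rows", digits = NA),
             paste0(stem, ".json"))
  invisible(stem)
}
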