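#' Parameter ranges for Morris screening of a signaling model
#'
#' Four decades around the nominal values:
#' \eqn{[10^{-2}\theta^{nom}, 10^{2}\theta^{nom}]} per parameter, matching
#' the prior support.  Parameters with nominal value 0 (e.g. a zeroed
#' total) are pinned to 0.
#'
#' @param model a `signaling_model`.
#' @return p x 2 matrix of (min, max) rows, named by parameter.
#' @export
morris_ranges <- function(model) {
  nom <- model$params_nominal
  cbind(min = nom * 1e-2, max = nom * 1e2)
}

#' Morris elementary-effects screening
#'
#' Classic one-at-a-time trajectory design: each of `n_trajectories`
#' trajectories starts at a random point of a `levels`-level grid on the
#' unit hypercube and perturbs each coordinate once, in random order, by a
#' step of magnitude \eqn{\Delta = levels / (2(levels - 1))} in unit-cube
#' units.  The elementary effect of coordinate i is the output change
#' divided by the signed step.  Reported per parameter: `mu_star` (mean of
#' |EE|) and `sigma` (sd of EE, signaling nonlinearity/interactions).
#'
#' @param objective function of a natural-scale parameter vector returning
#'   a scalar; may error or return non-finite values at up to 10% of design
#'   points.
#' @param ranges p x 2 matrix of (min, max) per parameter (see
#'   [morris_ranges()]).
#' @param n_trajectories number of trajectories (default 256, the
#'   per-direction sample count).
#' @param levels grid levels (default 4).
#' @param seed integer seed.
#' @param scale `"log10"` (sampling is uniform in log space, matching the
#'   lognormal prior geometry) or `"linear"`.
#' @return object of class `morris_result` with `mu_star`, `sigma`,
#'   `n_trajectories`, `levels`, `ranges`, `n_failed`.
#' @export
morris_screen <- function(objective, ranges, n_trajectories = 256,
                          levels = 4, seed = 1L,
                          scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  ranges <- as.matrix(ranges)
  p <- nrow(ranges)
  delta <- levels / (2 * (levels - 1))
  grid_vals <- seq(0, 1, length.out = levels)
  fixed <- ranges[, 2] <= ranges[, 1]    # zero-width ranges stay pinned
  map_unit <- function(u) {
    out <- numeric(p)
    for (j in seq_len(p)) {
      if (fixed[j]) { out[j] <- ranges[j, 1]; next }
      if (scale == "log10") {
        la <- log10(ranges[j, 1]); lb <- log10(ranges[j, 2])
        out[j] <- 10^(la + u[j] * (lb - la))
      } else {
        out[j] <- ranges[j, 1] + u[j] * (ranges[j, 2] - ranges[j, 1])
      }
    }
    names(out) <- rownames(ranges)
    out
  }
  eval_obj <- function(u) {
    val <- tryCatch(objective(map_unit(u)), error = function(e) NA_real_)
    if (!is.finite(val)) NA_real_ else val
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  ee <- matrix(NA_real_, n_trajectories, p)
  n_eval <- 0L
  n_failed <- 0L
  vary <- which(!fixed)
  for (tr in seq_len(n_trajectories)) {
    dirs <- sample(c(-delta, delta), p, replace = TRUE)
    u <- vapply(seq_len(p), function(j) {
      ok <- grid_vals[grid_vals + dirs[j] >= -1e-12 &
                      grid_vals + dirs[j] <= 1 + 1e-12]
      sample(ok, 1)
    }, numeric(1))
    f_cur <- eval_obj(u)
    n_eval <- n_eval + 1L
    if (is.na(f_cur)) n_failed <- n_failed + 1L
    for (j in sample(vary)) {
      u_new <- u
      u_new[j] <- min(max(u[j] + dirs[j], 0), 1)
      f_new <- eval_obj(u_new)
      n_eval <- n_eval + 1L
      if (is.na(f_new)) n_failed <- n_failed + 1L
      if (!is.na(f_cur) && !is.na(f_new))
        ee[tr, j] <- (f_new - f_cur) / dirs[j]
      u <- u_new
      f_cur <- f_new
    }
  }
  if (n_failed > 0.1 * n_eval)
    stop(sprintf("objective failed at %d of %d design points",
                 n_failed, n_eval), call. = FALSE)
  mu_star <- apply(ee, 2, function(col) mean(abs(col), na.rm = TRUE))
  sigma <- apply(ee, 2, function(col) stats::sd(col, na.rm = TRUE))
  mu_star[fixed] <- 0
  sigma[fixed] <- 0
  sigma[is.na(sigma)] <- 0
  names(mu_star) <- names(sigma) <- rownames(ranges)
  structure(list(mu_star = mu_star, sigma = sigma,
                 n_trajectories = n_trajectories, levels = levels,
                 ranges = ranges, n_failed = n_failed),
            class = "morris_result")
}

#' Influential-parameter classification
#'
#' A parameter is influential when
#' \eqn{\mu^*_i / \max_j \mu^*_j > threshold} or
#' \eqn{\sigma_i / \max_j \sigma_j > threshold}.
#'
#' @param result a `morris_result`.
#' @param threshold normalized cutoff (default 0.1).
#' @return named logical vector.
#' @export
influential_params <- function(result, threshold = 0.1) {
  mu_max <- max(result$mu_star)
  sg_max <- max(result$sigma)
  if (mu_max <= 0 && sg_max <= 0)
    stop("all elementary effects are zero", call. = FALSE)
  crit_mu <- if (mu_max > 0) result$mu_star / mu_max > threshold
             else rep(FALSE, length(result$mu_star))
  crit_sg <- if (sg_max > 0) result$sigma / sg_max > threshold
             else rep(FALSE, length(result$sigma))
  crit_mu | crit_sg
}

#' Screening quantity-of-interest objective for a signaling model
#'
#' Wraps the model solvers into a scalar objective for [morris_screen()]:
#' the steady-state active-ERK concentration (sustained models) or the
#' maximal active-ERK concentration over a 0-120 min simulation (transient
#' models), at a fixed EGF dose.
#'
#' @param model a `signaling_model`.
#' @param mode `"steady_state_erk"` or `"max_erk"`; defaults to the model's
#'   `transient` declaration.
#' @param egf EGF dose in nM (default 0.1).
#' @param settings a [solver_settings()].
#' @return function of a full natural-scale parameter vector.
#' @export
screening_qoi <- function(model,
                          mode = if (model$transient) "max_erk"
                                 else "steady_state_erk",
                          egf = 0.1, settings = solver_settings()) {
  mode <- match.arg(mode, c("steady_state_erk", "max_erk"))
  if (mode == "steady_state_erk") {
    function(theta) {
      ss <- steady_state(model, theta, egf = egf, settings = settings)
      unname(ss[model$obs_state])
    }
  } else {
    tg <- seq(0, 120, by = 2)
    function(theta) {
      tr <- simulate_model(model, theta, tg, egf = egf, settings = settings)
      max(active_erk(model, tr))
    }
  }
}

#' Write a Morris screening result as CSV
#'
#' Columns: parameter, mu_star, sigma, influential.
#'
#' @param result a `morris_result`.
#' @param path file path.
#' @param threshold passed to [influential_params()].
#' @export
write_morris_csv <- function(result, path, threshold = 0.1) {
  df <- data.frame(parameter = names(result$mu_star),
                   mu_star = as.numeric(result$mu_star),
                   sigma = as.numeric(result$sigma),
                   influential = as.logical(influential_params(result,
                                                               threshold)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
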