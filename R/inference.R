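#' Lognormal prior scale from a coverage requirement
#'
#' Returns the standard deviation `s` (on the log scale) such that a
#' lognormal density centered at a nominal value places `coverage`
#' probability mass within a multiplicative factor `mass_factor` of it:
#' \eqn{s = \ln(mass\_factor) / z}, with `z` the two-sided normal quantile
#' of `coverage`.  The default prior used throughout the package takes
#' `mass_factor = 100`, `coverage = 0.95`, i.e. 95% of prior mass in
#' \eqn{[10^{-2}\theta^{nom}, 10^{2}\theta^{nom}]}, giving `s = 2.350`.
#'
#' @param mass_factor multiplicative half-width of the coverage interval
#'   (> 1, or exactly 1 for a degenerate point prior).
#' @param coverage probability mass inside the interval, in (0, 1).
#' @return the prior standard deviation on the log scale.
#' @export
lognormal_prior_scale <- function(mass_factor = 100, coverage = 0.95) {
  stopifnot(mass_factor >= 1)
  if (!(coverage > 0 && coverage < 1))
    stop("coverage must be in (0, 1)", call. = FALSE)
  log(mass_factor) / stats::qnorm((1 + coverage) / 2)
}

#' Prior specification over a model's free parameters
#'
#' Lognormal priors centered (in log space) on the nominal values with a
#' common scale (default 2.350, see [lognormal_prior_scale()]).  Sampling
#' and density evaluation operate in log-parameter space, where the prior
#' is multivariate normal.
#'
#' @param model a `signaling_model`.
#' @param scale prior sd on the log scale.
#' @return object of class `prior_spec` with fields `mu` (log nominals of
#'   free parameters), `sd`, `names`, and closures `sample(n)` /
#'   `log_density(z)` operating on the log scale.
#' @export
prior_spec <- function(model, scale = lognormal_prior_scale()) {
  free <- names(model$free_mask)[model$free_mask]
  mu <- log(model$params_nominal[free])
  gaussian_prior(mu, rep(scale, length(mu)), names = free)
}

#' Independent Gaussian prior in sampling space
#'
#' Generic building block for [run_smc()]: a product of independent normals
#' over the sampling-space coordinates (for signaling models the sampling
#' space is log-parameter space, making the parameters lognormal).
#'
#' @param mu,sd location and scale per coordinate.
#' @param names optional coordinate names.
#' @return a `prior_spec` object.
#' @export
gaussian_prior <- function(mu, sd, names = NULL) {
  stopifnot(length(mu) == length(sd), all(sd >= 0))
  if (is.null(names)) names <- names(mu)
  obj <- list(mu = unname(as.numeric(mu)), sd = unname(as.numeric(sd)),
              names = names, p = length(mu))
  obj$sample <- function(n) {
    z <- matrix(stats::rnorm(n * obj$p), n, obj$p)
    sweep(sweep(z, 2, obj$sd, "*"), 2, obj$mu, "+")
  }
  obj$log_density <- function(z) {
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
    rowSums(vapply(seq_len(obj$p), function(j)
      stats::dnorm(z[, j], obj$mu[j], obj$sd[j], log = TRUE),
      numeric(nrow(z))))
  }
  class(obj) <- "prior_spec"
  obj
}

#' Model predictions on the scale of a calibration dataset
#'
#' For trajectory data: simulates at the dataset's EGF dose and normalizes
#' the active-ERK trajectory to its own maximum (model predictions and data
#' are both on a normalized scale).  For dose-response data: the
#' steady-state curve normalized to its maximum across the design doses.
#' Rap1-inhibited datasets zero the total Rap1 concentration before
#' simulating.
#'
#' @param model a `signaling_model`.
#' @param theta full parameter vector (natural scale).
#' @param data a [calibration_data()].
#' @param settings a [solver_settings()].
#' @return prediction vector aligned with `data$y`.
#' @export
model_predict <- function(model, theta, data, settings = solver_settings()) {
  if (data$rap1_inhibited && "Rap1_tot" %in% names(model$params_nominal))
    theta[["Rap1_tot"]] <- 0
  if (data$kind == "dose_response") {
    as.numeric(dose_response(model, theta, data$design, settings = settings))
  } else {
    tg <- data$design
    prepend <- tg[1] > 0
    if (prepend) tg <- c(0, tg)
    tr <- simulate_model(model, theta, tg, egf = data$egf,
                         settings = settings)
    act <- active_erk(model, tr)
    if (prepend) act <- act[-1]
    m <- max(act)
    if (m <= 0) stop("all-zero active-ERK prediction", call. = FALSE)
    act / m
  }
}

#' Gaussian log-likelihood of a parameter vector
#'
#' Independent Gaussian measurement noise: pointwise term
#' \eqn{\log N(y_i \mid \hat y_i(\theta), \sigma_i^2)}; the total is their
#' sum.  Integration or steady-state failures (expected at extreme prior
#' draws of a stiff system) yield a total of `-Inf` rather than an error.
#'
#' @inheritParams model_predict
#' @return list with `total` and `pointwise` (length `data$n_train`).
#' @export
log_likelihood <- function(theta, model, data, settings = solver_settings()) {
  pred <- tryCatch(model_predict(model, theta, data, settings = settings),
                   error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred)))
    return(list(total = -Inf, pointwise = rep(-Inf, data$n_train)))
  pw <- stats::dnorm(data$y, mean = pred, sd = data$sigma, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

#' Sequential Monte Carlo sampler settings
#'
#' @param n_chains number of independent SMC chains (default 4).
#' @param s_per_chain particles (= posterior samples) per chain
#'   (default 500).
#' @param ess_threshold target effective-sample-size fraction used to pick
#'   each tempering increment (default 0.85).
#' @param correlation_threshold mutation stops once the mean correlation
#'   between pre- and post-mutation particle coordinates drops below this
#'   value (default 0.01).
#' @param mh_max_passes hard cap on independent Metropolis-Hastings passes
#'   per tempering stage.
#' @param seed integer root seed; chain `c` uses a stream derived from it.
#' @return an `smc_settings` object.
#' @export
smc_settings <- function(n_chains = 4, s_per_chain = 500,
                         ess_threshold = 0.85, correlation_threshold = 0.01,
                         mh_max_passes = 15, seed = 1L) {
  stopifnot(ess_threshold > 0, ess_threshold < 1,
            correlation_threshold > 0, correlation_threshold < 1)
  structure(list(n_chains = n_chains, s_per_chain = s_per_chain,
                 ess_threshold = ess_threshold,
                 correlation_threshold = correlation_threshold,
                 mh_max_passes = mh_max_passes, seed = as.integer(seed)),
            class = "smc_settings")
}

#' Log-sum-exp
#'
#' \eqn{c + \log \sum_l \exp(x_l - c)} with \eqn{c = \max_l x_l}; exact for
#' finite inputs of any magnitude without overflow.
#'
#' @param x numeric vector (non-empty).
#' @return scalar log of the sum of exponentials.
#' @export
log_sum_exp <- function(x) {
  if (length(x) == 0) stop("log_sum_exp of empty vector", call. = FALSE)
  c0 <- max(x)
  if (!is.finite(c0)) return(c0)   # all -Inf (or a +Inf dominates)
  c0 + log(sum(exp(x - c0)))
}

# Systematic resampling from normalized weights; returns indices.
.systematic_resample <- function(w, n = length(w)) {
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(w)) + 1L
}

# One tempered-SMC chain in sampling (log-parameter) space.
.smc_chain <- function(loglik_fn, prior, settings, chain_seed) {
  n <- settings$s_per_chain
  set.seed(chain_seed)
  z <- prior$sample(n)                      # n x p particles
  ll <- apply(z, 1, function(row) loglik_fn(row)$total)
  if (all(!is.finite(ll)))
    stop("SMC initialization failure: every prior draw has -Inf likelihood",
         call. = FALSE)
  beta <- 0
  log_ml <- 0
  n_stages <- 0L
  while (beta < 1) {
    # adaptive tempering increment: largest delta with relative ESS at the
    # threshold (bisection on delta)
    ess_frac <- function(delta) {
      lw <- delta * ll
      lw[!is.finite(lw)] <- -Inf
      w <- exp(lw - max(lw[is.finite(lw)]))
      (sum(w)^2 / sum(w^2)) / n
    }
    delta_max <- 1 - beta
    if (ess_frac(delta_max) >= settings$ess_threshold) {
      delta <- delta_max
    } else {
      lo <- 0; hi <- delta_max
      for (it in 1:50) {
        mid <- (lo + hi) / 2
        if (ess_frac(mid) >= settings$ess_threshold) lo <- mid else hi <- mid
      }
      delta <- lo
      if (delta <= 0) delta <- delta_max * 1e-6
    }
    lw <- delta * ll
    lw[!is.finite(lw)] <- -Inf
    log_ml <- log_ml + log_sum_exp(lw) - log(n)
    w <- exp(lw - max(lw[is.finite(lw)]))
    w <- w / sum(w)
    idx <- .systematic_resample(w)
    z <- z[idx, , drop = FALSE]
    ll <- ll[idx]
    beta <- beta + delta
    n_stages <- n_stages + 1L

    # mutation: independent M-H with a moment-matched Gaussian proposal
    mu_q <- colMeans(z)
    cov_q <- stats::cov(z)
    # regularize: degenerate spread can occur after aggressive resampling
    diag(cov_q) <- diag(cov_q) + 1e-10
    chol_q <- tryCatch(chol(cov_q), error = function(e)
      diag(sqrt(pmax(diag(cov_q), 1e-8)), nrow(cov_q)))
    log_q <- function(zz) {
      d <- forwardsolve(t(chol_q), t(zz) - mu_q)
      -0.5 * colSums(d^2) - sum(log(diag(chol_q))) -
        0.5 * ncol(z) * log(2 * pi)
    }
    lp <- prior$log_density(z)
    lq <- log_q(z)
    z_pre <- z
    for (pass in seq_len(settings$mh_max_passes)) {
      prop <- matrix(stats::rnorm(n * ncol(z)), n) %*% chol_q
      prop <- sweep(prop, 2, mu_q, "+")
      ll_prop <- apply(prop, 1, function(row) loglik_fn(row)$total)
      lp_prop <- prior$log_density(prop)
      lq_prop <- log_q(prop)
      log_alpha <- (lp_prop + beta * ll_prop - lq_prop) -
                   (lp + beta * ll - lq)
      acc <- log(stats::runif(n)) < log_alpha
      acc[!is.finite(log_alpha)] <- FALSE
      z[acc, ] <- prop[acc, ]
      ll[acc] <- ll_prop[acc]
      lp[acc] <- lp_prop[acc]
      lq[acc] <- lq_prop[acc]
      # stop once particles have decorrelated from the stage start
      corr <- mean(vapply(seq_len(ncol(z)), function(j) {
        if (stats::sd(z[, j]) < 1e-12 || stats::sd(z_pre[, j]) < 1e-12)
          return(0)
        abs(stats::cor(z[, j], z_pre[, j]))
      }, numeric(1)))
      if (corr < settings$correlation_threshold) break
    }
  }
  list(z = z, ll = ll, log_ml = log_ml, n_stages = n_stages)
}

#' Tempered sequential Monte Carlo sampling
#'
#' Runs `n_chains` independent tempered-SMC chains.  Each chain anneals the
#' likelihood exponent from 0 to 1 with increments chosen adaptively so the
#' effective sample size of the incremental weights stays at
#' `ess_threshold`, resamples systematically, and mutates particles with an
#' independent Metropolis-Hastings kernel whose Gaussian proposal is
#' moment-matched to the current particles.  The log marginal likelihood
#' accumulates the log mean incremental weights over stages.
#'
#' @param loglik_fn function of a sampling-space coordinate row returning a
#'   list with `total` (and optionally `pointwise`); `-Inf` totals are
#'   allowed.
#' @param prior a `prior_spec` (see [gaussian_prior()] / [prior_spec()]).
#' @param settings an [smc_settings()].
#' @param pointwise_fn optional function of a coordinate row returning the
#'   pointwise log-likelihood vector evaluated at the final particles;
#'   defaults to `loglik_fn(row)$pointwise`.
#' @return object of class `posterior_ensemble`: `samples` (S x p matrix in
#'   sampling space), `pointwise_loglik` (S x N), `log_ml_per_chain`,
#'   `n_chains`, `s_per_chain`, `seed`.
#' @export
run_smc <- function(loglik_fn, prior, settings = smc_settings(),
                    pointwise_fn = NULL) {
  chains <- lapply(seq_len(settings$n_chains), function(cc) {
    .smc_chain(loglik_fn, prior, settings,
               chain_seed = (settings$seed + 104729L * cc) %% 2147483587L)
  })
  samples <- do.call(rbind, lapply(chains, `[[`, "z"))
  colnames(samples) <- prior$names
  if (is.null(pointwise_fn))
    pointwise_fn <- function(row) loglik_fn(row)$pointwise
  pw <- t(apply(samples, 1, pointwise_fn))
  if (nrow(pw) != nrow(samples)) pw <- t(pw)  # N = 1 edge case
  structure(list(samples = samples,
                 pointwise_loglik = pw,
                 log_ml_per_chain = vapply(chains, `[[`, numeric(1), "log_ml"),
                 n_chains = settings$n_chains,
                 s_per_chain = settings$s_per_chain,
                 n_stages = vapply(chains, `[[`, integer(1), "n_stages"),
                 seed = settings$seed),
            class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf(
    "<posterior_ensemble: %d draws (%d chains), %d parameters, log ML %.2f>\n",
    nrow(x$samples), x$n_chains, ncol(x$samples), average_log_ml(x)))
  invisible(x)
}

#' Chain-averaged log marginal likelihood
#'
#' Arithmetic mean of the per-chain log marginal likelihood estimates.
#'
#' @param ensemble a `posterior_ensemble`.
#' @return scalar log marginal likelihood estimate.
#' @export
average_log_ml <- function(ensemble) {
  mean(ensemble$log_ml_per_chain)
}

#' Calibrate a signaling model to a calibration dataset
#'
#' Convenience wrapper: builds the lognormal prior over the model's free
#' parameters, runs [run_smc()] on the log-parameter space, and returns the
#' ensemble with natural-scale parameter draws attached.
#'
#' @param model a `signaling_model`.
#' @param data a [calibration_data()] (or list of them, fit jointly with
#'   independent likelihood terms summed across datasets).
#' @param settings an [smc_settings()].
#' @param prior optional `prior_spec`; defaults to [prior_spec()] on the
#'   model.
#' @param solver a [solver_settings()].
#' @return a `posterior_ensemble`; `$theta` holds natural-scale draws of
#'   the free parameters, `$model` and `$data` the inputs.
#' @export
calibrate_model <- function(model, data, settings = smc_settings(),
                            prior = prior_spec(model),
                            solver = solver_settings()) {
  datasets <- if (inherits(data, "calibration_data")) list(data) else data
  free <- prior$names
  theta_full <- model$params_nominal
  loglik_fn <- function(z) {
    theta <- theta_full
    theta[free] <- exp(z)
    pw <- unlist(lapply(datasets, function(d)
      log_likelihood(theta, model, d, settings = solver)$pointwise))
    list(total = sum(pw), pointwise = pw)
  }
  ens <- run_smc(loglik_fn, prior, settings)
  ens$theta <- exp(ens$samples)
  ens$model <- model
  ens$data <- data
  ens
}

#' Serialize / load a posterior ensemble
#'
#' Writes a CSV/JSON bundle: `<stem>_samples.csv` (parameter draws),
#' `<stem>_pointwise.csv` (pointwise log-likelihood matrix) and
#' `<stem>_meta.json` (log ML per chain, settings, seed).
#'
#' @param ensemble a `posterior_ensemble`.
#' @param stem path stem (no extension).
#' @export
write_ensemble <- function(ensemble, stem) {
  utils::write.csv(as.data.frame(ensemble$samples),
                   paste0(stem, "_samples.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ensemble$pointwise_loglik),
                   paste0(stem, "_pointwise.csv"), row.names = FALSE)
  meta <- list(log_ml_per_chain = ensemble$log_ml_per_chain,
               n_chains = ensemble$n_chains,
               s_per_chain = ensemble$s_per_chain, seed = ensemble$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(stem, "_meta.json"))
  invisible(stem)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(stem) {
  samples <- as.matrix(utils::read.csv(paste0(stem, "_samples.csv")))
  pw <- as.matrix(utils::read.csv(paste0(stem, "_pointwise.csv")))
  meta <- jsonlite::fromJSON(paste0(stem, "_meta.json"))
  structure(list(samples = samples, pointwise_loglik = unname(pw),
                 log_ml_per_chain = meta$log_ml_per_chain,
                 n_chains = meta$n_chains, s_per_chain = meta$s_per_chain,
                 seed = meta$seed),
            class = "posterior_ensemble")
}
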