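# Shared fixtures: models, quick solver/SMC budgets, small synthetic
# datasets.  All randomness is seeded so the suite is reproducible.

ma_model <- build_model("MA_CASCADE")
fb_model <- build_model("FB_CASCADE")
rap1_model <- build_model("RAP1_CASCADE")

# desk-scale SMC budget for ODE fits inside tests
quick_smc <- function(seed, n_chains = 2, s_per_chain = 150) {
  smc_settings(n_chains = n_chains, s_per_chain = s_per_chain,
               mh_max_passes = 8, seed = seed)
}

# small FB-generated trajectory dataset (about 20 training points)
make_fb_trajectory_data <- function(seed, n_cells = 20,
                                    t_grid = seq(0, 40, by = 2),
                                    cell_cv = 0.15, noise_sd = 0.05) {
  truth <- synthetic_truth(fb_model, cell_cv = cell_cv, noise_sd = noise_sd,
                           seed = seed)
  cells <- generate_single_cell_trajectories(truth, n_cells = n_cells,
                                             t_grid = t_grid)
  aggregate_cells(normalize_min_max(cells))
}

# conjugate normal-normal reference quantities (analytic oracle)
conjugate_posterior <- function(y, m0, s0, sig) {
  n <- length(y)
  v <- 1 / (1 / s0^2 + n / sig^2)
  m <- v * (m0 / s0^2 + sum(y) / sig^2)
  # log evidence by sequential conditioning
  log_ev <- 0
  mu_c <- m0
  var_c <- s0^2
  for (i in seq_len(n)) {
    log_ev <- log_ev + dnorm(y[i], mu_c, sqrt(var_c + sig^2), log = TRUE)
    var_new <- 1 / (1 / var_c + 1 / sig^2)
    mu_c <- var_new * (mu_c / var_c + y[i] / sig^2)
    var_c <- var_new
  }
  # analytic leave-one-out predictive density
  loo_pw <- vapply(seq_len(n), function(i) {
    v_i <- 1 / (1 / s0^2 + (n - 1) / sig^2)
    m_i <- v_i * (m0 / s0^2 + sum(y[-i]) / sig^2)
    dnorm(y[i], m_i, sqrt(v_i + sig^2), log = TRUE)
  }, numeric(1))
  list(mean = m, var = v, log_evidence = log_ev, loo_pointwise = loo_pw,
       loo_total = sum(loo_pw))
}

conjugate_loglik <- function(y, sig) {
  function(z) {
    pw <- dnorm(y, z[1], sig, log = TRUE)
    list(total = sum(pw), pointwise = pw)
  }
}
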