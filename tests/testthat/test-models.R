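test_that("resting cells without stimulus have zero dynamics", {
  x0 <- model_initial_state(ma_model, ma_model$params_nominal, egf = 0)
  expect_equal(as.numeric(model_rhs(ma_model, x0, ma_model$params_nominal)),
               rep(0, ma_model$n_states))
  # steady state of the zero-dynamics system is the initial state
  ss <- steady_state(ma_model, ma_model$params_nominal, egf = 0)
  expect_equal(as.numeric(ss), as.numeric(x0), tolerance = 1e-8)
})

test_that("conserved pools have zero net flux at random states", {
  set.seed(101)
  for (model in list(ma_model, fb_model, rap1_model)) {
    for (rep in 1:5) {
      x <- runif(model$n_states, 0, 100)
      theta <- model$params_nominal * exp(runif(length(model$params_nominal),
                                                -1, 1))
      f <- model_rhs(model, x, theta)
      for (pool in model$conserved_totals)
        expect_equal(sum(f[pool]), 0, tolerance = 1e-10)
      expect_identical(f[1], 0)  # EGF derivative is identically zero
    }
  }
})

test_that("simulated trajectories keep EGF constant and conserve totals", {
  tg <- seq(0, 40, by = 1)
  st <- solver_settings()
  for (model in list(ma_model, fb_model, rap1_model)) {
    tr <- simulate_model(model, model$params_nominal, tg, egf = 0.1)
    expect_equal(unname(tr[, "EGF"]), rep(0.1, length(tg)))
    for (pool in names(model$conserved_totals)) {
      tot <- model$params_nominal[[paste0(pool, "_tot")]]
      drift <- abs(rowSums(tr[, model$conserved_totals[[pool]],
                              drop = FALSE]) - tot) / tot
      expect_lt(max(drift), 10 * st$rel_tol)
    }
    expect_true(all(tr > -10 * st$abs_tol))
  }
})

test_that("a single time point returns the initial state exactly", {
  tr <- simulate_model(fb_model, fb_model$params_nominal, t_grid = 0,
                       egf = 0.25)
  expect_identical(nrow(tr), 1L)
  expect_equal(as.numeric(tr[1, ]),
               as.numeric(model_initial_state(fb_model,
                                              fb_model$params_nominal, 0.25)))
})

test_that("default-tolerance solutions agree with a tight-tolerance reference", {
  tg <- seq(0, 40, by = 2)
  ref_settings <- solver_settings(abs_tol = 1e-9, rel_tol = 1e-9)
  for (model in list(ma_model, fb_model)) {
    a <- simulate_model(model, model$params_nominal, tg, egf = 0.1)
    b <- simulate_model(model, model$params_nominal, tg, egf = 0.1,
                        settings = ref_settings)
    rel_dev <- max(abs(a - b) / (1 + abs(b)))
    expect_lt(rel_dev, 1e-3)
  }
})

test_that("zeroing total Rap1 reduces RAP1_CASCADE to FB_CASCADE", {
  tg <- seq(0, 40, by = 1)
  theta_r <- rap1_model$params_nominal
  theta_r[["Rap1_tot"]] <- 0
  tr_r <- simulate_model(rap1_model, theta_r, tg, egf = 0.1)
  theta_f <- fb_model$params_nominal
  theta_f[] <- theta_r[names(theta_f)]   # matched shared parameters
  tr_f <- simulate_model(fb_model, theta_f, tg, egf = 0.1)
  shared <- fb_model$state_names
  expect_equal(tr_r[, shared], tr_f[, shared], tolerance = 1e-5)
})

test_that("steady-state solver satisfies its residual contract", {
  st <- solver_settings()
  for (model in list(ma_model, fb_model, rap1_model)) {
    ss <- steady_state(model, model$params_nominal, egf = 0.05)
    res <- attr(ss, "residual")
    expect_lte(res, st$newton_tol * (1 + sqrt(sum(ss^2))))
    # event-based state and Newton-refined state agree closely
    ev <- attr(ss, "event_state")
    expect_lt(max(abs(ss - ev) / (1 + abs(ss))), 1e-4)
    # long-time simulation limit agrees with the steady state
    tr <- simulate_model(model, model$params_nominal,
                         c(0, 2000), egf = 0.05)
    expect_equal(as.numeric(tr[2, ]), as.numeric(ss), tolerance = 1e-3)
  }
})

test_that("dose-response is normalized, ultrasensitive, and guards degenerate input", {
  doses <- default_egf_levels()
  dr <- dose_response(ma_model, ma_model$params_nominal, doses)
  expect_equal(max(dr), 1)
  expect_true(all(dr >= 0 & dr <= 1))
  # Hill-fit oracle on the computed curve: kinase cascades are switch-like
  df <- data.frame(u = doses, r = as.numeric(dr))
  fit <- nls(r ~ u^h / (ec50^h + u^h), data = df,
             start = list(h = 1, ec50 = 0.01))
  expect_gt(coef(fit)[["h"]], 1)
  expect_error(dose_response(ma_model, ma_model$params_nominal, 0.05),
               "two distinct")
  # all-zero response (no stimulus anywhere) is a degenerate normalization
  expect_error(dose_response(ma_model, ma_model$params_nominal, c(0, 0, 0)),
               "two distinct|degenerate")
})

test_that("EGF unit conversions follow the stated constants", {
  expect_identical(convert_egf_units(0, "ng/mL", "nM"), 0)
  expect_equal(convert_egf_units(6.048, "ng/mL", "nM"), 1)
  expect_equal(convert_egf_units(1, "nM", "molecules/cell"), 6.02214076e5,
               tolerance = 1e-6)
  expect_equal(convert_egf_units(1000, "pg/mL", "nM"),
               convert_egf_units(1, "ng/mL", "nM"))
  # round trips
  expect_equal(convert_egf_units(convert_egf_units(2.5, "nM", "ng/mL"),
                                 "ng/mL", "nM"), 2.5)
  expect_error(convert_egf_units(1, "nM", "furlongs"), "unknown unit")
})

test_that("unknown archetypes are rejected", {
  expect_error(build_model("NOT_A_MODEL"))
})
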