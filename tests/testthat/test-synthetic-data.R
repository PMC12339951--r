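test_that("dose-response data matches the stated design and noise model", {
  truth <- synthetic_truth(ma_model, seed = 5)
  d <- generate_dose_response_data(truth)
  expect_s3_class(d, "calibration_data")
  expect_identical(d$n_train, 10L)
  expect_equal(range(d$design), c(0.001, 0.106))
  expect_true(all(d$sigma == 0.1))
  # noiseless limit reproduces the model curve exactly
  d0 <- generate_dose_response_data(truth, noise_sd = 1e-300)
  expect_equal(d0$y, attr(d0, "noiseless"), tolerance = 1e-12)
})

test_that("replicate generations reproduce the 0.1 noise scale", {
  truth <- synthetic_truth(ma_model, seed = 5)
  noiseless <- attr(generate_dose_response_data(truth), "noiseless")
  # 1000 replicate noisy observations of the first dose
  reps <- vapply(1:1000, function(s) {
    generate_dose_response_data(truth, seed = s)$y[1]
  }, numeric(1))
  expect_lt(abs(sd(reps) - 0.1) / 0.1, 0.05)
  expect_lt(abs(mean(reps) - noiseless[1]), 0.015)
})

test_that("cell ensembles have the stated defaults and degenerate limits", {
  truth0 <- synthetic_truth(fb_model, cell_cv = 0, noise_sd = 0, seed = 2)
  cells0 <- generate_single_cell_trajectories(truth0, n_cells = 3,
                                              t_grid = seq(0, 10, by = 2))
  # no heterogeneity, no noise: all cells identical
  expect_equal(cells0$ratios[1, ], cells0$ratios[2, ])
  expect_equal(cells0$ratios[2, ], cells0$ratios[3, ])

  truth <- synthetic_truth(fb_model, seed = 2)
  cells <- generate_single_cell_trajectories(truth, n_cells = 4,
                                             t_grid = seq(0, 40, by = 5))
  expect_identical(nrow(cells$ratios), 4L)
  expect_equal(range(cells$times), c(0, 40))
  # default ensemble emulates 76 cells over 0-40 min (checked without
  # simulating all cells: defaults of the formals)
  fx <- formals(generate_single_cell_trajectories)
  expect_identical(eval(fx$n_cells), 76)
  expect_equal(range(eval(fx$t_grid)), c(0, 40))
})

test_that("Rap1-inhibited generation equals the reduced model's output", {
  truth_r <- synthetic_truth(rap1_model, seed = 9)
  cells_r <- generate_single_cell_trajectories(truth_r, n_cells = 3,
                                               t_grid = seq(0, 20, by = 4),
                                               condition = "+Rap1GAP")
  theta_f <- fb_model$params_nominal
  theta_f[] <- rap1_model$params_nominal[names(theta_f)]
  truth_f <- synthetic_truth(fb_model, theta_true = theta_f, seed = 9)
  cells_f <- generate_single_cell_trajectories(truth_f, n_cells = 3,
                                               t_grid = seq(0, 20, by = 4))
  # same root seed, but the models draw different numbers of per-cell
  # perturbations, so compare the noiseless deterministic limits
  truth_r0 <- synthetic_truth(rap1_model, cell_cv = 0, noise_sd = 0, seed = 9)
  truth_f0 <- synthetic_truth(fb_model, theta_true = theta_f, cell_cv = 0,
                              noise_sd = 0, seed = 9)
  c_r0 <- generate_single_cell_trajectories(truth_r0, n_cells = 1,
                                            t_grid = seq(0, 20, by = 4),
                                            condition = "+Rap1GAP")
  c_f0 <- generate_single_cell_trajectories(truth_f0, n_cells = 1,
                                            t_grid = seq(0, 20, by = 4))
  expect_equal(c_r0$ratios, c_f0$ratios, tolerance = 1e-6)
  expect_s3_class(cells_r, "cell_trajectories")
  expect_s3_class(cells_f, "cell_trajectories")
})

test_that("min-max normalization maps rows to [0,1] and is affine invariant", {
  set.seed(3)
  cells <- cell_trajectories(0:5, matrix(runif(18), 3))
  nm <- normalize_min_max(cells)
  expect_equal(apply(nm$ratios, 1, min), rep(0, 3))
  expect_equal(apply(nm$ratios, 1, max), rep(1, 3))
  # idempotence on an already-normalized ensemble
  expect_equal(normalize_min_max(nm)$ratios, nm$ratios)
  # affine invariance
  shifted <- cells
  shifted$ratios <- 3.7 * cells$ratios + 11
  expect_equal(normalize_min_max(shifted)$ratios, nm$ratios)
  # constant rows are degenerate
  flat <- cell_trajectories(0:2, rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_error(normalize_min_max(flat), "cell 2")
})

test_that("mean-max normalization pools the divisor across conditions", {
  a <- cell_trajectories(0:2, matrix(c(0, 1, 2), 1), condition = "EKAR4-only")
  b <- cell_trajectories(0:2, matrix(c(0, 2, 4), 1), condition = "+Rap1GAP")
  out <- normalize_mean_max(list(a, b))
  # cell-wise maxima 2 and 4, pooled divisor 3
  expect_equal(out[[1]]$ratios, a$ratios / 3)
  expect_equal(out[[2]]$ratios, b$ratios / 3)
  # between-condition ratios preserved
  expect_equal(out[[2]]$ratios / out[[1]]$ratios,
               b$ratios / a$ratios)
  # single condition, single cell: its max becomes exactly 1
  solo <- normalize_mean_max(list(a))
  expect_equal(max(solo[[1]]$ratios), 1)
  # global rescaling leaves the output unchanged
  a2 <- a; a2$ratios <- a$ratios * 7
  b2 <- b; b2$ratios <- b$ratios * 7
  out2 <- normalize_mean_max(list(a2, b2))
  expect_equal(out2[[1]]$ratios, out[[1]]$ratios)
})

test_that("cell aggregation computes mean, sample sd, halving and floors", {
  cells <- cell_trajectories(0:1, rbind(c(0, 1), c(1, 1)))
  d <- aggregate_cells(cells)
  expect_equal(d$y, c(0.5, 1))
  expect_equal(d$sigma[1], sd(c(0, 1)))       # sample sd = 0.7071
  expect_equal(d$sigma[2], 1e-6)              # zero sd floored
  d_half <- aggregate_cells(cells, sd_halving = TRUE)
  expect_equal(d_half$sigma[1], d$sigma[1] / 2)
  one_cell <- cell_trajectories(0:1, matrix(c(1, 2), 1))
  expect_error(aggregate_cells(one_cell), "at least 2")
})

test_that("truncation keeps the right points and errors when empty", {
  d <- calibration_data(design = seq(0, 40, by = 1),
                        y = rep(0.5, 41), sigma = rep(0.1, 41),
                        kind = "trajectory")
  expect_identical(truncate_data(d, 10)$n_train, 11L)
  expect_equal(truncate_data(d, 100)$y, d$y)
  expect_error(truncate_data(d, -5), "every data point")
})

test_that("cell subsampling is seeded, without replacement, and bounded", {
  set.seed(77)
  cells <- cell_trajectories(0:3, matrix(rnorm(40), 10))
  subs <- subsample_cells(cells, 4, n_replicates = 6, seed = 13)
  expect_length(subs, 6)
  for (s in subs) expect_identical(nrow(s$ratios), 4L)
  # determinism under the seed; difference across seeds
  subs2 <- subsample_cells(cells, 4, n_replicates = 6, seed = 13)
  expect_identical(lapply(subs, `[[`, "ratios"), lapply(subs2, `[[`, "ratios"))
  subs3 <- subsample_cells(cells, 4, n_replicates = 6, seed = 14)
  expect_false(identical(lapply(subs, `[[`, "ratios"),
                         lapply(subs3, `[[`, "ratios")))
  # full-size subsets recover the ensemble up to row order
  all10 <- subsample_cells(cells, 10, n_replicates = 2, seed = 1)
  for (s in all10)
    expect_equal(s$ratios[order(s$ratios[, 1]), ],
                 cells$ratios[order(cells$ratios[, 1]), ])
  expect_error(subsample_cells(cells, 11), "exceeds")
})

test_that("generator noise matches the Gaussian likelihood it implies", {
  # standardized residuals of many dose-response replicates are standard
  # normal within Monte-Carlo tolerance
  truth <- synthetic_truth(ma_model, seed = 21)
  noiseless <- attr(generate_dose_response_data(truth), "noiseless")
  resid <- unlist(lapply(1:200, function(s) {
    d <- generate_dose_response_data(truth, seed = 3000 + s)
    (d$y - noiseless) / d$sigma
  }))
  expect_lt(abs(mean(resid)), 3 / sqrt(length(resid)))
  expect_lt(abs(sd(resid) - 1), 0.05)
})

test_that("CSV round trips preserve datasets and ensembles", {
  truth <- synthetic_truth(ma_model, seed = 4)
  d <- generate_dose_response_data(truth)
  f <- tempfile(fileext = ".csv")
  write_calibration_csv(d, f)
  d2 <- read_calibration_csv(f)
  expect_equal(d2$y, d$y)
  expect_equal(d2$design, d$design)
  expect_identical(d2$kind, "dose_response")

  cells <- cell_trajectories(0:3, matrix(rnorm(12), 3))
  f2 <- tempfile(fileext = ".csv")
  write_trajectories_csv(cells, f2)
  cells2 <- read_trajectories_csv(f2)
  expect_equal(cells2$ratios, cells$ratios, ignore_attr = TRUE)
})
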