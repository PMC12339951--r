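test_that("model-set combinations enumerate unordered subsets", {
  models <- as.list(paste0("m", 1:10))
  expect_length(model_set_combinations(models, 2), 45)
  expect_length(model_set_combinations(models, 10), 1)
  expect_length(model_set_combinations(models, 1), 10)
  # deterministic order
  a <- model_set_combinations(models, 3)
  b <- model_set_combinations(models, 3)
  expect_identical(a, b)
})

test_that("single-model MMI degenerates to that model", {
  d <- make_fb_trajectory_data(seed = 700, n_cells = 8,
                               t_grid = seq(0, 40, by = 5))
  rep1 <- run_mmi(list(FB = fb_model), d,
                  smc = quick_smc(seed = 2, n_chains = 1,
                                  s_per_chain = 120),
                  n_mix = 500, seed = 3)
  for (w in rep1$weights)
    expect_equal(as.numeric(w$weights), 1)
  # mixture draws all come from the single model, so metrics agree with
  # the model's own push-forward up to resampling error
  expect_equal(rep1$metrics$rmse,
               rep(rep1$model_metrics$rmse, nrow(rep1$metrics)),
               tolerance = 0.15)
})

test_that("MMI on synthetic truth favors the generating model and is cached", {
  d <- make_fb_trajectory_data(seed = 701)
  report <- run_mmi(list(FB = fb_model, MA = ma_model), d,
                    smc = quick_smc(seed = 5), n_mix = 1000, seed = 5)
  for (w in report$weights)
    expect_gt(w$weights[["FB"]], 0.5)
  # mixture error does not exceed the worst single model's by much
  expect_lte(max(report$metrics$rmse),
             max(report$model_metrics$rmse) * 1.05)

  # model-set perturbation reuses cached calibrations
  pert <- perturb_model_set(report, drop = "worst_elpd")
  expect_identical(pert$recomputed, 0L)
  expect_identical(pert$dropped_model, "MA")
  # dropping a (near) zero-weight model leaves softmax weights unchanged
  # up to renormalization -- exact for BMA/pseudo-BMA
  keep <- setdiff(names(report$calibrations), "MA")
  w_full <- report$weights$PSEUDO_BMA$weights[keep]
  expect_equal(as.numeric(pert$weights$PSEUDO_BMA$weights),
               as.numeric(w_full / sum(w_full)))
  w_bma <- report$weights$BMA$weights[keep]
  expect_equal(as.numeric(pert$weights$BMA$weights),
               as.numeric(w_bma / sum(w_bma)))
  # dropping the top model redistributes stacking weight on the simplex
  pert_best <- perturb_model_set(report, drop = "best_elpd")
  expect_identical(pert_best$dropped_model, "FB")
  expect_equal(sum(pert_best$weights$STACKING$weights), 1)
})

test_that("report files are written with full provenance", {
  d <- make_fb_trajectory_data(seed = 702, n_cells = 8,
                               t_grid = seq(0, 40, by = 5))
  out <- tempfile("mmi")
  rep1 <- run_mmi(list(FB = fb_model), d,
                  smc = quick_smc(seed = 2, n_chains = 1,
                                  s_per_chain = 120),
                  n_mix = 200, seed = 3, out_dir = out)
  expect_true(file.exists(file.path(out, "weights.csv")))
  expect_true(file.exists(file.path(out, "mmi_metrics.csv")))
  ens <- read_ensemble(file.path(out, "ensemble_FB"))
  expect_equal(unname(ens$samples),
               unname(rep1$calibrations$FB$samples), tolerance = 1e-8)
})

test_that("data-length experiment scores the held-out window", {
  d <- make_fb_trajectory_data(seed = 703, n_cells = 10,
                               t_grid = seq(0, 40, by = 4))
  res <- data_length_experiment(list(FB = fb_model), d,
                                cut_points = c(20, 40),
                                smc = quick_smc(seed = 7, n_chains = 1,
                                                s_per_chain = 100),
                                methods = "PSEUDO_BMA", seed = 7)
  expect_true(all(c("cut", "predictor", "relative_error",
                    "mean_ci_width") %in% names(res)))
  # both cuts ran without error, including the degenerate full-length cut
  expect_setequal(unique(res$cut), c(20, 40))
  # single-model predictive uncertainty does not grow with more data
  fb_rows <- res[res$predictor == "FB", ]
  expect_lte(fb_rows$mean_ci_width[fb_rows$cut == 40],
             fb_rows$mean_ci_width[fb_rows$cut == 20] * 1.5)
})

test_that("data-quality experiment reports replicate spread", {
  truth <- synthetic_truth(fb_model, seed = 704)
  cells <- generate_single_cell_trajectories(truth, n_cells = 12,
                                             t_grid = seq(0, 40, by = 5))
  cells <- normalize_min_max(cells)
  res <- data_quality_experiment(list(FB = fb_model), cells,
                                 subset_sizes = c(4, 12), n_replicates = 2,
                                 smc = quick_smc(seed = 8, n_chains = 1,
                                                 s_per_chain = 100),
                                 methods = "PSEUDO_BMA", seed = 8)
  raw <- res[res$predictor == "raw_data", ]
  # full-ensemble subsets equal the reference: zero error, zero spread
  expect_equal(raw$relative_error[raw$size == 12], c(0, 0), tolerance = 1e-12)
  # smaller subsets deviate more from the full-data mean on average
  expect_gte(mean(raw$relative_error[raw$size == 4]),
             mean(raw$relative_error[raw$size == 12]))
})

test_that("hypothesis machinery builds coordinates and degenerates at K=1", {
  spec <- hypothesis_spec("Rap1_diff", location_specific = "Rap1")
  expect_s3_class(spec, "hypothesis_spec")
  expect_error(hypothesis_spec("x", location_specific = "nope"),
               "unknown parameter group")
  # coordinate layout: Rap1 group duplicated per location, rest shared
  model <- build_model("RAP1_CASCADE")
  coords <- erkmmi:::.hypothesis_coords(model, spec, c("CYTO", "PM"))
  expect_true("k1_C3G_deact@CYTO" %in% names(coords))
  expect_true("k1_C3G_deact@PM" %in% names(coords))
  expect_true("K_fb" %in% names(coords))
  expect_length(coords, 4 + 2 * 2)   # 4 shared free + 2 Rap1 x 2 locations

  # a single hypothesis receives weight 1
  truth <- synthetic_truth(rap1_model, seed = 705)
  cells <- generate_single_cell_trajectories(truth, n_cells = 6,
                                             t_grid = seq(0, 40, by = 8),
                                             location = "CYTO")
  d <- aggregate_cells(normalize_min_max(cells))
  rep1 <- hypothesis_comparison(list(spec), list(d),
                                smc = quick_smc(seed = 9, n_chains = 1,
                                                s_per_chain = 100))
  for (w in rep1$weights)
    expect_equal(as.numeric(w$weights), 1)
  expect_identical(nrow(rep1$table), 1L)
})
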