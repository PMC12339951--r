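#!/usr/bin/env Rscript
# Generate the synthetic study datasets.
#
# Three datasets emulate the study conditions:
#   * an emulated cytoplasmic ERK activity recording: 76 single-cell
#     40-min trajectories from the feedback cascade, with cell-to-cell
#     lognormal parameter variability (CV 0.15) and additive readout noise
#     (sd 0.05 normalized units), min-max normalized and averaged;
#   * a 10-point EGF-ERK dose-response curve from the mass-action cascade
#     over 0.001-0.106 nM with Gaussian noise of sd 0.1;
#   * two-location (cytoplasm / plasma membrane) recordings with and
#     without Rap1 inhibition from the Rap1-branch cascade, mean-max
#     normalized per location.
#
# Outputs under results/data/.

suppressMessages(library(erkmmi))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20240901L

fb <- build_model("FB_CASCADE")
ma <- build_model("MA_CASCADE")
rp <- build_model("RAP1_CASCADE")

## cytoplasmic-ERK-like trajectory ensemble ---------------------------------
truth_traj <- synthetic_truth(fb, cell_cv = 0.15, noise_sd = 0.05,
                              seed = seed)
cells <- generate_single_cell_trajectories(truth_traj, n_cells = 76,
                                           t_grid = seq(0, 40, by = 1))
cells_norm <- normalize_min_max(cells)
traj <- aggregate_cells(cells_norm)
write_trajectories_csv(cells_norm, file.path(out, "cyto_cells.csv"))
write_calibration_csv(traj, file.path(out, "cyto_trajectory.csv"))
message(sprintf("trajectory data: %d cells, %d time points, peak mean %.2f",
                nrow(cells$ratios), traj$n_train, max(traj$y)))

## dose-response dataset ------------------------------------------------------
truth_dr <- synthetic_truth(ma, seed = seed + 1L)
dr <- generate_dose_response_data(truth_dr)
write_calibration_csv(dr, file.path(out, "dose_response.csv"))
message(sprintf("dose-response data: %d levels spanning %.3f-%.3f nM",
                dr$n_train, min(dr$design), max(dr$design)))

## two-location inhibition-paired datasets ----------------------------------
theta_cyto <- rp$params_nominal
theta_cyto[c("k1_C3G_deact", "Km_Raf_Rap1", "K_fb")] <- c(4, 500, 1)
theta_pm <- rp$params_nominal
theta_pm[c("k1_C3G_deact", "Km_Raf_Rap1", "K_fb")] <- c(0.1, 20, 10)
for (loc in c("CYTO", "PM")) {
  theta <- if (loc == "CYTO") theta_cyto else theta_pm
  s <- seed + if (loc == "CYTO") 10L else 20L
  on <- generate_single_cell_trajectories(
    synthetic_truth(rp, theta_true = theta, seed = s),
    n_cells = 12, t_grid = seq(0, 40, by = 2.5), location = loc,
    baseline = 0, span = 1)
  off <- generate_single_cell_trajectories(
    synthetic_truth(rp, theta_true = theta, seed = s + 31L),
    n_cells = 12, t_grid = seq(0, 40, by = 2.5), condition = "+Rap1GAP",
    location = loc, baseline = 0, span = 1)
  nm <- normalize_mean_max(list(on, off))
  write_calibration_csv(aggregate_cells(nm[[1]]),
                        file.path(out, paste0(tolower(loc), "_ekar4.csv")))
  write_calibration_csv(aggregate_cells(nm[[2]], sd_halving = TRUE),
                        file.path(out, paste0(tolower(loc), "_rap1gap.csv")))
  message(sprintf("%s: uninhibited max %.2f, Rap1-inhibited max %.2f",
                  loc, max(nm[[1]]$ratios), max(nm[[2]]$ratios)))
}

## provenance ----------------------------------------------------------------
prov <- list(seed = seed,
             trajectory = list(model = "FB_CASCADE", cell_cv = 0.15,
                               noise_sd = 0.05, n_cells = 76),
             dose_response = list(model = "MA_CASCADE", noise_sd = 0.1,
                                  levels = 10),
             locations = list(model = "RAP1_CASCADE",
                              cyto = as.list(theta_cyto[c("k1_C3G_deact",
                                                          "Km_Raf_Rap1",
                                                          "K_fb")]),
                              pm = as.list(theta_pm[c("k1_C3G_deact",
                                                      "Km_Raf_Rap1",
                                                      "K_fb")])))
writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA),
           file.path(out, "ground_truth.json"))
message("wrote ", out)
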