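#' Solver settings for ODE integration and steady-state solving
#'
#' Tolerances and step limits used by [simulate_model()], [steady_state()]
#' and [dose_response()].  Defaults follow common stiff-solver practice for
#' signaling ODEs: adaptive integration at `abs_tol = rel_tol = 1e-6`, a
#' steady-state event criterion \eqn{\|dx/dt\|_2 \le atol_{ss} + rtol_{ss}\|x\|_2},
#' and Newton refinement of the event state.
#'
#' @param abs_tol,rel_tol absolute / relative integration tolerances.
#' @param max_steps maximum number of solver steps.
#' @param steady_state_abs_tol,steady_state_rel_tol tolerances of the
#'   steady-state event criterion.
#' @param newton_tol residual tolerance of the Newton refinement:
#'   the returned state satisfies
#'   \eqn{\|f(x^*)\|_2 \le newton\_tol (1 + \|x^*\|_2)}.
#' @param newton_max_steps maximum Newton iterations.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(abs_tol = 1e-6, rel_tol = 1e-6, max_steps = 6e6,
                            steady_state_abs_tol = 1e-5,
                            steady_state_rel_tol = 1e-6,
                            newton_tol = 1e-9, newton_max_steps = 100) {
  stopifnot(abs_tol > 0, rel_tol > 0, max_steps > 0,
            steady_state_abs_tol > 0, steady_state_rel_tol > 0,
            newton_tol > 0, newton_max_steps > 0)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol, max_steps = max_steps,
                 steady_state_abs_tol = steady_state_abs_tol,
                 steady_state_rel_tol = steady_state_rel_tol,
                 newton_tol = newton_tol, newton_max_steps = newton_max_steps),
            class = "solver_settings")
}

# Nominal parameters for the three archetypes.  Totals (in nM) are treated
# as known and fixed; kinetic rates carry per-reaction units (per-minute,
# per-nM-per-minute, or nM-per-minute for Vmax-type terms).
.ma_nominal <- c(
  k1_Raf_act = 10, k2_Raf_deact = 0.25,
  k3_MEK_phos = 0.02, k4_MEK_phos2 = 0.02,
  k5_MEK_dephos2 = 0.75, k6_MEK_dephos = 0.75,
  k7_ERK_phos = 0.02, k8_ERK_phos2 = 0.02,
  k9_ERK_dephos2 = 0.5, k10_ERK_dephos = 0.5,
  Raf_tot = 100, MEK_tot = 200, ERK_tot = 250
)
# free parameters follow the elementary-effects screening of the
# steady-state ERK response: the distal ERK (de)phosphorylation rates
# dominate; Raf kinetics set trajectory timescales
.ma_free <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
              FALSE, FALSE, FALSE, FALSE)

.fb_nominal <- c(
  k1_Raf_act = 3000, Km_Raf_act = 50,
  k2_Raf_deact = 100, Km_Raf_deact = 200,
  k3_MEK_act = 1, Km_MEK_act = 100,
  k4_MEK_deact = 60, Km_MEK_deact = 200,
  k5_ERK_act = 1, Km_ERK_act = 100,
  k6_ERK_deact = 75, Km_ERK_deact = 250,
  K_fb = 1,
  Raf_tot = 100, MEK_tot = 200, ERK_tot = 250
)
.fb_free <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
              TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)

.rap1_nominal <- c(
  .fb_nominal[1:13],
  k_C3G_act = 5, k1_C3G_deact = 0.4,
  k_Rap1_act = 0.05, k_Rap1_deact = 0.3,
  k_Raf_Rap1 = 0.2, Km_Raf_Rap1 = 50,
  Raf_tot = 100, MEK_tot = 200, ERK_tot = 250,
  C3G_tot = 50, Rap1_tot = 100
)
.rap1_free <- c(.fb_free[1:13], FALSE, TRUE, FALSE, FALSE, FALSE, TRUE,
                rep(FALSE, 5))

# Parameter groups used by shared-vs-location-specific hypotheses.
.rap1_groups <- list(
  Rap1 = c("k1_C3G_deact", "Km_Raf_Rap1"),
  negative_feedback = "K_fb",
  raf_deactivation = "k2_Raf_deact",
  erk_phosphorylation = "k5_ERK_act",
  erk_dephosphorylation = "k6_ERK_deact"
)

#' Build an archetypal ERK-cascade signaling model
#'
#' Three archetypes span the main structural axes of published EGF-to-ERK
#' models: kinetics (mass action vs Michaelis-Menten), presence of
#' ERK-to-Raf negative feedback, and presence of a Rap1 branch.
#'
#' * `MA_CASCADE` -- three-tier phosphorylation cascade with mass-action
#'   kinetics and distributive dual phosphorylation of MEK and ERK
#'   (Huang-Ferrell style); sustained, ultrasensitive response.
#' * `FB_CASCADE` -- Michaelis-Menten tiers with a divisive
#'   \eqn{(1 + aERK/K_{fb})^{-1}} negative-feedback factor on Raf
#'   activation; transient (adapting) response.
#' * `RAP1_CASCADE` -- `FB_CASCADE` plus an EGFR-C3G-Rap1-Raf branch that is
#'   not modulated by ERK feedback; the branch sustains ERK activity.
#'   Setting the total Rap1 concentration to zero reduces it exactly to
#'   `FB_CASCADE` (the construction used to simulate Rap1 inhibition).
#'
#' All models carry EGF as a state with identically zero time derivative
#' (sustained stimulus); signaling species start inactive with tier totals
#' taken from the parameter vector.
#'
#' @param archetype one of `"MA_CASCADE"`, `"FB_CASCADE"`, `"RAP1_CASCADE"`.
#' @return an object of class `signaling_model` with fields `name`,
#'   `n_states`, `state_names`, `params_nominal`, `free_mask`,
#'   `conserved_totals` (index sets with constant sums), `obs_state`
#'   (active-ERK state index), `transient` (screening-QoI declaration) and
#'   `param_groups`.
#' @export
build_model <- function(archetype = c("MA_CASCADE", "FB_CASCADE", "RAP1_CASCADE")) {
  archetype <- match.arg(archetype)
  m <- switch(archetype,
    MA_CASCADE = list(
      model_id = 1L,
      state_names = c("EGF", "Raf", "aRaf", "MEK", "pMEK", "ppMEK",
                      "ERK", "pERK", "ppERK"),
      params_nominal = .ma_nominal,
      free_mask = stats::setNames(.ma_free, names(.ma_nominal)),
      conserved_totals = list(Raf = 2:3, MEK = 4:6, ERK = 7:9),
      obs_state = 9L, transient = FALSE,
      param_groups = list()),
    FB_CASCADE = list(
      model_id = 2L,
      state_names = c("EGF", "Raf", "aRaf", "MEK", "aMEK", "ERK", "aERK"),
      params_nominal = .fb_nominal,
      free_mask = stats::setNames(.fb_free, names(.fb_nominal)),
      conserved_totals = list(Raf = 2:3, MEK = 4:5, ERK = 6:7),
      obs_state = 7L, transient = TRUE,
      param_groups = .rap1_groups[c("negative_feedback", "raf_deactivation",
                                    "erk_phosphorylation",
                                    "erk_dephosphorylation")]),
    RAP1_CASCADE = list(
      model_id = 3L,
      state_names = c("EGF", "Raf", "aRaf", "MEK", "aMEK", "ERK", "aERK",
                      "C3G", "aC3G", "Rap1", "aRap1"),
      params_nominal = .rap1_nominal,
      free_mask = stats::setNames(.rap1_free, names(.rap1_nominal)),
      conserved_totals = list(Raf = 2:3, MEK = 4:5, ERK = 6:7,
                              C3G = 8:9, Rap1 = 10:11),
      obs_state = 7L, transient = FALSE,
      param_groups = .rap1_groups))
  m$name <- archetype
  m$n_states <- length(m$state_names)
  class(m) <- "signaling_model"
  m
}

#' @export
print.signaling_model <- function(x, ...) {
  cat(sprintf("<signaling_model %s: %d states, %d parameters (%d free)>\n",
              x$name, x$n_states, length(x$params_nominal),
              sum(x$free_mask)))
  invisible(x)
}

#' Evaluate the model right-hand side f(x, theta)
#'
#' @param model a `signaling_model`.
#' @param x state vector (length `model$n_states`).
#' @param theta full parameter vector in nominal order.
#' @return the time-derivative vector.
#' @export
model_rhs <- function(model, x, theta) {
  rhs_eval_cpp(model$model_id, as.numeric(x), as.numeric(theta))
}

#' Initial state: resting cell with a sustained EGF stimulus
#'
#' All signaling species start inactive; tier totals come from `theta`;
#' the EGF state is initialized to the dose.
#'
#' @inheritParams model_rhs
#' @param egf EGF dose in nM.
#' @return named state vector.
#' @export
model_initial_state <- function(model, theta, egf) {
  x0 <- stats::setNames(numeric(model$n_states), model$state_names)
  x0["EGF"] <- egf
  for (pool in names(model$conserved_totals)) {
    idx <- model$conserved_totals[[pool]]
    x0[idx[1]] <- theta[[paste0(pool, "_tot")]]
  }
  x0
}

.pad_parms <- function(theta, settings) {
  p <- numeric(32)
  p[seq_along(theta)] <- theta
  p[31] <- settings$steady_state_abs_tol
  p[32] <- settings$steady_state_rel_tol
  p
}

.desolve_func <- function(model) {
  c("derivs_ma", "derivs_fb", "derivs_rap1")[model$model_id]
}

.check_solution <- function(out, model, theta, context) {
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop(sprintf("integration failure (%s) for model %s (istate = %d)",
                 context, model$name, istate[1]), call. = FALSE)
  if (any(!is.finite(out)))
    stop(sprintf("non-finite state (%s) for model %s", context, model$name),
         call. = FALSE)
  invisible(out)
}

#' Simulate a signaling model over a time grid
#'
#' Integrates the stiff ODE system with an adaptive implicit-capable solver
#' (`deSolve::lsoda`, which switches automatically to a BDF method on stiff
#' problems) at the tolerances in `settings`.
#'
#' @inheritParams model_rhs
#' @param t_grid strictly increasing time points in minutes, starting at 0.
#' @param egf EGF dose in nM (used when `x0` is `NULL`).
#' @param x0 optional initial state; defaults to
#'   [model_initial_state()] at the given dose.
#' @param settings a [solver_settings()] object.
#' @return matrix (time x states) with a `time` attribute; row `i` is the
#'   state at `t_grid[i]`.
#' @export
simulate_model <- function(model, theta, t_grid, egf = 0, x0 = NULL,
                           settings = solver_settings()) {
  stopifnot(length(t_grid) >= 1, t_grid[1] == 0,
            !is.unsorted(t_grid, strictly = TRUE), all(theta >= 0))
  if (is.null(x0)) x0 <- model_initial_state(model, theta, egf)
  if (length(t_grid) == 1) {
    res <- matrix(x0, nrow = 1, dimnames = list(NULL, model$state_names))
    attr(res, "time") <- t_grid
    return(res)
  }
  out <- deSolve::lsoda(
    y = as.numeric(x0), times = t_grid, func = .desolve_func(model),
    parms = .pad_parms(theta, settings), dllname = "erkmmi",
    initfunc = "initmod", atol = settings$abs_tol, rtol = settings$rel_tol,
    maxsteps = settings$max_steps)
  .check_solution(out, model, theta, "simulate")
  res <- unname(out[, -1, drop = FALSE])
  colnames(res) <- model$state_names
  attr(res, "time") <- t_grid
  res
}

#' Steady state of a signaling model at a sustained EGF dose
#'
#' Two-phase solve: (1) event-based integration runs the ODE solver until
#' \eqn{\|dx/dt\|_2 \le atol_{ss} + rtol_{ss}\|x\|_2}; (2) Newton's method,
#' initialized at the event state (a point along the ODE solution), solves
#' \eqn{f(x) = 0} directly with a finite-difference Jacobian.
#'
#' @inheritParams simulate_model
#' @param t_max horizon for the event-based phase (minutes).
#' @return named steady-state vector; attribute `event_state` holds the
#'   pre-Newton state and `residual` the final \eqn{\|f(x^*)\|_2}.
#' @export
steady_state <- function(model, theta, egf = 0, settings = solver_settings(),
                         t_max = 2000) {
  x0 <- model_initial_state(model, theta, egf)
  root_fun <- c("root_ma", "root_fb", "root_rap1")[model$model_id]
  out <- deSolve::lsodar(
    y = as.numeric(x0), times = c(0, t_max), func = .desolve_func(model),
    parms = .pad_parms(theta, settings), dllname = "erkmmi",
    initfunc = "initmod", rootfunc = root_fun, nroot = 1L,
    atol = settings$abs_tol, rtol = settings$rel_tol,
    maxsteps = settings$max_steps)
  .check_solution(out, model, theta, "steady_state")
  x_event <- out[nrow(out), -1]

  # Newton refinement on f(x) = 0 from the event state (a point along the
  # ODE solution).  Conserved pools and the frozen EGF state make the raw
  # Jacobian singular, so the redundant equations (EGF row; one row per
  # pool) are replaced by the constraints x_EGF = dose, sum(pool) = total.
  nt <- .newton_refine(model, as.numeric(x_event), theta, egf, settings)
  if (!nt$converged)
    stop(sprintf(
      "steady-state Newton refinement failed for model %s (residual %.3e)",
      model$name, nt$residual), call. = FALSE)
  res <- stats::setNames(nt$x, model$state_names)
  attr(res, "event_state") <- stats::setNames(as.numeric(x_event),
                                              model$state_names)
  attr(res, "residual") <- nt$residual
  res
}

.newton_refine <- function(model, x_start, theta, egf, settings) {
  totals <- vapply(names(model$conserved_totals),
                   function(pool) theta[[paste0(pool, "_tot")]], numeric(1))
  nt <- newton_ss_cpp(model$model_id, x_start, as.numeric(theta), egf,
                      unname(model$conserved_totals), unname(totals),
                      settings$newton_tol, settings$newton_max_steps)
  # reject nonphysical roots (Newton from a cold start can leave the
  # positive orthant)
  scale <- max(totals, 1)
  if (nt$converged && any(nt$x < -1e-8 * scale)) nt$converged <- FALSE
  nt$x <- pmax(nt$x, 0)
  nt
}

# Warm-started steady-state dose sweep: the first dose uses the full
# event-then-Newton path; each subsequent dose tries Newton from the
# previous dose's steady state and falls back to the full path if Newton
# fails.  Used by likelihood evaluations, where adjacent doses have close
# steady states.
.steady_state_sweep <- function(model, theta, egf_levels, settings) {
  out <- matrix(NA_real_, length(egf_levels), model$n_states)
  prev <- NULL
  for (i in seq_along(egf_levels)) {
    u <- egf_levels[i]
    x <- NULL
    if (!is.null(prev)) {
      start <- prev
      start[1] <- u
      nt <- .newton_refine(model, start, theta, u, settings)
      if (nt$converged) x <- nt$x
    }
    if (is.null(x))
      x <- as.numeric(steady_state(model, theta, egf = u,
                                   settings = settings))
    out[i, ] <- x
    prev <- x
  }
  colnames(out) <- model$state_names
  out
}

#' Normalized steady-state dose-response curve
#'
#' Computes the steady-state active-ERK concentration at each EGF level and
#' normalizes the curve to its maximum across levels ("% maximal ERK
#' activity" on the 0-1 scale).
#'
#' @inheritParams simulate_model
#' @param egf_levels at least two distinct EGF doses (nM).
#' @return numeric vector of normalized responses (max entry = 1), named by
#'   dose.
#' @export
dose_response <- function(model, theta, egf_levels,
                          settings = solver_settings()) {
  if (length(egf_levels) < 2 || length(unique(egf_levels)) < 2)
    stop("dose_response needs at least two distinct EGF levels", call. = FALSE)
  states <- .steady_state_sweep(model, theta, egf_levels, settings)
  q <- states[, model$obs_state]
  m <- max(q)
  if (m <= 0)
    stop("degenerate normalization: all steady-state responses are zero",
         call. = FALSE)
  stats::setNames(q / m, format(egf_levels, trim = TRUE))
}

#' Convert EGF amounts between units
#'
#' Linear conversions using an EGF molecular weight of 6048 g/mol, a cell
#' volume of 1 nL and the Avogadro constant.
#'
#' @param value numeric value(s) to convert.
#' @param from,to units among `"ng/mL"`, `"pg/mL"`, `"nM"`,
#'   `"molecules/cell"`.
#' @return converted value(s).
#' @export
convert_egf_units <- function(value, from, to) {
  units <- c("ng/mL", "pg/mL", "nM", "molecules/cell")
  if (!(from %in% units) || !(to %in% units))
    stop(sprintf("unknown unit pair %s -> %s", from, to), call. = FALSE)
  mw <- 6048          # g/mol
  vol <- 1e-9         # L (1 nL)
  avogadro <- 6.02214076e23
  # to nM first
  nm <- switch(from,
    "nM" = value,
    "ng/mL" = value * 1e-6 / mw * 1e9,        # g/L -> mol/L -> nM
    "pg/mL" = value * 1e-9 / mw * 1e9,
    "molecules/cell" = value / avogadro / vol * 1e9)
  switch(to,
    "nM" = nm,
    "ng/mL" = nm * 1e-9 * mw * 1e6,
    "pg/mL" = nm * 1e-9 * mw * 1e9,
    "molecules/cell" = nm * 1e-9 * vol * avogadro)
}

#' Active-ERK observation along a simulated trajectory
#'
#' @param model a `signaling_model`.
#' @param states a state matrix from [simulate_model()].
#' @return active-ERK concentration at each time point.
#' @export
active_erk <- function(model, states) {
  unname(states[, model$obs_state])
}

#' Export model metadata as JSON
#'
#' @param model a `signaling_model`.
#' @param path optional path to write to; if `NULL`, the JSON string is
#'   returned.
#' @export
model_metadata_json <- function(model, path = NULL) {
  meta <- list(name = model$name, n_states = model$n_states,
               state_names = model$state_names,
               params_nominal = as.list(model$params_nominal),
               free_mask = as.list(model$free_mask),
               transient = model$transient)
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
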