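#' 2D monodomain tissue grid
#'
#' A structured 2D sheet of electrically coupled atrial myocytes standing in
#' for the anatomical atria: node `(i, j)` sits at `((i-1)*dx, (j-1)*dx)` mm.
#' Propagation follows the monodomain reaction-diffusion equation
#' \deqn{\frac{1}{S_v}\nabla\cdot(D\nabla V_m) =
#'   C_m \frac{\partial V_m}{\partial t} + I_{ion} - I_{stim}}
#' solved with Godunov operator splitting (reaction then explicit diffusion,
#' zero-flux boundaries). Currents are expressed per unit capacitance, so the
#' effective diffusion coefficient entering the solver is `D / (Sv * Cm)`
#' (mm^2/ms).
#'
#' @param nx,ny node counts
#' @param dx node spacing (mm); 0.3 mm by default
#' @param D isotropic conductivity coefficient; the default yields a planar
#'   conduction velocity of roughly 60 cm/s in unremodeled tissue
#' @param Sv surface-to-volume ratio (default 0.02)
#' @param Cm membrane capacitance normalization (1 in the per-pF convention)
#' @return an object of class `tissue_grid`
#' @export
tissue_grid <- function(nx = 200, ny = 200, dx = 0.3, D = 0.0022,
                        Sv = 0.02, Cm = 1) {
  stopifnot(nx >= 2, ny >= 2, dx > 0, D >= 0, Sv > 0, Cm > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, D = D,
                 Sv = Sv, Cm = Cm),
            class = "tissue_grid")
}

deff <- function(grid) grid$D / (grid$Sv * grid$Cm)

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("tissue_grid %d x %d, dx = %g mm (%.1f x %.1f mm), D_eff = %.4g mm^2/ms\n",
              x$nx, x$ny, x$dx, (x$nx - 1) * x$dx, (x$ny - 1) * x$dx, deff(x)))
  invisible(x)
}

#' Linear node indices for a rectangular patch
#'
#' @param grid a [tissue_grid()]
#' @param i,j 1-based node ranges
#' @return integer vector of 1-based linear (column-major) node indices
#' @export
node_index <- function(grid, i, j) {
  stopifnot(all(i >= 1 & i <= grid$nx), all(j >= 1 & j <= grid$ny))
  as.integer(outer(i, (j - 1) * grid$nx, "+"))
}

#' Stimulus specification
#'
#' @param nodes 1-based linear node indices (see [node_index()])
#' @param amplitude pulse amplitude (pA/pF, > 0); 28 by default
#' @param duration pulse duration (ms)
#' @param onsets pulse onset times (ms)
#' @return an object of class `stimulus_spec`
#' @export
stimulus_spec <- function(nodes, amplitude = 28, duration = 2, onsets) {
  if (!length(nodes)) stop("stimulus node set must be nonempty")
  if (amplitude <= 0) stop("stimulus amplitude must be positive")
  structure(list(nodes = as.integer(nodes), amplitude = amplitude,
                 duration = duration, onsets = sort(as.numeric(onsets))),
            class = "stimulus_spec")
}

stim_end_time <- function(stims) {
  if (!length(stims)) return(-Inf)
  max(vapply(stims, function(s) max(s$onsets) + s$duration, numeric(1)))
}

#' Initial tissue state
#'
#' Broadcasts a single-cell state to every node.
#'
#' @param grid a [tissue_grid()]
#' @param state a [cell_state()]; the published resting state by default
#' @return a 21 x (nx*ny) state matrix
#' @export
tissue_states <- function(grid, state = default_cell_state()) {
  matrix(as_state_vector(state), nrow = 21, ncol = grid$nx * grid$ny)
}

#' Advance a tissue sheet
#'
#' One (or more) operator-split monodomain steps: a reaction substep (the
#' cell model at every node) followed by an explicit finite-difference
#' diffusion substep with zero-flux boundaries. With `D = 0` every node
#' evolves exactly like an isolated cell.
#'
#' @param grid a [tissue_grid()]
#' @param states 21 x (nx*ny) state matrix (see [tissue_states()])
#' @param params a [cell_params()]
#' @param dt time step (ms); must satisfy the explicit stability bound
#' @param n number of steps
#' @param stims list of [stimulus_spec()]s
#' @param t0 current simulation time (ms)
#' @return list with the updated `states` matrix and `t_end`
#' @export
step_tissue <- function(grid, states, params, dt = 0.02, n = 1,
                        stims = list(), t0 = 0) {
  res <- run_tissue(grid, states, params, duration = n * dt, dt = dt,
                    stims = stims, t0 = t0)
  list(states = res$states, t_end = res$t_end)
}

#' Run a tissue simulation
#'
#' Low-level driver behind [s1s2_protocol()] and friends. Optionally records
#' membrane-potential snapshots, per-node activation maps, and pseudo-unipolar
#' electrograms at electrodes above the sheet.
#'
#' @inheritParams step_tissue
#' @param duration simulated span (ms)
#' @param record_dt snapshot cadence (ms; 0 disables snapshots)
#' @param electrodes optional k x 3 matrix of electrode positions (mm); the z
#'   component is the height above the sheet (0.2 mm typical)
#' @param egm_dt electrogram sampling interval (ms)
#' @param K volume-conductor constant of the electrogram kernel (-0.0398)
#' @param thickness sheet thickness entering the electrogram volume element
#'   (mm)
#' @param early_exit stop once the tissue is quiescent (no activation for
#'   `quiesce_ms` and all nodes below `quiesce_vm`) after the last stimulus
#' @param quiesce_vm,quiesce_ms quiescence thresholds
#' @return an object of class `tissue_run`: final `states`, `t_end`,
#'   activation maps (`act_count`, `act_count_post`, `act_first`, `act_last`
#'   as nx x ny matrices), `last_activation`, optional `snapshots`
#'   (nx*ny x frames) with `snap_times`, optional `egm` matrix with
#'   `egm_times`, and the run's configuration
#' @export
run_tissue <- function(grid, states, params, duration, dt = 0.02,
                       stims = list(), t0 = 0, record_dt = 0,
                       electrodes = NULL, egm_dt = 1, K = -0.0398,
                       thickness = 0.3, early_exit = FALSE,
                       quiesce_vm = -65, quiesce_ms = 200) {
  stopifnot(inherits(grid, "tissue_grid"))
  cst <- lapply(stims, function(s) {
    stopifnot(inherits(s, "stimulus_spec"))
    list(nodes = s$nodes - 1L, amp = s$amplitude, dur = s$duration,
         onsets = s$onsets)
  })
  el <- if (is.null(electrodes)) matrix(numeric(0), 0, 3) else
    matrix(as.numeric(electrodes), ncol = 3)
  rec_every <- if (record_dt > 0) max(1L, as.integer(round(record_dt / dt))) else 0L
  egm_every <- max(1L, as.integer(round(egm_dt / dt)))
  res <- tissue_run_cpp(states, unclass(params), grid$nx, grid$ny, grid$dx,
                        deff(grid), dt, duration, t0, cst, rec_every, el,
                        egm_every, thickness, K, early_exit, quiesce_vm,
                        quiesce_ms, stim_end_time(stims))
  run <- list(grid = grid, params = params, dt = dt, t0 = t0,
              t_end = res$t_end, stims = stims,
              states = res$states,
              stopped_early = res$stopped_early,
              act_count = matrix(res$act_count, grid$nx, grid$ny),
              act_count_post = matrix(res$act_count_post, grid$nx, grid$ny),
              act_first = matrix(res$act_first, grid$nx, grid$ny),
              act_last = matrix(res$act_last, grid$nx, grid$ny),
              last_activation = res$last_activation,
              electrodes = if (nrow(el)) el else NULL,
              record_dt = record_dt, egm_dt = egm_dt,
              K = K, thickness = thickness,
              span = t0 + duration)
  if (!is.null(res$snapshots)) {
    run$snapshots <- res$snapshots
    run$snap_times <- res$snap_times
  }
  if (!is.null(res$egm)) {
    run$egm <- res$egm
    run$egm_times <- res$egm_times
  }
  class(run) <- "tissue_run"
  run
}

#' @export
print.tissue_run <- function(x, ...) {
  cat(sprintf("tissue_run on %d x %d sheet: t = [%g, %g] ms%s\n",
              x$grid$nx, x$grid$ny, x$t0, x$t_end,
              if (isTRUE(x$stopped_early)) " (quiescent, stopped early)" else ""))
  la <- x$last_activation
  cat(sprintf("  last activation: %s ms, max activations/node: %d\n",
              if (is.na(la)) "none" else sprintf("%.1f", la),
              max(x$act_count)))
  invisible(x)
}

#' Continue a tissue run
#'
#' Restarts the solver from the stored final state, optionally with modified
#' parameters. Continuing with identical parameters reproduces an
#' uninterrupted run bit for bit.
#'
#' @param run a [run_tissue()] result
#' @param duration additional span (ms)
#' @param params replacement [cell_params()] (default: unchanged)
#' @param stims further stimuli (onsets in absolute time)
#' @param ... passed to [run_tissue()]
#' @return a new `tissue_run` whose activation maps cover only the
#'   continuation
#' @export
continue_run <- function(run, duration, params = NULL, stims = list(), ...) {
  stopifnot(inherits(run, "tissue_run"))
  run_tissue(run$grid, run$states, params %||% run$params, duration,
             dt = run$dt, stims = stims, t0 = run$t_end, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' S1-S2 arrhythmia induction protocol
#'
#' 2D adaptation of the S1-S2 induction used in whole-atria simulations: a
#' planar S1 train from one edge (sinus-driven excitation) followed by a
#' burst of focal ectopic S2 beats from a cluster of nodes (pulmonary-vein
#' ectopy), then an observation window.
#'
#' @param grid a [tissue_grid()]
#' @param params a [cell_params()]
#' @param states initial state matrix; defaults to broadcasting `state0`
#' @param state0 single-cell state used to initialize every node
#' @param n_s1 number of planar S1 stimuli (paper protocol: 10)
#' @param s1_bcl S1 basic cycle length (ms)
#' @param n_s2 number of focal S2 stimuli
#' @param s2_cl S2 cycle length (ms); 130 ms per the induction protocol
#' @param s2_coupling interval from the last S1 to the first S2 (ms)
#' @param s2_center,s2_halfwidth S2 cluster center (node coordinates) and
#'   half-width; defaults to a square in the lower-left quadrant
#' @param observe observation window after the last stimulus (ms)
#' @param stim_amp,stim_dur stimulus amplitude (pA/pF) and duration (ms)
#' @param ... further arguments to [run_tissue()] (electrodes, record_dt,
#'   early_exit, ...)
#' @return a `tissue_run`
#' @export
s1s2_protocol <- function(grid, params, states = NULL,
                          state0 = default_cell_state(),
                          n_s1 = 10, s1_bcl = 1000, n_s2 = 6, s2_cl = 130,
                          s2_coupling = 180, s2_center = NULL,
                          s2_halfwidth = NULL, observe = 1000,
                          stim_amp = 28, stim_dur = 2, ...) {
  if (is.null(states)) states <- tissue_states(grid, state0)
  s1_nodes <- node_index(grid, 1:2, seq_len(grid$ny))
  if (is.null(s2_center))
    s2_center <- c(round(grid$nx * 0.3), round(grid$ny * 0.25))
  if (is.null(s2_halfwidth)) s2_halfwidth <- max(2L, round(grid$nx * 0.06))
  s2_i <- max(1, s2_center[1] - s2_halfwidth):min(grid$nx, s2_center[1] + s2_halfwidth)
  s2_j <- max(1, s2_center[2] - s2_halfwidth):min(grid$ny, s2_center[2] + s2_halfwidth)
  s2_nodes <- node_index(grid, s2_i, s2_j)
  if (length(intersect(s2_nodes, s1_nodes)))
    stop("S2 region must be disjoint from the S1 edge")
  s1_on <- (seq_len(n_s1) - 1) * s1_bcl
  stims <- list(stimulus_spec(s1_nodes, stim_amp, stim_dur, s1_on))
  t_last_s1 <- max(s1_on)
  if (n_s2 > 0) {
    s2_on <- t_last_s1 + s2_coupling + (seq_len(n_s2) - 1) * s2_cl
    stims <- c(stims, list(stimulus_spec(s2_nodes, stim_amp, stim_dur, s2_on)))
  }
  duration <- stim_end_time(stims) + observe
  run_tissue(grid, states, params, duration = duration, stims = stims, ...)
}

#' Apply drug block during a tissue run
#'
#' Rescales the blocked currents' maximal conductances instantaneously at
#' `t_apply` at every node and continues the simulation. The time of the last
#' activation anywhere in the sheet (the arrhythmia termination time, if the
#' activity dies out) is available as `last_activation` of the returned run.
#'
#' @param run an active `tissue_run` (its computed span must reach `t_apply`,
#'   and `t_apply` must not exceed the run's configured span)
#' @param profile a [drug_block_profile()]
#' @param t_apply application time (ms)
#' @param duration how long to continue after application (ms)
#' @param ... passed to [run_tissue()]
#' @return a `tissue_run` covering `[t_apply, t_apply + duration]`
#' @export
apply_drug_during_run <- function(run, profile, t_apply, duration, ...) {
  stopifnot(inherits(run, "tissue_run"))
  if (t_apply > run$span + 1e-9)
    stop("t_apply is beyond the run's configured span")
  if (t_apply < run$t_end - 1e-9)
    stop("run has already been computed past t_apply; re-run with a shorter duration")
  if (t_apply > run$t_end + 1e-9)
    run <- continue_run(run, duration = t_apply - run$t_end, ...)
  continue_run(run, duration = duration,
               params = apply_block(run$params, profile), ...)
}

#' Planar conduction velocity
#'
#' Measures CV from the first-activation map along the central row, between
#' two x positions well away from the stimulated edge and the far boundary.
#'
#' @param run a `tissue_run` of a planar wave launched from the left edge
#' @param x_frac two fractions of the sheet width to measure between
#' @return conduction velocity (cm/s)
#' @export
measure_cv <- function(run, x_frac = c(0.3, 0.7)) {
  g <- run$grid
  j <- round(g$ny / 2)
  i1 <- max(2, round(g$nx * x_frac[1]))
  i2 <- min(g$nx - 1, round(g$nx * x_frac[2]))
  t1 <- run$act_first[i1, j]
  t2 <- run$act_first[i2, j]
  if (is.na(t1) || is.na(t2) || t2 <= t1)
    stop("no propagating wavefront found between the measurement points")
  dist_mm <- (i2 - i1) * g$dx
  (dist_mm / (t2 - t1)) * 100  # mm/ms -> cm/s
}
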