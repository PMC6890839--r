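#' Uniformly sampled trace
#'
#' Container for a uniformly sampled signal (membrane potential or current)
#' with the stimulus times that produced it.
#'
#' @param values sampled values (mV or pA/pF)
#' @param dt sampling interval (ms)
#' @param t0 time of the first sample (ms)
#' @param stim_times stimulus onset times (ms)
#' @param label free-text label
#' @param final_state optional [cell_state()] at the end of the trace
#' @return an object of class `trace`
#' @export
new_trace <- function(values, dt, t0 = 0, stim_times = numeric(0),
                      label = "", final_state = NULL) {
  stopifnot(length(values) >= 2, dt > 0)
  structure(list(values = as.numeric(values), dt = dt, t0 = t0,
                 stim_times = as.numeric(stim_times), label = label,
                 final_state = final_state),
            class = "trace")
}

trace_times <- function(tr) tr$t0 + (seq_along(tr$values) - 1) * tr$dt

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("trace '%s': %d samples at %.3g ms (%.1f ms span), %d stimuli\n",
              x$label, length(x$values), x$dt,
              (length(x$values) - 1) * x$dt, length(x$stim_times)))
  invisible(x)
}

#' Pace an isolated cell at a fixed cycle length
#'
#' Applies a train of square stimulus pulses and integrates the cell model,
#' returning the membrane-potential trace. Every stimulus must elicit an
#' action potential (peak above 0 mV); failure to capture is an error naming
#' the beat.
#'
#' @param params a [cell_params()]
#' @param bcl basic cycle length (ms)
#' @param n_beats number of stimuli
#' @param stim stimulus amplitude (pA/pF), 28 by default
#' @param stim_dur stimulus duration (ms)
#' @param dt integration step (ms)
#' @param record_dt output sampling interval (ms)
#' @param state initial [cell_state()]; the published CRN resting state by
#'   default
#' @param check_capture verify an upstroke for every beat
#' @param use_tables use tabulated voltage-dependent rates
#' @return a [new_trace()] holding Vm, the stimulus times, and the final state
#' @export
pace_cell <- function(params, bcl = 1000, n_beats = 10, stim = 28,
                      stim_dur = 2, dt = 0.005, record_dt = 0.5,
                      state = default_cell_state(), check_capture = TRUE,
                      use_tables = TRUE) {
  stopifnot(bcl > stim_dur, n_beats >= 1)
  t0 <- state$t
  stim_times <- t0 + (seq_len(n_beats) - 1) * bcl
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  res <- crn_run_cpp(as_state_vector(state), unclass(params), dt,
                     n_beats * bcl, stim_times, stim, stim_dur, rec_every,
                     t0, use_tables)
  tr <- new_trace(res$Vm, dt = rec_every * dt, t0 = t0,
                  stim_times = stim_times, label = "paced Vm",
                  final_state = state_from_vector(res$state, t = res$t_end))
  if (check_capture) {
    tt <- trace_times(tr)
    for (b in seq_len(n_beats)) {
      i0 <- findInterval(stim_times[b], tt)
      i1 <- min(length(tr$values), findInterval(stim_times[b] + bcl, tt))
      if (max(tr$values[i0:i1]) <= 0)
        stop("failure to capture: no upstroke after stimulus of beat ", b)
    }
  }
  tr
}

#' Measure APD90 and resting membrane potential of one beat
#'
#' The activation time is the instant of maximal dV/dt within 10 ms of the
#' stimulus onset; the per-beat resting membrane potential (RMP) is the value
#' immediately before that beat's stimulus; APD90 is the time from activation
#' to the first subsequent crossing of
#' `peak - 0.9 * (peak - RMP)` (sub-sample resolution via linear
#' interpolation).
#'
#' @param trace a [new_trace()] with at least one stimulus
#' @param beat beat index to measure (defaults to the last)
#' @return an object of class `ap_measurement` with elements `APD90` (ms),
#'   `RMP` (mV), `peak` (mV) and `activation_time` (ms)
#' @export
measure_ap <- function(trace, beat = length(trace$stim_times)) {
  stopifnot(inherits(trace, "trace"))
  ns <- length(trace$stim_times)
  if (ns < 1) stop("trace has no stimulus times")
  if (beat < 1 || beat > ns) stop("beat index out of range")
  tt <- trace_times(trace)
  v <- trace$values
  t_stim <- trace$stim_times[beat]
  t_next <- if (beat < ns) trace$stim_times[beat + 1] else tail(tt, 1) + trace$dt

  i_pre <- findInterval(t_stim - 1e-9, tt)
  if (i_pre < 1) i_pre <- 1
  rmp <- v[i_pre]

  # activation: max dV/dt within 10 ms of stimulus onset (earliest on ties)
  i_win <- which(tt >= t_stim - 1e-9 & tt <= t_stim + 10)
  if (length(i_win) < 2) stop("trace too coarse around the stimulus")
  dv <- diff(v[i_win]) / diff(tt[i_win])
  act <- tt[i_win][which.max(dv)]

  i_cycle <- which(tt >= t_stim - 1e-9 & tt < t_next - 1e-9)
  peak <- max(v[i_cycle])
  i_peak <- i_cycle[which.max(v[i_cycle])]

  thr <- peak - 0.9 * (peak - rmp)
  i_after <- i_cycle[i_cycle >= i_peak]
  below <- which(v[i_after] <= thr)
  if (!length(below))
    stop("APD exceeds cycle length: no 90% repolarization before next stimulus")
  ib <- i_after[below[1]]
  if (ib == i_peak) {
    t_cross <- tt[ib]
  } else {
    # linear interpolation between the bracketing samples
    va <- v[ib - 1]; vb <- v[ib]
    w <- if (vb == va) 0 else (va - thr) / (va - vb)
    t_cross <- tt[ib - 1] + w * trace$dt
  }
  structure(list(APD90 = t_cross - act, RMP = rmp, peak = peak,
                 activation_time = act),
            class = "ap_measurement")
}

#' @export
print.ap_measurement <- function(x, ...) {
  cat(sprintf("APD90 = %.1f ms, RMP = %.2f mV, peak = %.1f mV (activation %.2f ms)\n",
              x$APD90, x$RMP, x$peak, x$activation_time))
  invisible(x)
}

#' Chloroquine titration of the remodeled atrial cell
#'
#' Reproduces the single-cell titration layout of the pharmacology study: the
#' remodeled cell is paced to quasi-steady state, the drug block for each
#' (concentration, current-mask) condition is applied instantaneously, pacing
#' continues, and APD90/RMP of the final beat are tabulated. A drug-free
#' baseline row (`mask = "none"`) is always included.
#'
#' @param params baseline (unremodeled) [cell_params()]
#' @param profile [remodeling_profile()]; the persistent-AF preset by default
#' @param concentrations drug concentrations (µM)
#' @param masks named list of character vectors naming the blocked currents
#'   for each condition, e.g. `list(dual = c("IK1", "IKACh"))`
#' @param ic50 IC50 preset, see [chloroquine_ic50()]
#' @param bcl pacing cycle length (ms)
#' @param n_pre beats paced before drug application
#' @param n_post beats paced after drug application; the last is measured
#' @param dt,stim,stim_dur,record_dt integration and stimulus settings as in
#'   [pace_cell()]
#' @return a data frame with one row per condition: `mask`, `concentration`,
#'   `APD90`, `RMP`, `peak`
#' @export
run_titration <- function(params = cell_params(),
                          profile = af_remodeling(),
                          concentrations = c(1.0, 2.5),
                          masks = titration_masks(),
                          ic50 = chloroquine_ic50(),
                          bcl = 1000, n_pre = 10, n_post = 5, dt = 0.005,
                          stim = 28, stim_dur = 2, record_dt = 0.5) {
  p_rem <- apply_remodeling(params, profile)
  pre <- pace_cell(p_rem, bcl = bcl, n_beats = n_pre, stim = stim,
                   stim_dur = stim_dur, dt = dt, record_dt = record_dt)
  base_state <- pre$final_state

  run_one <- function(p) {
    tr <- pace_cell(p, bcl = bcl, n_beats = n_post, stim = stim,
                    stim_dur = stim_dur, dt = dt, record_dt = record_dt,
                    state = base_state)
    measure_ap(tr, beat = n_post)
  }

  rows <- list()
  m0 <- run_one(p_rem)
  rows[[1]] <- data.frame(mask = "none", concentration = 0,
                          APD90 = m0$APD90, RMP = m0$RMP, peak = m0$peak)
  for (C in concentrations) {
    for (mn in names(masks)) {
      prof <- drug_block_profile(C, currents = masks[[mn]], ic50 = ic50)
      m <- run_one(apply_block(p_rem, prof))
      rows[[length(rows) + 1]] <-
        data.frame(mask = mn, concentration = C,
                   APD90 = m$APD90, RMP = m$RMP, peak = m$peak)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname run_titration
#' @details `titration_masks()` returns the five current masks of the study:
#'   each current alone, the dual \eqn{I_{K1}}+\eqn{I_{KACh}} block and the
#'   triple block.
#' @export
titration_masks <- function() {
  list(IKr = "IKr", IK1 = "IK1", IKACh = "IKACh",
       dual = c("IK1", "IKACh"),
       triple = c("IK1", "IKACh", "IKr"))
}
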