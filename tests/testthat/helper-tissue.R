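# Desk-scale tissue study conditions: a 72 x 72 sheet (21.3 mm) at dx =
# 0.3 mm with reduced coupling (planar CV ~30 cm/s) so that the remodeled
# wavelength fits the sheet; S1 planar edge train, S2 cross-field patch over
# the lower-left quadrant timed into the S1 repolarization tail.  Replicate
# variation comes from the S2 coupling interval, not random numbers.
TISSUE_NX <- 72
TISSUE_D <- 0.00085
TISSUE_DT <- 0.02
S2_COUPLINGS <- c(90, 100, 110)

reentry_grid <- function() tissue_grid(nx = TISSUE_NX, ny = TISSUE_NX,
                                       dx = 0.3, D = TISSUE_D)

cross_field_stims <- function(grid, coupling) {
  nx <- grid$nx
  list(stimulus_spec(node_index(grid, 1:2, seq_len(grid$ny)), 28, 2, 0),
       stimulus_spec(node_index(grid, 3:round(nx / 2), 1:round(grid$ny / 2)),
                     28, 2, coupling))
}

# baseline induction run: S1 + S2, rotor left to establish for 400 ms
reentry_baseline <- function(coupling) {
  memo(paste0("reentry_base_", coupling), {
    g <- reentry_grid()
    st0 <- prepace5_remodeled()
    run_tissue(g, tissue_states(g, st0), params_remodeled(),
               duration = coupling + 2 + 400, dt = TISSUE_DT,
               stims = cross_field_stims(g, coupling))
  })
}

prepace5_remodeled <- function() {
  memo("prepace5_remodeled",
       pace_cell(params_remodeled(), n_beats = 5)$final_state)
}

# undrugged continuation (sustainment control); the first replicate keeps an
# electrode above the sheet for the electrogram cross-check
reentry_control <- function(coupling, duration = 1100) {
  memo(paste0("reentry_ctl_", coupling, "_", duration), {
    base <- reentry_baseline(coupling)
    el <- if (coupling == S2_COUPLINGS[1]) {
      g <- base$grid
      matrix(c((g$nx / 2) * g$dx, (g$ny / 2) * g$dx, 0.2), 1, 3)
    } else NULL
    continue_run(base, duration = duration, early_exit = TRUE,
                 electrodes = el, egm_dt = 1)
  })
}

reentry_drugged <- function(coupling, condition, duration = 1200) {
  memo(paste0("reentry_drug_", coupling, "_", condition), {
    base <- reentry_baseline(coupling)
    prof <- switch(condition,
                   dual = drug_block_profile(1.0, currents = c("IK1", "IKACh")),
                   ikr30 = drug_block_profile(1.0, currents = "IKr"))
    continue_run(base, duration = duration,
                 params = apply_block(params_remodeled(), prof),
                 early_exit = TRUE)
  })
}

# same S1-S2 coupling scan applied to unremodeled tissue (plus couplings near
# the unremodeled refractory tail, so capture itself is exercised)
unremodeled_scan <- function() {
  memo("unremodeled_scan", {
    g <- reentry_grid()
    st0 <- memo("prepace5_unremodeled",
                pace_cell(params_unremodeled(), n_beats = 5)$final_state)
    lapply(c(S2_COUPLINGS, 310, 330), function(cp) {
      run_tissue(g, tissue_states(g, st0), params_unremodeled(),
                 duration = cp + 2 + 1100, dt = TISSUE_DT,
                 stims = cross_field_stims(g, cp), early_exit = TRUE)
    })
  })
}

planar_cv <- function(D, dx = 0.15, dt = 0.005, len_mm = 30, params = NULL) {
  nx <- round(len_mm / dx)
  g <- tissue_grid(nx = nx, ny = 7, dx = dx, D = D)
  st <- tissue_states(g)
  cols <- max(2, ceiling(1.8 / dx))
  stim <- stimulus_spec(node_index(g, 1:cols, 1:g$ny), 28, 2, 0)
  run <- run_tissue(g, st, params %||% params_unremodeled(), duration = 90,
                    dt = dt, stims = list(stim))
  measure_cv(run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
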