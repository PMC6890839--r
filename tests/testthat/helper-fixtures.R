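# Shared fixtures, memoised so expensive simulations run once per session.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

params_unremodeled <- function() cell_params()
params_remodeled <- function() apply_remodeling(cell_params(), af_remodeling())

# remodeled cell paced to quasi-steady state (10 beats at 1 Hz)
prepaced_remodeled <- function() {
  memo("prepaced_remodeled", {
    pace_cell(params_remodeled(), bcl = 1000, n_beats = 10)$final_state
  })
}

# the full chloroquine titration table of the study layout
titration_table <- function() {
  memo("titration_table", run_titration())
}

apd_of <- function(tab, mask, conc) {
  tab$APD90[tab$mask == mask & tab$concentration == conc]
}
rmp_of <- function(tab, mask, conc) {
  tab$RMP[tab$mask == mask & tab$concentration == conc]
}

# measure APD90/RMP of the final beat after continuing `n` beats from a state
apd_from_state <- function(params, state, n_beats = 5, bcl = 1000) {
  tr <- pace_cell(params, bcl = bcl, n_beats = n_beats, state = state)
  measure_ap(tr, beat = n_beats)
}
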