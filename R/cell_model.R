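#' @useDynLib atriablock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft sd setNames nls coef predict median approx
#' @importFrom utils head tail read.table write.table modifyList
NULL

GATE_NAMES <- c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                "d", "f", "fCa", "u", "v", "w")
CONC_NAMES <- c("Na_i", "K_i", "Ca_i", "Ca_up", "Ca_rel")

#' Membrane parameters of the human atrial myocyte model
#'
#' Builds the parameter set of the Courtemanche-Ramirez-Nattel (CRN) human
#' atrial action potential model, extended with the Kneller formulation of the
#' acetylcholine-activated inward rectifier \eqn{I_{KACh}}. All maximal
#' conductances are expressed per unit membrane capacitance (nS/pF), so every
#' sarcolemmal current carries units of pA/pF.
#'
#' @param ... named overrides of individual parameters. Available names are
#'   `gNa`, `gK1`, `gto`, `gKur` (dimensionless multiplier on the
#'   voltage-dependent \eqn{I_{Kur}} conductance), `gKr`, `gKs`, `gCaL`,
#'   `gbCa`, `gbNa`, `INaKmax`, `INaCamax`, `IpCamax`, `gKACh` (dimensionless
#'   multiplier on the Kneller expression), `ACh` (acetylcholine
#'   concentration, µM), and the external ion concentrations `Ko`, `Nao`,
#'   `Cao` (mM).
#' @return an object of class `cell_params` (a named numeric vector).
#' @examples
#' p <- cell_params(ACh = 0.005)
#' p[["gK1"]]
#' @export
cell_params <- function(...) {
  p <- crn_default_params_cpp()
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- vapply(ov, as.numeric, numeric(1))
  }
  if (any(p[setdiff(names(p), "ACh")] < 0))
    stop("maximal conductances must be non-negative")
  if (p[["ACh"]] < 0) stop("ACh must be non-negative")
  structure(p, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("CRN atrial cell parameters (pA/pF convention)\n")
  print(unclass(round(x, 6)))
  invisible(x)
}

#' State of a single atrial myocyte
#'
#' A `cell_state` bundles the membrane potential, the 15 CRN gating variables
#' and the 5 intracellular/compartment concentrations, plus the simulation
#' time. The default is the published CRN resting state.
#'
#' @param Vm membrane potential (mV)
#' @param gates named numeric vector of the 15 gating variables, each in
#'   \[0, 1\]
#' @param concentrations named numeric vector: `Na_i`, `K_i`, `Ca_i` (mM) and
#'   the sarcoplasmic-reticulum compartments `Ca_up`, `Ca_rel` (mM)
#' @param t simulation time (ms)
#' @return an object of class `cell_state`
#' @export
cell_state <- function(Vm, gates, concentrations, t = 0) {
  s <- list(Vm = as.numeric(Vm),
            gates = setNames(as.numeric(gates[GATE_NAMES]), GATE_NAMES),
            concentrations = setNames(as.numeric(concentrations[CONC_NAMES]),
                                      CONC_NAMES),
            t = as.numeric(t))
  class(s) <- "cell_state"
  validate_cell_state(s)
  s
}

#' @rdname cell_state
#' @export
default_cell_state <- function() {
  v <- crn_default_state_cpp()
  cell_state(Vm = v[1], gates = setNames(v[2:16], GATE_NAMES),
             concentrations = setNames(v[17:21], CONC_NAMES), t = 0)
}

validate_cell_state <- function(s) {
  if (!all(is.finite(c(s$Vm, s$gates, s$concentrations))))
    stop("non-finite cell state: ",
         paste(names(which(!is.finite(c(Vm = s$Vm, s$gates,
                                        s$concentrations)))), collapse = ", "))
  bad <- s$gates < -1e-9 | s$gates > 1 + 1e-9
  if (any(bad))
    stop("gating variable(s) outside [0, 1]: ",
         paste(names(s$gates)[bad], collapse = ", "))
  if (any(s$concentrations <= 0))
    stop("non-positive concentration(s): ",
         paste(names(s$concentrations)[s$concentrations <= 0], collapse = ", "))
  if (s$Vm < -100 || s$Vm > 60)
    stop("Vm outside the physiological range [-100, 60] mV")
  invisible(s)
}

as_state_vector <- function(s) {
  c(s$Vm, unname(s$gates), unname(s$concentrations))
}

state_from_vector <- function(v, t = 0) {
  cell_state(Vm = v[1], gates = setNames(v[2:16], GATE_NAMES),
             concentrations = setNames(v[17:21], CONC_NAMES), t = t)
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("cell_state at t = %.3f ms: Vm = %.2f mV, [Ca]_i = %.4g mM\n",
              x$t, x$Vm, x$concentrations[["Ca_i"]]))
  invisible(x)
}

#' Persistent-AF ionic remodeling profile
#'
#' Multiplicative conductance scalings that convert the baseline CRN cell into
#' a persistent-AF-remodeled cell: \eqn{I_{K1}} up-regulated, \eqn{I_{to}} and
#' \eqn{I_{Kur}} down-regulated, \eqn{I_{CaL}} strongly down-regulated, and a
#' constitutively active \eqn{I_{KACh}} enabled through a low acetylcholine
#' level.
#'
#' @param scale_IK1,scale_Ito,scale_IKur,scale_ICaL dimensionless multipliers
#'   (all must be >= 0)
#' @param ACh_uM acetylcholine concentration (µM) switched on by the profile
#' @return an object of class `remodeling_profile`
#' @seealso [af_remodeling()] for the persistent-AF preset
#' @export
remodeling_profile <- function(scale_IK1 = 1, scale_Ito = 1, scale_IKur = 1,
                               scale_ICaL = 1, ACh_uM = 0) {
  sc <- c(scale_IK1 = scale_IK1, scale_Ito = scale_Ito,
          scale_IKur = scale_IKur, scale_ICaL = scale_ICaL, ACh_uM = ACh_uM)
  if (any(sc < 0)) stop("remodeling scale factors must be non-negative")
  structure(as.list(sc), class = "remodeling_profile")
}

#' @rdname remodeling_profile
#' @details `af_remodeling()` returns the persistent-AF profile
#'   (2.0, 0.5, 0.5, 0.3, ACh 0.005 µM).
#' @export
af_remodeling <- function() {
  remodeling_profile(scale_IK1 = 2.0, scale_Ito = 0.5, scale_IKur = 0.5,
                     scale_ICaL = 0.3, ACh_uM = 0.005)
}

#' Apply an ionic remodeling profile to cell parameters
#'
#' Returns a new parameter set with the affected maximal conductances
#' multiplied by the profile's scale factors and the acetylcholine level set;
#' the input is not modified. Applying a profile twice composes
#' multiplicatively.
#'
#' @param params a [cell_params()] object
#' @param profile a [remodeling_profile()]
#' @return a new `cell_params` object
#' @export
apply_remodeling <- function(params, profile) {
  stopifnot(inherits(params, "cell_params"),
            inherits(profile, "remodeling_profile"))
  p <- params
  p[["gK1"]] <- p[["gK1"]] * profile$scale_IK1
  p[["gto"]] <- p[["gto"]] * profile$scale_Ito
  p[["gKur"]] <- p[["gKur"]] * profile$scale_IKur
  p[["gCaL"]] <- p[["gCaL"]] * profile$scale_ICaL
  p[["ACh"]] <- profile$ACh_uM
  p
}

#' Acetylcholine-activated inward rectifier current (Kneller formulation)
#'
#' \deqn{I_{KACh} = \frac{10}{1 + 9.13652/\mathrm{ACh}^{0.477811}}
#'   \left(0.0517 + \frac{0.4516}{1 + e^{(V_m+59.53)/17.18}}\right)(V_m - E_K)}
#'
#' with ACh in µM and the result in pA/pF. The concentration factor is
#' monotone increasing in ACh with supremum 10; `ACh = 0` returns 0 (the limit
#' value).
#'
#' @param Vm membrane potential (mV)
#' @param ACh acetylcholine concentration (µM, >= 0)
#' @param EK potassium Nernst potential (mV)
#' @return current density (pA/pF); vectorized over its arguments
#' @export
i_kach <- function(Vm, ACh, EK) {
  if (any(ACh < 0)) stop("ACh must be non-negative")
  dose <- ifelse(ACh > 0, 10 / (1 + 9.13652 / ACh^0.477811), 0)
  volt <- 0.0517 + 0.4516 / (1 + exp((Vm + 59.53) / 17.18))
  dose * volt * (Vm - EK)
}

#' Sarcolemmal currents at a given state
#'
#' Evaluates every CRN current plus \eqn{I_{KACh}} at the supplied state, in
#' pA/pF, together with the Nernst potentials and the total ionic current.
#'
#' @param state a [cell_state()]
#' @param params a [cell_params()]
#' @return a named list of class `current_set`
#' @export
compute_currents <- function(state, params) {
  stopifnot(inherits(state, "cell_state"), inherits(params, "cell_params"))
  validate_cell_state(state)
  v <- crn_currents_cpp(as_state_vector(state), unclass(params))
  structure(as.list(v), class = "current_set")
}

#' @export
print.current_set <- function(x, ...) {
  cat("Sarcolemmal currents (pA/pF):\n")
  print(round(unlist(x), 5))
  invisible(x)
}

#' Advance a single cell by one or more integration steps
#'
#' Rush-Larsen update for the gating variables and forward Euler for the
#' membrane potential and concentrations.
#'
#' @param state a [cell_state()]
#' @param params a [cell_params()]
#' @param dt time step (ms, > 0); 0.005 ms is the package default for
#'   single-cell work
#' @param Istim stimulus current density (pA/pF, depolarizing positive),
#'   applied for the whole span
#' @param n number of steps to take
#' @param use_tables use the tabulated voltage-dependent rates (default); set
#'   `FALSE` to evaluate every rate exactly at each step
#' @return the advanced `cell_state`
#' @export
step_cell <- function(state, params, dt = 0.005, Istim = 0, n = 1,
                      use_tables = TRUE) {
  stopifnot(dt > 0, n >= 1)
  validate_cell_state(state)
  stim_times <- if (Istim != 0) 0 else numeric(0)
  res <- crn_run_cpp(as_state_vector(state), unclass(params), dt, n * dt,
                     stim_times + state$t, Istim, n * dt, as.integer(n),
                     state$t, use_tables)
  state_from_vector(res$state, t = res$t_end)
}
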