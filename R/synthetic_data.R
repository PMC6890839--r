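with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Generate noisy Hill-type concentration-response data
#'
#' Samples normalized remaining current from [hill_response()] plus Gaussian
#' noise (truncated at 0), emulating whole-cell concentration-response
#' measurements. Identical arguments and seed give bit-identical output.
#'
#' @param IC50 true half-maximal inhibitory concentration (µM, > 0)
#' @param slope true signed Hill slope
#' @param concentrations concentrations to sample at (µM)
#' @param noise_sd Gaussian noise standard deviation
#' @param replicates replicates per concentration
#' @param seed RNG seed
#' @return a [conc_response()] with attributes `IC50`, `slope` (the truth)
#' @export
gen_conc_response <- function(IC50, slope, concentrations,
                              noise_sd = 0.05, replicates = 1, seed = 1) {
  stopifnot(IC50 > 0)
  if (!length(concentrations)) stop("empty concentration list")
  conc <- rep(concentrations, times = replicates)
  repl <- rep(seq_len(replicates), each = length(concentrations))
  y0 <- hill_response(log10(conc), log10(IC50), slope)
  y <- with_seed(seed, pmax(0, y0 + stats::rnorm(length(conc), 0, noise_sd)))
  out <- conc_response(conc, y, replicate = repl)
  attr(out, "IC50") <- IC50
  attr(out, "slope") <- slope
  out
}

#' Generate a channel-like pore geometry with known constriction radius
#'
#' Builds a membrane-slab of carbon-like pseudo-atoms (van der Waals radius
#' 1.7 Å) pierced by a cylindrical pore whose minimal free aperture equals
#' `aperture` analytically: every slab layer carries an exact ring of atoms
#' at radius `aperture + 1.7` around the axis, and the remaining slab is
#' filled with a watertight atom lattice out to the lateral edge of the
#' eventual voxel grid (so the only route from the extracellular to the
#' intracellular side is through the pore). Optionally a spherical
#' pseudo-ligand of radius `aperture - ligand_gap` is parked against the pore
#' wall at mid-height, leaving a crescent-shaped side passage whose largest
#' inscribed sphere has radius `ligand_gap` exactly.
#'
#' @param channel_length slab thickness along z (Å)
#' @param aperture free pore radius without the ligand (Å, > 0)
#' @param ligand_gap radius of the widest sphere that can still slip past the
#'   ligand (Å); `NULL` for no ligand; must be smaller than `aperture`
#' @param margin lateral slab extent beyond the pore ring (Å); smaller values
#'   give compact fixtures for brute-force cross-checks
#' @param seed RNG seed (ring phase and sub-voxel lattice jitter)
#' @return an [atom_set()] with attributes `aperture` and `ligand_gap`; use
#'   `pad_xy = 0.1` when voxelating so the slab reaches the grid boundary
#' @export
gen_pore_geometry <- function(channel_length = 6, aperture = 2.5,
                              ligand_gap = NULL, margin = 4.5, seed = 1) {
  stopifnot(aperture > 0, channel_length > 0, margin > 0)
  if (!is.null(ligand_gap) && ligand_gap >= aperture)
    stop("ligand_gap must be smaller than aperture (ligand would not constrict)")
  r_atom <- 1.7
  ring_R <- aperture + r_atom
  zs <- seq(-channel_length / 2, channel_length / 2, by = 0.8)
  half_w <- ring_R + margin  # lateral half-extent of the slab

  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    pts <- list()
    for (z in zs) {
      n_ring <- ceiling(2 * pi * ring_R / 0.8)
      th <- phase + 2 * pi * seq_len(n_ring) / n_ring
      pts[[length(pts) + 1]] <-
        cbind(ring_R * cos(th), ring_R * sin(th), z)
      # watertight filler lattice outside the ring
      gs <- seq(-half_w, half_w, by = 1.0)
      gp <- expand.grid(x = gs, y = gs)
      keep <- sqrt(gp$x^2 + gp$y^2) >= ring_R + 0.4
      gp <- gp[keep, , drop = FALSE]
      jit <- matrix(stats::runif(2 * nrow(gp), -0.05, 0.05), ncol = 2)
      pts[[length(pts) + 1]] <- cbind(gp$x + jit[, 1], gp$y + jit[, 2], z)
    }
    xyz <- do.call(rbind, pts)
    atoms <- atom_set(element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      ligand = FALSE, radius = r_atom)
    if (!is.null(ligand_gap)) {
      r_lig <- aperture - ligand_gap
      dir <- stats::runif(1, 0, 2 * pi)
      lig <- atom_set(element = "C",
                      x = ligand_gap * cos(dir), y = ligand_gap * sin(dir),
                      z = 0, ligand = TRUE, radius = r_lig, resid = "LIG")
      atoms <- rbind(atoms, lig)
      class(atoms) <- c("atom_set", "data.frame")
    }
    attr(atoms, "aperture") <- aperture
    attr(atoms, "ligand_gap") <- if (is.null(ligand_gap)) NA_real_ else ligand_gap
    atoms
  })
}

egm_spike <- function(t, center, width, amp) {
  -amp * exp(-(t - center)^2 / (2 * width^2))
}

#' Generate a labeled synthetic electrogram of known morphology
#'
#' Periodic activation complexes built from monophasic (negative) Gaussian
#' deflections of ~2 ms width: one per cycle for a single potential, two
#' 25 ms apart for a double potential, and `n_deflections` (>= 3) 12 ms apart
#' with alternating amplitude for a fractionated electrogram. Per-cycle
#' timing jitter and additive Gaussian noise emulate recording variability.
#'
#' @param class morphology class: `"single"`, `"double"` or `"fractionated"`
#' @param rate activation rate (Hz, between 2 and 15)
#' @param duration signal length (s)
#' @param noise_sd additive noise standard deviation (signal amplitude is 1)
#' @param fs sampling rate (Hz)
#' @param n_deflections deflections per complex for the fractionated class
#' @param seed RNG seed
#' @return an [egm_record()] with attributes `label` (the class) and
#'   `rate` (Hz)
#' @export
gen_egm_morphology <- function(class = c("single", "double", "fractionated"),
                               rate = 8, duration = 4, noise_sd = 0,
                               fs = 1000, n_deflections = 5, seed = 1) {
  class <- match.arg(class)
  if (rate < 2 || rate > 15) stop("rate must lie in [2, 15] Hz")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  cycle <- 1 / rate
  offsets <- switch(class,
                    single = 0,
                    double = c(0, 0.025),
                    fractionated = (seq_len(max(3, n_deflections)) - 1) * 0.012)
  amps <- switch(class,
                 single = 1,
                 double = c(1, 0.9),
                 fractionated = 0.8 + 0.2 * (seq_along(offsets) %% 2))
  with_seed(seed, {
    x <- numeric(n)
    centers <- seq(0.05, duration - 0.05, by = cycle)
    for (cc in centers) {
      jit <- stats::rnorm(1, 0, 0.002)
      for (k in seq_along(offsets))
        x <- x + egm_spike(t, cc + jit + offsets[k], 0.002, amps[k])
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    rec <- egm_record(x, fs = fs)
    attr(rec, "label") <- class
    attr(rec, "rate") <- rate
    rec
  })
}

#' Generate a ready-to-run tissue scenario
#'
#' Desk-scale analogues of the whole-atria stimulation protocols:
#' `planar_wave` is a single S1 edge stimulus for conduction-velocity work;
#' `re_entry_seed` is an S1 edge train plus a focal S2 cluster with a scan of
#' candidate S2 coupling intervals for spiral-wave induction.
#'
#' @param name `"planar_wave"` or `"re_entry_seed"`
#' @param size grid size `c(nx, ny)` (at least 50 x 50)
#' @param dx node spacing (mm)
#' @param seed RNG seed (S2 cluster placement jitter)
#' @return a list with `grid` ([tissue_grid()]), `stims` (list of
#'   [stimulus_spec()]), and for `re_entry_seed` an `s2_scan` vector of
#'   candidate coupling intervals (ms) plus `s2_nodes`
#' @export
gen_tissue_fixture <- function(name = c("planar_wave", "re_entry_seed"),
                               size = c(100, 100), dx = 0.3, seed = 1) {
  name <- match.arg(name)
  if (any(size < 50)) stop("size must be at least 50 x 50 nodes")
  grid <- tissue_grid(nx = size[1], ny = size[2], dx = dx)
  s1_nodes <- node_index(grid, 1:2, seq_len(grid$ny))
  if (name == "planar_wave") {
    return(list(grid = grid,
                stims = list(stimulus_spec(s1_nodes, 28, 2, 0))))
  }
  with_seed(seed, {
    ci <- round(grid$nx * 0.3) + sample(-2:2, 1)
    cj <- round(grid$ny * 0.25) + sample(-2:2, 1)
    hw <- max(2L, round(grid$nx * 0.06))
    s2_nodes <- node_index(grid, (ci - hw):(ci + hw), (cj - hw):(cj + hw))
    stopifnot(!length(intersect(s2_nodes, s1_nodes)))
    list(grid = grid,
         stims = list(stimulus_spec(s1_nodes, 28, 2, 0)),
         s2_nodes = s2_nodes,
         s2_scan = seq(150, 230, by = 20))
  })
}
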