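#' Bondi-style van der Waals radii (Å)
#'
#' Element radii used to fill the voxel grid; hydrogen is assigned 1.2 Å.
#'
#' @return named numeric vector, element symbols in upper case
#' @export
vdw_radii <- function() {
  setNames(
    c(1.2, 1.7, 1.55, 1.52, 1.8, 1.8, 1.47, 1.75, 1.85, 1.98,
      2.27, 2.75, 1.73, 2.31, 1.39, 2.0, 2.0, 1.4, 1.9, 1.92),
    c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
      "NA", "K", "MG", "CA", "ZN", "FE", "MN", "CU", "SE", "B"))
}

lookup_vdw <- function(element) {
  tab <- vdw_radii()
  el <- toupper(trimws(element))
  unknown <- setdiff(unique(el), names(tab))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  unname(tab[el])
}

#' Atom set of a protein-ligand complex
#'
#' @param element element symbols
#' @param x,y,z Cartesian coordinates (Å)
#' @param ligand logical flag per atom (ligand vs protein)
#' @param radius van der Waals radii (Å); looked up from [vdw_radii()] when
#'   omitted
#' @param chain,resid optional labels
#' @return an object of class `atom_set` (a data frame)
#' @export
atom_set <- function(element, x, y, z, ligand = FALSE, radius = NULL,
                     chain = "A", resid = "UNK") {
  n <- length(x)
  if (is.null(radius)) radius <- lookup_vdw(element)
  stopifnot(length(y) == n, length(z) == n, all(radius > 0),
            all(is.finite(c(x, y, z))))
  d <- data.frame(element = as.character(element), x = x, y = y, z = z,
                  radius = radius, chain = rep_len(chain, n),
                  resid = rep_len(resid, n),
                  ligand = rep_len(as.logical(ligand), n))
  class(d) <- c("atom_set", "data.frame")
  d
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records, resolves alternate locations by keeping the
#' highest-occupancy copy of each atom (first on ties), assigns van der Waals
#' radii from the bundled element table, and flags the ligand by residue name
#' and/or chain.
#'
#' @param path PDB file
#' @param ligand ligand selector: a residue name (e.g. `"CLQ"`), or a list
#'   with any of `resid`, `chain`
#' @return an [atom_set()]
#' @export
read_structure <- function(path, ligand) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  # altloc resolution: highest occupancy per (chain, resno, insert, elety)
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  occ <- ifelse(is.na(a$o), 1, a$o)
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(ix) {
    ix[which.max(occ[ix])]
  }), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]

  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || all(trimws(el) == "")) {
    el <- substr(trimws(a$elety), 1, 1)  # fall back to the atom-name initial
  } else {
    miss <- is.na(el) | trimws(el) == ""
    el[miss] <- substr(trimws(a$elety[miss]), 1, 1)
  }

  if (is.character(ligand)) ligand <- list(resid = ligand)
  lig <- rep(TRUE, nrow(a))
  if (!is.null(ligand$resid)) lig <- lig & a$resid %in% ligand$resid
  if (!is.null(ligand$chain)) lig <- lig & a$chain %in% ligand$chain
  if (!any(lig)) stop("ligand selection matched no atoms")

  atom_set(element = el, x = a$x, y = a$y, z = a$z, ligand = lig,
           chain = a$chain, resid = a$resid)
}

#' Voxelate an atom set
#'
#' Builds a cubic voxel grid around the atoms (padded on all sides) and
#' computes, at every voxel center, the clearance: the distance to the
#' nearest van der Waals surface (negative inside an atom). A voxel is
#' occupied in the van der Waals sense iff its clearance is negative, which
#' reproduces filling each atom's sphere with 0.2 Å cubes; keeping the signed
#' clearance as well lets the probe feasibility test work in continuous
#' distance, avoiding a second discretization.
#'
#' @param atoms an [atom_set()]
#' @param edge voxel edge length (Å); 0.2 by default
#' @param max_probe largest probe radius the grid must support (Å)
#' @param pad_xy,pad_z grid padding beyond the atom extent (Å); the default
#'   pads by the largest van der Waals radius plus `max_probe` on all sides.
#'   Synthetic membrane-slab fixtures use a small lateral pad so that the
#'   sheet effectively extends to the grid boundary.
#' @return an object of class `voxel_grid`: `origin`, `edge`, `dims`,
#'   `clearance` (3D array, Å), `atoms`
#' @export
voxelate <- function(atoms, edge = 0.2, max_probe = 3.9, pad_xy = NULL,
                     pad_z = NULL) {
  stopifnot(inherits(atoms, "atom_set"), nrow(atoms) > 0, edge > 0)
  pad_default <- max(atoms$radius) + max_probe
  if (is.null(pad_xy)) pad_xy <- pad_default
  if (is.null(pad_z)) pad_z <- pad_default
  lo <- c(min(atoms$x) - pad_xy, min(atoms$y) - pad_xy, min(atoms$z) - pad_z)
  hi <- c(max(atoms$x) + pad_xy, max(atoms$y) + pad_xy, max(atoms$z) + pad_z)
  dims <- as.integer(ceiling((hi - lo) / edge)) + 1L
  cap <- max_probe + 2 * edge
  clr <- pore_clearance_cpp(as.matrix(atoms[, c("x", "y", "z")]),
                            atoms$radius, lo, dims, edge, cap)
  structure(list(origin = lo, edge = edge, dims = dims, clearance = clr,
                 cap = cap, atoms = atoms),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %d x %d x %d at %.2g A (%d atoms, %.0f%% occupied)\n",
              x$dims[1], x$dims[2], x$dims[3], x$edge, nrow(x$atoms),
              100 * mean(x$clearance < 0)))
  invisible(x)
}

#' Van der Waals occupancy of a voxel grid
#'
#' @param grid a [voxel_grid()]
#' @return logical 3D array: voxel centers lying inside any atom's van der
#'   Waals sphere
#' @export
occupancy <- function(grid) {
  o <- grid$clearance < 0
  dim(o) <- grid$dims
  o
}

#' Can a probe sphere traverse the pore?
#'
#' A probe center is feasible iff its distance to every atom center is at
#' least the atom's van der Waals radius plus the probe radius. The verdict
#' is `pass` iff a connected feasible path (26-connectivity by default)
#' exists from the entry slab at the grid top (the extracellular opening) to
#' the exit slab at the bottom; the search is an exhaustive flood fill, so
#' every lateral adjustment of the probe position is explored. If the entry
#' slab admits no feasible position at all the verdict is `blocked` with
#' `no_aperture = TRUE`.
#'
#' @param grid a [voxel_grid()]
#' @param probe_radius probe radius (Å, > 0, at most the grid's supported
#'   maximum)
#' @param connectivity 26 (default) or 6
#' @param slab entry/exit slab thickness (Å)
#' @param method `"clearance"` (continuous-distance feasibility, default) or
#'   `"edt"` (feasibility by thresholding the Euclidean distance transform of
#'   the van der Waals occupancy — the fully voxelized variant)
#' @return list with `pass` (logical) and `no_aperture` (logical)
#' @export
probe_traverses <- function(grid, probe_radius, connectivity = 26, slab = 2,
                            method = c("clearance", "edt")) {
  stopifnot(inherits(grid, "voxel_grid"), probe_radius > 0)
  method <- match.arg(method)
  if (probe_radius > grid$cap)
    stop("probe radius exceeds the grid's supported maximum (", grid$cap, " A)")
  field <- switch(method,
                  clearance = grid$clearance,
                  edt = grid_edt(grid))
  nz_slab <- max(1L, as.integer(round(slab / grid$edge)))
  code <- pore_flood_cpp(field, grid$dims, probe_radius,
                         as.integer(connectivity), nz_slab)
  list(pass = code == 2L, no_aperture = code == 0L)
}

grid_edt <- function(grid) {
  if (!is.null(grid$edt)) return(grid$edt)
  occ <- grid$clearance < 0
  pore_edt_cpp(occ, grid$dims, grid$edge)
}

#' Probe-radius scan of a protein-ligand complex
#'
#' Voxelates the complex and runs [probe_traverses()] over a ladder of probe
#' radii (1.4 Å, the bare K+ ionic radius, to 3.9 Å in 0.1 Å steps by
#' default). Verdicts are monotone by construction: the feasible set shrinks
#' as the radius grows. The scan is repeated with the ligand removed so that
#' ligand-caused occlusion can be told apart from the channel's intrinsic
#' constriction.
#'
#' @param atoms an [atom_set()] containing at least one ligand atom (unless
#'   `ligand_free_only`)
#' @param radii probe radii to scan (Å, ascending)
#' @param edge voxel edge (Å)
#' @param connectivity,slab,method passed to [probe_traverses()]
#' @param pad_xy,pad_z passed to [voxelate()]
#' @param ligand_free_only skip the with-ligand scan
#' @return an object of class `probe_result`: `verdicts` data frame
#'   (radius, pass, no_aperture, pass_ligand_free), `min_blocking_radius`,
#'   `max_passing_radius`, and the ligand-free equivalents
#' @export
blocking_scan <- function(atoms, radii = seq(1.4, 3.9, by = 0.1), edge = 0.2,
                          connectivity = 26, slab = 2,
                          method = c("clearance", "edt"),
                          pad_xy = NULL, pad_z = NULL,
                          ligand_free_only = FALSE) {
  method <- match.arg(method)
  if (is.unsorted(radii)) stop("radii must be sorted ascending")
  scan_one <- function(a) {
    g <- voxelate(a, edge = edge, max_probe = max(radii), pad_xy = pad_xy,
                  pad_z = pad_z)
    if (identical(method, "edt")) g$edt <- grid_edt(g)
    t(vapply(radii, function(r) {
      v <- probe_traverses(g, r, connectivity = connectivity, slab = slab,
                           method = method)
      c(pass = v$pass, no_aperture = v$no_aperture)
    }, logical(2)))
  }
  with_lig <- if (ligand_free_only) NULL else scan_one(atoms)
  prot <- atoms[!atoms$ligand, , drop = FALSE]
  free <- scan_one(if (nrow(prot)) prot else atoms)
  v_main <- if (is.null(with_lig)) free else with_lig

  verdicts <- data.frame(radius = radii,
                         pass = v_main[, "pass"],
                         no_aperture = v_main[, "no_aperture"],
                         pass_ligand_free = free[, "pass"])
  summarize <- function(pass) {
    blocked <- which(!pass)
    passing <- which(pass)
    list(min_block = if (length(blocked)) radii[blocked[1]] else NA_real_,
         max_pass = if (length(passing)) radii[max(passing)] else NA_real_)
  }
  s <- summarize(verdicts$pass)
  sf <- summarize(verdicts$pass_ligand_free)
  structure(list(verdicts = verdicts,
                 min_blocking_radius = s$min_block,
                 max_passing_radius = s$max_pass,
                 min_blocking_radius_ligand_free = sf$min_block,
                 max_passing_radius_ligand_free = sf$max_pass,
                 radii = radii, method = method),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("probe scan over %.1f-%.1f A (%d radii):\n",
              min(x$radii), max(x$radii), length(x$radii)))
  fmt <- function(v) if (is.na(v)) "none in scan" else sprintf("%.1f A", v)
  cat("  max passing radius: ", fmt(x$max_passing_radius), "\n", sep = "")
  cat("  min blocking radius:", fmt(x$min_blocking_radius), "\n")
  cat("  ligand-free min blocking radius:",
      fmt(x$min_blocking_radius_ligand_free), "\n")
  invisible(x)
}
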