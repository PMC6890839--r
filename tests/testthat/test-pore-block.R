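write_mini_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1.0, el = "C", rec = "ATOM  ", alt = " ") {
  sprintf("%s%5d %4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, alt, resn, chain, resno, x, y, z, occ, 0.0, el)
}

test_that("read_structure separates HETATM ligands and errors on empty selection", {
  f <- write_mini_pdb(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " N  ", "ALA", "A", 1, 1.5, 0, 0, el = "N"),
    pdb_atom_line(3, " C1 ", "CLQ", "B", 9, 3, 3, 3, rec = "HETATM")))
  a <- read_structure(f, ligand = "CLQ")
  expect_equal(nrow(a), 3)
  expect_equal(sum(a$ligand), 1)
  expect_equal(a$resid[a$ligand], "CLQ")
  expect_equal(a$x[2], 1.5)
  expect_equal(a$radius[2], 1.55)  # nitrogen
  expect_error(read_structure(f, ligand = "XYZ"), "no atoms")
})

test_that("altloc duplicates collapse to the highest-occupancy copy", {
  f <- write_mini_pdb(c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, " CA ", "ALA", "A", 1, 0.5, 0, 0, occ = 0.6, alt = "B"),
    pdb_atom_line(3, " C1 ", "CLQ", "B", 9, 3, 3, 3, rec = "HETATM")))
  a <- read_structure(f, ligand = "CLQ")
  expect_equal(nrow(a), 2)
  expect_equal(a$x[!a$ligand], 0.5)  # the 0.6-occupancy copy won
})

test_that("unknown elements are rejected by name", {
  expect_error(atom_set("Xx", 0, 0, 0), "unknown element.*XX")
})

test_that("voxel occupancy matches the analytic sphere volume within 3%", {
  a <- atom_set("C", 0, 0, 0)  # radius 1.7
  g <- voxelate(a, edge = 0.2, max_probe = 1.0)
  n_occ <- sum(g$clearance < 0)
  expect_equal(n_occ * 0.2^3, 4 / 3 * pi * 1.7^3, tolerance = 0.03)
  # far-away regions are unoccupied and fully clear
  expect_gte(max(g$clearance), 1.0)
})

test_that("occupancy of overlapping atoms is the set union", {
  a1 <- atom_set("C", 0, 0, 0)
  a2 <- atom_set("C", 1.0, 0, 0)
  both <- rbind(a1, a2); class(both) <- c("atom_set", "data.frame")
  # common grid so voxel centers align
  pad <- 2
  g_both <- voxelate(both, edge = 0.2, max_probe = 1, pad_xy = pad, pad_z = pad)
  occ_both <- occupancy(g_both)
  # recompute single-atom occupancies on the same grid via clearance calls
  clr1 <- atriablock:::pore_clearance_cpp(as.matrix(a1[, c("x", "y", "z")]),
                                          a1$radius, g_both$origin,
                                          g_both$dims, 0.2, g_both$cap)
  clr2 <- atriablock:::pore_clearance_cpp(as.matrix(a2[, c("x", "y", "z")]),
                                          a2$radius, g_both$origin,
                                          g_both$dims, 0.2, g_both$cap)
  expect_identical(as.vector(occ_both), as.vector(clr1 < 0 | clr2 < 0))
})

test_that("an annular constriction passes below and blocks above its aperture", {
  atoms <- gen_pore_geometry(aperture = 2.0, seed = 11)
  g <- voxelate(atoms, pad_xy = 0.1)
  expect_true(probe_traverses(g, 1.9)$pass)
  expect_false(probe_traverses(g, 2.1)$pass)
})

test_that("verdicts are monotone across the probe-radius scan", {
  atoms <- gen_pore_geometry(aperture = 2.6, seed = 5)
  res <- blocking_scan(atoms, pad_xy = 0.1, ligand_free_only = TRUE)
  v <- res$verdicts$pass
  expect_true(all(diff(v) <= 0))  # once blocked, stays blocked
  expect_equal(res$min_blocking_radius, res$max_passing_radius + 0.1,
               tolerance = 1e-9)
})

test_that("a wide channel passes the whole scan; one-radius scans degenerate cleanly", {
  atoms <- gen_pore_geometry(aperture = 5.0, seed = 3)
  res <- blocking_scan(atoms, pad_xy = 0.1, ligand_free_only = TRUE)
  expect_true(all(res$verdicts$pass))
  expect_true(is.na(res$min_blocking_radius))
  one <- blocking_scan(atoms, radii = 2.0, pad_xy = 0.1,
                       ligand_free_only = TRUE)
  expect_equal(nrow(one$verdicts), 1)
  expect_true(one$verdicts$pass)
})

test_that("a parked ligand shifts the blocking radius to its side gap", {
  atoms <- gen_pore_geometry(aperture = 3.5, ligand_gap = 2.0, seed = 2)
  res <- blocking_scan(atoms, pad_xy = 0.1)
  expect_equal(res$min_blocking_radius, 2.1, tolerance = 0.100001)
  # ligand-free scan recovers the intrinsic aperture
  expect_equal(res$min_blocking_radius_ligand_free, 3.5, tolerance = 0.100001)
  # ligand monotonicity: the ligand never increases the passing radius
  expect_lte(res$max_passing_radius, res$max_passing_radius_ligand_free)
})

test_that("the verdict is invariant under rigid motion within one voxel", {
  atoms <- gen_pore_geometry(channel_length = 2.4, aperture = 2.2,
                             margin = 1.6, seed = 8)
  res0 <- blocking_scan(atoms, radii = seq(1.4, 2.7, 0.1), pad_xy = 0.1,
                        pad_z = 4.6, ligand_free_only = TRUE)
  th <- 0.31
  rot <- atoms
  rot$x <- cos(th) * atoms$x - sin(th) * atoms$y + 0.37
  rot$y <- sin(th) * atoms$x + cos(th) * atoms$y - 0.21
  res1 <- blocking_scan(rot, radii = seq(1.4, 2.7, 0.1), pad_xy = 0.1,
                        pad_z = 4.6, ligand_free_only = TRUE)
  expect_lte(abs(res1$min_blocking_radius - res0$min_blocking_radius),
             0.2 + 1e-9)
})

test_that("halving the voxel edge moves the blocking radius by at most one coarse edge", {
  atoms <- gen_pore_geometry(channel_length = 2.4, aperture = 2.2,
                             margin = 1.6, seed = 4)
  r2 <- blocking_scan(atoms, radii = seq(1.4, 2.7, 0.1), edge = 0.2,
                      pad_xy = 0.1, pad_z = 4.6, ligand_free_only = TRUE)
  r1 <- blocking_scan(atoms, radii = seq(1.4, 2.7, 0.1), edge = 0.1,
                      pad_xy = 0.1, pad_z = 4.6, ligand_free_only = TRUE)
  expect_lte(abs(r1$min_blocking_radius - r2$min_blocking_radius), 0.2 + 1e-9)
})

test_that("a sealed wall blocks at every radius; a closed entry is reported as no aperture", {
  # a solid wall: dense slab with no pore
  gs <- expand.grid(x = seq(-4, 4, 1), y = seq(-4, 4, 1), z = c(-0.5, 0.5))
  wall <- atom_set("C", gs$x, gs$y, gs$z)
  g <- voxelate(wall, edge = 0.2, max_probe = 2.0, pad_xy = 0.1)
  v <- probe_traverses(g, 1.5)
  expect_false(v$pass)
  expect_false(v$no_aperture)  # entry headroom exists above the wall
  # shallow headroom: no feasible entry position at all
  g2 <- voxelate(wall, edge = 0.2, max_probe = 2.0, pad_xy = 0.1, pad_z = 2.0)
  v2 <- probe_traverses(g2, 1.5)
  expect_false(v2$pass)
  expect_true(v2$no_aperture)
})

test_that("flood-fill verdicts agree with the brute-force distance-transform oracle", {
  for (seed in 1:3) {
    ap <- c(1.85, 2.15, 2.45)[seed]
    g <- small_pore_grid(aperture = ap, seed = seed)
    expect_lte(prod(g$dims), 40^3)
    edt <- brute_edt(occupancy(g), g$edge)
    for (r in seq(1.4, 2.6, by = 0.3)) {
      pkg <- probe_traverses(g, r, method = "edt")
      orc <- oracle_traverses(g, r, edt = edt)
      expect_identical(pkg$pass, orc$pass,
                       label = sprintf("seed %d radius %.1f", seed, r))
    }
    # the continuous-clearance and voxelized feasibility variants agree to
    # within one voxel on the blocking radius
    radii <- seq(1.4, 2.6, 0.1)
    mb <- function(method) {
      pass <- vapply(radii, function(r)
        probe_traverses(g, r, method = method)$pass, logical(1))
      radii[which(!pass)[1]]
    }
    expect_lte(abs(mb("clearance") - mb("edt")), 0.3 + 1e-9)
  }
})
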