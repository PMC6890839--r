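# Brute-force oracle for the probe traversal: Euclidean distance transform of
# the van der Waals occupancy computed by direct minimization over occupied
# voxel centers, thresholded at the probe radius, followed by connectivity
# analysis via iterative 26-neighbor dilation.  Fully independent of the C++
# flood fill / separable-EDT implementation.

brute_edt <- function(occ, edge) {
  dims <- dim(occ)
  out <- array(Inf, dims)
  occ_idx <- which(occ, arr.ind = TRUE)
  if (!nrow(occ_idx)) return(out)
  # only surface voxels of the occupied set can be nearest to outside points
  surf <- rep(FALSE, nrow(occ_idx))
  for (d in 1:3) for (s in c(-1L, 1L)) {
    nb <- occ_idx
    nb[, d] <- nb[, d] + s
    inside <- nb[, d] >= 1 & nb[, d] <= dims[d]
    free <- !inside
    free[inside] <- !occ[nb[inside, , drop = FALSE]]
    surf <- surf | free
  }
  occ_pts <- occ_idx[surf, , drop = FALSE]
  q <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                             k = seq_len(dims[3])))
  o2 <- rowSums(occ_pts^2)
  n <- nrow(q)
  dmin <- numeric(n)
  chunk <- 4000L
  for (s in seq(1, n, by = chunk)) {
    ix <- s:min(n, s + chunk - 1)
    qq <- q[ix, , drop = FALSE]
    cross <- tcrossprod(qq, occ_pts)          # (chunk x nocc)
    d2 <- outer(rowSums(qq^2), o2, "+") - 2 * cross
    dmin[ix] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out[] <- dmin * edge
  out[occ] <- 0
  out
}

oracle_traverses <- function(grid, probe_radius, slab = 2, edt = NULL) {
  if (is.null(edt)) edt <- brute_edt(occupancy(grid), grid$edge)
  feas <- edt >= probe_radius
  d <- dim(feas)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nz_slab <- max(1L, as.integer(round(slab / grid$edge)))
  entry <- array(FALSE, d); entry[, , (nz - nz_slab + 1):nz] <- TRUE
  visited <- rep(FALSE, length(feas))
  frontier <- which(feas & entry)
  if (!length(frontier)) return(list(pass = FALSE, no_aperture = TRUE))
  visited[frontier] <- TRUE
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  feas_lin <- as.vector(feas)
  repeat {
    ai <- arrayInd(frontier, d)
    if (any(ai[, 3] <= nz_slab)) return(list(pass = TRUE, no_aperture = FALSE))
    newf <- integer(0)
    for (m in seq_len(nrow(offs))) {
      ii <- ai[, 1] + offs[m, 1]; jj <- ai[, 2] + offs[m, 2]
      kk <- ai[, 3] + offs[m, 3]
      ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & kk >= 1 & kk <= nz
      nidx <- ii[ok] + (jj[ok] - 1L) * nx + (kk[ok] - 1L) * nx * ny
      nidx <- nidx[feas_lin[nidx] & !visited[nidx]]
      visited[nidx] <- TRUE
      newf <- c(newf, nidx)
    }
    frontier <- unique(newf)
    if (!length(frontier)) return(list(pass = FALSE, no_aperture = FALSE))
  }
}

# compact constricted-pore fixture small enough for the brute-force oracle;
# pad_z leaves vdW radius + max probe of headroom so the entry slab is open
small_pore_grid <- function(aperture, seed = 1, edge = 0.3, max_probe = 2.7) {
  atoms <- gen_pore_geometry(channel_length = 2.4, aperture = aperture,
                             seed = seed, margin = 1.6)
  voxelate(atoms, edge = edge, max_probe = max_probe, pad_xy = 0.1,
           pad_z = 1.7 + max_probe + 0.2)
}
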