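#' Electrogram record
#'
#' @param values raw extracellular potential samples (arbitrary units)
#' @param fs sampling rate (Hz)
#' @param t0 time of the first sample (s)
#' @return an object of class `egm_record` with elements `raw`, `fs`, `t0`
#'   and (after [condition_egm()]) `conditioned`
#' @export
egm_record <- function(values, fs, t0 = 0) {
  stopifnot(fs > 0, length(values) >= 1)
  structure(list(raw = as.numeric(values), conditioned = NULL, fs = fs,
                 t0 = t0),
            class = "egm_record")
}

#' @export
print.egm_record <- function(x, ...) {
  cat(sprintf("egm_record: %d samples at %g Hz (%.2f s)%s\n",
              length(x$raw), x$fs, length(x$raw) / x$fs,
              if (is.null(x$conditioned)) "" else ", conditioned"))
  invisible(x)
}

#' Synthesize a pseudo-unipolar electrogram from a tissue run
#'
#' Discretizes the large-volume-conductor integral
#' \deqn{\Phi_e(r) = -K \iiint \nabla' V_m(r') \cdot
#'   \nabla' \frac{1}{|r' - r|} \, dv}
#' over the recorded membrane-potential snapshots: the transmembrane gradient
#' is taken by central differences, the kernel gradient analytically, and the
#' volume element is `dx^2 * thickness`. `K = -0.0398` absorbs the
#' conductivity ratio.
#'
#' @param run a [run_tissue()] result with snapshots (`record_dt > 0`)
#' @param electrode electrode position `c(x, y, z)` in mm; `z` is the height
#'   above the sheet and must be nonzero
#' @param K volume-conductor constant
#' @param thickness sheet thickness (mm)
#' @return an [egm_record()] sampled at the snapshot cadence
#' @export
compute_egm <- function(run, electrode, K = -0.0398, thickness = 0.3) {
  stopifnot(inherits(run, "tissue_run"))
  if (is.null(run$snapshots))
    stop("run has no snapshots; re-run with record_dt > 0")
  if (abs(electrode[3]) < 1e-9)
    stop("electrode lies in the tissue plane")
  g <- run$grid
  nx <- g$nx; ny <- g$ny; dx <- g$dx
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx
  rx <- outer(xs - electrode[1], rep(1, ny))
  ry <- outer(rep(1, nx), ys - electrode[2])
  rz <- -electrode[3]
  d3 <- (rx^2 + ry^2 + rz^2)^1.5
  dv <- dx^2 * thickness
  # phi_e = -K * sum gradVm . grad'[1/|r'-r|] dv, grad'[...] = -(r'-r)/|r'-r|^3
  wx <- -K * (-rx / d3) * dv
  wy <- -K * (-ry / d3) * dv

  nframes <- ncol(run$snapshots)
  phi <- numeric(nframes)
  for (f in seq_len(nframes)) {
    V <- matrix(run$snapshots[, f], nx, ny)
    gx <- (V[c(2:nx, nx), ] - V[c(1, 1:(nx - 1)), ]) / (2 * dx)
    gy <- (V[, c(2:ny, ny)] - V[, c(1, 1:(ny - 1))]) / (2 * dx)
    phi[f] <- sum(wx * gx) + sum(wy * gy)
  }
  fs <- if (nframes >= 2) 1000 / diff(run$snap_times[1:2]) else 1
  egm_record(phi, fs = fs, t0 = run$snap_times[1] / 1000)
}

#' Condition an electrogram for spectral analysis
#'
#' The standard dominant-frequency preprocessing chain: 40-250 Hz band-pass
#' (4th-order Butterworth), full-wave rectification, then a 20 Hz low-pass
#' (4th-order Butterworth). Both filters are applied forward-backward for
#' zero phase.
#'
#' @param x an [egm_record()] or a numeric signal
#' @param fs sampling rate (Hz); taken from the record if omitted
#' @param band band-pass corner frequencies (Hz)
#' @param lp low-pass corner (Hz)
#' @return for a record input, the record with `conditioned` filled in;
#'   otherwise the conditioned numeric signal
#' @export
condition_egm <- function(x, fs = NULL, band = c(40, 250), lp = 20) {
  rec <- NULL
  if (inherits(x, "egm_record")) {
    rec <- x
    fs <- x$fs
    x <- x$raw
  }
  if (is.null(fs)) stop("fs is required for a plain numeric signal")
  if (fs < 2 * band[2])
    stop("sampling rate too low for the ", band[2], " Hz band edge")
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  lo <- signal::butter(4, lp / (fs / 2), type = "low")
  y <- signal::filtfilt(bp, x)
  y <- abs(y)
  y <- signal::filtfilt(lo, y)
  if (!is.null(rec)) {
    rec$conditioned <- y
    rec
  } else y
}

#' Dominant frequency of a conditioned electrogram
#'
#' FFT-based power spectrum (Hann window, zero padding to the next power of
#' two); the dominant frequency is the frequency of the highest power peak
#' within the analysis band.
#'
#' @param x conditioned signal (numeric) or an [egm_record()] with a
#'   `conditioned` element
#' @param fs sampling rate (Hz); taken from the record if omitted
#' @param band analysis band (Hz), default 2-20 Hz
#' @return an object of class `spectrum_result`: `frequency`, `power`, `df`
#' @export
dominant_frequency <- function(x, fs = NULL, band = c(2, 20)) {
  if (inherits(x, "egm_record")) {
    fs <- x$fs
    x <- if (!is.null(x$conditioned)) x$conditioned else
      stop("record is not conditioned; call condition_egm() first")
  }
  if (is.null(fs)) stop("fs is required for a plain numeric signal")
  n <- length(x)
  if (n / fs < 2)
    stop("signal shorter than 2 s: insufficient frequency resolution")
  if (all(x == 0)) stop("all-zero signal has no spectral peak")
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  nfft <- 2^ceiling(log2(n))
  xp <- c(x * w, numeric(nfft - n))
  p <- Mod(fft(xp))^2
  freq <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("analysis band contains no frequency bins")
  f_band <- freq[keep]
  p_band <- p[keep]
  structure(list(frequency = f_band, power = p_band,
                 df = f_band[which.max(p_band)],
                 resolution = fs / nfft),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("dominant frequency: %.2f Hz (resolution %.3f Hz)\n",
              x$df, x$resolution))
  invisible(x)
}

#' Classify electrogram morphology per activation window
#'
#' Activation windows are segmented from the conditioned envelope (peaks
#' above `envelope_frac` of the envelope maximum); within each window the
#' deflections of the raw signal are counted as local extrema whose swing
#' exceeds `prominence_frac` of the window's peak-to-peak amplitude,
#' separated by at least `min_separation` ms. One deflection is a single
#' potential, two a double potential, more than two a fractionated
#' electrogram; windows with no deflection above threshold are reported as
#' unclassified.
#'
#' @param x an [egm_record()] (conditioned on the fly if needed) or a raw
#'   numeric signal
#' @param fs sampling rate (Hz) for a plain numeric signal
#' @param envelope_frac envelope peak threshold (fraction of maximum)
#' @param prominence_frac deflection threshold (fraction of window
#'   peak-to-peak)
#' @param min_separation minimal deflection separation (ms)
#' @return a data frame with one row per activation window: `t_start`,
#'   `t_end` (s), `n_deflections`, `class`
#' @export
classify_egm <- function(x, fs = NULL, envelope_frac = 0.3,
                         prominence_frac = 0.2, min_separation = 10) {
  if (inherits(x, "egm_record")) {
    if (is.null(x$conditioned)) x <- condition_egm(x)
    fs <- x$fs
    env <- x$conditioned
    raw <- x$raw
  } else {
    if (is.null(fs)) stop("fs is required for a plain numeric signal")
    raw <- x
    env <- condition_egm(x, fs = fs)
  }
  n <- length(raw)

  # envelope peaks above threshold, >= 40 ms apart
  thr <- envelope_frac * max(env)
  if (max(env) <= 0) stop("zero envelope: no detected activation window")
  min_gap <- round(0.040 * fs)
  pk <- which(diff(sign(diff(env))) == -2) + 1
  pk <- pk[env[pk] >= thr]
  if (!length(pk)) stop("no detected activation window")
  keep <- pk[1]
  for (p in pk[-1]) {
    if (p - tail(keep, 1) < min_gap) {
      if (env[p] > env[tail(keep, 1)]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  pk <- keep

  half <- if (length(pk) > 1) round(min(diff(pk)) / 2) else round(0.06 * fs)
  half <- min(half, round(0.08 * fs))

  sep <- round(min_separation / 1000 * fs)
  ksm <- max(1, round(0.0015 * fs))       # ~1.5 ms smoothing for noise
  if (ksm %% 2 == 0) ksm <- ksm + 1
  rows <- lapply(seq_along(pk), function(q) {
    i0 <- max(1, pk[q] - half)
    i1 <- min(n, pk[q] + half)
    seg <- raw[i0:i1]
    if (ksm > 1)
      seg <- as.numeric(stats::filter(seg, rep(1 / ksm, ksm), sides = 2))
    dev <- seg - median(seg, na.rm = TRUE)
    dev[is.na(dev)] <- 0
    ndef <- 0L
    amax <- max(abs(dev))
    if (amax > 0) {
      thr <- prominence_frac * amax
      # a deflection = a signed excursion beyond the threshold; excursions
      # closer than the separation are merged (largest kept)
      lab <- integer(length(dev))
      lab[dev > thr] <- 1L
      lab[dev < -thr] <- -1L
      r <- rle(lab)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      exc <- which(r$values != 0L)
      if (length(exc)) {
        peak_at <- vapply(exc, function(m) {
          ix <- starts[m]:ends[m]
          ix[which.max(abs(dev[ix]))]
        }, integer(1))
        peak_amp <- abs(dev[peak_at])
        ord <- order(peak_amp, decreasing = TRUE)
        chosen <- integer(0)
        for (m in ord) {
          if (!length(chosen) || all(abs(peak_at[m] - chosen) >= sep))
            chosen <- c(chosen, peak_at[m])
        }
        ndef <- length(chosen)
      }
    }
    cls <- if (ndef == 0) "unclassified" else if (ndef == 1) "single"
           else if (ndef == 2) "double" else "fractionated"
    data.frame(t_start = (i0 - 1) / fs, t_end = (i1 - 1) / fs,
               n_deflections = ndef, class = cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
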