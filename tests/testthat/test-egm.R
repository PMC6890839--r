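# minimal hand-built "tissue run" carrying snapshots for the forward model
fake_run <- function(V_list, nx, ny, dx = 0.3, dt_ms = 1) {
  snaps <- vapply(V_list, as.vector, numeric(nx * ny))
  structure(list(grid = tissue_grid(nx = nx, ny = ny, dx = dx, D = 0),
                 snapshots = matrix(snaps, nrow = nx * ny),
                 snap_times = (seq_along(V_list) - 1) * dt_ms),
            class = "tissue_run")
}

test_that("a spatially uniform field produces a null electrogram", {
  V <- matrix(-80, 20, 20)
  run <- fake_run(list(V, V + 100, V - 10), 20, 20)
  egm <- compute_egm(run, electrode = c(3, 3, 0.2))
  expect_equal(egm$raw, c(0, 0, 0))
})

test_that("antisymmetric gradients about the electrode cancel", {
  nx <- 21
  V <- matrix(-80, nx, nx)
  V[8, 11] <- -60    # equal and opposite bumps mirrored about the electrode
  V[14, 11] <- -100
  run <- fake_run(list(V), nx, nx)
  center <- c(10 * 0.3, 10 * 0.3, 0.2)  # on the symmetry axis
  egm <- compute_egm(run, electrode = center)
  expect_lt(abs(egm$raw[1]), 1e-12)
})

test_that("a single dipole matches the analytic kernel to 1e-12 relative", {
  nx <- 15; dx <- 0.3; K <- -0.0398; th <- 0.3
  V <- matrix(0, nx, nx)
  V[7, 8] <- 50  # one interior bump; only its neighborhood has gradients
  run <- fake_run(list(V), nx, nx, dx = dx)
  el <- c(1.1, 2.3, 0.7)
  egm <- compute_egm(run, electrode = el, K = K, thickness = th)
  # independent evaluation: sum over nodes of gradV . grad'(1/r) dv
  phi <- 0
  for (i in 1:nx) for (j in 1:nx) {
    gx <- (V[min(i + 1, nx), j] - V[max(i - 1, 1), j]) / (2 * dx)
    gy <- (V[i, min(j + 1, nx)] - V[i, max(j - 1, 1)]) / (2 * dx)
    if (gx == 0 && gy == 0) next
    r <- c((i - 1) * dx - el[1], (j - 1) * dx - el[2], -el[3])
    gk <- -r / sum(r^2)^1.5
    phi <- phi - K * sum(c(gx, gy) * gk[1:2]) * dx^2 * th
  }
  expect_equal(egm$raw[1], phi, tolerance = 1e-12)
})

test_that("the forward model is linear in the membrane potential field", {
  nx <- 12
  set.seed(42)
  V1 <- matrix(rnorm(nx * nx, -70, 20), nx, nx)
  V2 <- matrix(rnorm(nx * nx, -40, 30), nx, nx)
  el <- c(1.5, 1.8, 0.2)
  phi <- function(V) compute_egm(fake_run(list(V), nx, nx), el)$raw[1]
  expect_equal(phi(2 * V1 - 3 * V2), 2 * phi(V1) - 3 * phi(V2),
               tolerance = 1e-10)
})

test_that("electrogram amplitude decays monotonically with electrode height", {
  nx <- 15
  V <- matrix(0, nx, nx); V[7, 8] <- 50
  run <- fake_run(list(V), nx, nx)
  amps <- vapply(c(0.2, 0.4, 0.8, 1.6, 3.2), function(h)
    abs(compute_egm(run, electrode = c(2.0, 2.1, h))$raw[1]), numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("an electrode inside the tissue plane is rejected", {
  V <- matrix(0, 10, 10)
  run <- fake_run(list(V), 10, 10)
  expect_error(compute_egm(run, electrode = c(1, 1, 0)), "plane")
})

test_that("online (solver) and offline (snapshot) electrograms agree", {
  g <- tissue_grid(nx = 40, ny = 20, dx = 0.3, D = 0.0034)
  stim <- stimulus_spec(node_index(g, 1:3, 1:20), 28, 2, 0)
  el <- matrix(c(5, 3, 0.2), 1, 3)
  run <- run_tissue(g, tissue_states(g), params_unremodeled(), duration = 40,
                    dt = 0.02, stims = list(stim), record_dt = 1,
                    electrodes = el, egm_dt = 1)
  off <- compute_egm(run, electrode = el[1, ])
  expect_equal(as.vector(run$egm), off$raw, tolerance = 1e-9)
})

test_that("conditioning attenuates sub-band tones and demodulates envelopes", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  # 10 Hz tone: >= 20 dB down after the band-pass stage
  bp <- signal::filtfilt(signal::butter(2, c(40, 250) / (fs / 2), "pass"),
                         sin(2 * pi * 10 * t))
  expect_lt(20 * log10(max(abs(bp[500:3500]))), -20)
  # 100 Hz carrier AM-modulated at 11 Hz: strongest conditioned peak at 11 Hz
  x <- (1 + 0.8 * sin(2 * pi * 11 * t)) * sin(2 * pi * 100 * t)
  y <- condition_egm(x, fs = fs)
  expect_equal(dominant_frequency(y, fs = fs)$df, 11, tolerance = 0.3)
  # zero in, zero out
  expect_equal(condition_egm(numeric(1000), fs = fs), numeric(1000))
  # sampling rate too low for the 250 Hz edge
  expect_error(condition_egm(numeric(1000), fs = 400), "sampling rate")
})

test_that("dominant frequency finds construction rates and the larger peak", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  # impulse train at 8 Hz
  x <- as.numeric((seq_along(t) - 1) %% round(fs / 8) == 0)
  sp <- dominant_frequency(x, fs = fs)
  expect_equal(sp$df, 8, tolerance = sp$resolution + 1e-9)
  # larger peak wins
  y <- sin(2 * pi * 6 * t) + 2 * sin(2 * pi * 9 * t)
  expect_equal(dominant_frequency(y, fs = fs)$df, 9, tolerance = 0.3)
  # amplitude invariance
  expect_equal(dominant_frequency(0.001 * y, fs = fs)$df,
               dominant_frequency(1000 * y, fs = fs)$df)
  expect_error(dominant_frequency(numeric(4000), fs = fs), "all-zero")
  expect_error(dominant_frequency(y[1:1000], fs = fs), "2 s")
})

test_that("generated morphologies round-trip through the classifier", {
  for (cls in c("single", "double", "fractionated")) {
    rec <- gen_egm_morphology(cls, rate = 8, duration = 4, noise_sd = 0,
                              seed = 1)
    out <- classify_egm(rec)
    expect_true(all(out$class == cls), label = cls)
  }
  # five-deflection complexes are fractionated even under noise
  rec <- gen_egm_morphology("fractionated", n_deflections = 5, rate = 6,
                            duration = 4, noise_sd = 0.05, seed = 7)
  out <- classify_egm(rec)
  expect_true(all(out$class == "fractionated"))
  expect_true(all(out$n_deflections >= 3))
})

test_that("classifier matches generator labels on >= 95% of noisy fixtures", {
  hit <- 0; tot <- 0
  for (s in 1:8) for (cls in c("single", "double", "fractionated")) {
    out <- classify_egm(gen_egm_morphology(cls, rate = 8, duration = 4,
                                           noise_sd = 0.05, seed = s))
    hit <- hit + sum(out$class == cls)
    tot <- tot + nrow(out)
  }
  expect_gte(hit / tot, 0.95)
})

test_that("the DF of a generated 8 Hz fixture equals its rate", {
  rec <- condition_egm(gen_egm_morphology("single", rate = 8, duration = 4,
                                          noise_sd = 0.02, seed = 2))
  sp <- dominant_frequency(rec)
  expect_equal(sp$df, 8, tolerance = sp$resolution + 1e-9)
})
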