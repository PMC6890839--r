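test_that("uncoupled tissue reproduces the isolated cell exactly", {
  g <- tissue_grid(nx = 6, ny = 5, dx = 0.3, D = 0)
  p <- params_remodeled()
  st <- tissue_states(g)
  stim <- stimulus_spec(node_index(g, 1:6, 1:5), 28, 2, 0)
  res <- run_tissue(g, st, p, duration = 100, dt = 0.02, stims = list(stim))
  cell <- atriablock:::crn_run_cpp(
    atriablock:::as_state_vector(default_cell_state()), unclass(p), 0.02,
    100, 0, 28, 2, 1000000L, 0, TRUE)
  for (id in seq_len(ncol(res$states)))
    expect_lt(max(abs(res$states[, id] - cell$state)), 1e-9)
})

test_that("diffusion of a uniform field is exactly zero", {
  g <- tissue_grid(nx = 8, ny = 8, dx = 0.3, D = 0.0034)
  res <- run_tissue(g, tissue_states(g), params_unremodeled(),
                    duration = 5, dt = 0.02)
  vm <- res$states[1, ]
  expect_true(all(vm == vm[1]))
})

test_that("the diffusion substep conserves the spatial mean of Vm", {
  g0 <- tissue_grid(nx = 20, ny = 20, dx = 0.3, D = 0)
  g1 <- tissue_grid(nx = 20, ny = 20, dx = 0.3, D = 0.0034)
  # corner stimulus creates strong gradients
  stim <- stimulus_spec(node_index(g0, 1:4, 1:4), 28, 2, 0)
  p <- params_unremodeled()
  s0 <- tissue_states(g0)
  mean_drift <- function(n_ms) {
    a <- run_tissue(g1, s0, p, duration = n_ms, dt = 0.02,
                    stims = list(stim))
    b <- run_tissue(g0, s0, p, duration = n_ms, dt = 0.02,
                    stims = list(stim))
    # reaction is node-local, so any mean difference comes from diffusion;
    # compare single-step means to isolate the substep
    abs(mean(a$states[1, ]) - mean(b$states[1, ]))
  }
  expect_lt(mean_drift(0.02), 1e-10)   # one split step
})

test_that("reflected grid and stimuli reflect the solution bit for bit", {
  g <- tissue_grid(nx = 14, ny = 10, dx = 0.3, D = 0.0034)
  p <- params_unremodeled()
  stim <- stimulus_spec(node_index(g, 2:4, 2:5), 28, 2, 0)
  a <- run_tissue(g, tissue_states(g), p, duration = 20, dt = 0.02,
                  stims = list(stim))
  # mirror in x: node (i, j) -> (nx + 1 - i, j)
  mirror_nodes <- node_index(g, g$nx + 1 - (2:4), 2:5)
  b <- run_tissue(g, tissue_states(g), p, duration = 20, dt = 0.02,
                  stims = list(stimulus_spec(mirror_nodes, 28, 2, 0)))
  va <- matrix(a$states[1, ], g$nx, g$ny)
  vb <- matrix(b$states[1, ], g$nx, g$ny)
  expect_identical(va, vb[g$nx:1, ])
})

test_that("planar conduction velocity scales as the square root of D", {
  cv1 <- planar_cv(0.0034)
  cv4 <- planar_cv(4 * 0.0034)
  expect_equal(cv4 / cv1, 2, tolerance = 0.05)
})

test_that("planar CV is consistent under spatial refinement", {
  cv_a <- planar_cv(0.0034, dx = 0.15, dt = 0.005)
  cv_b <- planar_cv(0.0034, dx = 0.075, dt = 0.0025)
  expect_lt(abs(cv_b - cv_a) / cv_a, 0.05)
})

test_that("unstable diffusion settings are rejected with advice", {
  g <- tissue_grid(nx = 10, ny = 10, dx = 0.1, D = 0.0136)
  expect_error(run_tissue(g, tissue_states(g), params_unremodeled(),
                          duration = 1, dt = 0.02),
               "reduce dt")
})

test_that("S1-only pacing gives one activation per beat then quiescence", {
  g <- tissue_grid(nx = 50, ny = 50, dx = 0.3, D = 0.00085)
  st0 <- prepace5_remodeled()
  run <- s1s2_protocol(g, params_remodeled(), state0 = st0, n_s1 = 3,
                       s1_bcl = 350, n_s2 = 0, observe = 600, dt = 0.02,
                       early_exit = TRUE)
  expect_true(all(run$act_count == 3))
  expect_true(run$stopped_early)
})

test_that("S2 region must be disjoint from the S1 edge", {
  g <- tissue_grid(nx = 60, ny = 60, dx = 0.3)
  expect_error(s1s2_protocol(g, params_remodeled(),
                             s2_center = c(2, 30), s2_halfwidth = 3,
                             n_s1 = 1, observe = 0),
               "disjoint")
})

test_that("cross-field S2 in the vulnerable window sustains re-entry in remodeled tissue", {
  ctl <- reentry_control(S2_COUPLINGS[1], duration = 2100)
  stim_end <- S2_COUPLINGS[1] + 2
  # activity persists >= 1000 ms beyond the last stimulus
  expect_false(ctl$stopped_early)
  expect_gt(ctl$last_activation - stim_end, 1000)
  expect_gte(max(ctl$act_count_post), 5)
})

test_that("the same S1-S2 scan does not sustain re-entry in unremodeled tissue", {
  runs <- unremodeled_scan()
  for (run in runs) {
    stim_end <- atriablock:::stim_end_time(run$stims)
    expect_true(run$stopped_early)
    la <- run$last_activation
    if (!is.na(la)) expect_lt(la - stim_end, 600)
  }
})

test_that("a zero-fraction drug profile leaves the trajectory bitwise unchanged", {
  base <- reentry_baseline(S2_COUPLINGS[1])
  prof0 <- drug_block_profile(0, currents = c("IK1", "IKACh", "IKr"))
  a <- continue_run(base, duration = 50)
  b <- apply_drug_during_run(base, prof0, t_apply = base$t_end, duration = 50)
  expect_identical(a$states, b$states)
})

test_that("dual IK1/IKACh block terminates re-entry; 30% IKr block does not", {
  term_dual <- vapply(S2_COUPLINGS, function(cp)
    reentry_drugged(cp, "dual")$stopped_early, logical(1))
  term_ikr <- vapply(S2_COUPLINGS, function(cp)
    reentry_drugged(cp, "ikr30")$stopped_early, logical(1))
  expect_gt(sum(term_dual), sum(term_ikr))
  # termination times after application are on the sub-second scale
  tterm <- vapply(S2_COUPLINGS[term_dual], function(cp) {
    dr <- reentry_drugged(cp, "dual")
    dr$last_activation - dr$t0
  }, numeric(1))
  expect_true(all(tterm < 1000))
})

test_that("heavy IKr-only block leaves the dynamics indistinguishable from control", {
  base <- reentry_baseline(S2_COUPLINGS[1])
  prof <- drug_block_profile(22.5, currents = "IKr")  # 90% block
  dr <- continue_run(base, duration = 1100,
                     params = apply_block(params_remodeled(), prof),
                     early_exit = TRUE)
  ctl <- reentry_control(S2_COUPLINGS[1])
  expect_false(dr$stopped_early)
  # activation rate at the sheet center matches the control within 15%
  mid <- c(round(dr$grid$nx / 2), round(dr$grid$ny / 2))
  r_dr <- dr$act_count[mid[1], mid[2]] / (dr$t_end - dr$t0)
  r_ctl <- ctl$act_count[mid[1], mid[2]] / (ctl$t_end - ctl$t0)
  expect_lt(abs(r_dr - r_ctl) / r_ctl, 0.15)
})

test_that("drug application timing is validated", {
  base <- reentry_baseline(S2_COUPLINGS[1])
  prof <- drug_block_profile(1.0)
  expect_error(apply_drug_during_run(base, prof, t_apply = base$span + 500,
                                     duration = 10),
               "beyond")
})
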