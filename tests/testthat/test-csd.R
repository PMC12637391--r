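test_that("standard CSD with Vaknin correction matches analytic profiles", {
  depths <- seq(100, 1300, by = 80)
  n <- length(depths)

  # constant potential -> zero CSD everywhere, edges included
  lfp <- list(phi = matrix(3, n, 5), time = 1:5)
  csd <- standard_csd_vaknin(lfp, depths, sigma = 0.3)
  expect_equal(max(abs(csd$values)), 0)

  # phi = a z^2 -> CSD = -2 a sigma at all interior channels
  a <- 1e-6   # mV per um^2
  phi <- matrix(a * depths^2, n, 1)
  csd2 <- standard_csd_vaknin(list(phi = phi, time = 1), depths, sigma = 0.3)
  # analytic: -sigma d2(phi)/dz2 with phi in V, z in m:
  expected <- -0.3 * 2 * (a * 1e-3) / (1e-6)^2
  expect_equal(csd2$values[2:(n - 1), 1], rep(expected, n - 2),
               tolerance = 1e-9)

  expect_error(standard_csd_vaknin(lfp, c(0, 80, 200)), "uniform")
  expect_error(standard_csd_vaknin(list(phi = matrix(0, 2, 1), time = 1),
                                   c(0, 80)), "3 electrodes")
})

test_that("step-iCSD inverts its own forward model exactly", {
  depths <- seq(40, 1480, by = 80)
  n <- length(depths)
  F <- step_icsd_forward_matrix(depths, rho = 500, sigma = 0.3)
  # known step profile (nA/mm^3 = A/m^3)
  C_true <- matrix(0, n, 2)
  C_true[4:6, 1] <- 80; C_true[9:11, 1] <- -80
  C_true[2:5, 2] <- -40; C_true[10:14, 2] <- 40
  phi <- (F %*% C_true) * 1e3    # V -> mV
  est <- step_icsd(list(phi = phi, time = 1:2), depths, rho = 500,
                   sigma = 0.3)
  expect_equal(est$values, C_true, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(is.finite(est$params$condition_number))

  # zero LFP -> zero CSD
  z <- step_icsd(list(phi = matrix(0, n, 3), time = 1:3), depths)
  expect_equal(max(abs(z$values)), 0)
})

test_that("standard CSD recovers the sign pattern of a two-disk source", {
  depths <- seq(40, 1480, by = 80)
  n <- length(depths)
  F <- step_icsd_forward_matrix(depths, rho = 500, sigma = 0.3)
  C_true <- numeric(n); C_true[5] <- 100; C_true[10] <- -100
  phi <- (F %*% C_true) * 1e3
  csd <- standard_csd_vaknin(list(phi = phi, time = 1), depths, sigma = 0.3)
  v <- csd$values[, 1]
  expect_equal(which.max(v), 5)
  expect_equal(which.min(v), 10)
  # zero crossing within one channel of the midpoint between the disks
  expect_true(sign(v[7]) != sign(v[8]))
})

test_that("for wide disks iCSD approaches the standard estimate", {
  depths <- seq(40, 1480, by = 80)
  n <- length(depths)
  # smooth dipolar source
  C_true <- 50 * sin((depths - 40) / 1440 * 2 * pi)
  F <- step_icsd_forward_matrix(depths, rho = 5e4, sigma = 0.3)
  phi <- (F %*% C_true) * 1e3
  icsd <- step_icsd(list(phi = phi, time = 1), depths, rho = 5e4)
  std <- standard_csd_vaknin(list(phi = phi, time = 1), depths)
  interior <- 4:(n - 3)
  rel <- abs(std$values[interior, 1] - icsd$values[interior, 1]) /
    max(abs(icsd$values))
  expect_lt(max(rel), 0.05)
})

test_that("dipole-moment density matches the two-disk closed form", {
  # +C over [z1-h/2, z1+h/2], -C over [z2-h/2, z2+h/2]:
  # p = C h (z1 - z2); C = 1 nA/mm^3, h = 0.1 mm, z1 = 0.5, z2 = 1.0 mm
  h_um <- 100
  depths <- seq(0, 1500, by = h_um)
  vals <- matrix(0, length(depths), 1)
  vals[depths == 500, 1] <- 1
  vals[depths == 1000, 1] <- -1
  csd <- csd_profile(depths, 1, vals, "step_icsd",
                     params = list(h = h_um))
  # closed form C h (z1 - z2) with C = 1 nA/mm^3, h = 0.1 mm, z1 = 0.5 mm,
  # z2 = 1.0 mm: -0.05 nA.mm/mm^2 = -5e-5 nA.m/mm^2 in the reported unit
  p <- dipole_moment_density(csd, t = 1)
  expect_equal(as.numeric(p), 1 * 0.1 * (0.5 - 1.0) * 1e-3,
               tolerance = 1e-12)

  expect_equal(as.numeric(dipole_moment_density(
    csd_profile(depths, 1, matrix(0, length(depths), 1), "step_icsd"),
    t = 1)), 0)

  # zero-monopole profiles: p invariant under depth translation
  vals2 <- matrix(0, length(depths), 1)
  vals2[4:6, 1] <- 2; vals2[8:10, 1] <- -2
  vals3 <- rbind(matrix(0, 2, 1), vals2[1:(length(depths) - 2), , drop = FALSE])
  p2 <- dipole_moment_density(csd_profile(depths, 1, vals2, "step_icsd"), 1)
  p3 <- dipole_moment_density(csd_profile(depths, 1, vals3, "step_icsd"), 1)
  expect_equal(as.numeric(p2), as.numeric(p3), tolerance = 1e-9)

  expect_error(dipole_moment_density(
    csd_profile(numeric(0), numeric(0),
                matrix(0, 0, 0), "step_icsd")), "empty")
})

test_that("EEG amplitude estimates follow the reciprocity scaling", {
  # p = 0.023 nAm/mm^2, lead = 4 V/mm/A, r = 0.25 mm -> ~1.8e-8 V
  per_col <- eeg_from_dipole(0.023, r = 0.25, lead = 4)
  expect_equal(per_col, pi * 0.25^2 * 0.023 * 4 * 1e-6, tolerance = 1e-12)
  expect_equal(per_col, 1.8e-8, tolerance = 0.01)

  expect_equal(eeg_from_dipole(0, r = 0.25, lead = 4), 0)
  expect_equal(circuit_eeg_estimate(1.85e-8, 7), 1.295e-7)
})

test_that("the LFP-CSD-dipole chain is consistent with the direct EEG", {
  circ <- build_circuit(default_circuit_config("original", scale = 0.7),
                        seed = 3)
  compiled <- compile_circuit(circ)
  stim <- stimulus_spec(n_stimuli = 1L, onset = 30,
                        n_fibers = length(population_ids(circ, "THAL")))
  thal <- generate_thalamic_spikes(stim, population_ids(circ, "THAL"),
                                   seed = 3)
  out <- simulate_connected(compiled, thal, trial_seed = 3, t_sim = 130)
  depths <- seq(40, 1480, by = 80)
  lfp <- compute_lfp(out$currents, laminar_lfp_weights(compiled, depths))
  lfp_sep <- postprocess_sep(lfp, 30, which_stimulus = 1,
                             window = c(-10, 100))
  csd <- step_icsd(lfp_sep, depths, rho = circ$config$radius)

  # currents conserve charge, so the depth profile is monopole-free
  ti <- which.max(abs(dipole_moment_series(csd)))
  expect_lt(monopole_ratio(csd, csd$time[ti]), 0.05)

  p_peak <- max(abs(dipole_moment_series(csd)))
  espec <- electrode_spec(c(0, 0, -1500))
  est <- eeg_from_dipole(p_peak, r = circ$config$radius / 1000,
                         lead = dipole_lead_field(espec, depths))
  w <- point_electrode_weights(compartment_centers(compiled), espec)
  sep <- postprocess_sep(compute_signal(out$currents, w,
                                        keep_contributions = FALSE),
                         30, which_stimulus = 1, window = c(-10, 100))
  direct <- max(abs(sep$values))
  expect_gt(est / direct, 0.5)
  expect_lt(est / direct, 2)
})

test_that("monopole ratio is small for balanced profiles", {
  depths <- seq(50, 1450, by = 100)
  vals <- matrix(0, length(depths), 1)
  vals[3:5, 1] <- 1; vals[9:11, 1] <- -1
  csd <- csd_profile(depths, 1, vals, "step_icsd")
  expect_lt(monopole_ratio(csd, 1), 1e-9)
})
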