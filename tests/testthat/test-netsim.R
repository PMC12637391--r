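test_that("a quiescent circuit stays silent with vanishing currents", {
  cfg <- tiny_config(p = 0, noise_mean = 0, spike_mode = "none")
  circ <- build_circuit(cfg, seed = 1)
  out <- simulate_connected(circ, spike_record(), trial_seed = 1, t_sim = 20)
  expect_equal(nrow(out$spikes), 0L)
  expect_lt(max(abs(out$currents$currents)), 1e-12)
})

test_that("per-neuron transmembrane currents sum to zero at every step", {
  cfg <- tiny_config(n_e = 8L, n_fib = 10L, p = 0.4, noise_mean = 1.2,
                     spike_mode = "eif")
  circ <- build_circuit(cfg, seed = 2)
  spec <- stimulus_spec(n_fibers = 10L, active_fraction = 0.5, n_stimuli = 1L)
  thal <- generate_thalamic_spikes(spec, population_ids(circ, "THAL"),
                                   seed = 2)
  out <- simulate_connected(circ, thal, trial_seed = 2, t_sim = 40)
  expect_lt(check_charge_conservation(out$currents, tol = 1e-9), 1e-9)
})

test_that("a single synaptic event matches an independent dense integrator", {
  cfg <- tiny_config(n_e = 1L, n_fib = 1L, p = 1, gmax = 2,
                     spike_mode = "none")
  circ <- build_circuit(cfg, seed = 4)
  expect_equal(nrow(circ$synapses), 1L)
  syn <- circ$synapses
  t_spk <- 10
  thal <- spike_record(population_ids(circ, "THAL"), t_spk)
  out <- simulate_connected(circ, thal, trial_seed = 1, t_sim = 40)

  # conductance onset at spike time + axonal delay
  onset <- t_spk + syn$delay
  before <- out$currents$time < onset - 0.2
  after <- out$currents$time > onset + 1 & out$currents$time < onset + 5
  expect_lt(max(abs(out$currents$currents[before, ])), 1e-12)
  expect_gt(max(abs(out$currents$currents[after, ])), 1e-6)

  # independent reference: dense-matrix implicit Euler on the same cell
  m <- circ$morphologies[[syn$post]]
  ref <- reference_single_cell(
    m, circ$passive, syn_seg = syn$segment, syn_g_uS = syn$gmax * 1e-3,
    syn_tau = syn$tau, syn_e = syn$e_rev,
    event_times = t_spk + syn$delay, t_sim = 40)
  expect_equal(out$currents$currents, ref$I, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("OU conductance stream has the calibrated statistics", {
  expect_equal(ou_noise_stream(10, 0, tau = 3, dt = 0.1, n_steps = 1000),
               rep(10, 1000))

  g <- ou_noise_stream(10, 0.4, tau = 3, dt = 0.1, n_steps = 1e6,
                       stream_key = 7)
  r <- sd(g) / mean(g)
  expect_gt(r, 0.38); expect_lt(r, 0.42)

  # lag-tau autocorrelation ~ 1/e
  lag <- 30   # tau / dt
  ac <- cor(g[-(1:lag)], g[seq_len(length(g) - lag)])
  expect_lt(abs(ac - exp(-1)), 0.02)

  expect_identical(ou_noise_stream(5, 0.4, 3, 0.1, 100, stream_key = 1),
                   ou_noise_stream(5, 0.4, 3, 0.1, 100, stream_key = 1))
  expect_false(identical(ou_noise_stream(5, 0.4, 3, 0.1, 100, stream_key = 1),
                         ou_noise_stream(5, 0.4, 3, 0.1, 100, stream_key = 2)))
  expect_error(ou_noise_stream(5, 0.4, tau = 3, dt = 3, n_steps = 10),
               "smaller than")
})

test_that("replaying every population reproduces the connected run", {
  cfg <- default_circuit_config("original", scale = 0.3)
  circ <- build_circuit(cfg, seed = 5)
  compiled <- compile_circuit(circ)
  stim <- stimulus_spec(n_stimuli = 1L, n_fibers =
                          length(population_ids(circ, "THAL")))
  thal <- generate_thalamic_spikes(stim, population_ids(circ, "THAL"),
                                   seed = 5)
  con <- simulate_connected(compiled, thal, trial_seed = 5, t_sim = 60)
  plan <- replay_plan(circ, con$spikes, thal, exclude = NULL)
  dec <- simulate_decoupled(compiled, plan, trial_seed = 5, t_sim = 60)
  expect_lt(max(abs(con$currents$currents - dec$currents$currents)), 1e-6)
  expect_identical(con$spikes$time, dec$spikes$time)
})

test_that("excluding a population with no efferent synapses changes nothing", {
  cfg <- tiny_config(n_e = 6L, n_fib = 8L, p = 0.4, noise_mean = 1.0,
                     spike_mode = "eif")
  circ <- build_circuit(cfg, seed = 6)
  stim <- stimulus_spec(n_fibers = 8L, active_fraction = 0.5, n_stimuli = 1L)
  thal <- generate_thalamic_spikes(stim, population_ids(circ, "THAL"),
                                   seed = 6)
  con <- simulate_connected(circ, thal, trial_seed = 6, t_sim = 50)
  # L5E has no efferent synapses in this circuit
  plan <- replay_plan(circ, con$spikes, thal, exclude = "L5E")
  dec <- simulate_decoupled(circ, plan, trial_seed = 6, t_sim = 50)
  expect_lt(max(abs(con$currents$currents - dec$currents$currents)), 1e-9)
})

test_that("replay plans are validated", {
  circ <- build_circuit(tiny_config(), seed = 1)
  expect_error(replay_plan(circ, spike_record(), NULL, exclude = "L9X"),
               "does not exist")
  bad <- spike_record(999L, 5)
  plan <- replay_plan(circ, bad, NULL, exclude = NULL)
  expect_error(simulate_decoupled(circ, plan, trial_seed = 1, t_sim = 20),
               "unknown neuron")
  late <- spike_record(population_ids(circ, "L5E")[1], 500)
  plan2 <- replay_plan(circ, late, NULL, exclude = NULL)
  expect_error(simulate_decoupled(circ, plan2, trial_seed = 1, t_sim = 20),
               "outside the simulation window")
})

test_that("all outputs are pure functions of the trial seed", {
  cfg <- tiny_config(n_e = 5L, n_fib = 6L, p = 0.4, noise_mean = 1.0,
                     spike_mode = "eif")
  circ <- build_circuit(cfg, seed = 8)
  stim <- stimulus_spec(n_fibers = 6L, active_fraction = 0.5, n_stimuli = 1L)
  thal <- generate_thalamic_spikes(stim, population_ids(circ, "THAL"),
                                   seed = 8)
  a <- simulate_connected(circ, thal, trial_seed = 3, t_sim = 40)
  set.seed(987)   # outer RNG state must not leak in
  b <- simulate_connected(circ, thal, trial_seed = 3, t_sim = 40)
  expect_identical(a$currents$currents, b$currents$currents)
  expect_identical(a$spikes, b$spikes)
  c3 <- simulate_connected(circ, thal, trial_seed = 4, t_sim = 40)
  expect_false(identical(a$currents$currents, c3$currents$currents))
})
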