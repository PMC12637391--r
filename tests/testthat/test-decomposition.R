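# A feed-forward linear chain (thalamic fibers -> A -> B with current-based
# synapses, passive membranes, spike detection only) admits exact
# superposition, so the decomposition can be checked against a directly
# simulated pathway response.
ff_chain_config <- function() {
  list(
    layers = list(L1 = 0, L23 = 150, L4 = 500, L5 = 750, L6 = 1100,
                  bottom = 1500),
    radius = 150, min_radius = 25,
    synapse_model = "current", spike_mode = "detect",
    noise = list(mean_ns = 0, ratio = 0, tau_ms = 3),
    spike = utils::modifyList(sepdecomp:::default_spike(),
                              list(v_thresh = -69.2, t_ref = 4)),
    populations = list(
      list(name = "A", layer = "L4", class = "EXC", n = 8L,
           dend_length = 300, n_dend = 4L),
      list(name = "B", layer = "L5", class = "EXC", n = 8L,
           dend_length = 500, n_dend = 4L),
      list(name = "THAL", layer = "L6", class = "fiber", n = 10L)),
    projections = c(
      sepdecomp:::proj("THAL", "A", 0.5, gmax = 1.5, tau = 2, e = 0),
      sepdecomp:::proj("A", "B", 0.4, gmax = 1.0, tau = 2, e = 0)))
}

ff_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      circ <- build_circuit(ff_chain_config(), seed = 21)
      compiled <- compile_circuit(circ)
      stim <- stimulus_spec(psth_bins = seq(0, 20, 1),
                            psth_rates = rep(150, 20), n_fibers = 10L,
                            active_fraction = 0.5, n_stimuli = 1L,
                            onset = 5)
      thal <- generate_thalamic_spikes(stim, population_ids(circ, "THAL"),
                                       seed = 21)
      con <- simulate_connected(compiled, thal, trial_seed = 21, t_sim = 60)
      w <- point_electrode_weights(compartment_centers(compiled),
                                   electrode_spec(c(0, 0, -1500)))
      w$comp_neuron <- compiled$comps$neuron
      net <- compute_signal(con$currents, w)
      cache <<- list(circ = circ, compiled = compiled, thal = thal,
                     con = con, w = w, net = net)
    }
    cache
  }
})

test_that("presynaptic contribution equals the directly simulated pathway", {
  fx <- ff_fixture()
  expect_gt(nrow(fx$con$spikes), 0)   # A must actually fire

  plan <- replay_plan(fx$circ, fx$con$spikes, fx$thal, exclude = "A")
  dec <- simulate_decoupled(fx$compiled, plan, trial_seed = 21, t_sim = 60)
  dec_tr <- compute_signal(dec$currents, fx$w)
  contrib <- presynaptic_contribution(fx$net, dec_tr)

  # direct superposition oracle: a circuit with only the A->B synapses,
  # driven by A's recorded spikes
  cfg2 <- ff_chain_config()
  cfg2$projections <- sepdecomp:::proj("A", "B", 0.4, gmax = 1.0, tau = 2,
                                       e = 0)
  circ2 <- build_circuit(cfg2, seed = 21)   # same seed -> same placements
  a_spk <- fx$con$spikes[fx$con$spikes$id %in%
                           population_ids(fx$circ, "A"), ]
  plan2 <- replay_plan(circ2, spike_record(a_spk$id, a_spk$time),
                       thalamic = NULL, exclude = NULL)
  direct <- simulate_decoupled(circ2, plan2, trial_seed = 21, t_sim = 60)
  direct_tr <- compute_signal(direct$currents, fx$w)

  scale <- max(abs(fx$net$values))
  expect_lt(max(abs(contrib$values - direct_tr$values)) / scale, 1e-9)
})

test_that("identical traces subtract to zero and grids are checked", {
  fx <- ff_fixture()
  z <- presynaptic_contribution(fx$net, fx$net)
  expect_equal(max(abs(z$values)), 0)
  shifted <- signal_trace(fx$net$time + 1, fx$net$values)
  expect_error(presynaptic_contribution(fx$net, shifted), "grids differ")
})

test_that("pathway contributions partition the presynaptic contribution", {
  fx <- ff_fixture()
  plan <- replay_plan(fx$circ, fx$con$spikes, fx$thal, exclude = "THAL")
  dec <- simulate_decoupled(fx$compiled, plan, trial_seed = 21, t_sim = 60)
  dec_tr <- compute_signal(dec$currents, fx$w)
  pre <- presynaptic_contribution(fx$net, dec_tr)
  pa <- pathway_contribution(fx$net, dec_tr, "A", fx$circ)
  pb <- pathway_contribution(fx$net, dec_tr, "B", fx$circ)
  scale <- max(abs(pre$values))
  expect_lt(max(abs(pa$values + pb$values - pre$values)) / scale, 1e-12)

  expect_error(pathway_contribution(fx$net, dec_tr, "nope", fx$circ),
               "unknown population")
})

test_that("postsynaptic contributions sum to the total signal", {
  fx <- ff_fixture()
  pa <- postsynaptic_contribution(fx$net, "A", fx$circ)
  pb <- postsynaptic_contribution(fx$net, "B", fx$circ)
  scale <- max(abs(fx$net$values))
  expect_lt(max(abs(pa$values + pb$values - fx$net$values)) / scale, 1e-12)
  # brute-force per-neuron summation oracle for one population
  ids <- population_ids(fx$circ, "B")
  brute <- rowSums(fx$net$contributions[, fx$net$neuron_ids %in% ids,
                                        drop = FALSE])
  expect_equal(max(pb$values) - min(pb$values), max(brute) - min(brute))
})

test_that("thalamic contribution is the whole signal in a pure TC circuit", {
  cfg <- tiny_config(n_e = 6L, n_fib = 8L, p = 0.5, spike_mode = "none")
  circ <- build_circuit(cfg, seed = 22)
  compiled <- compile_circuit(circ)
  stim <- stimulus_spec(n_fibers = 8L, active_fraction = 0.5, n_stimuli = 1L)
  thal <- generate_thalamic_spikes(stim, population_ids(circ, "THAL"),
                                   seed = 22)
  con <- simulate_connected(compiled, thal, trial_seed = 22, t_sim = 50)
  w <- point_electrode_weights(compartment_centers(compiled),
                               electrode_spec(c(0, 0, -1500)))
  w$comp_neuron <- compiled$comps$neuron
  net <- compute_signal(con$currents, w)
  plan <- replay_plan(circ, con$spikes, thal, exclude = "THAL")
  dec <- simulate_decoupled(compiled, plan, trial_seed = 22, t_sim = 50)
  th <- thalamic_contribution(net, compute_signal(dec$currents, w))
  expect_equal(th$values, net$values, tolerance = 1e-12)
})

test_that("linear-sum residual metric behaves as a relative RMS", {
  tt <- seq(0, 100, 0.1)
  total <- signal_trace(tt, sin(tt / 5))
  half <- signal_trace(tt, total$values / 2)
  cs <- contribution_set(total, presynaptic = list(a = half, b = half))
  v <- validate_linear_sum(cs)
  expect_equal(v$metric, 0)

  # white noise of RMS eps x RMS(total) added to one part -> metric ~ eps
  eps <- 0.07
  set.seed(33)
  noise <- rnorm(length(tt))
  noise <- noise / sqrt(mean(noise^2)) * eps * sqrt(mean(total$values^2))
  noisy <- signal_trace(tt, half$values + noise)
  cs2 <- contribution_set(total, presynaptic = list(a = half, b = noisy))
  expect_equal(validate_linear_sum(cs2)$metric, eps, tolerance = 1e-12)
})
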