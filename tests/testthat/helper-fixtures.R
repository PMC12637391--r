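# Shared fixtures, built in code at test time.

# Two-population miniature circuit: thalamic fibers -> passive pyramids.
tiny_config <- function(n_e = 10L, n_fib = 10L, p = 0.3, gmax = 1,
                        synapse_model = "conductance", spike_mode = "none",
                        noise_mean = 0) {
  list(
    layers = list(L1 = 0, L23 = 150, L4 = 500, L5 = 750, L6 = 1100,
                  bottom = 1500),
    radius = 150, min_radius = 25,
    synapse_model = synapse_model, spike_mode = spike_mode,
    noise = list(mean_ns = noise_mean, ratio = 0.4, tau_ms = 3),
    populations = list(
      list(name = "L5E", layer = "L5", class = "EXC", n = n_e,
           dend_length = 600, n_dend = 6L),
      list(name = "THAL", layer = "L6", class = "fiber", n = n_fib)),
    projections = sepdecomp:::proj("THAL", "L5E", p, gmax = gmax, tau = 2,
                                   e = 0, nsyn = 1L))
}

# Independent single-cell reference: dense implicit-Euler integration of one
# ball-and-stick neuron with one conductance synapse, using a full-matrix
# solve (no Thomas algorithm, no group batching).
reference_single_cell <- function(morph, passive, syn_seg, syn_g_uS, syn_tau,
                                  syn_e, event_times, t_sim, dt = 0.025,
                                  record_every = 4L) {
  area <- segment_areas(morph)
  len <- segment_lengths(morph)
  K <- nrow(morph$segments)
  C <- passive$cm_uf_cm2 * area * 1e-5
  gL <- area * 1e-5 / passive$rm_kohm_cm2
  r <- morph$segments$radius
  r_ax <- passive$ra_ohm_cm * 1e4 *
    (len[-K] / 2 / (pi * r[-K]^2) + len[-1] / 2 / (pi * r[-1]^2))
  ga <- 1e6 / r_ax
  A <- matrix(0, K, K)
  for (k in seq_len(K - 1L)) {
    A[k, k] <- A[k, k] + ga[k]
    A[k + 1L, k + 1L] <- A[k + 1L, k + 1L] + ga[k]
    A[k, k + 1L] <- A[k, k + 1L] - ga[k]
    A[k + 1L, k] <- A[k + 1L, k] - ga[k]
  }
  n_steps <- ceiling(t_sim / dt)
  V <- rep(passive$e_leak, K)
  gs <- 0
  bins <- floor(event_times / dt) + 1L
  rec <- seq.int(record_every, n_steps, by = record_every)
  Vout <- matrix(NA_real_, length(rec), K)
  Iout <- matrix(NA_real_, length(rec), K)
  ri <- 0L
  for (s in seq_len(n_steps)) {
    gs <- gs * exp(-dt / syn_tau) + syn_g_uS * sum(bins == s)
    M <- A + diag(C / dt + gL, K)
    M[syn_seg, syn_seg] <- M[syn_seg, syn_seg] + gs
    b <- (C / dt) * V + gL * passive$e_leak
    b[syn_seg] <- b[syn_seg] + gs * syn_e
    V <- solve(M, b)
    if (ri < length(rec) && s == rec[ri + 1L]) {
      ri <- ri + 1L
      Vout[ri, ] <- V
      Iax <- numeric(K)
      for (k in seq_len(K - 1L)) {
        d <- ga[k] * (V[k + 1L] - V[k])
        Iax[k] <- Iax[k] + d
        Iax[k + 1L] <- Iax[k + 1L] - d
      }
      Iout[ri, ] <- Iax
    }
  }
  list(time = rec * dt, V = Vout, I = Iout)
}
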