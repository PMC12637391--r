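# Network membrane dynamics and transmembrane current recording.
#
# Units: time ms, voltage mV, conductance uS, current nA, capacitance nF.
# With these, C dV/dt [nF mV/ms] = nA, and g*V [uS mV] = nA, so no further
# conversion appears in the update.
#
# Integration: fixed-step implicit (backward) Euler on the passive cable.
# Synaptic conductances decay analytically between event increments and are
# known at the end-of-step time, so the voltage solve is a per-neuron
# tridiagonal system; morphologies are unbranched chains, and neurons with
# the same compartment count are solved simultaneously (vectorized Thomas
# algorithm across neurons).  The exponential spike-initiation current is
# evaluated explicitly at the soma.
#
# Transmembrane currents are recorded as the net axial current arriving at
# each compartment (what comes in axially must leave through the membrane,
# capacitive displacement included).  This makes the per-neuron sum of
# compartment currents exactly zero at every step - the charge-conservation
# property the EEG forward model relies on.  Soma-only neurons therefore
# contribute no extracellular signal, as a point source with no return path
# cannot.

#' Compile a circuit into flat simulation arrays
#'
#' Groups neurons by compartment count, converts geometry to electrical
#' parameters, and indexes synapses by (group, row, column) target.  The
#' global compartment ordering defined here is shared by the currents report
#' and every weights table.
#'
#' @param circuit circuit_model
#' @return object of class `compiled_circuit`
#' @export
compile_circuit <- function(circuit) {
  pas <- circuit$passive
  cell_ids <- sort(unlist(lapply(circuit$populations, function(p) {
    if (identical(p$class, "fiber")) integer(0) else p$ids
  })))
  pop_of <- character(max(unlist(lapply(circuit$populations, `[[`, "ids"))))
  for (p in circuit$populations) pop_of[p$ids] <- p$name

  K_of <- vapply(cell_ids, function(i) nrow(circuit$morphologies[[i]]$segments),
                 integer(1))
  groups <- list()
  comp_rows <- list()
  cell_tab <- data.frame(id = cell_ids, pop = pop_of[cell_ids], K = K_of,
                         group = NA_integer_, row = NA_integer_,
                         area_um2 = NA_real_)
  for (gi in seq_along(sort(unique(K_of)))) {
    K <- sort(unique(K_of))[gi]
    members <- cell_ids[K_of == K]
    n <- length(members)
    C <- matrix(0, n, K); gL <- matrix(0, n, K)
    ga <- if (K > 1) matrix(0, n, K - 1) else matrix(0, n, 0)
    geom <- vector("list", n)
    for (r in seq_len(n)) {
      m <- circuit$morphologies[[members[r]]]
      seg <- m$segments
      if (K > 1 && !all(seg$parent == c(0L, seq_len(K - 1L)))) {
        stop("simulator requires chain (unbranched) morphologies")
      }
      area <- segment_areas(m)          # um^2
      len <- segment_lengths(m)         # um
      C[r, ] <- pas$cm_uf_cm2 * area * 1e-5          # nF
      gL[r, ] <- area * 1e-5 / pas$rm_kohm_cm2       # uS
      if (K > 1) {
        # axial conductance between compartment centers k and k+1
        r_ax <- pas$ra_ohm_cm * 1e4 *
          (len[-K] / 2 / (pi * seg$radius[-K]^2) +
           len[-1] / 2 / (pi * seg$radius[-1]^2))    # Ohm
        ga[r, ] <- 1e6 / r_ax                        # uS
      }
      geom[[r]] <- cbind(as.matrix(seg[, c("x0", "y0", "z0", "x1", "y1", "z1",
                                           "radius")]),
                         is_soma = as.numeric(seq_len(K) == m$soma))
    }
    groups[[gi]] <- list(K = K, ids = members, n = n, C = C, gL = gL, ga = ga)
    cell_tab$group[match(members, cell_tab$id)] <- gi
    cell_tab$row[match(members, cell_tab$id)] <- seq_len(n)
    cell_tab$area_um2[match(members, cell_tab$id)] <-
      rowSums(C) / (pas$cm_uf_cm2 * 1e-5)
    comp_rows[[gi]] <- do.call(rbind, lapply(seq_len(n), function(r) {
      cbind(neuron = members[r], seg = seq_len(K), geom[[r]])
    }))
  }
  comps <- as.data.frame(do.call(rbind, comp_rows))
  # global compartment order: neuron id, then chain position
  comps <- comps[order(comps$neuron, comps$seg), ]
  rownames(comps) <- NULL
  lookup <- new.env()
  for (i in seq_len(nrow(comps))) {
    key <- paste(comps$neuron[i], comps$seg[i])
    assign(key, i, envir = lookup)
  }
  comp_of <- function(neuron, seg) {
    vapply(seq_along(neuron),
           function(j) get(paste(neuron[j], seg[j]), envir = lookup),
           integer(1))
  }

  # synapse classes: unique (tau, e_rev)
  s <- circuit$synapses
  classes <- unique(data.frame(tau = s$tau, e_rev = s$e_rev))
  rownames(classes) <- NULL
  syn <- NULL
  if (nrow(s)) {
    cl <- match(paste(s$tau, s$e_rev), paste(classes$tau, classes$e_rev))
    post_group <- cell_tab$group[match(s$post, cell_tab$id)]
    post_row <- cell_tab$row[match(s$post, cell_tab$id)]
    syn <- data.frame(
      id = s$id, pre = s$pre, post = s$post,
      group = post_group, row = post_row, col = s$segment,
      class = cl,
      g_uS = s$gmax * 1e-3,
      # current-based amplitude: conductance x driving force at rest
      i_nA = s$gmax * 1e-3 * (s$e_rev - pas$e_leak),
      delay = s$delay, p_rel = s$release_prob,
      comp = comp_of(s$post, s$segment),
      projection = s$projection)
    syn$flat <- vapply(seq_len(nrow(syn)), function(i) {
      (syn$col[i] - 1L) * groups[[syn$group[i]]]$n + syn$row[i]
    }, numeric(1))
  }
  eff <- if (!is.null(syn)) split(syn, syn$pre) else list()

  # per group: global compartment indices in (neuron row, chain position)
  # flattening order, so a group's current matrix can be written with one
  # assignment per record step
  grp_cols <- lapply(groups, function(g) {
    comp_of(rep(g$ids, each = g$K), rep(seq_len(g$K), times = g$n))
  })

  structure(list(
    circuit = circuit, cells = cell_tab, groups = groups,
    comps = comps, classes = classes, syn = syn, eff = eff,
    comp_of = comp_of, grp_cols = grp_cols,
    n_comp = nrow(comps)), class = "compiled_circuit")
}

#' Compartment center coordinates of a compiled circuit (micrometres)
#' @param compiled compiled_circuit
#' @return matrix n_comp x 3 (x, y, z)
#' @export
compartment_centers <- function(compiled) {
  cc <- compiled$comps
  cbind(x = (cc$x0 + cc$x1) / 2, y = (cc$y0 + cc$y1) / 2,
        z = (cc$z0 + cc$z1) / 2)
}

#' Ornstein-Uhlenbeck conductance series
#'
#' Exact-update OU process with stationary mean `mean` and standard
#' deviation `ratio * mean`; negative excursions are clipped at zero.
#' Identical `stream_key` yields an identical series regardless of the
#' caller's RNG state.
#'
#' @param mean stationary mean, nS
#' @param ratio sd/mean ratio (dimensionless); the background-noise
#'   calibration fixes this at 0.4
#' @param tau correlation time, ms
#' @param dt time step, ms (must be < tau)
#' @param n_steps number of steps
#' @param stream_key list/vector of key components identifying the stream
#' @return numeric vector of length `n_steps`, nS
#' @export
ou_noise_stream <- function(mean, ratio, tau, dt, n_steps, stream_key = 1L) {
  stopifnot(mean >= 0, ratio >= 0, tau > 0)
  if (dt >= tau) stop("dt must be smaller than the OU correlation time")
  a <- exp(-dt / tau)
  sdv <- ratio * mean
  b <- sdv * sqrt(1 - a^2)
  with_stream(do.call(stream_seed, c(list("ou_stream"), as.list(stream_key))), {
    eps <- stats::rnorm(n_steps)
    g <- numeric(n_steps)
    cur <- mean
    for (i in seq_len(n_steps)) {
      cur <- mean + (cur - mean) * a + b * eps[i]
      if (cur < 0) cur <- 0
      g[i] <- cur
    }
    g
  })
}

# Build per-bin synaptic event lists from a set of presynaptic spike trains.
# Release outcomes are keyed by (trial_seed, synapse id, per-neuron spike
# index), so a replayed train reproduces the connected run's outcomes.
events_from_spikes <- function(compiled, spikes, trial_seed, dt, n_steps) {
  ev_bin <- integer(0); ev_group <- integer(0); ev_flat <- integer(0)
  ev_class <- integer(0); ev_g <- numeric(0); ev_i <- numeric(0)
  if (nrow(spikes) == 0L || is.null(compiled$syn)) {
    return(list(bin = ev_bin, group = ev_group, flat = ev_flat,
                class = ev_class, g = ev_g, i = ev_i))
  }
  spl <- split(spikes$time, spikes$id)
  for (nid in names(spl)) {
    ef <- compiled$eff[[nid]]
    if (is.null(ef)) next
    tt <- sort(spl[[nid]])
    for (k in seq_along(tt)) {
      u <- vapply(ef$id, function(sid)
        counter_uniform(trial_seed, "rel", sid, k), numeric(1))
      keep <- u < ef$p_rel
      if (!any(keep)) next
      bins <- floor((tt[k] + ef$delay[keep]) / dt) + 1L
      ok <- bins >= 1L & bins <= n_steps
      if (!any(ok)) next
      ev_bin <- c(ev_bin, bins[ok])
      ev_group <- c(ev_group, ef$group[keep][ok])
      ev_flat <- c(ev_flat, ef$flat[keep][ok])
      ev_class <- c(ev_class, ef$class[keep][ok])
      ev_g <- c(ev_g, ef$g_uS[keep][ok])
      ev_i <- c(ev_i, ef$i_nA[keep][ok])
    }
  }
  list(bin = ev_bin, group = ev_group, flat = ev_flat, class = ev_class,
       g = ev_g, i = ev_i)
}

#' Replay plan for a decoupled simulation
#'
#' @param circuit circuit_model (or compiled_circuit)
#' @param spikes recorded cortical spike_record from the connected run
#' @param thalamic thalamic spike_record of the same trial
#' @param exclude population name whose efferent synapses stay silent, or
#'   `NULL` to replay every population (the replay-all control)
#' @return list of class `replay_plan`
#' @export
replay_plan <- function(circuit, spikes, thalamic, exclude = NULL) {
  circ <- if (inherits(circuit, "compiled_circuit")) circuit$circuit else circuit
  pops <- population_names(circ)
  if (!is.null(exclude) && !exclude %in% pops) {
    stop("excluded population does not exist: ", exclude)
  }
  structure(list(spikes = spikes, thalamic = thalamic, exclude = exclude,
                 replay = setdiff(pops, exclude), transmit_intrinsic = FALSE),
            class = "replay_plan")
}

#' Simulate the connected circuit
#'
#' Thalamic spikes drive the network; cortical spikes are transmitted by
#' efferent synapses as they occur.  All stochastic outcomes (noise path,
#' synaptic release) are pure functions of `trial_seed`.
#'
#' @param circuit circuit_model or compiled_circuit
#' @param thalamic spike_record of thalamic fiber spikes
#' @param trial_seed integer trial seed
#' @param t_sim simulated time, ms
#' @param dt integration step, ms
#' @param record_every report currents every this many steps
#' @return list with elements `spikes` (spike_record) and `currents`
#'   (currents_report: `time`, `currents` [time x compartment, nA],
#'   `comp_neuron`, `comp_pop`)
#' @export
simulate_connected <- function(circuit, thalamic, trial_seed = 1L,
                               t_sim = 100, dt = 0.025, record_every = 4L) {
  compiled <- as_compiled(circuit)
  run_sim(compiled, thalamic, replay = NULL, trial_seed = trial_seed,
          t_sim = t_sim, dt = dt, record_every = record_every)
}

#' Simulate a decoupled replay run
#'
#' Efferent synapses of every replayed population are activated at the
#' recorded spike times (plus delay); the excluded population's efferents
#' are never activated; spikes generated intrinsically in this run are
#' recorded but never transmitted.  Noise paths and release outcomes are
#' identical to the connected run with the same `trial_seed`.
#'
#' @param circuit circuit_model or compiled_circuit
#' @param plan replay_plan
#' @inheritParams simulate_connected
#' @export
simulate_decoupled <- function(circuit, plan, trial_seed = 1L,
                               t_sim = 100, dt = 0.025, record_every = 4L) {
  compiled <- as_compiled(circuit)
  stopifnot(inherits(plan, "replay_plan"))
  run_sim(compiled, thalamic = plan$thalamic, replay = plan,
          trial_seed = trial_seed, t_sim = t_sim, dt = dt,
          record_every = record_every)
}

as_compiled <- function(x) {
  if (inherits(x, "compiled_circuit")) x else compile_circuit(x)
}

run_sim <- function(compiled, thalamic, replay, trial_seed, t_sim, dt,
                    record_every) {
  circ <- compiled$circuit
  n_steps <- as.integer(ceiling(t_sim / dt))
  cond_based <- identical(circ$synapse_model, "conductance")
  spike_mode <- circ$spike_mode
  spk <- circ$spike
  pas <- circ$passive

  decoupled <- !is.null(replay)
  all_ids <- unlist(lapply(circ$populations, `[[`, "ids"))
  if (decoupled) {
    if (nrow(replay$spikes) && !all(replay$spikes$id %in% all_ids)) {
      stop("replay spike references unknown neuron")
    }
    if (nrow(replay$spikes) && any(replay$spikes$time > t_sim)) {
      stop("replay spike time outside the simulation window")
    }
    # events from replayed populations (thalamus counts as a population)
    keep_ids <- unlist(lapply(replay$replay, function(p)
      circ$populations[[p]]$ids))
    rs <- replay$spikes[replay$spikes$id %in% keep_ids, , drop = FALSE]
    th <- if ("THAL" %in% names(circ$populations) &&
              !identical(replay$exclude, "THAL") &&
              !is.null(replay$thalamic)) replay$thalamic else NULL
    src <- rbind(as.data.frame(rs)[, c("id", "time")],
                 if (!is.null(th)) as.data.frame(th)[, c("id", "time")])
    input_events <- events_from_spikes(compiled, src, trial_seed, dt, n_steps)
  } else {
    src <- if (!is.null(thalamic)) as.data.frame(thalamic)[, c("id", "time")]
           else data.frame(id = integer(0), time = numeric(0))
    input_events <- events_from_spikes(compiled, src, trial_seed, dt, n_steps)
  }
  ev_list <- vector("list", n_steps)
  if (length(input_events$bin)) {
    spl_ev <- split(seq_along(input_events$bin), input_events$bin)
    for (nm in names(spl_ev)) ev_list[[as.integer(nm)]] <- spl_ev[[nm]]
  }

  groups <- compiled$groups
  nG <- length(groups)
  classes <- compiled$classes
  nC <- nrow(classes)
  decay <- exp(-dt / classes$tau)
  # (group, class) pairs that any synapse can ever touch; others stay zero
  used <- matrix(FALSE, nG, max(nC, 1L))
  if (!is.null(compiled$syn) && nrow(compiled$syn)) {
    used[cbind(compiled$syn$group, compiled$syn$class)] <- TRUE
  }

  # per-group constants for the implicit update
  Cdt <- lapply(groups, function(g) g$C / dt)
  Dconst <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    d <- Cdt[[gi]] + g$gL
    if (g$K > 1L) {                 # constant axial terms of the diagonal
      d[, -g$K] <- d[, -g$K] + g$ga
      d[, -1L] <- d[, -1L] + g$ga
    }
    d
  })
  Bconst <- lapply(groups, function(g) g$gL * pas$e_leak)

  # state
  V <- lapply(groups, function(g) matrix(pas$e_leak, g$n, g$K))
  gsyn <- lapply(groups, function(g) {
    lapply(seq_len(max(nC, 1L)), function(j) matrix(0, g$n, g$K))
  })
  inj <- lapply(groups, function(g) numeric(g$n))   # soma spike current, nA

  # OU noise at the soma, one stream per trial covering all cells in a fixed
  # order; identical between connected and decoupled runs by construction.
  # The configured mean conductance refers to a 1e4 um^2 reference membrane
  # and scales with each cell's total membrane area, so small interneurons
  # receive proportionally weaker background drive.
  cells <- compiled$cells
  n_cells <- nrow(cells)
  noise <- circ$noise
  ou_mean <- (noise$mean_ns %||% 0) * 1e-3 * cells$area_um2 / 1e4   # uS
  ou_a <- exp(-dt / (noise$tau_ms %||% 3))
  ou_b <- (noise$ratio %||% 0) * ou_mean * sqrt(1 - ou_a^2)
  gou <- ou_mean
  ou_on <- any(ou_mean > 0)
  # soma position of each cell inside its group matrices
  soma_of <- lapply(seq_len(nG), function(gi) which(cells$group == gi))

  # recording
  rec_steps <- seq.int(record_every, n_steps, by = record_every)
  n_rec <- length(rec_steps)
  out <- matrix(0, n_rec, compiled$n_comp)
  rec_i <- 0L

  # spike bookkeeping
  ref_until <- rep(-Inf, n_cells)
  prev_vs <- rep(pas$e_leak, n_cells)
  spike_id <- integer(0); spike_t <- numeric(0)
  spike_count <- integer(max(all_ids))
  n_wave <- max(1L, as.integer(round(spk$spike_dur_ms / dt)))
  wave <- spk$spike_amp_na * sin(2 * pi * (seq_len(n_wave) - 0.5) / n_wave)
  act_cell <- integer(0); act_step <- integer(0)

  # pending (dynamically scheduled) events, by bin
  pend <- vector("list", n_steps + 1L)

  # hot-loop locals
  e_rev <- classes$e_rev
  eif <- identical(spike_mode, "eif")
  v_thresh <- spk$v_thresh; v_reset <- spk$v_reset
  delta_t <- spk$delta_t; v_t <- spk$v_t; t_ref <- spk$t_ref
  e_leak <- pas$e_leak

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(stream_seed(trial_seed, "ou_trial"))

  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    # 1. decay synaptic state, apply events landing in this bin
    if (nC > 0) {
      for (gi in seq_len(nG)) {
        for (j in seq_len(nC)) {
          if (used[gi, j]) gsyn[[gi]][[j]] <- gsyn[[gi]][[j]] * decay[j]
        }
      }
    }
    idx <- ev_list[[step]]
    if (!is.null(idx)) {
      w <- if (cond_based) input_events$g[idx] else input_events$i[idx]
      gg <- input_events$group[idx]; fl <- input_events$flat[idx]
      cl <- input_events$class[idx]
      for (j in seq_along(idx)) {
        gsyn[[gg[j]]][[cl[j]]][fl[j]] <- gsyn[[gg[j]]][[cl[j]]][fl[j]] + w[j]
      }
    }
    pd <- pend[[step]]
    if (!is.null(pd)) {
      for (j in seq_len(nrow(pd))) {
        gsyn[[pd[j, 1L]]][[pd[j, 3L]]][pd[j, 2L]] <-
          gsyn[[pd[j, 1L]]][[pd[j, 3L]]][pd[j, 2L]] + pd[j, 4L]
      }
    }
    # 2. OU noise update (clipped at zero)
    if (ou_on) {
      gou <- ou_mean + (gou - ou_mean) * ou_a + ou_b * stats::rnorm(n_cells)
      gou[gou < 0] <- 0
    }
    # 3. implicit voltage update per group
    ci <- 0L
    for (gi in seq_len(nG)) {
      g <- groups[[gi]]
      d <- Dconst[[gi]]
      rhs <- Cdt[[gi]] * V[[gi]] + Bconst[[gi]]
      if (nC > 0) {
        for (j in seq_len(nC)) {
          if (!used[gi, j]) next
          Gj <- gsyn[[gi]][[j]]
          if (cond_based) {
            d <- d + Gj
            rhs <- rhs + Gj * e_rev[j]
          } else {
            rhs <- rhs + Gj   # current-based: state holds nA directly
          }
        }
      }
      # soma-targeted terms: OU conductance (reversal 0 mV), injected spike
      # current, exponential spike-initiation current
      rows_g <- soma_of[[gi]]
      if (ou_on) d[, 1L] <- d[, 1L] + gou[rows_g]
      rhs[, 1L] <- rhs[, 1L] + inj[[gi]]
      if (eif) {
        # spike-initiation current, capped near threshold: past the cap the
        # reset takes over, so the unbounded exponential is never integrated
        ex <- pmin((V[[gi]][, 1L] - v_t) / delta_t, 5)
        rhs[, 1L] <- rhs[, 1L] + g$gL[, 1L] * delta_t * exp(ex)
      }
      if (g$K > 1L) {
        V[[gi]] <- thomas_solve(d, -g$ga, rhs)
      } else {
        V[[gi]] <- rhs / d
      }
    }
    # 4. spiking
    vs <- numeric(n_cells)
    for (gi in seq_len(nG)) vs[soma_of[[gi]]] <- V[[gi]][, 1L]
    if (!identical(spike_mode, "none")) {
      firing <- if (eif) {
        which(vs >= v_thresh & t_now >= ref_until)
      } else {
        which(vs >= v_thresh & prev_vs < v_thresh & t_now >= ref_until)
      }
      if (length(firing)) {
        fid <- cells$id[firing]
        spike_id <- c(spike_id, fid)
        spike_t <- c(spike_t, rep(t_now, length(fid)))
        ref_until[firing] <- t_now + t_ref
        if (eif) {
          for (ci2 in firing) {
            V[[cells$group[ci2]]][cells$row[ci2], 1L] <- v_reset
          }
          act_cell <- c(act_cell, firing)
          act_step <- c(act_step, rep(step, length(firing)))
        }
        # transmit efferents (connected mode only)
        if (!decoupled) {
          for (ci2 in seq_along(fid)) {
            nid <- fid[ci2]
            ef <- compiled$eff[[as.character(nid)]]
            spike_count[nid] <- spike_count[nid] + 1L
            if (is.null(ef)) next
            k <- spike_count[nid]
            u <- vapply(ef$id, function(sid)
              counter_uniform(trial_seed, "rel", sid, k), numeric(1))
            keep <- which(u < ef$p_rel)
            if (!length(keep)) next
            bins <- floor((t_now + ef$delay[keep]) / dt) + 1L
            ok <- which(bins <= n_steps)
            if (!length(ok)) next
            w <- if (cond_based) ef$g_uS[keep][ok] else ef$i_nA[keep][ok]
            add <- cbind(ef$group[keep][ok], ef$flat[keep][ok],
                         ef$class[keep][ok], w)
            for (b in unique(bins[ok])) {
              sel <- bins[ok] == b
              pend[[b]] <- rbind(pend[[b]], add[sel, , drop = FALSE])
            }
          }
        }
      }
    }
    prev_vs <- vs
    # stereotyped spike current injection (1 ms biphasic waveform)
    if (length(act_cell)) {
      for (gi in seq_len(nG)) inj[[gi]][] <- 0
      phase <- step - act_step + 1L
      live <- phase <= n_wave
      if (any(live)) {
        for (j in which(live)) {
          ci2 <- act_cell[j]
          gi <- cells$group[ci2]
          inj[[gi]][cells$row[ci2]] <- inj[[gi]][cells$row[ci2]] + wave[phase[j]]
        }
      }
      act_cell <- act_cell[live]; act_step <- act_step[live]
    } else {
      for (gi in seq_len(nG)) if (any(inj[[gi]] != 0)) inj[[gi]][] <- 0
    }
    # 5. record transmembrane currents (net axial inflow)
    if (rec_i < n_rec && step == rec_steps[rec_i + 1L]) {
      rec_i <- rec_i + 1L
      col0 <- 0L
      for (gi in seq_len(nG)) {
        g <- groups[[gi]]
        Vg <- V[[gi]]
        I <- matrix(0, g$n, g$K)
        if (g$K > 1L) {
          dv <- g$ga * (Vg[, -1L, drop = FALSE] - Vg[, -g$K, drop = FALSE])
          I[, -g$K] <- I[, -g$K, drop = FALSE] + dv
          I[, -1L] <- I[, -1L, drop = FALSE] - dv
        }
        # write into global compartment order (neuron-major, chain order)
        out[rec_i, compiled$grp_cols[[gi]]] <- as.vector(t(I))
      }
    }
  }

  spikes <- spike_record(spike_id, spike_t, t_max = t_sim)
  currents <- structure(list(
    time = rec_steps * dt,
    currents = out,
    comp_neuron = compiled$comps$neuron,
    comp_pop = compiled$cells$pop[match(compiled$comps$neuron,
                                        compiled$cells$id)]),
    class = "currents_report")
  list(spikes = spikes, currents = currents)
}

# Vectorized Thomas algorithm: solves, for each row r, the tridiagonal system
# with diagonal d[r, ], sub/super-diagonal e[r, ] (symmetric), rhs b[r, ].
thomas_solve <- function(d, e, b) {
  K <- ncol(d)
  cp <- matrix(0, nrow(d), K - 1L)
  dp <- matrix(0, nrow(d), K)
  cp[, 1L] <- e[, 1L] / d[, 1L]
  dp[, 1L] <- b[, 1L] / d[, 1L]
  if (K > 2L) {
    for (k in 2:(K - 1L)) {
      m <- d[, k] - e[, k - 1L] * cp[, k - 1L]
      cp[, k] <- e[, k] / m
      dp[, k] <- (b[, k] - e[, k - 1L] * dp[, k - 1L]) / m
    }
  }
  m <- d[, K] - e[, K - 1L] * cp[, K - 1L]
  dp[, K] <- (b[, K] - e[, K - 1L] * dp[, K - 1L]) / m
  x <- dp
  for (k in (K - 1L):1L) {
    x[, k] <- dp[, k] - cp[, k] * x[, k + 1L]
  }
  x
}

#' Verify per-neuron charge conservation of a currents report
#'
#' @param currents currents_report
#' @param tol absolute tolerance, nA, per neuron per step
#' @return maximum absolute per-neuron current sum (invisibly errors if
#'   above `tol`)
#' @export
check_charge_conservation <- function(currents, tol = 1e-9) {
  sums <- rowsum(t(currents$currents), currents$comp_neuron)
  mx <- max(abs(sums))
  if (mx > tol * length(unique(currents$comp_neuron))) {
    stop("charge conservation violated: max per-neuron current sum ", mx, " nA")
  }
  mx
}
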