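# Synthetic layered circuit stand-ins.
#
# A circuit is a set of populations spanning cytological layers L1-L6 plus a
# virtual thalamic fiber population (no compartments inside the modeled
# volume), connected by conductance- or current-based synapses whose
# placement on postsynaptic morphologies follows a per-projection profile
# (distributed vs perisomatic).  The perisomatic profile on inhibitory
# projections onto L5 pyramidal cells is what distinguishes the rewired
# ("SM") variant from the original circuit at this scale.

#' Build a synthetic circuit
#'
#' Deterministic given `(config, seed)`.  See [default_circuit_config()] for
#' the configuration structure and the desk-scale defaults.
#'
#' @param config nested list: `layers` (named depth boundaries, micrometres,
#'   strictly increasing), `populations` (list of name, layer, class
#'   (`EXC`/`INH`/`PeriTC`/`fiber`), n, morphology parameters), `projections`
#'   (list of pre, post, p (connection probability), gmax (nS), tau (ms),
#'   e_rev (mV), release_prob, profile, nsyn per connection), `noise`
#'   (`mean_ns`, `ratio`, `tau_ms`), `passive`, `spike`, `synapse_model`
#'   (`"conductance"` or `"current"`), `spike_mode` (`"eif"`, `"detect"` or
#'   `"none"`), `radius` / `min_radius` (lateral extent, micrometres).
#' @param seed integer master seed for all structural randomness
#' @return object of class `circuit_model`
#' @export
build_circuit <- function(config, seed = 1L) {
  check_layers(config$layers)
  pops <- config$populations
  if (length(pops) < 2L) stop("config must name at least two populations")
  for (p in pops) {
    if (is.null(p$n) || p$n < 1L) stop("zero-count population: ", p$name)
  }

  # --- neurons and morphologies -------------------------------------------
  ids <- list(); morphs <- list(); next_id <- 1L
  pop_tab <- list()
  for (p in pops) {
    pid <- seq.int(next_id, next_id + p$n - 1L)
    next_id <- next_id + p$n
    ids[[p$name]] <- pid
    pop_tab[[p$name]] <- list(name = p$name, layer = p$layer,
                              class = p$class, ids = pid)
    if (identical(p$class, "fiber")) next  # fibers carry no compartments
    zr <- layer_depth_range(config$layers, p$layer)
    m <- with_stream(stream_seed(seed, "morph", p$name), {
      depth <- stats::runif(p$n, zr[1] + 25, zr[2] - 25)
      ang <- stats::runif(p$n, 0, 2 * pi)
      rad <- sqrt(stats::runif(p$n,
                               (config$min_radius %||% 20)^2,
                               (config$radius %||% 250)^2))
      lapply(seq_len(p$n), function(i) {
        if (identical(p$morph %||% "ball_and_stick", "soma_only")) {
          soma_only(depth[i], x = rad[i] * cos(ang[i]), y = rad[i] * sin(ang[i]))
        } else {
          dl <- min(p$dend_length %||% 400, depth[i] - 30)
          ball_and_stick(depth[i], dl, n_dend = p$n_dend %||% 10L,
                         x = rad[i] * cos(ang[i]), y = rad[i] * sin(ang[i]))
        }
      })
    })
    morphs[pid] <- m
  }

  # --- synapses ------------------------------------------------------------
  syn <- list()
  for (pr in config$projections) {
    pre_ids <- ids[[pr$pre]]; post_ids <- ids[[pr$post]]
    if (is.null(pre_ids) || is.null(post_ids)) {
      stop("projection references unknown population: ", pr$pre, " -> ", pr$post)
    }
    if (!(pr$profile %||% "distributed") %in% c("distributed", "perisomatic")) {
      stop("unknown placement profile name: ", pr$profile)
    }
    pairs <- with_stream(stream_seed(seed, "conn", pr$pre, pr$post), {
      u <- stats::runif(length(pre_ids) * length(post_ids))
      k <- which(u < pr$p)
      if (length(k) == 0L) NULL else {
        data.frame(pre = pre_ids[((k - 1L) %% length(pre_ids)) + 1L],
                   post = post_ids[((k - 1L) %/% length(pre_ids)) + 1L])
      }
    })
    if (is.null(pairs)) next
    pairs <- pairs[pairs$pre != pairs$post, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    nsyn <- pr$nsyn %||% 1L
    pairs <- pairs[rep(seq_len(nrow(pairs)), each = nsyn), , drop = FALSE]
    # placement on each postsynaptic morphology
    plc <- lapply(split(seq_len(nrow(pairs)), pairs$post), function(rows) {
      pid <- pairs$post[rows[1]]
      place_synapses(morphs[[pid]], length(rows),
                     profile = pr$profile %||% "distributed",
                     seed = stream_seed(seed, "placeseed", pr$pre, pr$post, pid),
                     max_path_dist = pr$max_path_dist %||% 50)
    })
    ord <- unlist(split(seq_len(nrow(pairs)), pairs$post), use.names = FALSE)
    plc <- do.call(rbind, plc)[order(ord), , drop = FALSE]
    syn[[length(syn) + 1L]] <- data.frame(
      pre = pairs$pre, post = pairs$post,
      segment = plc$segment, offset = plc$offset,
      gmax = pr$gmax, tau = pr$tau, e_rev = pr$e_rev,
      delay = NA_real_, release_prob = pr$release_prob %||% 1,
      projection = paste0(pr$pre, "->", pr$post))
  }
  synapses <- if (length(syn)) do.call(rbind, syn) else data.frame(
    pre = integer(0), post = integer(0), segment = integer(0),
    offset = numeric(0), gmax = numeric(0), tau = numeric(0),
    e_rev = numeric(0), delay = numeric(0), release_prob = numeric(0),
    projection = character(0))
  rownames(synapses) <- NULL
  synapses$id <- seq_len(nrow(synapses))

  circ <- structure(list(
    populations = pop_tab,
    morphologies = morphs,
    synapses = synapses,
    layers = config$layers,
    passive = config[["passive"]] %||% default_passive(),
    spike = config[["spike"]] %||% default_spike(),
    noise = config[["noise"]] %||% list(mean_ns = 0, ratio = 0.4, tau_ms = 3),
    synapse_model = config[["synapse_model"]] %||% "conductance",
    spike_mode = config[["spike_mode"]] %||% "eif",
    config = config, seed = seed), class = "circuit_model")
  circ <- assign_axonal_delays(circ,
                               base_delay = config$base_delay %||% 1,
                               velocity = config$velocity %||% 300)
  validate_circuit(circ)
  circ
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_layers <- function(layers) {
  if (is.null(layers) || length(layers) < 2L) stop("layer boundaries required")
  d <- unlist(layers)
  if (any(diff(d) <= 0)) stop("overlapping layer boundaries: depths must strictly increase")
  invisible(layers)
}

layer_depth_range <- function(layers, layer) {
  nm <- names(layers)
  i <- match(layer, nm)
  if (is.na(i) || i == length(nm)) stop("unknown layer label: ", layer)
  c(layers[[i]], layers[[i + 1L]])
}

default_passive <- function() {
  # conventional passive constants: Cm 1 uF/cm^2, Rm 20 kOhm cm^2, Ra 150 Ohm cm
  list(cm_uf_cm2 = 1, rm_kohm_cm2 = 20, ra_ohm_cm = 150, e_leak = -70)
}

default_spike <- function() {
  # exponential-integrate-and-fire soma + stereotyped 1-ms biphasic spike
  # current; the 3 nA amplitude matches the capacitive current of an action
  # potential upstroke for the 10 um soma (~12.6 pF x ~240 V/s), so spike
  # timing leaves a visible high-frequency signature in the EEG without
  # dominating the synaptically generated waveform
  list(v_thresh = -50, v_reset = -65, t_ref = 2.5, delta_t = 2, v_t = -54,
       spike_amp_na = 3, spike_dur_ms = 1)
}

#' Validate circuit invariants
#' @param circ circuit_model
#' @return `circ`, invisibly; errors on violation
#' @export
validate_circuit <- function(circ) {
  all_ids <- unlist(lapply(circ$populations, `[[`, "ids"))
  if (anyDuplicated(all_ids)) stop("neuron ids overlap across populations")
  for (p in circ$populations) {
    if (identical(p$class, "fiber")) {
      if (any(!vapply(circ$morphologies[p$ids], is.null, logical(1)))) {
        stop("thalamic fiber populations must not carry compartments")
      }
    }
  }
  s <- circ$synapses
  if (nrow(s)) {
    if (!all(s$pre %in% all_ids) || !all(s$post %in% all_ids)) {
      stop("synapse references unknown neuron id")
    }
    for (i in seq_len(nrow(s))) {
      m <- circ$morphologies[[s$post[i]]]
      if (is.null(m) || s$segment[i] > nrow(m$segments)) {
        stop("synapse references nonexistent segment")
      }
    }
    if (any(s$offset < 0 | s$offset > 1)) stop("synapse offset outside [0, 1]")
    if (any(s$gmax < 0)) stop("negative synaptic conductance")
  }
  invisible(circ)
}

#' @export
print.circuit_model <- function(x, ...) {
  n_cell <- sum(vapply(x$populations,
                       function(p) if (identical(p$class, "fiber")) 0L else length(p$ids),
                       integer(1)))
  cat(sprintf("<circuit_model: %d populations, %d neurons, %d synapses>\n",
              length(x$populations), n_cell, nrow(x$synapses)))
  invisible(x)
}

#' Assign distance-based axonal delays
#'
#' Delay of every synapse is `base_delay` plus the distance from the bottom
#' of layer 6 to the synapse location, divided by the conduction velocity.
#' This reproduces the depth-dependent activation order of thalamocortical
#' input (deep synapses are reached first).
#'
#' @param circuit circuit_model
#' @param base_delay minimal delay, ms
#' @param velocity conduction velocity, micrometres per ms
#' @return circuit with the `delay` column of its synapse table filled
#' @export
assign_axonal_delays <- function(circuit, base_delay = 1, velocity = 300) {
  stopifnot(velocity > 0)
  z_bottom <- max(unlist(circuit$layers))
  s <- circuit$synapses
  if (nrow(s)) {
    z_syn <- vapply(seq_len(nrow(s)), function(i) {
      m <- circuit$morphologies[[s$post[i]]]
      seg <- m$segments[s$segment[i], ]
      seg$z0 + (seg$z1 - seg$z0) * s$offset[i]
    }, numeric(1))
    dist <- z_bottom - z_syn
    if (any(dist < 0)) stop("synapse below the bottom of layer 6")
    circuit$synapses$delay <- base_delay + dist / velocity
  }
  circuit
}

#' Desk-scale default circuit configuration
#'
#' A layered column stand-in with excitatory ball-and-stick pyramidal cells
#' and soma-only interneurons in L2/3-L6, a perisomatic-targeting basket-cell
#' population in L5, and 100 virtual thalamic fibers.  `variant = "sm"`
#' moves the inhibitory L5 projections onto L5 pyramidal cells from
#' distributed to perisomatic placement, emulating the rewired circuit; all
#' other parameters are identical.
#'
#' @param variant `"original"` or `"sm"`
#' @param scale multiplier on population sizes (default 1 gives ~290 cells)
#' @return config list for [build_circuit()]
#' @export
default_circuit_config <- function(variant = c("original", "sm"), scale = 1) {
  variant <- match.arg(variant)
  peri_prof <- if (variant == "sm") "perisomatic" else "distributed"
  n <- function(k) max(2L, as.integer(round(k * scale)))
  list(
    variant = variant,
    layers = list(L1 = 0, L23 = 150, L4 = 500, L5 = 750, L6 = 1100, bottom = 1500),
    radius = 250, min_radius = 25,
    base_delay = 1, velocity = 300,
    synapse_model = "conductance", spike_mode = "eif",
    noise = list(mean_ns = 1.25, ratio = 0.4, tau_ms = 3),
    populations = list(
      list(name = "L23E", layer = "L23", class = "EXC", n = n(50),
           dend_length = 280, n_dend = 5L),
      list(name = "L23I", layer = "L23", class = "INH", n = n(12), morph = "soma_only"),
      list(name = "L4E",  layer = "L4",  class = "EXC", n = n(30),
           dend_length = 420, n_dend = 5L),
      list(name = "L4I",  layer = "L4",  class = "INH", n = n(8),  morph = "soma_only"),
      list(name = "L5E",  layer = "L5",  class = "EXC", n = n(40),
           dend_length = 750, n_dend = 5L),
      list(name = "L5I",  layer = "L5",  class = "INH", n = n(10), morph = "soma_only"),
      list(name = "L5PeriTC", layer = "L5", class = "PeriTC", n = n(8),
           morph = "soma_only"),
      list(name = "L6E",  layer = "L6",  class = "EXC", n = n(40),
           dend_length = 650, n_dend = 5L),
      list(name = "L6I",  layer = "L6",  class = "INH", n = n(10), morph = "soma_only"),
      list(name = "THAL", layer = "L6",  class = "fiber", n = n(100))
    ),
    projections = c(
      # thalamocortical input targets primarily L5, plus L2/3, L4, L6 and
      # interneurons; placement is proximal (basal-dendrite emulation: the
      # synaptic sink sits deep, the return current superficial, making the
      # early evoked deflection surface-positive), except on L6 pyramids,
      # whose apical TC synapses drive a slow surface-negative component
      proj("THAL", "L23E", 0.10, gmax = 2.5, tau = 2, e = 0,
           profile = "perisomatic", max_path_dist = 80),
      proj("THAL", "L4E",  0.12, gmax = 2.5, tau = 2, e = 0,
           profile = "perisomatic", max_path_dist = 80),
      proj("THAL", "L5E",  0.18, gmax = 2.5, tau = 2, e = 0,
           profile = "perisomatic", max_path_dist = 80),
      proj("THAL", "L6E",  0.12, gmax = 2.5, tau = 2, e = 0),
      proj("THAL", "L4I",  0.10, gmax = 0.4, tau = 2, e = 0),
      proj("THAL", "L5I",  0.10, gmax = 0.4, tau = 2, e = 0),
      proj("THAL", "L5PeriTC", 0.12, gmax = 0.4, tau = 2, e = 0),
      # recurrent excitation
      proj("L23E", "L23E", 0.06, gmax = 0.35, tau = 2, e = 0),
      proj("L4E",  "L23E", 0.08, gmax = 0.4,  tau = 2, e = 0),
      proj("L4E",  "L4E",  0.06, gmax = 0.35, tau = 2, e = 0),
      proj("L5E",  "L5E",  0.06, gmax = 0.4,  tau = 2, e = 0),
      proj("L6E",  "L5E",  0.05, gmax = 0.35, tau = 2, e = 0),
      proj("L6E",  "L6E",  0.05, gmax = 0.35, tau = 2, e = 0),
      # excitation of interneurons
      proj("L23E", "L23I", 0.10, gmax = 0.5, tau = 2, e = 0),
      proj("L4E",  "L4I",  0.10, gmax = 0.5, tau = 2, e = 0),
      proj("L5E",  "L5I",  0.10, gmax = 0.5, tau = 2, e = 0),
      proj("L5E",  "L5PeriTC", 0.10, gmax = 0.5, tau = 2, e = 0),
      proj("L6E",  "L6I",  0.10, gmax = 0.5, tau = 2, e = 0),
      # inhibition: basket-type interneurons target perisomatic compartments
      # in both variants; only the L5 PeriTC projection onto L5 pyramidal
      # cells switches from distributed to perisomatic in the rewired
      # variant (the connectivity change under study)
      proj("L23I", "L23E", 0.15, gmax = 0.5, tau = 8, e = -80,
           profile = "perisomatic"),
      proj("L4I",  "L4E",  0.15, gmax = 0.5, tau = 8, e = -80,
           profile = "perisomatic"),
      proj("L5I",  "L5E",  0.18, gmax = 0.6, tau = 8, e = -80,
           profile = "perisomatic"),
      proj("L5PeriTC", "L5E", 0.22, gmax = 0.7, tau = 8, e = -80,
           profile = peri_prof, nsyn = 4L),
      proj("L6I",  "L6E",  0.15, gmax = 0.5, tau = 8, e = -80,
           profile = "perisomatic"),
      proj("L6I",  "L5E",  0.08, gmax = 0.45, tau = 8, e = -80,
           profile = "perisomatic")
    )
  )
}

proj <- function(pre, post, p, gmax, tau, e, profile = "distributed",
                 release_prob = 1, nsyn = 2L, max_path_dist = 50) {
  list(list(pre = pre, post = post, p = p, gmax = gmax, tau = tau, e_rev = e,
            profile = profile, release_prob = release_prob, nsyn = nsyn,
            max_path_dist = max_path_dist))
}

#' Neuron ids of a population
#' @param circuit circuit_model
#' @param population population name
#' @export
population_ids <- function(circuit, population) {
  p <- circuit$populations[[population]]
  if (is.null(p)) stop("unknown population: ", population)
  p$ids
}

#' Names of populations that can spike (everything incl. fibers)
#' @param circuit circuit_model
#' @export
population_names <- function(circuit) names(circuit$populations)
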