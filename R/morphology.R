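# Stand-in neuron morphologies.
#
# Pyramidal cells are represented as ball-and-stick: a spherical soma plus a
# single unbranched apical cable pointing toward the pia.  Interneurons and
# perisomatic-targeting basket cells are soma-only.  These are the minimal
# shapes that still produce dipolar transmembrane current patterns (soma
# current + apical return current), which is the feature the EEG forward
# model is sensitive to.
#
# Coordinate frame: z is depth in micrometres, 0 at the pia, increasing
# downward.  x/y are lateral offsets from the column axis.

#' Construct a morphology from a segment table
#'
#' @param segments data.frame with columns `x0,y0,z0,x1,y1,z1` (proximal and
#'   distal endpoint coordinates, micrometres), `radius` (micrometres) and
#'   `parent` (integer index of the parent segment, 0 for the root soma).
#' @param soma integer index of the soma segment.
#' @return object of class `morphology`
#' @export
morphology <- function(segments, soma = 1L) {
  stopifnot(is.data.frame(segments),
            all(c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "parent")
                %in% names(segments)))
  m <- structure(list(segments = segments, soma = as.integer(soma)),
                 class = "morphology")
  validate_morphology(m)
  m
}

#' Validate morphology invariants
#'
#' Exactly one root (the soma), acyclic tree parentage, strictly positive
#' radii and non-soma segment lengths.
#'
#' @param m morphology
#' @return `m`, invisibly; errors on violation
#' @export
validate_morphology <- function(m) {
  seg <- m$segments
  n <- nrow(seg)
  roots <- which(seg$parent == 0L)
  if (length(roots) != 1L || roots != m$soma) {
    stop("morphology must have exactly one root segment, the soma")
  }
  if (any(seg$radius <= 0)) stop("all segment radii must be positive")
  len <- segment_lengths(m)
  if (any(len[-m$soma] <= 0)) stop("all non-soma segment lengths must be positive")
  # tree check: repeatedly follow parents; every node must reach the root
  for (i in seq_len(n)) {
    j <- i
    hops <- 0L
    while (seg$parent[j] != 0L) {
      j <- seg$parent[j]
      hops <- hops + 1L
      if (hops > n) stop("cycle detected in morphology parentage")
    }
  }
  invisible(m)
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology: %d segments, soma depth %.0f um>\n",
              nrow(x$segments), segment_centers(x)[x$soma, "z"]))
  invisible(x)
}

#' Segment midpoint coordinates (micrometres)
#' @param m morphology
#' @return matrix with columns x, y, z
#' @export
segment_centers <- function(m) {
  seg <- m$segments
  cbind(x = (seg$x0 + seg$x1) / 2,
        y = (seg$y0 + seg$y1) / 2,
        z = (seg$z0 + seg$z1) / 2)
}

#' Segment lengths (micrometres); the soma reports its diameter
#' @param m morphology
#' @export
segment_lengths <- function(m) {
  seg <- m$segments
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
  len[m$soma] <- 2 * seg$radius[m$soma]
  len
}

#' Segment membrane areas (micrometres squared)
#'
#' Cylindrical lateral area for cable segments, spherical area for the soma.
#' @param m morphology
#' @export
segment_areas <- function(m) {
  seg <- m$segments
  len <- segment_lengths(m)
  area <- 2 * pi * seg$radius * len
  area[m$soma] <- 4 * pi * seg$radius[m$soma]^2
  area
}

#' Path distance from each segment center to the soma (micrometres)
#' @param m morphology
#' @export
path_distance_to_soma <- function(m) {
  seg <- m$segments
  len <- segment_lengths(m)
  n <- nrow(seg)
  d <- numeric(n)
  for (i in seq_len(n)) {
    if (i == m$soma) next
    # distance = half of own length + full lengths of intervening segments
    acc <- len[i] / 2
    j <- seg$parent[i]
    while (j != 0L && j != m$soma) {
      acc <- acc + len[j]
      j <- seg$parent[j]
    }
    d[i] <- acc
  }
  d
}

#' Ball-and-stick pyramidal-cell stand-in
#'
#' Soma at depth `soma_depth`, apical cable of `n_dend` equal segments running
#' straight up toward the pia.
#'
#' @param soma_depth soma center depth, micrometres below the pia
#' @param dend_length total apical cable length, micrometres (must not poke
#'   above the pia)
#' @param n_dend number of cable segments (equal length)
#' @param soma_radius soma radius, micrometres
#' @param dend_radius cable radius, micrometres
#' @param x,y lateral position of the cell axis, micrometres
#' @return morphology
#' @export
ball_and_stick <- function(soma_depth, dend_length, n_dend = 10L,
                           soma_radius = 10, dend_radius = 1.5,
                           x = 0, y = 0) {
  stopifnot(n_dend >= 1L, dend_length > 0, soma_depth - dend_length >= 0)
  zb <- seq(soma_depth, soma_depth - dend_length, length.out = n_dend + 1L)
  soma <- data.frame(x0 = x, y0 = y, z0 = soma_depth + soma_radius,
                     x1 = x, y1 = y, z1 = soma_depth - soma_radius,
                     radius = soma_radius, parent = 0L)
  dend <- data.frame(x0 = x, y0 = y, z0 = zb[-length(zb)],
                     x1 = x, y1 = y, z1 = zb[-1L],
                     radius = dend_radius,
                     parent = seq_len(n_dend))  # chain: soma(1) <- 2 <- 3 ...
  morphology(rbind(soma, dend), soma = 1L)
}

#' Soma-only interneuron stand-in
#'
#' @inheritParams ball_and_stick
#' @return morphology
#' @export
soma_only <- function(soma_depth, soma_radius = 7.5, x = 0, y = 0) {
  soma <- data.frame(x0 = x, y0 = y, z0 = soma_depth + soma_radius,
                     x1 = x, y1 = y, z1 = soma_depth - soma_radius,
                     radius = soma_radius, parent = 0L)
  morphology(soma, soma = 1L)
}

#' Sample synapse placements on a morphology
#'
#' `distributed` places synapses with probability proportional to segment
#' membrane area (the default, area-uniform innervation).  `perisomatic`
#' restricts candidate segments to those whose center lies within
#' `max_path_dist` micrometres of the soma along the cable, emulating
#' basket-cell targeting of soma-proximal compartments.
#'
#' @param post_morphology morphology of the postsynaptic cell
#' @param n number of placements (>= 0)
#' @param profile `"distributed"` or `"perisomatic"`
#' @param seed integer seed; placements are a pure function of
#'   (morphology, n, profile, seed)
#' @param max_path_dist perisomatic path-distance bound, micrometres
#' @return data.frame with columns `segment` (index) and `offset` in `[0, 1]`
#' @export
place_synapses <- function(post_morphology, n, profile = c("distributed", "perisomatic"),
                           seed = 1L, max_path_dist = 50) {
  profile <- match.arg(profile)
  stopifnot(n >= 0)
  if (n == 0) {
    return(data.frame(segment = integer(0), offset = numeric(0)))
  }
  area <- segment_areas(post_morphology)
  if (profile == "perisomatic") {
    eligible <- which(path_distance_to_soma(post_morphology) <= max_path_dist)
    if (length(eligible) == 0L) {
      stop("no compartment within ", max_path_dist, " um of the soma")
    }
  } else {
    eligible <- seq_along(area)
  }
  with_stream(stream_seed(seed, "place", profile, n), {
    segs <- sample(eligible, n, replace = TRUE, prob = area[eligible])
    data.frame(segment = as.integer(segs), offset = stats::runif(n))
  })
}
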