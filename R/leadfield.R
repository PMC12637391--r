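# Lead fields: per-compartment EEG sensitivity weights and per-segment LFP
# coefficients.
#
# EEG uses the reciprocity principle: the weight of a compartment for an
# electrode pair equals the potential that a unit current driven between the
# recording and reference electrodes would create at the compartment.  For a
# homogeneous medium of conductivity sigma this is the point-source potential
# w = 1/(4 pi sigma) (1/r_rec - 1/r_ref); the recording-minus-reference
# subtraction is folded into the single per-compartment scalar.  LFP uses the
# line-source approximation: each cable segment is a uniform line of current
# in an infinite homogeneous medium; somata are treated as point sources.
#
# Weights are stored in V/nA so that the dot product with transmembrane
# currents in nA yields volts directly.

#' Electrode specification
#'
#' @param position recording electrode xyz, micrometres
#' @param reference reference electrode xyz (micrometres) or `"infinity"`
#' @param sigma medium conductivity, S/m (gray-matter convention 0.3)
#' @return list of class `electrode_spec`
#' @export
electrode_spec <- function(position, reference = "infinity", sigma = 0.3) {
  stopifnot(length(position) == 3, sigma > 0)
  if (!identical(reference, "infinity")) {
    stopifnot(length(reference) == 3)
    if (all(position == reference)) stop("electrode positions must be distinct")
  }
  structure(list(position = as.numeric(position), reference = reference,
                 sigma = sigma), class = "electrode_spec")
}

#' Reciprocity point-electrode EEG weights
#'
#' @param centers matrix n x 3 of compartment centers, micrometres
#' @param spec electrode_spec
#' @return object of class `weights_table`: list with `weights` (V/nA, one
#'   per compartment), `electrode` metadata and optional `comp_neuron` map
#' @export
point_electrode_weights <- function(centers, spec) {
  stopifnot(inherits(spec, "electrode_spec"))
  centers <- as.matrix(centers)
  r_rec <- sqrt(rowSums(sweep(centers, 2, spec$position)^2)) * 1e-6  # m
  if (any(r_rec == 0)) stop("compartment coincides with the recording electrode")
  w <- 1 / r_rec
  if (!identical(spec$reference, "infinity")) {
    r_ref <- sqrt(rowSums(sweep(centers, 2, spec$reference)^2)) * 1e-6
    if (any(r_ref == 0)) stop("compartment coincides with the reference electrode")
    w <- w - 1 / r_ref
  }
  w <- w / (4 * pi * spec$sigma) * 1e-9   # V/A -> V/nA
  weights_table(w, electrode = spec)
}

#' Construct a weights table
#'
#' @param weights numeric vector, V/nA, in the compartment order of the
#'   currents report
#' @param electrode electrode metadata (electrode_spec or list)
#' @param comp_neuron integer neuron id per compartment (optional)
#' @export
weights_table <- function(weights, electrode = NULL, comp_neuron = NULL) {
  if (any(!is.finite(weights))) stop("weights must be finite")
  structure(list(weights = as.numeric(weights), electrode = electrode,
                 comp_neuron = comp_neuron), class = "weights_table")
}

#' @export
print.weights_table <- function(x, ...) {
  cat(sprintf("<weights_table: %d compartments, range [%.3g, %.3g] V/nA>\n",
              length(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Line-source LFP coefficients for one electrode
#'
#' Each cable segment contributes the analytic potential of a uniform line
#' current of unit magnitude; the soma (flagged `is_soma`) contributes the
#' point-source potential at its center.
#'
#' @param segments data.frame/matrix with columns `x0,y0,z0,x1,y1,z1`
#'   (micrometres) and `is_soma` (0/1)
#' @param position electrode xyz, micrometres
#' @param sigma conductivity, S/m
#' @return numeric vector of coefficients, V/nA
#' @export
line_source_weights <- function(segments, position, sigma = 0.3) {
  seg <- as.data.frame(segments)
  n <- nrow(seg)
  w <- numeric(n)
  p <- as.numeric(position)
  for (i in seq_len(n)) {
    a <- c(seg$x0[i], seg$y0[i], seg$z0[i])
    b <- c(seg$x1[i], seg$y1[i], seg$z1[i])
    if (seg$is_soma[i] > 0) {
      r <- sqrt(sum((p - (a + b) / 2)^2)) * 1e-6
      if (r == 0) stop("electrode coincides with a soma")
      w[i] <- 1 / (4 * pi * sigma * r)
      next
    }
    L <- sqrt(sum((b - a)^2))
    u <- (b - a) / L
    s <- sum((p - a) * u)            # axial projection of electrode, from a
    rho <- sqrt(max(sum((p - a)^2) - s^2, 0)) * 1e-6
    # signed longitudinal distances from the projection to the two ends
    l <- (0 - s) * 1e-6
    h <- (L - s) * 1e-6
    if (rho == 0) {
      if (l <= 0 && h >= 0) {
        stop("electrode lies on a segment axis within the segment span")
      }
      # on-axis limit: asinh(h/rho) - asinh(l/rho) -> ln(h/l)
      w[i] <- abs(log(abs(h) / abs(l))) / (4 * pi * sigma * (L * 1e-6))
    } else {
      w[i] <- (asinh(h / rho) - asinh(l / rho)) / (4 * pi * sigma * (L * 1e-6))
    }
  }
  w * 1e-9   # V/A -> V/nA
}

#' LFP weights table for a laminar electrode array
#'
#' @param compiled compiled_circuit
#' @param depths electrode depths, micrometres (array on the column axis)
#' @param x,y lateral position of the array axis, micrometres
#' @param sigma conductivity, S/m
#' @return matrix n_comp x n_electrodes of coefficients (V/nA)
#' @export
laminar_lfp_weights <- function(compiled, depths, x = 0, y = 0, sigma = 0.3) {
  seg <- compiled$comps
  sapply(depths, function(zd) {
    line_source_weights(seg, c(x, y, zd), sigma = sigma)
  })
}

#' Shift compartment weights to center their range on zero
#'
#' Only spatial gradients of the weights affect the signal when every
#' neuron's compartment currents sum to zero (gauge freedom), so a constant
#' can be subtracted.  The shift centers the range over the given scope:
#' after shifting, max + min of the scoped weights is zero.
#'
#' @param weights weights_table
#' @param scope integer indices of the compartments in scope (default: all)
#' @return shifted weights_table
#' @export
gauge_shift <- function(weights, scope = seq_along(weights$weights)) {
  if (length(scope) == 0L) stop("gauge shift scope must be nonempty")
  w <- weights$weights
  shift <- (max(w[scope]) + min(w[scope])) / 2
  weights_table(w - shift, electrode = weights$electrode,
                comp_neuron = weights$comp_neuron)
}

#' Per-neuron weights-range statistic
#'
#' For each sampled neuron, the difference between the 90th and 10th
#' percentiles of its compartment weights; averaged over the sample.  A
#' larger range implies a larger possible postsynaptic contribution.
#'
#' @param weights weights_table with a `comp_neuron` map
#' @param sample neuron ids to include (default: a random sample of up to
#'   `sample_size` neurons)
#' @param sample_size default sample size when `sample` is NULL
#' @param seed seed for the default sampling
#' @return mean 90th-10th percentile range, V/nA
#' @export
weights_range_stat <- function(weights, sample = NULL, sample_size = 100L,
                               seed = 1L) {
  if (is.null(weights$comp_neuron)) stop("weights table lacks a neuron map")
  ids <- unique(weights$comp_neuron)
  if (is.null(sample)) {
    sample <- if (length(ids) <= sample_size) ids else {
      with_stream(stream_seed(seed, "wrs"), sort(sample(ids, sample_size)))
    }
  }
  if (length(sample) == 0L) stop("neuron sample must be nonempty")
  rng <- vapply(sample, function(id) {
    w <- weights$weights[weights$comp_neuron == id]
    if (length(w) < 2L) return(0)
    unname(diff(stats::quantile(w, c(0.1, 0.9))))
  }, numeric(1))
  mean(rng)
}

#' Write a weights table to a plain-text file
#'
#' Tab-separated compartment table preceded by `#`-prefixed JSON metadata;
#' full double precision so that write-read round-trips are lossless.
#'
#' @param weights weights_table
#' @param path file path
#' @export
write_weights <- function(weights, path) {
  meta <- list(
    electrode = if (inherits(weights$electrode, "electrode_spec")) {
      list(position = weights$electrode$position,
           reference = weights$electrode$reference,
           sigma = weights$electrode$sigma)
    } else weights$electrode)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  df <- data.frame(compartment = seq_along(weights$weights),
                   neuron = if (is.null(weights$comp_neuron)) NA_integer_
                            else weights$comp_neuron,
                   weight = sprintf("%.17g", weights$weights))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a weights table written by [write_weights()]
#'
#' @param path file path
#' @return weights_table
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[meta_lines[1]]))
  df <- utils::read.table(text = lines[-meta_lines], header = TRUE, sep = "\t")
  cn <- if (all(is.na(df$neuron))) NULL else df$neuron
  el <- meta$electrode
  spec <- if (!is.null(el$position)) {
    electrode_spec(el$position,
                   reference = if (is.character(el$reference)) el$reference
                               else as.numeric(el$reference),
                   sigma = el$sigma)
  } else el
  weights_table(as.numeric(df$weight), electrode = spec, comp_neuron = cn)
}
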