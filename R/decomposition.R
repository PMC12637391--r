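# Network-minus-decoupled contribution calculus.
#
# The presynaptic contribution of a population is the difference between the
# network EEG and the EEG of a decoupled replay in which that population's
# efferent synapses stay silent while every other population's recorded
# spikes are replayed.  Because both runs share noise paths and release
# outcomes, the difference isolates the synaptic and return currents the
# population elicits downstream (plus a replay-timing noise floor from
# active currents).  Restricting the per-neuron difference to one
# postsynaptic population yields a pathway (pre -> post) contribution;
# summing a population's own per-neuron contributions yields its
# postsynaptic contribution.

subtract_traces <- function(a, b) {
  if (!isTRUE(all.equal(a$time, b$time))) stop("trace time grids differ")
  fa <- isTRUE(a$meta$filtered); fb <- isTRUE(b$meta$filtered)
  if (fa != fb) stop("traces differ in filtering state")
  contrib <- NULL
  if (!is.null(a$contributions) && !is.null(b$contributions)) {
    if (!identical(a$neuron_ids, b$neuron_ids)) {
      stop("traces carry different neuron orderings")
    }
    contrib <- a$contributions - b$contributions
  }
  signal_trace(a$time, a$values - b$values, contrib, a$neuron_ids,
               meta = utils::modifyList(a$meta, list(kind = "contribution")))
}

#' Presynaptic contribution of a population
#'
#' @param network network signal_trace (connected run)
#' @param decoupled decoupled signal_trace (replay with the population's
#'   efferents silent), same grid and filtering state
#' @return signal_trace of the contribution (per-neuron matrix is the
#'   per-neuron difference)
#' @export
presynaptic_contribution <- function(network, decoupled) {
  subtract_traces(network, decoupled)
}

#' Pathway (pre -> post) contribution
#'
#' Per-neuron network-minus-decoupled difference restricted to the neurons
#' of one postsynaptic population, then summed.
#'
#' @inheritParams presynaptic_contribution
#' @param post_population postsynaptic population name
#' @param circuit circuit_model (for the population membership)
#' @export
pathway_contribution <- function(network, decoupled, post_population, circuit) {
  if (is.null(network$contributions) || is.null(decoupled$contributions)) {
    stop("per-neuron contributions required for pathway restriction")
  }
  d <- subtract_traces(network, decoupled)
  ids <- population_ids(circuit, post_population)
  cols <- which(d$neuron_ids %in% ids)
  vals <- if (length(cols)) rowSums(d$contributions[, cols, drop = FALSE])
          else numeric(length(d$time))
  signal_trace(d$time, vals, meta = utils::modifyList(
    d$meta, list(kind = "pathway", post = post_population)))
}

#' Postsynaptic contribution of a population
#'
#' @param network signal_trace with per-neuron contributions
#' @param population population name
#' @param circuit circuit_model
#' @export
postsynaptic_contribution <- function(network, population, circuit) {
  if (is.null(network$contributions)) {
    stop("per-neuron contributions required")
  }
  ids <- population_ids(circuit, population)
  cols <- which(network$neuron_ids %in% ids)
  vals <- if (length(cols))
    rowSums(network$contributions[, cols, drop = FALSE])
  else numeric(length(network$time))
  signal_trace(network$time, vals, meta = utils::modifyList(
    network$meta, list(kind = "postsynaptic", population = population)))
}

#' Thalamic contribution
#'
#' Network trace minus a decoupled run in which all cortical spikes are
#' replayed but the thalamic synapses stay silent.
#'
#' @param network network signal_trace
#' @param decoupled_without_thalamus decoupled trace with thalamus excluded
#' @export
thalamic_contribution <- function(network, decoupled_without_thalamus) {
  subtract_traces(network, decoupled_without_thalamus)
}

#' Assemble a contribution set
#'
#' @param total network signal_trace
#' @param presynaptic named list of presynaptic contribution traces
#'   (including `THAL` if computed)
#' @param pathways named list (names `"pre__post"`) of pathway traces
#' @param postsynaptic named list of postsynaptic contribution traces
#' @return object of class `contribution_set`
#' @export
contribution_set <- function(total, presynaptic = list(), pathways = list(),
                             postsynaptic = list()) {
  structure(list(total = total, presynaptic = presynaptic,
                 pathways = pathways, postsynaptic = postsynaptic),
            class = "contribution_set")
}

#' @export
print.contribution_set <- function(x, ...) {
  cat(sprintf("<contribution_set: %d presynaptic, %d pathway, %d postsynaptic traces>\n",
              length(x$presynaptic), length(x$pathways),
              length(x$postsynaptic)))
  invisible(x)
}

#' Linear-sum validation of a contribution set
#'
#' The sum of all presynaptic contributions (thalamic included) should
#' approximate the network signal; the residual carries the replay-timing
#' noise, which is concentrated at high frequencies when neurons spike.
#'
#' @param contributions contribution_set with all presynaptic traces present
#' @return list: `metric` = RMS(total - sum)/RMS(total), `residual` trace,
#'   `band_power_ratio` = power above vs below `split_hz`
#' @param split_hz band split frequency for the residual spectrum, Hz
#' @export
validate_linear_sum <- function(contributions, split_hz = 100) {
  stopifnot(inherits(contributions, "contribution_set"))
  if (length(contributions$presynaptic) == 0L) {
    stop("no presynaptic traces present")
  }
  tot <- contributions$total$values
  s <- Reduce(`+`, lapply(contributions$presynaptic, `[[`, "values"))
  resid <- tot - s
  metric <- sqrt(mean(resid^2)) / sqrt(mean(tot^2))
  dt <- stats::median(diff(contributions$total$time))
  list(metric = metric,
       residual = signal_trace(contributions$total$time, resid,
                               meta = list(kind = "residual")),
       band_power_ratio = band_power_ratio(resid, fs = 1000 / dt,
                                           split = split_hz))
}

#' Ratio of spectral power above vs below a split frequency
#'
#' @param x signal samples
#' @param fs sampling rate, Hz
#' @param split split frequency, Hz
#' @return dimensionless power ratio (high/low)
#' @export
band_power_ratio <- function(x, fs, split = 100) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  hi <- sum(p[half & f > split])
  lo <- sum(p[half & f <= split & f > 0])
  hi / lo
}
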