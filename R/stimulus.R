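# Stimulus-locked thalamic input.
#
# A whisker flick is modeled by activating a fixed fraction (10% by default)
# of the virtual thalamic fibers; each active fiber draws spike times from an
# inhomogeneous Poisson process whose rate follows a piecewise-constant PSTH
# (baseline firing plus a stimulus-locked bump), repeated for each stimulus
# at the inter-stimulus interval.

#' Construct a spike record
#'
#' @param id integer neuron ids
#' @param time spike times, ms
#' @param t_max simulation span covering all spikes (optional)
#' @return data.frame of class `spike_record`, sorted by time
#' @export
spike_record <- function(id = integer(0), time = numeric(0), t_max = NULL) {
  stopifnot(length(id) == length(time))
  o <- order(time, id)
  structure(data.frame(id = as.integer(id[o]), time = as.numeric(time[o])),
            class = c("spike_record", "data.frame"), t_max = t_max)
}

#' Stimulus specification
#'
#' The default PSTH is a 0.5 Hz baseline plus a Gaussian bump peaking at
#' 80 Hz, centered 5 ms post-stimulus with a 2 ms width, discretized on 1 ms
#' bins; it approximates the sharp stimulus-locked thalamic response used to
#' drive the column.
#'
#' @param psth_bins bin edges, ms relative to stimulus onset (length nb + 1)
#' @param psth_rates piecewise-constant rates, Hz (length nb, all >= 0)
#' @param n_fibers number of thalamic fibers
#' @param active_fraction fraction of fibers activated per stimulus
#' @param n_stimuli number of stimuli per trial
#' @param isi inter-stimulus interval, ms
#' @param onset time of the first stimulus, ms
#' @return list of class `stimulus_spec`
#' @export
stimulus_spec <- function(psth_bins = NULL, psth_rates = NULL,
                          n_fibers = 100L, active_fraction = 0.1,
                          n_stimuli = 2L, isi = 150, onset = 10) {
  if (is.null(psth_bins)) {
    psth_bins <- seq(0, 50, by = 1)
    tc <- (psth_bins[-1] + psth_bins[-length(psth_bins)]) / 2
    psth_rates <- 0.5 + 80 * exp(-(tc - 5)^2 / (2 * 2^2))
  }
  stopifnot(length(psth_rates) == length(psth_bins) - 1L,
            all(psth_rates >= 0), active_fraction >= 0, active_fraction <= 1,
            n_fibers >= 1L, n_stimuli >= 1L)
  structure(list(psth_bins = psth_bins, psth_rates = psth_rates,
                 n_fibers = as.integer(n_fibers),
                 active_fraction = active_fraction,
                 n_stimuli = as.integer(n_stimuli), isi = isi, onset = onset),
            class = "stimulus_spec")
}

#' Stimulus onset times of a spec
#' @param spec stimulus_spec
#' @export
stimulus_onsets <- function(spec) {
  spec$onset + (seq_len(spec$n_stimuli) - 1L) * spec$isi
}

#' Draw thalamic spike trains for one trial
#'
#' Exactly `round(active_fraction * n_fibers)` fibers are selected per
#' stimulus (selection re-drawn per stimulus); each selected fiber emits an
#' inhomogeneous Poisson train from the PSTH, offset to the stimulus onset.
#'
#' @param spec stimulus_spec
#' @param fiber_ids integer ids of the thalamic fibers (length `n_fibers`)
#' @param seed integer trial seed; output is a pure function of
#'   (spec, fiber_ids, seed)
#' @return spike_record
#' @export
generate_thalamic_spikes <- function(spec, fiber_ids = seq_len(spec$n_fibers),
                                     seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"), length(fiber_ids) == spec$n_fibers)
  if (length(spec$psth_rates) == 0L) stop("empty PSTH")
  n_active <- round(spec$active_fraction * spec$n_fibers)
  widths <- diff(spec$psth_bins)
  ids <- integer(0); times <- numeric(0)
  for (s in seq_len(spec$n_stimuli)) {
    t0 <- spec$onset + (s - 1L) * spec$isi
    active <- with_stream(stream_seed(seed, "fibersel", s),
                          sample(fiber_ids, n_active))
    for (f in active) {
      tt <- with_stream(stream_seed(seed, "fiberspk", s, f), {
        counts <- stats::rpois(length(widths), spec$psth_rates * widths / 1000)
        if (sum(counts) == 0) numeric(0) else {
          b <- rep(seq_along(counts), counts)
          sort(spec$psth_bins[b] + stats::runif(sum(counts)) * widths[b])
        }
      })
      if (length(tt)) {
        ids <- c(ids, rep(f, length(tt)))
        times <- c(times, t0 + tt)
      }
    }
  }
  spike_record(ids, times)
}
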