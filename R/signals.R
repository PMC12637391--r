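# Signal assembly and SEP post-processing.
#
# The EEG (or one LFP channel) is the dot product of the per-compartment
# transmembrane currents with the per-compartment weights; summing weighted
# currents within each neuron first yields per-neuron contributions whose
# sum equals the total exactly (linearity of the forward model).  SEP
# post-processing isolates the response to the second stimulus (to account
# for accommodation), band-passes it with a second-order Butterworth filter
# (1-500 Hz by default), and averages across trials.

#' Construct a signal trace
#'
#' @param time time grid, ms
#' @param values signal values (V for EEG, mV for LFP); vector or matrix
#'   (one column per electrode)
#' @param contributions optional per-neuron contribution matrix
#'   (time x neuron); columns must sum to `values`
#' @param neuron_ids neuron id per contribution column
#' @param meta provenance list (trial seeds, mode, filter state)
#' @return object of class `signal_trace`
#' @export
signal_trace <- function(time, values, contributions = NULL,
                         neuron_ids = NULL, meta = list()) {
  structure(list(time = as.numeric(time), values = values,
                 contributions = contributions, neuron_ids = neuron_ids,
                 meta = meta), class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace: %d samples [%.1f, %.1f] ms%s>\n",
              length(x$time), min(x$time), max(x$time),
              if (!is.null(x$contributions))
                sprintf(", %d neuron contributions", ncol(x$contributions))
              else ""))
  invisible(x)
}

#' Compute a signal from currents and weights
#'
#' @param currents currents_report from a simulation
#' @param weights weights_table in the same compartment order
#' @param keep_contributions retain the per-neuron contribution matrix
#' @return signal_trace (units V for EEG weights)
#' @export
compute_signal <- function(currents, weights, keep_contributions = TRUE) {
  w <- weights$weights
  if (length(w) != ncol(currents$currents)) {
    stop("weights / currents compartment count mismatch")
  }
  weighted <- currents$currents * rep(w, each = nrow(currents$currents))
  total <- rowSums(weighted)
  contrib <- NULL; ids <- NULL
  if (keep_contributions) {
    grp <- factor(currents$comp_neuron, levels = unique(currents$comp_neuron))
    contrib <- t(rowsum(t(weighted), grp))
    ids <- as.integer(levels(grp))
    colnames(contrib) <- ids
  }
  signal_trace(currents$time, total, contrib, ids,
               meta = list(kind = "eeg", filtered = FALSE))
}

#' Multi-channel LFP from currents and a laminar weights matrix
#'
#' @param currents currents_report
#' @param weight_matrix n_comp x n_electrode matrix (V/nA)
#' @return signal_trace with a time x electrode value matrix in mV
#' @export
compute_lfp <- function(currents, weight_matrix) {
  stopifnot(nrow(weight_matrix) == ncol(currents$currents))
  vals <- currents$currents %*% weight_matrix * 1e3   # V -> mV
  signal_trace(currents$time, vals,
               meta = list(kind = "lfp", filtered = FALSE))
}

# Zero-phase second-order Butterworth band-pass with reflection padding.
# Forward-backward application avoids latency distortion of the P1 timing;
# reflection padding suppresses edge transients.
bandpass_zero_phase <- function(x, fs, low, high, order = 2) {
  if (low >= high) stop("invalid filter band: low >= high")
  if (high >= fs / 2) stop("invalid filter band: high cutoff at or above Nyquist")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- length(x)
  np <- min(n - 1L, max(100L, as.integer(round(fs / low))))
  pre <- 2 * x[1] - x[seq(np + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - np)]
  xp <- c(pre, x, post)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[seq(np + 1L, np + n)]
}

#' Post-process a raw trace into an SEP
#'
#' Re-zeroes time to the onset of the requested stimulus (the second by
#' default), crops to `window`, and applies the zero-phase band-pass filter
#' to the total and, identically, to every per-neuron contribution so that
#' the summation invariant survives filtering.
#'
#' @param raw signal_trace on the raw report grid
#' @param stimulus_times stimulus onset times, ms
#' @param which_stimulus index of the stimulus to extract
#' @param window time window around the stimulus onset, ms (relative)
#' @param filter `c(order, low_hz, high_hz)` or NULL to skip filtering
#' @param baseline_correct subtract the pre-stimulus mean (the band-pass
#'   low cutoff of 1 Hz cannot remove a standing offset within a
#'   ~100 ms window, so the conventional baseline subtraction is applied
#'   explicitly)
#' @return signal_trace on the stimulus-relative grid
#' @export
postprocess_sep <- function(raw, stimulus_times, which_stimulus = 2L,
                            window = c(-10, 100),
                            filter = c(2, 1, 500), baseline_correct = TRUE) {
  if (which_stimulus > length(stimulus_times)) {
    stop("second-response extraction requested but fewer stimuli available")
  }
  t0 <- stimulus_times[which_stimulus]
  dt <- stats::median(diff(raw$time))
  fs <- 1000 / dt
  vals <- raw$values
  contrib <- raw$contributions
  if (!is.null(filter)) {
    vals <- if (is.matrix(vals)) {
      apply(vals, 2, bandpass_zero_phase, fs = fs, low = filter[2],
            high = filter[3], order = filter[1])
    } else {
      bandpass_zero_phase(vals, fs, filter[2], filter[3], filter[1])
    }
    if (!is.null(contrib)) {
      contrib <- apply(contrib, 2, bandpass_zero_phase, fs = fs,
                       low = filter[2], high = filter[3], order = filter[1])
    }
  }
  rel <- raw$time - t0
  keep <- rel >= window[1] & rel <= window[2]
  vals <- if (is.matrix(vals)) vals[keep, , drop = FALSE] else vals[keep]
  if (!is.null(contrib)) contrib <- contrib[keep, , drop = FALSE]
  if (baseline_correct) {
    pre <- rel[keep] < 0
    if (any(pre)) {
      if (is.matrix(vals)) {
        mu <- colMeans(vals[pre, , drop = FALSE])
        vals <- sweep(vals, 2, mu)
      } else {
        vals <- vals - mean(vals[pre])
      }
      if (!is.null(contrib)) {
        contrib <- sweep(contrib, 2, colMeans(contrib[pre, , drop = FALSE]))
      }
    }
  }
  signal_trace(rel[keep],
               vals,
               contrib,
               raw$neuron_ids,
               meta = utils::modifyList(raw$meta,
                 list(filtered = !is.null(filter), filter = filter,
                      stimulus = which_stimulus)))
}

#' Average traces across trials, sample-wise
#'
#' @param traces list of signal_trace on identical grids
#' @return signal_trace
#' @export
average_trials <- function(traces) {
  stopifnot(length(traces) >= 1L)
  tg <- traces[[1]]$time
  for (tr in traces) {
    if (!isTRUE(all.equal(tr$time, tg))) stop("trial time grids differ")
  }
  vals <- Reduce(`+`, lapply(traces, `[[`, "values")) / length(traces)
  contrib <- NULL
  if (!is.null(traces[[1]]$contributions)) {
    contrib <- Reduce(`+`, lapply(traces, `[[`, "contributions")) /
      length(traces)
  }
  signal_trace(tg, vals, contrib, traces[[1]]$neuron_ids,
               meta = utils::modifyList(traces[[1]]$meta,
                                        list(n_trials = length(traces))))
}

#' Normalize a trace to the P1 peak of a reference trace
#'
#' @param trace signal_trace to scale
#' @param reference signal_trace providing the P1 peak (often the trace
#'   itself, or the original-circuit SEP when comparing variants)
#' @param p1_window P1 search window, ms post-stimulus
#' @return scaled signal_trace (dimensionless, P1 of the reference = 1)
#' @export
normalize_to_p1 <- function(trace, reference = trace, p1_window = c(8, 16)) {
  sel <- reference$time >= p1_window[1] & reference$time <= p1_window[2]
  if (!any(sel)) stop("reference trace does not span the P1 window")
  peak <- max(reference$values[sel])
  if (peak <= 0) stop("reference P1 peak must be positive")
  signal_trace(trace$time, trace$values / peak,
               if (!is.null(trace$contributions)) trace$contributions / peak,
               trace$neuron_ids,
               meta = utils::modifyList(trace$meta, list(normalized = TRUE)))
}

#' Check the contribution summation invariant of a trace
#'
#' @param trace signal_trace with contributions
#' @param tol relative tolerance
#' @return max relative deviation, invisibly errors above `tol`
#' @export
check_contribution_sum <- function(trace, tol = 1e-12) {
  if (is.null(trace$contributions)) stop("trace has no contribution matrix")
  s <- rowSums(trace$contributions)
  scale <- max(abs(trace$values), .Machine$double.eps)
  dev <- max(abs(s - trace$values)) / scale
  if (dev > tol) stop("contribution sum deviates from total: ", dev)
  dev
}
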