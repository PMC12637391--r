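# SEP waveform features and FWHM pathway attribution.
#
# P1 is the maximum in the 8-16 ms post-stimulus window, N1 the minimum in
# the 16-40 ms window.  The N1 full width at half maximum is measured from
# the pre-stimulus baseline down to the trough: the half level is
# baseline - depth/2, and the two crossings nearest the trough are linearly
# interpolated between samples.  Removing a pathway trace from the total and
# re-measuring the FWHM quantifies that pathway's contribution to the N1
# width; differencing the attribution between two circuit variants gives the
# pathway's share of the width change.

#' Detect response onset as baseline + 3 SD crossing
#'
#' @param time time grid, ms
#' @param values trace or PSTH values
#' @param baseline_window `c(from, to)` ms defining the baseline samples
#'   (must precede the response)
#' @param n_sd threshold in baseline standard deviations
#' @return onset time, ms, or `NA` when no sample exceeds the threshold
#' @export
detect_onset <- function(time, values, baseline_window, n_sd = 3) {
  sel <- time >= baseline_window[1] & time <= baseline_window[2]
  if (!any(sel)) stop("baseline window outside the trace")
  mu <- mean(values[sel]); sdv <- stats::sd(values[sel])
  after <- which(time > baseline_window[2])
  hit <- after[values[after] > mu + n_sd * sdv]
  if (length(hit) == 0L) return(NA_real_)
  time[hit[1]]
}

#' Extract SEP waveform features
#'
#' @param trace signal_trace (stimulus-relative time)
#' @param p1_window P1 search window, ms
#' @param n1_window N1 search window, ms
#' @param baseline_window pre-stimulus baseline window, ms
#' @return list of class `sep_features`: baseline mean/sd, onset, P1
#'   amplitude/time, N1 amplitude/time (NA when no negative deflection),
#'   peak-to-peak, N1 FWHM
#' @export
sep_features <- function(trace, p1_window = c(8, 16), n1_window = c(16, 40),
                         baseline_window = c(-10, 0)) {
  tt <- trace$time; v <- trace$values
  for (w in list(p1_window, n1_window)) {
    if (w[1] < min(tt) || w[2] > max(tt)) stop("feature window outside trace span")
  }
  bsel <- tt >= baseline_window[1] & tt <= baseline_window[2]
  base_mu <- if (any(bsel)) mean(v[bsel]) else 0
  base_sd <- if (any(bsel)) stats::sd(v[bsel]) else 0

  p1sel <- which(tt >= p1_window[1] & tt <= p1_window[2])
  p1_i <- p1sel[which.max(v[p1sel])]
  n1sel <- which(tt >= n1_window[1] & tt <= n1_window[2])
  n1_i <- n1sel[which.min(v[n1sel])]

  p1_amp <- v[p1_i]; p1_t <- tt[p1_i]
  # N1 counts as defined only when the trough is a real negative deflection:
  # below baseline by more than the baseline noise and by a nonnegligible
  # fraction of the P1 excursion
  depth_min <- max(3 * base_sd, 0.01 * abs(p1_amp - base_mu))
  n1_defined <- v[n1_i] < base_mu - depth_min
  n1_amp <- if (n1_defined) v[n1_i] else NA_real_
  n1_t <- if (n1_defined) tt[n1_i] else NA_real_

  fwhm <- NA_real_
  if (n1_defined) {
    fwhm <- fwhm_at(tt, v, trough_i = n1_i, baseline = base_mu)
  }
  onset <- if (any(bsel)) detect_onset(tt, v, baseline_window) else NA_real_

  structure(list(baseline_mean = base_mu, baseline_sd = base_sd,
                 onset = onset, p1_amplitude = p1_amp, p1_time = p1_t,
                 n1_amplitude = n1_amp, n1_time = n1_t,
                 peak_to_peak = if (n1_defined) p1_amp - n1_amp else NA_real_,
                 n1_fwhm = fwhm),
            class = "sep_features")
}

#' @export
print.sep_features <- function(x, ...) {
  cat(sprintf(
    "<sep_features: P1 %.3g @ %.1f ms; N1 %s @ %s ms; FWHM %s ms>\n",
    x$p1_amplitude, x$p1_time,
    if (is.na(x$n1_amplitude)) "undef" else sprintf("%.3g", x$n1_amplitude),
    if (is.na(x$n1_time)) "-" else sprintf("%.1f", x$n1_time),
    if (is.na(x$n1_fwhm)) "-" else sprintf("%.2f", x$n1_fwhm)))
  invisible(x)
}

# FWHM of the trough at index trough_i, measured at half the trough depth
# below `baseline`; crossings nearest the trough, linearly interpolated.
fwhm_at <- function(tt, v, trough_i, baseline) {
  depth <- baseline - v[trough_i]
  if (depth <= 0) return(NA_real_)
  half <- baseline - depth / 2
  below <- v < half
  # left crossing: last sample at/above half before the trough
  li <- trough_i
  while (li > 1L && below[li - 1L]) li <- li - 1L
  ri <- trough_i
  n <- length(v)
  while (ri < n && below[ri + 1L]) ri <- ri + 1L
  if (li == 1L || ri == n) return(NA_real_)  # trough not bracketed
  # interpolate between (li-1, li) and (ri, ri+1)
  tl <- tt[li - 1L] + (half - v[li - 1L]) / (v[li] - v[li - 1L]) *
    (tt[li] - tt[li - 1L])
  tr <- tt[ri] + (half - v[ri]) / (v[ri + 1L] - v[ri]) *
    (tt[ri + 1L] - tt[ri])
  tr - tl
}

#' FWHM pathway attribution
#'
#' For every pathway trace in a contribution set, forms the removed signal
#' (total minus pathway), measures the N1 FWHM of the removed signal, and
#' reports the pathway's contribution FWHM_c - FWHM_{c, x->y}.  With a
#' second contribution set (the other circuit variant), also reports the
#' cross-circuit attribution Delta_{x->y} = DeltaFWHM - DeltaFWHM_{x->y}.
#'
#' @param contribs_a contribution_set of circuit A (e.g. original)
#' @param contribs_b optional contribution_set of circuit B (e.g. rewired)
#' @param p1_window,n1_window,baseline_window feature windows, ms
#' @return data.frame of class `fwhm_attribution`: pathway, FWHM of the
#'   removed signals, contributions, and (two-circuit case) `delta`;
#'   pathways whose removed signal has no defined N1 are flagged
#'   `n1_defined = FALSE` and carry NA statistics
#' @export
fwhm_attribution <- function(contribs_a, contribs_b = NULL,
                             p1_window = c(8, 16), n1_window = c(16, 40),
                             baseline_window = c(-10, 0)) {
  feat <- function(trace) sep_features(trace, p1_window, n1_window,
                                       baseline_window)
  one_circuit <- function(cs) {
    f_tot <- feat(cs$total)
    rows <- lapply(names(cs$pathways), function(nm) {
      removed <- signal_trace(cs$total$time,
                              cs$total$values - cs$pathways[[nm]]$values)
      f <- feat(removed)
      data.frame(pathway = nm, fwhm_total = f_tot$n1_fwhm,
                 fwhm_removed = f$n1_fwhm,
                 contribution = f_tot$n1_fwhm - f$n1_fwhm,
                 n1_defined = !is.na(f$n1_fwhm))
    })
    do.call(rbind, rows)
  }
  a <- one_circuit(contribs_a)
  if (is.null(contribs_b)) {
    class(a) <- c("fwhm_attribution", "data.frame")
    return(a)
  }
  b <- one_circuit(contribs_b)
  m <- merge(a, b, by = "pathway", suffixes = c("_a", "_b"))
  d_fwhm <- m$fwhm_total_a - m$fwhm_total_b
  d_fwhm_xy <- m$fwhm_removed_a - m$fwhm_removed_b
  m$delta_fwhm <- d_fwhm
  m$delta <- d_fwhm - d_fwhm_xy
  m$n1_defined <- m$n1_defined_a & m$n1_defined_b
  class(m) <- c("fwhm_attribution", "data.frame")
  m
}

#' Percent narrowing between two widths
#'
#' @param fwhm_a reference width, ms (must be positive)
#' @param fwhm_b comparison width, ms
#' @return percent narrowing, 100 (a - b) / a
#' @export
percent_narrowing <- function(fwhm_a, fwhm_b) {
  if (fwhm_a <= 0) stop("reference FWHM must be positive")
  100 * (fwhm_a - fwhm_b) / fwhm_a
}

#' Compress spikes of a window to a single time
#'
#' Spikes of the given neurons falling inside `window` (relative to
#' `onset`) are moved to `target`; all other spikes are unchanged.  Used to
#' test whether sharper population spike timing alone reshapes the SEP.
#'
#' @param spikes spike_record
#' @param ids neuron ids to compress (default: all)
#' @param window `c(from, to)` ms post-stimulus
#' @param target new spike time, ms post-stimulus
#' @param onset stimulus onset, ms (absolute time of post-stimulus zero)
#' @return spike_record with the same number of spikes
#' @export
compress_spikes <- function(spikes, ids = unique(spikes$id),
                            window = c(10, 40), target = 15, onset = 0) {
  stopifnot(window[1] < window[2])
  tt <- spikes$time
  rel <- tt - onset
  move <- spikes$id %in% ids & rel >= window[1] & rel <= window[2]
  tt[move] <- onset + target
  spike_record(spikes$id, tt, t_max = attr(spikes, "t_max"))
}
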