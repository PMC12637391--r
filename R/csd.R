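# Current source density and dipole-moment analysis of laminar LFP.
#
# Two estimators: the standard second-spatial-difference CSD with the Vaknin
# boundary correction (duplicated edge potentials so edge channels are
# estimable), and the step-iCSD method, which assumes the CSD is
# piecewise-constant within cylindrical disks of radius rho centered on each
# electrode and inverts the analytic disk forward matrix.  The depth
# integral of z * CSD gives the dipole-moment density per unit cortical
# surface area, from which the reciprocity theorem yields an EEG amplitude
# estimate pi r^2 p E for a patch of radius r and dipole-aligned lead
# field E.
#
# Unit conventions: depths um, LFP mV, conductivity S/m, CSD nA/mm^3
# (numerically equal to A/m^3), dipole density nA.m/mm^2.

#' Construct a CSD profile
#'
#' @param depths electrode depths, micrometres (strictly increasing)
#' @param time time grid, ms
#' @param values depth x time CSD matrix, nA/mm^3
#' @param method `"standard_vaknin"` or `"step_icsd"`
#' @param params method parameters (sigma, h, rho, condition number)
#' @export
csd_profile <- function(depths, time, values, method, params = list()) {
  stopifnot(all(diff(depths) > 0), all(diff(time) > 0),
            method %in% c("standard_vaknin", "step_icsd"))
  structure(list(depths = as.numeric(depths), time = as.numeric(time),
                 values = values, method = method, params = params),
            class = "csd_profile")
}

lfp_matrix <- function(lfp) {
  # depth x time matrix from a laminar signal_trace (time x electrode)
  if (inherits(lfp, "signal_trace")) {
    list(phi = t(lfp$values), time = lfp$time)
  } else {
    list(phi = lfp$phi, time = lfp$time)
  }
}

#' Standard CSD with Vaknin correction
#'
#' CSD_j = -sigma (phi_{j+1} - 2 phi_j + phi_{j-1}) / h^2; the boundary
#' potentials are duplicated so the estimate covers all electrodes.
#'
#' @param lfp laminar signal_trace (values time x electrode, mV) or a list
#'   with elements `phi` (depth x time) and `time`
#' @param depths electrode depths, micrometres, uniformly spaced
#' @param sigma conductivity, S/m
#' @return csd_profile in nA/mm^3
#' @export
standard_csd_vaknin <- function(lfp, depths, sigma = 0.3) {
  m <- lfp_matrix(lfp)
  phi <- m$phi
  n <- nrow(phi)
  if (n < 3L) stop("at least 3 electrodes required")
  h <- unique_spacing(depths)
  phi_pad <- rbind(phi[1, , drop = FALSE], phi, phi[n, , drop = FALSE])
  d2 <- phi_pad[seq_len(n) + 2L, , drop = FALSE] -
    2 * phi_pad[seq_len(n) + 1L, , drop = FALSE] +
    phi_pad[seq_len(n), , drop = FALSE]
  # SI: sigma [S/m] * phi [V] / h^2 [m^2] = A/m^3 = nA/mm^3
  csd <- -sigma * (d2 * 1e-3) / (h * 1e-6)^2
  csd_profile(depths, m$time, csd, "standard_vaknin",
              params = list(sigma = sigma, h = h))
}

unique_spacing <- function(depths) {
  dd <- diff(depths)
  if (any(abs(dd - dd[1]) > 1e-9 * abs(dd[1]))) {
    stop("electrode spacing must be uniform")
  }
  dd[1]
}

# Analytic forward integral of a unit-CSD disk of radius rho_m and thickness
# [z_lo, z_hi] (metres) at electrode depth z_j (metres):
# (1/(2 sigma)) * Int_{z_lo}^{z_hi} [ sqrt((z_j - z)^2 + rho^2) - |z_j - z| ] dz
disk_forward <- function(z_j, z_lo, z_hi, rho_m, sigma) {
  anti <- function(u) {
    0.5 * (u * sqrt(u^2 + rho_m^2) + rho_m^2 * asinh(u / rho_m)) -
      0.5 * u * abs(u)
  }
  # substitute u = z_j - z (integrand even in u)
  (anti(z_j - z_lo) - anti(z_j - z_hi)) / (2 * sigma)
}

#' Step-iCSD forward matrix
#'
#' @param depths electrode depths, micrometres, uniform spacing h
#' @param rho disk radius, micrometres
#' @param sigma conductivity, S/m
#' @return n x n matrix mapping disk CSD (A/m^3) to potentials (V)
#' @export
step_icsd_forward_matrix <- function(depths, rho = 500, sigma = 0.3) {
  h <- unique_spacing(depths) * 1e-6
  z <- depths * 1e-6
  rho_m <- rho * 1e-6
  n <- length(z)
  F <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      F[j, k] <- disk_forward(z[j], z[k] - h / 2, z[k] + h / 2, rho_m, sigma)
    }
  }
  F
}

#' Step inverse CSD
#'
#' Assumes piecewise-constant CSD within cylindrical disks of radius `rho`
#' and thickness equal to the electrode spacing, and solves the analytic
#' disk forward model for the CSD at every time step.
#'
#' @inheritParams standard_csd_vaknin
#' @param rho disk radius, micrometres
#' @return csd_profile in nA/mm^3 (condition number of the forward matrix
#'   reported in `params`)
#' @export
step_icsd <- function(lfp, depths, rho = 500, sigma = 0.3) {
  m <- lfp_matrix(lfp)
  phi <- m$phi
  if (nrow(phi) < 3L) stop("at least 3 electrodes required")
  stopifnot(rho > 0)
  F <- step_icsd_forward_matrix(depths, rho, sigma)
  cond <- kappa(F, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    stop("ill-conditioned iCSD forward matrix (condition number ", cond, ")")
  }
  csd <- solve(F, phi * 1e-3)   # A/m^3 = nA/mm^3
  csd_profile(depths, m$time, csd, "step_icsd",
              params = list(sigma = sigma, h = unique_spacing(depths),
                            rho = rho, condition_number = cond))
}

#' Dipole-moment density from a CSD profile
#'
#' Trapezoidal integral of z * CSD(z, t) over the electrode span, evaluated
#' at time `t` (nearest sample) or, when omitted, at the time of the peak
#' total current density (max over t of the integral of |CSD| dz).
#'
#' @param csd csd_profile
#' @param t evaluation time, ms (optional)
#' @return dipole-moment density, nA.m/mm^2 (attribute `t` gives the time
#'   used)
#' @export
dipole_moment_density <- function(csd, t = NULL) {
  if (length(csd$time) == 0L || length(csd$depths) == 0L) {
    stop("empty CSD profile")
  }
  z_m <- csd$depths * 1e-6
  if (is.null(t)) {
    tot <- apply(abs(csd$values), 2, function(col) trapz_int(z_m, col))
    ti <- which.max(tot)
  } else {
    ti <- which.min(abs(csd$time - t))
  }
  # A/m^3 * m * m = A/m; 1 A/m = 1e3 nA.m/mm^2
  p <- trapz_int(z_m, z_m * csd$values[, ti]) * 1e3
  structure(p, t = csd$time[ti])
}

trapz_int <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Dipole-moment density as a function of time
#'
#' The depth integral of z * CSD at every time sample.  The peak of this
#' series is the quantity that predicts the peak EEG; in small columns the
#' time of peak rectified current can be quadrupole-dominated, so the peak
#' dipole need not coincide with it.
#'
#' @param csd csd_profile
#' @return numeric vector (nA.m/mm^2) on the profile's time grid
#' @export
dipole_moment_series <- function(csd) {
  z_m <- csd$depths * 1e-6
  apply(csd$values, 2, function(col) trapz_int(z_m, z_m * col)) * 1e3
}

#' Total (monopole) CSD integral relative to the rectified integral
#'
#' For LFP generated by charge-conserving neuron currents the net CSD over
#' the full depth span should be near zero; this returns the ratio
#' |Int CSD dz| / Int |CSD| dz at a given time.
#'
#' @param csd csd_profile
#' @param t time, ms (defaults to the peak-current time)
#' @export
monopole_ratio <- function(csd, t = NULL) {
  z_m <- csd$depths * 1e-6
  if (is.null(t)) {
    tot <- apply(abs(csd$values), 2, function(col) trapz_int(z_m, col))
    ti <- which.max(tot)
  } else {
    ti <- which.min(abs(csd$time - t))
  }
  abs(trapz_int(z_m, csd$values[, ti])) / trapz_int(z_m, abs(csd$values[, ti]))
}

#' EEG amplitude estimate from a dipole-moment density
#'
#' Reciprocity estimate for a cortical patch of radius `r`: the per-patch
#' EEG is pi r^2 * p * lead; the circuit estimate multiplies by the number
#' of columns.
#'
#' @param p dipole-moment density, nA.m/mm^2
#' @param r patch radius, mm
#' @param lead dipole-aligned lead field, V/mm/A
#' @param n_columns number of columns contributing
#' @return EEG amplitude, V
#' @export
eeg_from_dipole <- function(p, r, lead, n_columns = 1) {
  stopifnot(r > 0, lead > 0, n_columns >= 1)
  # mm^2 * nA.m/mm^2 * V/(mm.A) = 1e-9 V.m/mm = 1e-6 V
  pi * r^2 * p * lead * 1e-6 * n_columns
}

#' Dipole-aligned lead field of an electrode configuration
#'
#' The component of the reciprocal electric field parallel to the column
#' axis, i.e. the depth gradient of the per-compartment reciprocity weight
#' along the column, averaged over the depth span.  This is the lead-field
#' value consistent with the package's own analytic electrode model; a
#' head-model-derived value can be supplied to [eeg_from_dipole()] instead.
#'
#' @param spec electrode_spec
#' @param depths depth samples along the column axis, micrometres
#' @param x,y lateral position of the column axis, micrometres
#' @return mean |dw/dz|, V/mm/A
#' @export
dipole_lead_field <- function(spec, depths, x = 0, y = 0) {
  w <- point_electrode_weights(cbind(x, y, depths), spec)$weights  # V/nA
  dwdz <- diff(w) / diff(depths)   # V/nA/um
  mean(abs(dwdz)) * 1e12           # -> V/(mm.A)
}

#' Scale a per-column EEG contribution to the whole circuit
#'
#' @param per_column per-column EEG amplitude, V
#' @param n_columns number of columns
#' @return circuit EEG amplitude, V
#' @export
circuit_eeg_estimate <- function(per_column, n_columns = 7) {
  per_column * n_columns
}
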