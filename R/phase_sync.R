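#' Analytic signal (instantaneous amplitude and phase) of a real series
#'
#' Extends the mean-removed series \eqn{x(t)} into the complex plane as
#' \eqn{R(t) = x(t) + i x_H(t)}, where \eqn{x_H} is the Hilbert transform,
#' computed spectrally: the FFT of the series is multiplied by 2 on
#' positive frequencies, left unchanged at DC (and Nyquist for even
#' lengths) and zeroed on negative frequencies, then inverse-transformed.
#' Writing \eqn{R(t) = A(t) e^{i\phi(t)}} gives the instantaneous amplitude
#' \eqn{A \ge 0} and the phase \eqn{\phi}, returned continuous (unwrapped).
#'
#' @param x real numeric series, length >= 16, finite, non-constant.
#' @param detrend if \code{TRUE}, remove a least-squares linear trend
#'   instead of just the mean (default \code{FALSE}).
#' @return List with components \code{amplitude} and \code{phase} (radians,
#'   unwrapped), both the length of \code{x}.
#' @examples
#' t <- 0:4999
#' a <- analytic_signal(cos(2 * pi * t / 500))
#' range(a$amplitude[200:4800])  # ~1 away from the edges
#' @export
analytic_signal <- function(x, detrend = FALSE) {
  n <- length(x)
  if (n < 16) stop("series too short for phase analysis (need >= 16)",
                   call. = FALSE)
  if (any(!is.finite(x))) stop("series must be finite", call. = FALSE)
  x <- x - mean(x)
  if (detrend) {
    tt <- seq_len(n) - (n + 1) / 2
    x <- x - sum(x * tt) / sum(tt * tt) * tt
  }
  if (var(x) == 0)
    stop("constant input: instantaneous phase is undefined", call. = FALSE)
  # zero-pad to the next 2^a 3^b 5^c length: R's mixed-radix FFT is
  # quadratic in any large prime factor of the length
  m <- stats::nextn(n, c(2L, 3L, 5L))
  xp <- if (m > n) c(x, numeric(m - n)) else x
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1
    h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  a <- (fft(fft(xp) * h, inverse = TRUE) / m)[seq_len(n)]
  list(amplitude = Mod(a), phase = as.numeric(signal::unwrap(Arg(a))))
}

#' Phase difference between a response and the periodic forcing
#'
#' \deqn{\delta\Phi(t) = \phi(t) - \Omega t,} the unwrapped instantaneous
#' phase of the response minus the linearly advancing forcing phase.
#'
#' @param phi unwrapped phase series (radians).
#' @param omega forcing angular frequency (> 0).
#' @param t time array aligned with \code{phi}.
#' @return Unwrapped phase-difference series.
#' @export
phase_difference <- function(phi, omega, t) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("'omega' must be a positive scalar", call. = FALSE)
  if (length(phi) != length(t))
    stop("'phi' and 't' lengths differ", call. = FALSE)
  phi - omega * t
}

#' Histogram of phase differences wrapped modulo 2*pi
#'
#' Reduces the series modulo \eqn{2\pi} into \eqn{[0, 2\pi)} and bins it
#' into \code{n_bins} equal-width bins.
#'
#' @param delta_phi phase-difference series (any real values).
#' @param n_bins number of bins (>= 2); default 36, i.e. 10-degree bins.
#' @return List of class \code{eco_phase_hist} with \code{edges}
#'   (length \code{n_bins + 1}), \code{prob} (bin probabilities, sum 1),
#'   \code{counts} and \code{n_bins}.
#' @export
wrapped_histogram <- function(delta_phi, n_bins = 36L) {
  if (length(delta_phi) == 0) stop("empty phase-difference series",
                                   call. = FALSE)
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  wrapped <- delta_phi %% (2 * pi)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  idx <- pmin(floor(wrapped / (2 * pi) * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(edges = edges, prob = counts / length(wrapped),
                 counts = counts, n_bins = as.integer(n_bins)),
            class = "eco_phase_hist")
}

#' Relative standard deviation of a phase histogram, in percent
#'
#' \eqn{100 \cdot \mathrm{sd}(p) / \mathrm{mean}(p)} over the bin
#' probabilities \eqn{p}, using the population standard deviation. A
#' perfectly uniform histogram scores 0; a point mass scores the maximum
#' \eqn{100\sqrt{n_{bins} - 1}}. The value depends on the bin count, which
#' is therefore carried alongside it in reports.
#'
#' @param histogram an object from [wrapped_histogram()].
#' @return Percentage (scalar >= 0).
#' @export
rel_std_pct <- function(histogram) {
  stopifnot(inherits(histogram, "eco_phase_hist"))
  p <- histogram$prob
  100 * sqrt(mean((p - mean(p))^2)) / mean(p)
}

#' Kolmogorov-Smirnov test of phase uniformity
#'
#' One-sample KS test of the wrapped phase differences against the uniform
#' distribution on \eqn{[0, 2\pi)}. A small p-value rejects uniformity,
#' i.e. indicates 1:1 phase synchronization.
#'
#' @param delta_phi_wrapped series of wrapped phases in \eqn{[0, 2\pi)}
#'   (>= 8 values).
#' @return List with \code{statistic} and \code{p_value}.
#' @export
ks_uniformity <- function(delta_phi_wrapped) {
  if (length(delta_phi_wrapped) < 8)
    stop("need at least 8 samples for the uniformity test", call. = FALSE)
  kt <- suppressWarnings(
    ks.test(delta_phi_wrapped, "punif", min = 0, max = 2 * pi))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Phase-synchronization report for a forced trajectory
#'
#' Runs the full analysis chain for population density and culture against
#' the periodic climate forcing: analytic-signal phase extraction,
#' phase difference \eqn{\delta\Phi = \phi - \Omega t}, edge trimming,
#' wrapping modulo \eqn{2\pi}, equal-width histogram, relative-standard-
#' deviation metric and KS uniformity test. Non-uniformity of the wrapped
#' phase-difference distribution is the signature of 1:1 phase
#' synchronization between the model and the forcing.
#'
#' A fraction of samples at each end of the series is discarded before the
#' statistics (Hilbert-transform edge artifacts). By default the KS test
#' uses all retained (autocorrelated) samples; \code{decimate = TRUE}
#' thins them to one sample per eighth of a forcing period for more
#' conservative inference.
#'
#' @param traj an [simulate_ecoculture()] trajectory (>= 20 forcing periods
#'   recommended).
#' @param forcing periodic [climate_forcing()]; defaults to the trajectory's
#'   own forcing attribute.
#' @param n_bins histogram bin count (default 36).
#' @param edge_fraction fraction of samples dropped at each end
#'   (default 0.05).
#' @param decimate if \code{TRUE}, decimate phases before the KS test.
#' @param detrend passed to [analytic_signal()].
#' @param variables which trajectory variables to analyze.
#' @return Named list (one element per variable) of class
#'   \code{eco_sync_report}; each element holds \code{variable_name},
#'   \code{delta_phi_unwrapped}, \code{delta_phi_wrapped},
#'   \code{histogram}, \code{rel_std_pct}, \code{ks_statistic},
#'   \code{ks_pvalue}, \code{n_bins}, \code{edge_fraction_discarded} and
#'   \code{decimation_stride}.
#' @examples
#' p <- eco_params(n_steps = 50000, kappa = 0.5, omega = 2 * pi / 2000)
#' rep <- synchronization_report(simulate_ecoculture(p))
#' rep$rho$rel_std_pct
#' @export
synchronization_report <- function(traj, forcing = NULL, n_bins = 36L,
                                   edge_fraction = 0.05, decimate = FALSE,
                                   detrend = FALSE,
                                   variables = c("rho", "c")) {
  stopifnot(inherits(traj, "eco_trajectory"))
  if (is.null(forcing)) forcing <- attr(traj, "forcing")
  stopifnot(inherits(forcing, "eco_forcing"))
  if (forcing$kind != "periodic")
    stop("phase synchronization is defined against a periodic forcing",
         call. = FALSE)
  if (edge_fraction < 0 || edge_fraction >= 0.5)
    stop("'edge_fraction' must be in [0, 0.5)", call. = FALSE)
  n <- nrow(traj)
  dt <- traj$t[2] - traj$t[1]
  period_steps <- 2 * pi / forcing$omega / dt
  stride <- if (decimate) max(1L, as.integer(round(period_steps / 8))) else 1L
  drop <- floor(edge_fraction * n)
  keep <- seq.int(drop + 1L, n - drop)
  out <- lapply(variables, function(v) {
    x <- traj[[v]]
    sig <- analytic_signal(x, detrend = detrend)
    dphi <- phase_difference(sig$phase, forcing$omega, traj$t)[keep]
    wrapped <- dphi %% (2 * pi)
    h <- wrapped_histogram(dphi, n_bins = n_bins)
    ks_in <- if (stride > 1L) wrapped[seq(1L, length(wrapped), by = stride)]
             else wrapped
    kt <- ks_uniformity(ks_in)
    structure(list(variable_name = v,
                   delta_phi_unwrapped = dphi,
                   delta_phi_wrapped = wrapped,
                   histogram = h,
                   rel_std_pct = rel_std_pct(h),
                   ks_statistic = kt$statistic,
                   ks_pvalue = kt$p_value,
                   n_bins = as.integer(n_bins),
                   edge_fraction_discarded = edge_fraction,
                   decimation_stride = stride),
              class = "eco_phase_sync")
  })
  names(out) <- variables
  class(out) <- "eco_sync_report"
  out
}

#' @export
print.eco_phase_sync <- function(x, ...) {
  cat(sprintf(
    "Phase sync [%s]: rel std %.1f%% (%d bins), KS D = %.4g, p = %.3g\n",
    x$variable_name, x$rel_std_pct, x$n_bins, x$ks_statistic, x$ks_pvalue))
  invisible(x)
}

#' @export
print.eco_sync_report <- function(x, ...) {
  cat("Phase-synchronization report (response vs climate forcing)\n")
  for (v in x) print(v)
  invisible(x)
}
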