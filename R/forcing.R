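#' Climate forcing of the baseline carrying capacity
#'
#' The unperturbed carrying capacity can be held constant,
#' \eqn{K_0(t) = K_0^*}, or modulated sinusoidally,
#' \eqn{K_0(t) = K_0^* [1 + \kappa \cos(\Omega t)]}, mimicking slow
#' climate cycles (e.g. Milankovic-type wet-dry alternations) in the
#' resource base. With \eqn{0 \le \kappa < 1} the forced baseline stays
#' strictly positive.
#'
#' @param kind \code{"constant"} or \code{"periodic"}.
#' @param K0_star baseline capacity (> 0).
#' @param kappa amplitude fraction, \code{0 <= kappa < 1}.
#' @param omega angular frequency (> 0 for periodic forcing). Exactly one of
#'   \code{omega} and \code{period} may be given; \code{period = 2*pi/omega}.
#' @param period forcing period in time units (alternative to \code{omega}).
#' @return An object of class \code{eco_forcing}.
#' @examples
#' f <- climate_forcing("periodic", kappa = 0.5, period = 10000)
#' forcing_value(f, c(0, 2500, 5000))
#' @seealso [standard_climate_forcing()], [forcing_value()]
#' @export
climate_forcing <- function(kind = c("constant", "periodic"), K0_star = 1,
                            kappa = 0.5, omega = NULL, period = NULL) {
  kind <- match.arg(kind)
  if (!is.null(omega) && !is.null(period))
    stop("give either 'omega' or 'period', not both", call. = FALSE)
  if (kind == "constant") {
    kappa <- 0
    omega <- 0
  } else {
    if (is.null(omega)) {
      if (is.null(period)) stop("periodic forcing needs 'omega' or 'period'",
                                call. = FALSE)
      omega <- 2 * pi / period
    }
    if (omega <= 0) stop("periodic forcing needs omega > 0", call. = FALSE)
    if (kappa <= 0) stop("periodic forcing needs kappa > 0", call. = FALSE)
  }
  if (K0_star <= 0) stop("'K0_star' must be > 0", call. = FALSE)
  if (kappa < 0 || kappa >= 1)
    stop("'kappa' must satisfy 0 <= kappa < 1", call. = FALSE)
  structure(list(kind = kind, K0_star = K0_star, kappa = kappa, omega = omega),
            class = "eco_forcing")
}

#' Evaluate the forcing at given times
#'
#' @param forcing an [climate_forcing()] object.
#' @param t numeric vector of times (>= 0).
#' @return \code{K0(t)}, same length as \code{t}.
#' @export
forcing_value <- function(forcing, t) {
  stopifnot(inherits(forcing, "eco_forcing"), is.numeric(t))
  if (forcing$kind == "constant") {
    rep(forcing$K0_star, length(t))
  } else {
    forcing$K0_star * (1 + forcing$kappa * cos(forcing$omega * t))
  }
}

#' The standard periodic climate forcing
#'
#' Sinusoidal baseline-capacity forcing with \code{K0_star = 1},
#' \code{kappa = 0.5} and period 10000 time units
#' (\code{omega = 2*pi/10000}), the configuration used in the periodically
#' forced experiments.
#'
#' @return An \code{eco_forcing} object.
#' @examples
#' standard_climate_forcing()
#' @export
standard_climate_forcing <- function() {
  climate_forcing("periodic", K0_star = 1, kappa = 0.5, omega = 2 * pi / 10000)
}

# Derive the forcing implied by a parameter set (kappa > 0 and omega > 0
# select periodic forcing, otherwise constant at K0_star).
forcing_from_params <- function(params) {
  if (params$kappa > 0 && params$omega > 0) {
    climate_forcing("periodic", K0_star = params$K0_star,
                    kappa = params$kappa, omega = params$omega)
  } else {
    climate_forcing("constant", K0_star = params$K0_star)
  }
}

#' @export
print.eco_forcing <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("Constant climate forcing: K0 = %g\n", x$K0_star))
  } else {
    cat(sprintf(
      "Periodic climate forcing: K0(t) = %g * (1 + %g cos(%g t)), period %g\n",
      x$K0_star, x$kappa, x$omega, 2 * pi / x$omega))
  }
  invisible(x)
}
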