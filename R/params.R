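#' Model parameters for the ecocultural consumer-resource model
#'
#' Bundles every rate constant, noise parameter, forcing setting, initial
#' condition and integration setting of the three-equation model
#' \deqn{d\rho/dt = \alpha \rho [1 - \rho/(K(1+c))]}
#' \deqn{dc/dt   = -\lambda c + \sigma \xi_t \rho}
#' \deqn{dK/dt   = -\eta (K - K_0(t)) - \mu \rho}
#' where \eqn{\xi_t} are i.i.d. Weibull-distributed innovation draws.
#'
#' Defaults are the "standard run" rates: \code{alpha = 0.01},
#' \code{lam = 0.01}, \code{mu = 0.001}, \code{eta = 0.1},
#' \code{sigma = 1e-8}, with Weibull scale 1 and shape 0.1 (heavy-tailed,
#' bursty innovations). Initial conditions default to a small founding
#' population \code{rho0 = 0.01 * K0_star}, initial culture \code{c0 = 1} and
#' an unperturbed resource base \code{K_init = K0_star}.
#'
#' @param alpha intrinsic population growth rate per time unit (> 0).
#' @param lam intergenerational cultural loss rate per time unit (>= 0).
#' @param mu resource depletion (grazing) rate per time unit (>= 0).
#' @param eta resource replenishment rate per time unit (>= 0); \code{1/eta}
#'   is the resource recovery e-folding time.
#' @param sigma innovation amplitude (>= 0); \code{sigma = 0} switches
#'   cultural innovation off and makes the model deterministic.
#' @param weibull_shape,weibull_scale shape and scale of the Weibull
#'   innovation distribution (both > 0).
#' @param K0_star baseline unperturbed carrying capacity (> 0).
#' @param kappa climate forcing amplitude as a fraction of \code{K0_star}
#'   (0 <= kappa < 1 keeps the forced baseline strictly positive).
#' @param omega climate forcing angular frequency per time unit (>= 0);
#'   \code{kappa > 0} together with \code{omega > 0} selects periodic forcing.
#' @param rho0 initial population density (> 0).
#' @param c0 initial culture (>= 0).
#' @param K_init initial carrying capacity (> 0).
#' @param dt integration time step. The innovation draw is per step and not
#'   rescaled by \code{sqrt(dt)}: the discrete Euler-forward scheme at
#'   \code{dt = 1} defines the stochastic process, so changing \code{dt}
#'   changes the stochastic model (the deterministic part still converges).
#' @param n_steps integer number of Euler steps (>= 1).
#' @param seed integer seed for the innovation draws.
#'
#' @return An object of class \code{eco_params} (a validated named list).
#' @examples
#' p <- eco_params(sigma = 0, n_steps = 5000)
#' p$alpha
#' @seealso [simulate_ecoculture()], [climate_forcing()], [eco_regimes()]
#' @export
eco_params <- function(alpha = 0.01, lam = 0.01, mu = 0.001, eta = 0.1,
                       sigma = 1e-8, weibull_shape = 0.1, weibull_scale = 1,
                       K0_star = 1, kappa = 0, omega = 0,
                       rho0 = 0.01 * K0_star, c0 = 1, K_init = K0_star,
                       dt = 1, n_steps = 200000L, seed = 1L) {
  p <- list(alpha = alpha, lam = lam, mu = mu, eta = eta, sigma = sigma,
            weibull_shape = weibull_shape, weibull_scale = weibull_scale,
            K0_star = K0_star, kappa = kappa, omega = omega,
            rho0 = rho0, c0 = c0, K_init = K_init,
            dt = dt, n_steps = as.integer(n_steps), seed = as.integer(seed))
  validate_eco_params(p)
  class(p) <- "eco_params"
  p
}

validate_eco_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("alpha", "lam", "mu", "eta", "sigma", "weibull_shape",
              "weibull_scale", "K0_star", "kappa", "omega", "rho0", "c0",
              "K_init", "dt", "n_steps", "seed")) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite scalar",
                            call. = FALSE)
  }
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(p$alpha > 0, "'alpha' must be > 0")
  chk(p$lam >= 0, "'lam' must be >= 0")
  chk(p$mu >= 0, "'mu' must be >= 0")
  chk(p$eta >= 0, "'eta' must be >= 0")
  chk(p$sigma >= 0, "'sigma' must be >= 0")
  chk(p$weibull_shape > 0, "'weibull_shape' must be > 0")
  chk(p$weibull_scale > 0, "'weibull_scale' must be > 0")
  chk(p$K0_star > 0, "'K0_star' must be > 0")
  chk(p$kappa >= 0 && p$kappa < 1, "'kappa' must satisfy 0 <= kappa < 1")
  chk(p$omega >= 0, "'omega' must be >= 0")
  chk(p$rho0 > 0, "'rho0' must be > 0")
  chk(p$c0 >= 0, "'c0' must be >= 0")
  chk(p$K_init > 0, "'K_init' must be > 0")
  chk(p$dt > 0, "'dt' must be > 0")
  chk(p$n_steps >= 1, "'n_steps' must be >= 1")
  invisible(p)
}

#' @export
print.eco_params <- function(x, ...) {
  cat("Ecocultural model parameters\n")
  cat(sprintf("  rates:   alpha=%g  lambda=%g  mu=%g  eta=%g\n",
              x$alpha, x$lam, x$mu, x$eta))
  cat(sprintf("  noise:   sigma=%g  Weibull(shape=%g, scale=%g)\n",
              x$sigma, x$weibull_shape, x$weibull_scale))
  cat(sprintf("  forcing: K0*=%g  kappa=%g  omega=%g\n",
              x$K0_star, x$kappa, x$omega))
  cat(sprintf("  init:    rho0=%g  c0=%g  K_init=%g\n", x$rho0, x$c0, x$K_init))
  cat(sprintf("  steps:   dt=%g  n_steps=%d  seed=%d\n",
              x$dt, x$n_steps, x$seed))
  invisible(x)
}

#' Named parameter sets for the studied model regimes
#'
#' Returns the six experiment configurations explored with the model, all at
#' baseline capacity \code{K0_star = 1}:
#' \describe{
#'   \item{no_culture}{\code{sigma = 0}: deterministic logistic growth,
#'     culture decays to zero.}
#'   \item{standard}{the standard stochastic run
#'     (\code{lam = 0.01, alpha = 0.01, mu = 0.001, eta = 0.1, sigma = 1e-8}),
#'     the baseline showing boom-and-bust cycles.}
#'   \item{slow_recovery}{\code{eta = 1e-5}: resources regrow 10000 times more
#'     slowly; a single boom/bust is followed by long-term collapse.}
#'   \item{high_depletion}{\code{mu = 0.01}: more frequent, smaller
#'     boom-and-bust cycles and roughly tenfold lower mean density.}
#'   \item{no_loss}{\code{lam = 0}: perfect intergenerational transmission,
#'     culture accumulates without decay.}
#'   \item{no_depletion}{\code{mu = 0, lam = 0}: unbounded accelerating growth
#'     of culture and population.}
#' }
#'
#' @param n_steps,seed passed through to every [eco_params()] set.
#' @return Named list of \code{eco_params}.
#' @examples
#' names(eco_regimes())
#' @export
eco_regimes <- function(n_steps = 200000L, seed = 1L) {
  list(
    no_culture     = eco_params(sigma = 0, n_steps = n_steps, seed = seed),
    standard       = eco_params(n_steps = n_steps, seed = seed),
    slow_recovery  = eco_params(eta = 1e-5, n_steps = n_steps, seed = seed),
    high_depletion = eco_params(mu = 0.01, n_steps = n_steps, seed = seed),
    no_loss        = eco_params(lam = 0, n_steps = n_steps, seed = seed),
    no_depletion   = eco_params(lam = 0, mu = 0, n_steps = n_steps, seed = seed)
  )
}
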