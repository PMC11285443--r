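#' Deterministic drift of the ecocultural model
#'
#' Evaluates the noise-free right-hand sides at a given state:
#' \deqn{d\rho/dt = \alpha \rho [1 - \rho/(K(1+c))], \quad
#'       dc/dt = -\lambda c, \quad
#'       dK/dt = -\eta (K - K_0) - \mu \rho.}
#' Extinction is absorbing: at \code{rho = 0} the density drift is zero
#' regardless of the state of the resources. For \code{rho > 0} a
#' non-positive effective carrying capacity \eqn{K(1+c)} is a degenerate
#' state and raises an error.
#'
#' @param rho,c,K current population density, culture and carrying capacity.
#' @param K0_now current value of the forcing baseline \eqn{K_0(t)}.
#' @param params an [eco_params()] object (only the rates are used).
#' @return Named numeric vector \code{c(drho =, dc =, dK =)}.
#' @examples
#' p <- eco_params()
#' deterministic_drift(rho = 0.5, c = 1, K = 1, K0_now = 1, params = p)
#' @export
deterministic_drift <- function(rho, c, K, K0_now, params) {
  stopifnot(inherits(params, "eco_params"))
  if (rho < 0 || c < 0) stop("rho and c must be non-negative", call. = FALSE)
  if (rho == 0) {
    drho <- 0
  } else {
    keff <- K * (1 + c)
    if (keff <= 0)
      stop("degenerate state: effective carrying capacity K(1+c) = ",
           signif(keff, 6), " is not positive", call. = FALSE)
    drho <- params$alpha * rho * (1 - rho / keff)
  }
  c(drho = drho,
    dc = -params$lam * c,
    dK = -params$eta * (K - K0_now) - params$mu * rho)
}

#' Draw Weibull-distributed cultural innovations
#'
#' Innovations are i.i.d. draws from a positive-support Weibull distribution
#' with density \eqn{(k/s)(x/s)^{k-1} e^{-(x/s)^k}}. The default model uses
#' scale 1 and shape 0.1, a very heavy-tailed choice under which most draws
#' are tiny but rare draws are enormous ("cultural bursting"). Draws come
#' from R's global RNG stream; seed it (or use [simulate_ecoculture()], which
#' seeds it from \code{params$seed}) for reproducibility.
#'
#' @param n number of draws (>= 1).
#' @param shape,scale Weibull parameters (both > 0).
#' @return Numeric vector of \code{n} non-negative draws.
#' @examples
#' set.seed(1)
#' summary(draw_innovations(1000, shape = 0.1, scale = 1))
#' @export
draw_innovations <- function(n, shape = 0.1, scale = 1) {
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(scale) || scale <= 0)
    stop("Weibull 'shape' and 'scale' must be positive", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  rweibull(n, shape = shape, scale = scale)
}

#' One explicit Euler step of the full stochastic model
#'
#' Advances the state by \code{dt} using the fully explicit scheme: all
#' right-hand sides are evaluated at the current state before any component
#' is updated, and the innovation term \eqn{\sigma \xi \rho} uses the
#' pre-update density. If the density update would cross zero (a steep
#' logistic collapse overshooting in one step), the step falls back to the
#' positivity-preserving multiplicative update
#' \eqn{\rho \exp(dt \, \dot\rho/\rho)}, which lands on the small positive
#' value the relative drift implies instead of annihilating the population;
#' a negative culture update is clipped to zero. Both interventions are
#' flagged.
#'
#' @param state named list or vector with elements \code{t, rho, c, K}.
#' @param xi_now innovation draw for this step (>= 0).
#' @param K0_now forcing baseline at the step's start time.
#' @param params an [eco_params()] object.
#' @param barren policy when resources are exhausted
#'   (\eqn{K(1+c) \le 0} with \eqn{\rho > 0}); see
#'   [simulate_ecoculture()].
#' @return Named list \code{t, rho, c, K, clipped} for the successor state;
#'   \code{clipped} counts components clipped at this step (0, 1 or 2).
#' @examples
#' p <- eco_params()
#' euler_step(list(t = 0, rho = 0.01, c = 1, K = 1), xi_now = 0,
#'            K0_now = 1, params = p)
#' @export
euler_step <- function(state, xi_now, K0_now, params,
                       barren = c("decline", "error")) {
  stopifnot(inherits(params, "eco_params"))
  barren <- match.arg(barren)
  if (xi_now < 0) stop("'xi_now' must be >= 0", call. = FALSE)
  d <- if (barren == "decline" && state$rho > 0 &&
             state$K * (1 + state$c) <= 0) {
    c(drho = -params$alpha * state$rho, dc = -params$lam * state$c,
      dK = -params$eta * (state$K - K0_now) - params$mu * state$rho)
  } else {
    deterministic_drift(state$rho, state$c, state$K, K0_now, params)
  }
  rho_new <- state$rho + params$dt * d[["drho"]]
  c_new <- state$c +
    params$dt * (d[["dc"]] + params$sigma * xi_now * state$rho)
  K_new <- state$K + params$dt * d[["dK"]]
  clipped <- 0L
  if (rho_new <= 0 && state$rho > 0) {
    g <- max(params$dt * d[["drho"]] / state$rho, -600)
    rho_new <- state$rho * exp(g)
    clipped <- clipped + 1L
  }
  if (c_new < 0) { c_new <- 0; clipped <- clipped + 1L }
  if (!all(is.finite(c(rho_new, c_new, K_new))))
    stop("integration failure: non-finite state after step at t = ",
         state$t, call. = FALSE)
  list(t = state$t + params$dt, rho = rho_new, c = c_new, K = K_new,
       clipped = clipped)
}

#' Simulate the stochastic ecocultural model
#'
#' Integrates the three coupled equations with the Euler-forward scheme.
#' One Weibull innovation is drawn per step from a generator seeded with
#' \code{params$seed}; the forcing baseline is evaluated at each step's
#' start time. With \code{sigma = 0} the trajectory is deterministic and
#' independent of the seed.
#'
#' Under heavy depletion a large innovation burst can exhaust the resource
#' base entirely: the depletion term drives \eqn{K} below zero and the
#' effective carrying capacity \eqn{K(1+c)} becomes non-positive. The raw
#' logistic term is explosive there (a negative capacity makes the bracket
#' exceed 1, so the population would grow without bound; numerically the
#' state diverges within a few thousand steps). The integrator therefore
#' applies a barren-state rule, selected by \code{barren}:
#' \describe{
#'   \item{\code{"decline"} (default)}{while \eqn{K(1+c) \le 0} the
#'     population declines at its intrinsic demographic rate,
#'     \eqn{d\rho/dt = -\alpha\rho}; \eqn{K} keeps its own dynamics
#'     (unclipped) and recovers through replenishment. Barren steps are
#'     counted in the \code{n_barren} attribute.}
#'   \item{\code{"error"}}{the degenerate state raises an error carrying
#'     the step index.}
#' }
#' Barren episodes never occur in the moderate-depletion regimes at the
#' default horizons; they matter for high depletion (\code{mu = 0.01}) and
#' very long runs.
#'
#' @param params an [eco_params()] object.
#' @param forcing an [climate_forcing()] object, or \code{NULL} to derive it
#'   from \code{params} (\code{kappa > 0} and \code{omega > 0} select
#'   periodic forcing, otherwise constant at \code{K0_star}).
#' @param barren barren-state policy, \code{"decline"} or \code{"error"}
#'   (see Details).
#' @return An object of class \code{eco_trajectory}: a data frame with one
#'   row per time point (\code{n_steps + 1} rows) and columns
#'   \describe{
#'     \item{t}{time,}
#'     \item{rho}{population density,}
#'     \item{c}{culture,}
#'     \item{K}{carrying capacity,}
#'     \item{K0}{forcing baseline \eqn{K_0(t)},}
#'     \item{per_capita}{resources per capita \eqn{K/\rho} (\code{NA} where
#'       \eqn{\rho = 0}),}
#'     \item{xi}{the innovation drawn for the step starting at \code{t}
#'       (\code{NA} on the final row).}
#'   }
#'   Attributes: \code{params}, \code{forcing}, \code{n_clipped} (the
#'   number of positivity interventions: density soft landings plus
#'   culture clips, see [euler_step()]) and \code{n_barren} (steps spent
#'   in the barren state).
#' @examples
#' traj <- simulate_ecoculture(eco_params(sigma = 0, n_steps = 2000))
#' tail(traj$per_capita, 1)  # approaches 1 at the no-culture equilibrium
#' @export
simulate_ecoculture <- function(params, forcing = NULL,
                                barren = c("decline", "error")) {
  stopifnot(inherits(params, "eco_params"))
  barren <- match.arg(barren)
  if (is.null(forcing)) forcing <- forcing_from_params(params)
  stopifnot(inherits(forcing, "eco_forcing"))
  n <- params$n_steps
  t_grid <- seq(0, by = params$dt, length.out = n + 1)
  set.seed(params$seed)
  xi <- draw_innovations(n, shape = params$weibull_shape,
                         scale = params$weibull_scale)
  K0_all <- forcing_value(forcing, t_grid)
  out <- euler_simulate_cpp(params$rho0, params$c0, params$K_init,
                            params$alpha, params$lam, params$mu, params$eta,
                            params$sigma, xi, K0_all[seq_len(n)], params$dt,
                            barren_decline = (barren == "decline"))
  per_capita <- ifelse(out$rho > 0, out$K / out$rho, NA_real_)
  traj <- data.frame(t = t_grid, rho = out$rho, c = out$c, K = out$K,
                     K0 = K0_all, per_capita = per_capita,
                     xi = c(xi, NA_real_))
  attr(traj, "params") <- params
  attr(traj, "forcing") <- forcing
  attr(traj, "n_clipped") <- out$n_clipped
  attr(traj, "n_barren") <- out$n_barren
  class(traj) <- c("eco_trajectory", "data.frame")
  traj
}

#' @export
print.eco_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  f <- attr(x, "forcing")
  cat(sprintf("Ecocultural trajectory: %d steps, dt = %g, seed = %d\n",
              nrow(x) - 1L, p$dt, p$seed))
  cat(sprintf("  forcing: %s | clipping events: %d | barren steps: %d\n",
              f$kind, attr(x, "n_clipped"), attr(x, "n_barren")))
  cat(sprintf("  rho in [%.4g, %.4g], c in [%.4g, %.4g], K in [%.4g, %.4g]\n",
              min(x$rho), max(x$rho), min(x$c), max(x$c), min(x$K), max(x$K)))
  invisible(x)
}

#' Deterministic fixed point of the noise-free model
#'
#' With \code{sigma = 0} and constant forcing, culture decays to zero and
#' the remaining predator-prey pair settles at the joint solution of
#' \eqn{\rho = K} and \eqn{K = K_0 - \mu \rho / \eta}:
#' \deqn{\rho^* = K^* = \frac{K_0}{1 + \mu/\eta}, \quad c^* = 0,}
#' so resources per capita \eqn{K/\rho} tend to exactly 1.
#'
#' @param params an [eco_params()] object with \code{sigma = 0}.
#' @return Named numeric vector \code{c(rho_star =, K_star =, c_star =)}.
#' @examples
#' equilibrium_fixed_point(eco_params(sigma = 0))  # rho* = 1/1.01
#' @export
equilibrium_fixed_point <- function(params) {
  stopifnot(inherits(params, "eco_params"))
  if (params$sigma > 0)
    stop("fixed point applies to the deterministic model only (sigma = 0)",
         call. = FALSE)
  if (params$eta == 0 && params$mu > 0)
    stop("no finite fixed point with depletion but no replenishment",
         call. = FALSE)
  ratio <- if (params$mu == 0) 0 else params$mu / params$eta
  rho_star <- params$K0_star / (1 + ratio)
  c(rho_star = rho_star, K_star = rho_star, c_star = 0)
}
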