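#' Closed-form solutions used as independent integration oracles
#'
#' Each of the three model equations admits an explicit solution once the
#' other variables are treated as known paths on a time grid. These
#' solutions are evaluated by numerical quadrature and serve as oracles for
#' the Euler integrator: on matched grids the two routes agree to O(dt).
#'
#' The initial-condition terms are damped (`K_init * exp(-eta t)`,
#' `c0 * exp(-lambda t)`), the exact solution of the linear equations; an
#' undamped initial term would not satisfy the equations asymptotically.
#'
#' The default `rule = "left"` left-endpoint quadrature matches the Euler
#' scheme's order on the same grid; `rule = "trapezoid"` is available for
#' convergence studies on finer grids.
#'
#' @name closed_form
NULL

# Exponentially damped quadrature: returns, on the grid t_grid,
#   Q_n = sum_{j < n} g_j * exp(-rate * (t_n - t_j)) * dt_j      (left)
# or its trapezoid analogue. Evaluated by a stable recurrence
#   Q_n = exp(-rate*dt_n) * (Q_{n-1} + g_{n-1} * dt_n)
# so no intermediate exp() can overflow.
damped_quadrature <- function(g, t_grid, rate, rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  n <- length(t_grid)
  if (length(g) != n)
    stop("path and time grid lengths differ (", length(g), " vs ", n, ")",
         call. = FALSE)
  Q <- numeric(n)
  if (n == 1L) return(Q)
  dt <- diff(t_grid)
  decay <- exp(-rate * dt)
  if (rule == "left") {
    for (i in 2:n)
      Q[i] <- decay[i - 1] * (Q[i - 1] + g[i - 1] * dt[i - 1])
  } else {
    for (i in 2:n)
      Q[i] <- decay[i - 1] * Q[i - 1] +
        0.5 * dt[i - 1] * (decay[i - 1] * g[i - 1] + g[i])
  }
  Q
}

#' Closed-form logistic solution with a time-varying effective capacity
#'
#' Evaluates
#' \deqn{\rho(t) = \frac{\rho_0 e^{\alpha t}}
#'   {1 + \rho_0 \int_0^t \alpha \, [K_{eff}(\tau)]^{-1} e^{\alpha \tau}
#'    d\tau}}
#' for constant growth rate \eqn{\alpha} and a positive effective carrying
#' capacity path \eqn{K_{eff}(t) = K(t)(1 + c(t))} given on the grid.
#' Computed in the numerically stable form
#' \eqn{\rho(t) = \rho_0 / (e^{-\alpha t} + \rho_0 J(t))} with a damped
#' quadrature, so long horizons do not overflow.
#'
#' @param rho0 initial density (> 0).
#' @param alpha growth rate (> 0).
#' @param effective_K numeric path of the effective capacity on
#'   \code{t_grid}, or a function of time.
#' @param t_grid increasing time grid starting at the initial time.
#' @param rule quadrature rule, \code{"left"} (matches Euler order) or
#'   \code{"trapezoid"}.
#' @return Density path on \code{t_grid}.
#' @examples
#' tg <- seq(0, 2000, by = 1)
#' rho <- logistic_solution(0.01, 0.01, rep(1, length(tg)), tg)
#' tail(rho, 1)  # sigmoid saturation towards 1
#' @family closed-form oracles
#' @export
logistic_solution <- function(rho0, alpha, effective_K, t_grid,
                              rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  if (is.function(effective_K)) effective_K <- effective_K(t_grid)
  if (length(effective_K) != length(t_grid))
    stop("'effective_K' and 't_grid' lengths differ", call. = FALSE)
  if (any(!is.finite(effective_K)) || any(effective_K <= 0))
    stop("'effective_K' must be finite and strictly positive", call. = FALSE)
  if (rho0 <= 0) stop("'rho0' must be > 0", call. = FALSE)
  tau <- t_grid - t_grid[1]
  J <- damped_quadrature(alpha / effective_K, t_grid, alpha, rule)
  rho0 / (exp(-alpha * tau) + rho0 * J)
}

#' Closed-form carrying-capacity solution for a known density path
#'
#' Evaluates the relaxation-with-depletion solution
#' \deqn{K(t) = K(0) e^{-\eta t} + \int_0^t e^{-\eta (t - t')}
#'   [\eta K_0(t') - \mu \rho(t')] \, dt'}
#' by damped quadrature on the grid.
#'
#' @param K_init initial capacity.
#' @param eta replenishment rate (>= 0).
#' @param mu depletion rate (>= 0).
#' @param K0_path forcing baseline path on \code{t_grid} (vector or function).
#' @param rho_path density path on \code{t_grid} (vector or function).
#' @param t_grid increasing time grid.
#' @param rule quadrature rule, see [logistic_solution()].
#' @return Capacity path on \code{t_grid}.
#' @examples
#' tg <- seq(0, 100, by = 1)
#' # pure relaxation towards K0 = 1 from K(0) = 2 with no population
#' K <- carrying_capacity_solution(2, 0.1, 0.001, rep(1, 101),
#'                                 rep(0, 101), tg)
#' @family closed-form oracles
#' @export
carrying_capacity_solution <- function(K_init, eta, mu, K0_path, rho_path,
                                       t_grid, rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  if (is.function(K0_path)) K0_path <- K0_path(t_grid)
  if (is.function(rho_path)) rho_path <- rho_path(t_grid)
  if (length(K0_path) != length(t_grid) || length(rho_path) != length(t_grid))
    stop("path lengths must match 't_grid'", call. = FALSE)
  if (any(!is.finite(K0_path)) || any(!is.finite(rho_path)))
    stop("paths must be finite", call. = FALSE)
  tau <- t_grid - t_grid[1]
  K_init * exp(-eta * tau) +
    damped_quadrature(eta * K0_path - mu * rho_path, t_grid, eta, rule)
}

#' Closed-form culture solution for known density and innovation paths
#'
#' The culture equation is linear in \eqn{c}, so given the density path and
#' the realized innovation draws the solution is the exponentially decaying
#' past-history accumulation
#' \deqn{c(t) = c(0) e^{-\lambda t} + \sigma \int_0^t
#'   \rho(t') \xi(t') e^{-\lambda (t - t')} \, dt'.}
#' Because the equation is linear, re-using the innovations recorded by
#' [simulate_ecoculture()] reproduces the stochastic Euler culture path to
#' within quadrature error even for \code{sigma > 0}.
#'
#' @param c0 initial culture (>= 0).
#' @param lam cultural loss rate (>= 0).
#' @param sigma innovation amplitude (>= 0).
#' @param rho_path density path on \code{t_grid}.
#' @param xi_path innovation draws, one per step
#'   (\code{length(t_grid) - 1}, or \code{length(t_grid)} with a trailing
#'   value that left-endpoint quadrature never uses, e.g. the \code{xi}
#'   column of a trajectory).
#' @param t_grid increasing time grid.
#' @param rule quadrature rule, see [logistic_solution()].
#' @return Culture path on \code{t_grid}.
#' @examples
#' tg <- seq(0, 500, by = 1)
#' cc <- culture_solution(1, 0.01, 0, rep(1, 501), rep(0, 500), tg)
#' all.equal(cc, exp(-0.01 * tg))  # pure exponential decay
#' @family closed-form oracles
#' @export
culture_solution <- function(c0, lam, sigma, rho_path, xi_path, t_grid,
                             rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  n <- length(t_grid)
  if (is.function(rho_path)) rho_path <- rho_path(t_grid)
  if (length(xi_path) == n - 1L) xi_path <- c(xi_path, 0)
  xi_path[is.na(xi_path)] <- 0
  if (length(rho_path) != n || length(xi_path) != n)
    stop("path lengths must match 't_grid'", call. = FALSE)
  tau <- t_grid - t_grid[1]
  c0 * exp(-lam * tau) +
    sigma * damped_quadrature(rho_path * xi_path, t_grid, lam, rule)
}

#' Maximum deviation between the Euler integrator and the closed forms
#'
#' Runs the integrator for a parameter set, then feeds the simulated paths
#' back into the three closed-form solutions on the same grid and reports
#' the maximum absolute deviation per variable. Used as the oracle check:
#' deviations shrink as O(dt).
#'
#' @param params an [eco_params()] object.
#' @param forcing optional [climate_forcing()]; defaults to the one implied
#'   by \code{params}.
#' @return Named numeric vector \code{c(rho =, c =, K =)} of maximum
#'   absolute deviations.
#' @examples
#' oracle_deviations(eco_params(sigma = 0, n_steps = 2000))
#' @export
oracle_deviations <- function(params, forcing = NULL) {
  traj <- simulate_ecoculture(params, forcing)
  keff <- traj$K * (1 + traj$c)
  rho_cf <- logistic_solution(params$rho0, params$alpha, keff, traj$t)
  K_cf <- carrying_capacity_solution(params$K_init, params$eta, params$mu,
                                     traj$K0, traj$rho, traj$t)
  c_cf <- culture_solution(params$c0, params$lam, params$sigma,
                           traj$rho, traj$xi, traj$t)
  c(rho = max(abs(rho_cf - traj$rho)),
    c = max(abs(c_cf - traj$c)),
    K = max(abs(K_cf - traj$K)))
}
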