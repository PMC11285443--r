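#' Run a multi-member ensemble and compute expectation values
#'
#' Simulates \code{n_members} realizations that differ only in their
#' innovation seeds (member \code{i} uses \code{seed_base + i - 1}) and
#' computes expectation values of density, culture and capacity as averages
#' pooled over every time index of every member. By default no burn-in is
#' excluded.
#'
#' @param params an [eco_params()] object (its \code{seed} is ignored in
#'   favour of \code{seed_base}).
#' @param forcing optional [climate_forcing()]; defaults to the forcing
#'   implied by \code{params}.
#' @param n_members number of ensemble members (>= 1); the reference
#'   protocol uses 16 members of 2e5 steps each.
#' @param seed_base first member seed; member \code{i} gets
#'   \code{seed_base + i - 1}.
#' @param burn_in number of initial steps to drop from the averages
#'   (default 0).
#' @param keep_members if \code{TRUE}, attach the member trajectories.
#' @return An object of class \code{eco_ensemble}: list with pooled means
#'   \code{E_rho}, \code{E_c}, \code{E_K}, a \code{per_member_means} data
#'   frame (member, seed, mean_rho, mean_c, mean_K), \code{member_seeds},
#'   \code{n_members}, \code{n_steps}, and optionally \code{members}.
#' @examples
#' ens <- run_ensemble(eco_params(n_steps = 2000), n_members = 4,
#'                     seed_base = 1)
#' ens$E_rho
#' @seealso [eco_sweep()]
#' @export
run_ensemble <- function(params, forcing = NULL, n_members = 16L,
                         seed_base = 1L, burn_in = 0L, keep_members = FALSE) {
  stopifnot(inherits(params, "eco_params"), n_members >= 1, burn_in >= 0,
            burn_in < params$n_steps)
  if (is.null(forcing)) forcing <- forcing_from_params(params)
  keep_idx <- seq.int(burn_in + 1L, params$n_steps + 1L)
  pm <- vector("list", n_members)
  members <- if (keep_members) vector("list", n_members) else NULL
  seeds <- seed_base + seq_len(n_members) - 1L
  for (i in seq_len(n_members)) {
    p_i <- params
    p_i$seed <- as.integer(seeds[i])
    traj <- tryCatch(simulate_ecoculture(p_i, forcing), error = function(e)
      stop("ensemble member ", i, " (seed ", seeds[i], ") failed: ",
           conditionMessage(e), call. = FALSE))
    pm[[i]] <- data.frame(member = i, seed = seeds[i],
                          mean_rho = mean(traj$rho[keep_idx]),
                          mean_c = mean(traj$c[keep_idx]),
                          mean_K = mean(traj$K[keep_idx]))
    if (keep_members) members[[i]] <- traj
  }
  pm <- do.call(rbind, pm)
  res <- list(n_members = as.integer(n_members),
              n_steps = params$n_steps,
              burn_in = as.integer(burn_in),
              E_rho = mean(pm$mean_rho), E_c = mean(pm$mean_c),
              E_K = mean(pm$mean_K),
              per_member_means = pm, member_seeds = seeds,
              params = params, forcing = forcing, members = members)
  class(res) <- "eco_ensemble"
  res
}

#' @export
print.eco_ensemble <- function(x, ...) {
  cat(sprintf("Ecocultural ensemble: %d members x %d steps (burn-in %d)\n",
              x$n_members, x$n_steps, x$burn_in))
  cat(sprintf("  E[rho] = %.6g   E[C] = %.6g   E[K] = %.6g\n",
              x$E_rho, x$E_c, x$E_K))
  invisible(x)
}

#' Factorial (lambda, mu) parameter sweep of ensemble expectations
#'
#' Runs [run_ensemble()] on the full factorial grid of cultural-loss and
#' depletion rates, re-using the identical member seeds in every cell so
#' that differences between cells are parameter-driven, not sampling noise.
#' The default grid spans four decades around the standard rates,
#' \eqn{\lambda, \mu \in \{10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}\}}.
#'
#' @param base_params an [eco_params()] object supplying all rates except
#'   \code{lam} and \code{mu}.
#' @param lam_values,mu_values numeric grids (non-empty).
#' @param forcing optional [climate_forcing()] shared by all cells
#'   (defaults to the forcing implied by \code{base_params}, typically
#'   constant).
#' @param n_members,seed_base,burn_in passed to [run_ensemble()].
#' @return An object of class \code{eco_sweep}: a long-format data frame
#'   with columns \code{lam, mu, E_rho, E_c, E_K, n_members, n_steps}, plus
#'   attributes \code{lam_values} and \code{mu_values}.
#' @examples
#' sw <- eco_sweep(eco_params(n_steps = 1000), lam_values = c(0.01, 0.1),
#'                 mu_values = 0.001, n_members = 2)
#' sw
#' @export
eco_sweep <- function(base_params, lam_values = 10^(-4:-1),
                      mu_values = 10^(-4:-1), forcing = NULL,
                      n_members = 16L, seed_base = 1L, burn_in = 0L) {
  stopifnot(length(lam_values) >= 1, length(mu_values) >= 1)
  if (is.null(forcing)) forcing <- forcing_from_params(base_params)
  grid <- expand.grid(lam = lam_values, mu = mu_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- base_params
    p$lam <- grid$lam[g]
    p$mu <- grid$mu[g]
    validate_eco_params(p)
    ens <- tryCatch(
      run_ensemble(p, forcing, n_members = n_members, seed_base = seed_base,
                   burn_in = burn_in),
      error = function(e)
        stop(sprintf("sweep cell (lambda = %g, mu = %g) failed: %s",
                     grid$lam[g], grid$mu[g], conditionMessage(e)),
             call. = FALSE))
    rows[[g]] <- data.frame(lam = grid$lam[g], mu = grid$mu[g],
                            E_rho = ens$E_rho, E_c = ens$E_c, E_K = ens$E_K,
                            n_members = ens$n_members, n_steps = ens$n_steps)
  }
  out <- do.call(rbind, rows)
  attr(out, "lam_values") <- lam_values
  attr(out, "mu_values") <- mu_values
  class(out) <- c("eco_sweep", "data.frame")
  out
}
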