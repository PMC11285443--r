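test_that("analytic signal recovers amplitude and phase of a cosine", {
  tt <- 0:9999
  om <- 2 * pi / 500
  a <- analytic_signal(cos(om * tt))
  interior <- 500:9500
  expect_true(all(a$amplitude >= 0))
  expect_equal(unname(a$amplitude[interior]), rep(1, length(interior)),
               tolerance = 1e-3)
  resid <- a$phase[interior] - om * tt[interior]
  expect_lt(diff(range(resid)), 1e-2)  # phase tracks the carrier linearly
  # a phase-shifted cosine shows up as a constant offset
  b <- analytic_signal(cos(om * tt + pi / 4))
  offset <- median(b$phase[interior] - a$phase[interior])
  expect_equal(offset, pi / 4, tolerance = 1e-3)
})

test_that("degenerate inputs to the analytic signal are rejected", {
  expect_error(analytic_signal(rep(1, 100)), "constant")
  expect_error(analytic_signal(1:10), "short")
  expect_error(analytic_signal(c(1:99, NA)), "finite")
})

test_that("phase difference is the phase minus the forcing ramp", {
  tt <- seq(0, 100, by = 0.5)
  phi <- 0.3 * tt
  expect_equal(phase_difference(phi, 0.3, tt), rep(0, length(tt)))
  expect_equal(phase_difference(phi + pi / 4, 0.3, tt),
               rep(pi / 4, length(tt)))
  # incommensurate frequency drifts linearly at the frequency mismatch
  d <- phase_difference(0.35 * tt, 0.3, tt)
  expect_equal(unique(round(diff(d) / 0.5, 12)), 0.05)
  expect_error(phase_difference(phi, -1, tt), "omega")
  expect_error(phase_difference(phi, 0.3, tt[-1]), "length")
})

test_that("wrapped histogram is a probability distribution on [0, 2pi)", {
  h <- wrapped_histogram(rep(1.234, 1000), n_bins = 36)
  expect_equal(sum(h$prob), 1)
  expect_equal(max(h$prob), 1)  # point mass lands in a single bin
  set.seed(99)
  u <- runif(2e5, 0, 2 * pi)
  hu <- wrapped_histogram(u, n_bins = 36)
  expect_equal(sum(hu$prob), 1)
  expect_true(all(abs(hu$prob - 1 / 36) < 0.002))  # ~5 MC sd
  # arbitrary reals wrap into range: histogram of x and x + 2*pi agree
  set.seed(100)
  x <- rnorm(5000, sd = 10)
  expect_equal(wrapped_histogram(x, 24)$prob,
               wrapped_histogram(x + 2 * pi, 24)$prob)
  expect_error(wrapped_histogram(numeric(0)), "empty")
  expect_error(wrapped_histogram(1:10, n_bins = 1), "n_bins")
})

test_that("relative standard deviation spans its extremal values", {
  u <- wrapped_histogram(seq(0, 2 * pi - 1e-9, length.out = 36000), 36)
  expect_equal(rel_std_pct(u), 0)  # exactly uniform
  pm <- wrapped_histogram(rep(pi, 100), 36)
  expect_equal(rel_std_pct(pm), 100 * sqrt(35))  # all mass in one bin
  set.seed(7)
  for (i in 1:20) {
    h <- wrapped_histogram(runif(50, 0, 2 * pi), sample(2:64, 1))
    r <- rel_std_pct(h)
    expect_gte(r, 0)
    expect_lte(r, 100 * sqrt(h$n_bins - 1) + 1e-9)
  }
})

test_that("KS uniformity test calibrates against its null", {
  set.seed(123)
  kt <- ks_uniformity(runif(1e5, 0, 2 * pi))
  expect_gt(kt$p_value, 0.01)
  expect_gte(kt$statistic, 0)
  expect_lte(kt$statistic, 1)
  # a point mass sits half a CDF away from uniform
  pm <- ks_uniformity(rep(pi, 1000))
  expect_equal(pm$statistic, 0.5, tolerance = 1e-3)
  expect_lt(pm$p_value, 1e-10)
  expect_error(ks_uniformity(rep(1, 5)), "8")
})

test_that("a capacity-tracking response yields a sharp phase histogram", {
  # sigma = 0 with slow periodic forcing: alpha^-1 = 100 << period, so the
  # density is in quasi-equilibrium with the forcing and phase-locks 1:1
  p <- det_params(n_steps = 100000L, kappa = 0.5, omega = 2 * pi / 5000)
  traj <- simulate_ecoculture(p)
  rep <- synchronization_report(traj, variables = "rho")
  expect_gt(rep$rho$rel_std_pct, 100)
  expect_lt(rep$rho$ks_pvalue, 1e-6)
  # most of the mass concentrates in few bins
  expect_gt(max(rep$rho$histogram$prob), 0.2)
})

test_that("an unrelated forcing frequency shows no phase preference", {
  # surrogate: unforced stochastic run analyzed against a frequency the
  # model never saw; decimated KS should rarely reject at 99%
  n_rej <- 0L
  n_sur <- 60L
  for (s in seq_len(n_sur)) {
    p <- std_params(n_steps = 100000L, seed = 4000L + s)
    traj <- simulate_ecoculture(p)
    fake <- climate_forcing("periodic", kappa = 0.5, omega = 2 * pi / 9100)
    rep <- synchronization_report(traj, forcing = fake, decimate = TRUE,
                                  variables = "c")
    if (rep$c$ks_pvalue < 0.01) n_rej <- n_rej + 1L
  }
  expect_lte(n_rej / n_sur, 0.05)
})

test_that("synchronization report validates its inputs", {
  p <- std_params(n_steps = 1000L)
  traj <- simulate_ecoculture(p)  # constant forcing
  expect_error(synchronization_report(traj), "periodic")
  p2 <- std_params(n_steps = 1000L, kappa = 0.5, omega = 2 * pi / 100)
  t2 <- simulate_ecoculture(p2)
  expect_error(synchronization_report(t2, edge_fraction = 0.7),
               "edge_fraction")
  rep <- synchronization_report(t2, n_bins = 18, edge_fraction = 0.1)
  expect_named(rep, c("rho", "c"))
  expect_equal(rep$rho$n_bins, 18L)
  expect_equal(rep$rho$edge_fraction_discarded, 0.1)
  expect_equal(length(rep$c$delta_phi_wrapped), 1001 - 2 * 100)
  expect_true(all(rep$c$delta_phi_wrapped >= 0 &
                    rep$c$delta_phi_wrapped < 2 * pi))
})
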