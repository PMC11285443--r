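test_that("logistic solution reproduces the textbook sigmoid", {
  tg <- seq(0, 2000, by = 0.1)
  rho <- logistic_solution(0.01, 0.01, rep(1, length(tg)), tg,
                           rule = "trapezoid")
  exact <- 0.01 * exp(0.01 * tg) / (1 + 0.01 * (exp(0.01 * tg) - 1))
  expect_equal(rho, exact, tolerance = 1e-4)
  expect_equal(tail(rho, 1), 1, tolerance = 1e-3)
  # equilibrium initial condition stays put
  flat <- logistic_solution(1, 0.01, rep(1, 501), seq(0, 500),
                            rule = "trapezoid")
  expect_equal(flat, rep(1, 501), tolerance = 1e-3)
})

test_that("logistic solution rejects bad inputs", {
  tg <- 0:10
  expect_error(logistic_solution(0.01, 0.01, rep(-1, 11), tg), "positive")
  expect_error(logistic_solution(0, 0.01, rep(1, 11), tg), "rho0")
  expect_error(logistic_solution(0.01, 0.01, rep(1, 5), tg), "length")
})

test_that("capacity solution handles pure relaxation and depletion limits", {
  tg <- seq(0, 200, by = 0.05)
  n <- length(tg)
  # no population: K relaxes from 2 to K0 = 1 exponentially
  K <- carrying_capacity_solution(2, 0.1, 0.001, rep(1, n), rep(0, n), tg,
                                  rule = "trapezoid")
  expect_equal(K, 1 + (2 - 1) * exp(-0.1 * tg), tolerance = 1e-4)
  # constant population: K -> K0 - mu*rho/eta
  tg2 <- seq(0, 500, by = 0.05)
  n2 <- length(tg2)
  K2 <- carrying_capacity_solution(1, 0.1, 0.001, rep(1, n2),
                                   rep(0.99, n2), tg2, rule = "trapezoid")
  expect_equal(tail(K2, 1), 1 - 0.001 * 0.99 / 0.1, tolerance = 1e-4)
  expect_error(carrying_capacity_solution(1, 0.1, 0.001, rep(1, 5),
                                          rep(0, n), tg), "length")
})

test_that("culture solution: pure decay and pure accumulation limits", {
  tg <- seq(0, 500, by = 1)
  cc <- culture_solution(1, 0.01, 0, rep(1, 501), rep(0, 500), tg)
  expect_equal(cc, exp(-0.01 * tg))  # exact: no quadrature with sigma = 0
  # lam = 0: kernel is 1, plain left-endpoint accumulation
  rho <- runif(501)
  xi <- runif(500)
  cc0 <- culture_solution(0.5, 0, 2, rho, xi, tg)
  expect_equal(cc0, 0.5 + 2 * c(0, cumsum(rho[-501] * xi)))
  expect_error(culture_solution(1, 0.01, -1, rho, xi, tg), "sigma")
})

test_that("closed forms agree with the Euler integrator at O(dt)", {
  # sigma = 0 variants of all studied regimes, two step sizes
  for (nm in c("no_culture", "slow_recovery", "high_depletion",
               "no_loss", "no_depletion")) {
    base <- eco_regimes(n_steps = 100L)[[nm]]
    dev <- sapply(c(1, 0.5), function(dt) {
      p <- base
      p$sigma <- 0
      p$dt <- dt
      p$n_steps <- as.integer(2000 / dt)
      max(oracle_deviations(p))
    })
    # error shrinks roughly linearly in dt
    expect_lt(dev[2], dev[1])
    expect_gt(dev[1] / dev[2], 1.4)
    expect_lt(dev[1] / dev[2], 3)
  }
})

test_that("recorded innovations reproduce the stochastic culture path", {
  # the culture equation is linear in c, so the closed form with the
  # realized draws tracks the stochastic Euler path
  p <- std_params(n_steps = 20000L, seed = 5L)
  traj <- simulate_ecoculture(p)
  cc <- culture_solution(p$c0, p$lam, p$sigma, traj$rho, traj$xi, traj$t)
  expect_gt(max(traj$c), 1)  # the run actually had innovation bursts
  expect_lt(max(abs(cc - traj$c)) / max(traj$c), 0.02)
})
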