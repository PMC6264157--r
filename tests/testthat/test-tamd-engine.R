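test_that("extended potential reduces to V when the spring is relaxed or off", {
  sys <- sys_harmonic(k_w = 2, x0 = 0.5)
  pa <- tamd_params()
  expect_equal(extended_potential(1, 1, sys, pa), sys$potential(1))
  pa0 <- tamd_params(kappa = 1e-300)
  expect_equal(extended_potential(1, -3, sys, pa0), sys$potential(1),
               tolerance = 1e-12)
  # V = 0, theta = x, kappa = 100, x = 1, z = 0 -> 50
  flat <- system_model(1, function(x) 0, function(x) 0,
                       function(x) x[1], function(x) matrix(1, 1, 1))
  expect_equal(extended_potential(1, 0, flat, tamd_params()), 50)
  expect_error(extended_potential(c(1, 2), 0, sys, pa), "dimension")
})

test_that("declared gradients are validated against finite differences", {
  expect_error(
    system_model(1, potential = function(x) x[1]^2,
                 gradient = function(x) 3 * x[1],   # wrong by construction
                 cv = function(x) x[1],
                 cv_jacobian = function(x) matrix(1, 1, 1)),
    "mismatch")
})

test_that("deterministic stiff-spring step makes z track theta", {
  sys <- sys_harmonic(k_w = 1)
  pa <- tamd_params(seed = 1)
  st <- tamd_state(sys, x = 0.6, z = 0.5)
  # zero noise: drift of z is dt*kappa*(theta - z)/gamma_bar = 4e-4
  st2 <- tamd_step(st, sys, pa, noise_x = 0, noise_z = 0)
  expect_equal(st2$z - st$z, 0.002 * 100 * 0.1 / 50, tolerance = 1e-12)
  # theta = z exactly: z does not move
  st3 <- tamd_state(sys, x = 0.5, z = 0.5)
  st4 <- tamd_step(st3, sys, pa, noise_x = 0, noise_z = 0)
  expect_equal(st4$z, st3$z)
})

test_that("identical seeds give identical trajectories, different seeds diverge", {
  sys <- sys_double_well()
  r1 <- run_tamd(sys, tamd_params(seed = 5), 2000, record_every = 10)
  r2 <- run_tamd(sys, tamd_params(seed = 5), 2000, record_every = 10)
  expect_identical(r1$z, r2$z)
  expect_identical(r1$x, r2$x)
  r3 <- run_tamd(sys, tamd_params(seed = 6), 2000, record_every = 10)
  expect_false(identical(r1$z, r3$z))
})

test_that("the CV tracks theta more tightly as the spring stiffens", {
  sys <- sys_harmonic(k_w = 1)
  rms <- vapply(c(10, 100, 1000), function(kap) {
    pa <- tamd_params(kappa = kap, beta_bar_inv = 0.6, gamma_bar = 50,
                      seed = 9)
    r <- run_tamd(sys, pa, 5e4, record_every = 5)
    sqrt(mean((r$theta - r$z)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
  # adiabatic scaling: RMS ~ 1/sqrt(kappa), so each decade shrinks ~sqrt(10)
  expect_equal(rms[1] / rms[2], sqrt(10), tolerance = 0.25)
  expect_equal(rms[2] / rms[3], sqrt(10), tolerance = 0.25)
})

test_that("physical kinetic energy satisfies equipartition on a harmonic run", {
  # gamma = 5 ps^-1 keeps the velocity correlation time to ~0.2 ps so the
  # kinetic-energy average has a ~2% standard error over this run
  sys <- sys_harmonic(k_w = 1)
  pa <- tamd_params(gamma = 5, beta_bar_inv = 0.6, gamma_bar = 1, seed = 14)
  set.seed(pa$seed)
  st <- tamd_state(sys)
  ke <- numeric(5e4)
  for (i in seq_along(ke)) {
    st <- tamd_step(st, sys, pa)
    ke[i] <- 0.5 * sys$mass * st$v^2
  }
  expect_equal(mean(ke[-(1:2000)]), 0.5 * pa$beta_inv, tolerance = 0.05)
})

test_that("clamped-CV force average converges to the coupled-spring closed form", {
  # z clamped at x0 + delta: G -> -k_w*kappa*delta/(k_w + kappa)
  sys <- sys_harmonic(k_w = 10)
  pa <- tamd_params(gamma = 5, seed = 7)
  delta <- 1
  cal <- calibrate_gamma_bar(sys, pa, z_fixed = delta, duration = 800,
                             record_every = 5)
  target <- -10 * 100 * delta / 110
  expect_equal(unname(cal$G_final), target, tolerance = 0.05)
  expect_lt(cal$last_quarter_sd, abs(target) * 0.05)
  # symmetric clamp at the minimum: average force vanishes
  cal0 <- calibrate_gamma_bar(sys, pa, z_fixed = 0, duration = 800,
                              record_every = 5)
  expect_lt(abs(cal0$G_final), 0.5)
})

test_that("unstable CV friction settings are rejected up front", {
  expect_error(tamd_params(gamma_bar = 0.05), "unstable")
  expect_error(tamd_params(kappa = -1), "positive")
})

test_that("free energy of a box potential is flat and of a double well symmetric", {
  sysf <- sys_flat_box(half_width = 2)
  pf <- tamd_params(beta_bar_inv = 0.6, gamma_bar = 1, seed = 3)
  rf <- run_tamd(sysf, pf, 4e5, record_every = 10)
  fe <- free_energy_estimate(rf$z[, 1], bins = 15, beta_bar_inv = 0.6)
  core <- fe$F[abs(fe$z) < 1.5]
  expect_lt(max(core, na.rm = TRUE) - min(core, na.rm = TRUE), 0.3)

  sysd <- sys_double_well(h = 6)
  pd <- tamd_params(beta_bar_inv = 15, seed = 4)
  rd <- run_tamd(sysd, pd, 4e5, record_every = 10,
                 state = tamd_state(sysd, x = -1))
  fed <- free_energy_estimate(rd$z[, 1], bins = 31, beta_bar_inv = 15)
  f_at <- function(x0) fed$F[which.min(abs(fed$z - x0))]
  expect_lt(abs(f_at(-1) - f_at(1)), 1.5)
})

test_that("free energy estimation refuses underpowered input", {
  expect_error(free_energy_estimate(rnorm(100)), "1e4|10000")
})

test_that("center-of-group CVs average coordinates with a 1/N Jacobian", {
  cc <- make_center_cv(c(1L, 3L), n_points = 3L)
  x <- c(1, 2, 3, 10, 20, 30, 5, 6, 9)  # three points, flattened
  expect_equal(cc$cv(x), c(3, 4, 6))
  J <- cc$jacobian(x)
  expect_equal(dim(J), c(3L, 9L))
  expect_equal(J[1, 1], 0.5)
  expect_equal(rowSums(J), rep(1, 3))
})

test_that("the elastic-network dimer surrogate runs stably from its reference", {
  bn <- sys_bundle_network(ref_model, cutoff = 9)
  expect_equal(bn$system$n_cv, 12L)
  pa <- tamd_params(beta_bar_inv = 2, seed = 3)
  r <- run_tamd(bn$system, pa, 500, record_every = 10,
                state = tamd_state(bn$system, x = bn$x0))
  expect_true(all(is.finite(r$z)))
  expect_true(all(is.finite(r$U)))
  # at the reference the network is at its energy minimum
  expect_equal(bn$system$potential(bn$x0), 0)
  expect_lt(max(abs(bn$system$gradient(bn$x0))), 1e-10)
})

test_that("TAMD records can be written to and reread from CSV", {
  sys <- sys_harmonic()
  r <- run_tamd(sys, tamd_params(seed = 2), 500, record_every = 50)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tamd_record(r, f)
  back <- read.csv(f)
  expect_equal(back$t, r$t)
  expect_equal(back$z_1, r$z[, 1])
  expect_equal(back$U, r$U)
})
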