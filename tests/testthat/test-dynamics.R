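test_that("OU propagation has the exact stationary and diffusive limits", {
  set.seed(101)
  sp <- spring_params(k = 2, sigma = 0.8, x_eq = c(1, -2, 0.5))
  # k dt -> inf: stationary Gaussian with per-axis variance sigma^2 / (2 k)
  x0 <- matrix(5, 1e5, 3)
  x1 <- ou_propagate(x0, sp, dt = 50)
  v_stat <- 0.8^2 / (2 * 2)
  for (i in 1:3) {
    expect_within_se(mean(x1[, i]), sp$x_eq[i], sqrt(v_stat / 1e5), 4)
    expect_equal(var(x1[, i]), v_stat, tolerance = 4 * sqrt(2 / 1e5))
  }
  # k dt << 1: per-step variance ~ sigma^2 dt within 1%
  kdt <- 1e-4
  x2 <- ou_propagate(matrix(0, 4e4, 3), spring_params(k = 1, sigma = 1),
                     dt = kdt)
  expect_equal(var(x2[, 1]), kdt, tolerance = 0.015)
})

test_that("a long stationary OU trajectory decorrelates at rate k", {
  set.seed(102)
  k_true <- 1
  sp <- spring_params(k = k_true, sigma = 1)
  n <- 20000
  x <- matrix(rnorm(n * 3, 0, sqrt(1 / (2 * k_true))), n, 3)
  dt <- 0.1
  nlag <- 10
  series <- matrix(NA_real_, n, nlag + 1)
  series[, 1] <- x[, 1]
  for (l in seq_len(nlag)) {
    x <- ou_propagate(x, sp, dt)
    series[, l + 1] <- x[, 1]
  }
  rho <- vapply(seq_len(nlag), function(l) cor(series[, 1], series[, l + 1]), 0)
  fit <- lm(log(rho) ~ 0 + I((1:nlag) * dt))
  expect_equal(-unname(coef(fit)), k_true, tolerance = 0.05)
})

test_that("exact OU kernel matches a fine-step Euler-Maruyama oracle", {
  set.seed(103)
  for (kdt in c(0.01, 0.1, 1)) {
    sp <- spring_params(k = 1, sigma = 1.3, x_eq = c(0.7, 0, 0))
    n <- 1e4
    exact <- ou_propagate(matrix(2, n, 3), sp, dt = kdt)[, 1]
    orac <- euler_ou_sample(n, 2, 1, 1.3, 0.7, kdt)
    expect_gt(ks.test(exact, orac)$p.value, 0.01)
  }
})

test_that("stationary spring sampling honours mean, symmetry and anisotropy", {
  set.seed(104)
  iso <- spring_params(k = 0.5, sigma = 1, x_eq = c(3, 3, 3))
  s <- spring_equilibrium_sample(iso, 1e5)
  v <- apply(s, 2, var)
  for (i in 1:3) expect_within_se(mean(s[, i]), 3, sd(s[, i]) / sqrt(1e5), 4)
  expect_lt(max(v) / min(v), 1.05)
  aniso <- spring_params(k = 0.5, sigma = 1, p = 0.5, stiff_axis = 1L)
  sa <- spring_equilibrium_sample(aniso, 1e5)
  va <- apply(sa, 2, var)
  expect_equal(va[2] / va[1], 2, tolerance = 0.05)
  expect_equal(va[3] / va[1], 2, tolerance = 0.05)
  # stationary covariance is diagonal
  cv <- cov(sa)
  expect_lt(max(abs(cv[upper.tri(cv)])) / max(diag(cv)), 0.02)
})

test_that("pendulum drift root and restoring force behave deterministically", {
  tiny <- 1e-12
  par <- pendulum_params(k_r = 1, k_theta = 1, r_eq = 1, sigma_r = tiny,
                         sigma_theta = tiny, sigma_phi = tiny, c_r = 1)
  root <- (1 + sqrt(5)) / 2
  expect_equal(pendulum_rest_radius(par), root, tolerance = 1e-12)
  # the drift root is a fixed point at zero noise
  p <- pendulum_step(c(root, pi / 2, 0), par, dt = 0.01, n_steps = 500)
  expect_equal(unname(p[nrow(p), "r"]), root, tolerance = 1e-6)
  # a polar perturbation decays monotonically toward the pole
  p2 <- pendulum_step(c(root, 0.8, 0), par, dt = 0.01, n_steps = 300)
  expect_true(all(diff(p2[, "theta"]) < 1e-9))
  expect_lt(p2[nrow(p2), "theta"], 0.05)
})

test_that("noisy pendulum keeps a positive radius over long runs", {
  set.seed(105)
  par <- pendulum_params(k_r = 0.01, k_theta = 0.008, r_eq = 18.86,
                         sigma_r = 0.283, sigma_theta = 1.37, c_r = 1)
  p <- pendulum_step(c(pendulum_rest_radius(par), 1, 0), par, dt = 10,
                     n_steps = 5e4)
  expect_true(all(p[, "r"] > 0))
  expect_true(all(p[, "theta"] >= 0 & p[, "theta"] <= pi))
})

test_that("sphere stepping attains and preserves the uniform law", {
  set.seed(106)
  # long-trajectory cos(theta) is Uniform[-1, 1] on decorrelated samples
  v <- sphere_step(c(0.3, 0.2), D = 0.5, dt = 0.01, n_steps = 5e5)
  ct <- v[seq(5000, 5e5, by = 1000), 3]
  expect_gt(ks.test(ct, "punif", -1, 1)$p.value, 0.01)
  # one-step ensembles started from uniform stay uniform
  n <- 2e4
  z1 <- vapply(seq_len(n), function(i)
    sphere_step(c(acos(1 - 2 * runif(1)), 2 * pi * runif(1)),
                D = 0.2, dt = 0.05)[3], 0)
  expect_gt(ks.test(z1, "punif", -1, 1)$p.value, 0.01)
  # orientation norm preserved to 1e-9
  expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-9)
})

test_that("a pole start is regular and small-step MSD matches 4 D dt", {
  set.seed(107)
  out <- sphere_step(c(0, 0), D = 1, dt = 0.01)
  expect_true(all(is.finite(out)))
  expect_equal(sum(out^2), 1, tolerance = 1e-9)
  D <- 0.1; dt <- 0.001
  n <- 2e5
  start <- c(sin(0.8), 0, cos(0.8))
  ang2 <- vapply(seq_len(n), function(i) {
    m <- sphere_step(c(0.8, 0), D, dt)
    acos(min(1, max(-1, sum(m * start))))^2
  }, 0)
  expect_equal(mean(ang2), 4 * D * dt, tolerance = 0.02)
})

test_that("rotational diffusion follows the spherical Stokes-Einstein form", {
  expect_equal(rotational_diffusion_coefficient(1, 1 / (8 * pi), 1), 1)
  D1 <- rotational_diffusion_coefficient(4.11, 0.9, 5)
  expect_equal(rotational_diffusion_coefficient(4.11, 0.9, 10), D1 / 8)
  expect_gt(D1, 0)
  rp <- rotation_params(kT = 4.11, viscosity = 0.9, R_h = 5)
  expect_equal(rp$D_donor, D1)
})

test_that("coordinate conversions round-trip to tight tolerance", {
  set.seed(108)
  for (i in 1:50) {
    x <- rnorm(3)
    expect_equal(unname(spherical_to_cartesian(cartesian_to_spherical(x))), x,
                 tolerance = 1e-10)
  }
})

test_that("dye-pair trajectories honour degenerate and exchangeable limits", {
  set.seed(109)
  tiny <- 1e-30
  don <- spring_params(k = 1, sigma = tiny, x_eq = c(0, 0, 0))
  acc <- spring_params(k = 1, sigma = tiny, x_eq = c(50, 0, 0))
  tr <- simulate_dye_pair("isotropic", duration = 100,
                          timescales = timescale_config(1, 0.01),
                          donor = don, acceptor = acc,
                          rotation = rotation_params(D = tiny))
  expect_lt(max(abs(tr$distance - tr$distance[1])), 1e-9)
  expect_lt(max(abs(sweep(tr$mu_donor, 2, tr$mu_donor[1, ]))), 1e-9)
  # seed swap changes paths, not the stationary summaries
  cfgd <- fret_config("isotropic")
  mk <- function(seed) {
    set.seed(seed)
    simulate_dye_pair("isotropic", duration = 1e5,
                      timescales = timescale_config(10, 1),
                      rotation = rotation_params(D = 0.01),
                      orientational_stride = 100L)
  }
  t1 <- mk(1); t2 <- mk(2)
  expect_false(isTRUE(all.equal(t1$distance, t2$distance)))
  # stationary summaries agree within sampling error of the burst means
  expect_equal(mean(t1$distance), mean(t2$distance), tolerance = 0.05)
})

test_that("spring inter-dye distances are unimodal", {
  set.seed(110)
  cfg <- fret_config("isotropic")
  spD <- fretsim:::.spring_from_config(cfg, c(0, 0, 0), "isotropic")
  spA <- fretsim:::.spring_from_config(cfg, c(50, 0, 0), "isotropic")
  d <- sqrt(rowSums((spring_equilibrium_sample(spA, 4000) -
                       spring_equilibrium_sample(spD, 4000))^2))
  expect_gt(silverman_test(d, n_boot = 100)$p_value, 0.05)
})

test_that("time-scale ordering is enforced", {
  expect_error(timescale_config(0.001, 0.1), "ordering")
  expect_error(ou_propagate(c(0, 0, 0), spring_params(1, 1), dt = -1), "dt")
})
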