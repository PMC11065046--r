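pp <- photophysics_params(k_D = 0.25, k_A = 0.5, R0_ref = 50)

test_that("kappa reproduces the canonical dipole geometries", {
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  expect_equal(kappa_factor(ex, ex, ex), -2)   # collinear: kappa^2 = 4
  expect_equal(kappa_factor(ex, ey, ez), 0)    # mutually orthogonal: no transfer
  expect_equal(kappa_factor(ey, ey, ex), 1)    # parallel, perpendicular to r
  expect_error(kappa_factor(c(1, 1, 0), ex, ex), "unit")
})

test_that("kappa^2 is bounded in [0, 4] over random orientations", {
  set.seed(201)
  for (i in 1:2000) {
    u <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
    k <- kappa_factor(u(), u(), u())
    expect_gte(k^2, 0); expect_lte(k^2, 4)
  }
})

test_that("uniform independent dipoles average kappa^2 to 2/3", {
  set.seed(202)
  n <- 5e4
  k2 <- vapply(seq_len(n), function(i) {
    u <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
    kappa_factor(u(), u(), u())^2
  }, 0)
  expect_within_se(mean(k2), 2 / 3, sd(k2) / sqrt(n), 3)
})

test_that("Forster radius and transfer rate scale as the theory dictates", {
  expect_equal(forster_radius6(pp$C, 0), 0)
  expect_equal(forster_radius6(pp$C, 2 / 3), pp$R0_ref^6)
  expect_equal(forster_radius6(pp$C, 1.2), 2 * forster_radius6(pp$C, 0.6))
  expect_equal(transfer_rate(50, 2 / 3, pp), pp$k_D)
  expect_equal(transfer_rate(25, 2 / 3, pp), 64 * pp$k_D)
  expect_lt(transfer_rate(1e4, 2 / 3, pp), 1e-10)
  expect_error(transfer_rate(0, 2 / 3, pp), "caller")
  expect_error(forster_radius6(pp$C, 5), "0, 4")
})

test_that("static efficiency has its defining closed-form values", {
  expect_identical(static_efficiency(pp$R0_ref, pp), 0.5)
  expect_identical(static_efficiency(0, pp), 1)
  expect_equal(static_efficiency(2 * pp$R0_ref, pp), 1 / 65)
})

test_that("integrated hazard is exact on degenerate paths and refined grids", {
  flat0 <- kappa_path(c(0, 10), c(0, 0), 50)
  expect_equal(integrated_hazard(flat0, c(0, 5, 10), pp), c(0, 0, 0))
  cst <- kappa_path(c(0, 10), c(2 / 3, 2 / 3), 50)
  expect_equal(integrated_hazard(cst, c(0, 2.5, 10), pp),
               pp$k_D * c(0, 2.5, 10))
  set.seed(203)
  path <- kappa_path(seq(0, 20, length.out = 21), runif(21, 0, 4), 45)
  fine <- kappa_path(seq(0, 20, length.out = 201),
                     approx(path$times, path$kappa_sq,
                            seq(0, 20, length.out = 201))$y, 45)
  tq <- seq(0.3, 19.7, length.out = 37)
  expect_equal(integrated_hazard(path, tq, pp), integrated_hazard(fine, tq, pp),
               tolerance = 1e-6)
  # monotone nondecreasing with H(0) = 0
  H <- integrated_hazard(path, seq(0, 20, by = 0.1), pp)
  expect_equal(H[1], 0)
  expect_true(all(diff(H) >= -1e-12))
})

test_that("path-history efficiency reduces to the homogeneous closed forms", {
  cst <- kappa_path(c(0, 40), c(2 / 3, 2 / 3), pp$R0_ref)
  # constant k_ET = k_D (r = R0, kappa^2 = 2/3): efficiency 1/2 for all T
  expect_equal(time_dependent_efficiency(cst, c(1, 5, 40), pp),
               rep(0.5, 3))
  zero <- kappa_path(c(0, 40), c(0, 0), 50)
  expect_equal(time_dependent_efficiency(zero, 10, pp), 0)
  half <- kappa_path(c(0, 10, 10 + 1e-9, 40), c(2 / 3, 2 / 3, 0, 0), pp$R0_ref)
  expect_equal(time_dependent_efficiency(half, 20, pp), 1 / 3, tolerance = 1e-6)
  # homogeneous consistency with the static formula at any distance
  for (r in c(40, 50, 60)) {
    p <- kappa_path(c(0, 40), c(2 / 3, 2 / 3), r)
    expect_equal(time_dependent_efficiency(p, 17, pp), static_efficiency(r, pp),
                 tolerance = 1e-12)
  }
  expect_error(time_dependent_efficiency(cst, 100, pp), "cover")
})

test_that("the rate matrix is a proper generator with absorbing photon states", {
  Q <- build_rate_matrix(0.7, pp)
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
  expect_equal(Q["D", "A"], 0.7)
  expect_true(all(Q[c("FD", "FA"), ] == 0))
  Q0 <- build_rate_matrix(0, pp)
  expect_equal(Q0["D", "FD"], pp$k_D)
  expect_equal(Q0["D", "A"], 0)
  expect_error(build_rate_matrix(-1, pp), "nonnegative")
})

test_that("sampler state occupation matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(204)
  kET <- pp$k_D
  t_eval <- 1 / pp$k_D
  P <- as.matrix(Matrix::expm(build_rate_matrix(kET, pp) * t_eval))
  n <- 4e4
  ev <- sample_excitation_events(n, pp$R0_ref, pp, "static")
  acc_dwell <- ifelse(ev$outcome == "acceptor_photon",
                      ev$emission_delay - ev$donor_dwell, Inf)
  state <- ifelse(ev$donor_dwell > t_eval, "D",
            ifelse(ev$outcome == "donor_photon", "FD",
             ifelse(ev$donor_dwell + acc_dwell > t_eval, "A", "FA")))
  for (s in c("D", "A", "FD", "FA")) {
    p_emp <- mean(state == s)
    expect_within_se(p_emp, P["D", s], sqrt(P["D", s] * (1 - P["D", s]) / n), 3.5)
  }
})

test_that("homogeneous excitation events have exponential competing exits", {
  set.seed(205)
  n <- 2e4
  ev <- sample_excitation_events(n, pp$R0_ref, pp, "static")
  ktot <- 2 * pp$k_D
  p_donor <- mean(ev$outcome == "donor_photon")
  expect_within_se(p_donor, 0.5, sqrt(0.25 / n), 3)
  expect_gt(ks.test(ev$donor_dwell, "pexp", ktot)$p.value, 0.01)
  # the static path mean is the configured kappa^2
  expect_equal(unique(ev$path_mean_kappa_sq), 2 / 3)
})

test_that("zero separation reduces the chain to the acceptor two-state system", {
  set.seed(206)
  n <- 5e3
  ev <- sample_excitation_events(n, 0, pp, "static")
  expect_true(all(ev$outcome == "acceptor_photon"))
  expect_gt(ks.test(ev$emission_delay, "pexp", pp$k_A)$p.value, 0.01)
})

test_that("donor-only control recovers the bare donor lifetime", {
  set.seed(207)
  n <- 2e4
  ev <- sample_excitation_events(n, 50, pp, "static", kappa_sq = 0)
  expect_true(all(ev$outcome == "donor_photon"))
  expect_within_se(mean(ev$emission_delay), 1 / pp$k_D,
                   sd(ev$emission_delay) / sqrt(n), 3)
})

test_that("frozen-dipole dynamic events match their homogeneous limit", {
  set.seed(208)
  dip <- rbind(c(1.1, 0.4), c(2.0, 2.5))
  mu <- function(a) c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
  k2 <- kappa_factor(mu(dip[1, ]), mu(dip[2, ]), c(1, 0, 0))^2
  ktot <- pp$k_D + transfer_rate(50, k2, pp)
  n <- 5e3
  dw <- vapply(seq_len(n), function(i)
    sample_excitation_event(50, pp, "dynamic",
                            rotation = list(D_donor = 0, D_acceptor = 0),
                            dipoles = dip)$donor_dwell, 0)
  expect_gt(ks.test(dw, "pexp", ktot)$p.value, 0.01)
})

test_that("thinning and hazard-inversion dwell samplers agree on random paths", {
  set.seed(209)
  for (i in 1:20) {
    path <- random_kappa_path(t_max = 200, n_knots = 80,
                              r = runif(1, 40, 65))
    a <- thinning_dwell(5000, path, pp)
    b <- inversion_dwell(5000, path, pp)
    expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.001)
  }
})

test_that("dynamic-event dwell survival matches exp(-k_D t - H(t))", {
  set.seed(210)
  # oscillating kappa^2 path, checked through the R-level thinning sampler
  tt <- seq(0, 200, length.out = 400)
  path <- kappa_path(tt, 2 / 3 + 0.5 * sin(2 * pi * tt / 7), 50)
  dw <- thinning_dwell(2e4, path, pp)
  tg <- seq(0.5, 15, length.out = 30)
  S_emp <- vapply(tg, function(t) mean(dw > t), 0)
  S_the <- exp(-pp$k_D * tg - integrated_hazard(path, tg, pp))
  expect_lt(max(abs(S_emp - S_the)), 0.01)
})

test_that("photophysics parameterisation ties C and the reference radius", {
  p2 <- photophysics_params(C = pp$C)
  expect_equal(p2$R0_ref, pp$R0_ref)
  expect_equal(pp$R0_ref^6, pp$C * 2 / 3)
  expect_error(photophysics_params(k_D = -1), "k_D")
})
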