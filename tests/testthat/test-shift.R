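test_that("dynamic shift evaluates its defining geometry", {
  expect_equal(dynamic_shift(0.5, 0.5, "printed"), 0)
  expect_equal(dynamic_shift(0.5, 0.5, "perpendicular"), 0)
  expect_equal(dynamic_shift(0.8, 0.6, "printed"), 0.4)   # denominator is 1
  expect_equal(dynamic_shift(1, 1, "printed"), 1 / sqrt(2))
  expect_equal(dynamic_shift(1, 1, "perpendicular"), 1 / sqrt(2))
  expect_error(dynamic_shift(0, 0, "printed"), "undefined")
  expect_equal(dynamic_shift(0, 0, "perpendicular"), -1 / sqrt(2))
})

test_that("the shift vanishes on the static line and is signed across it", {
  set.seed(401)
  E <- runif(1e4)
  tau <- 1 - E
  for (v in c("printed", "perpendicular")) {
    expect_equal(dynamic_shift(E[E + tau > 0], tau[E + tau > 0], v),
                 rep(0, sum(E + tau > 0)), tolerance = 1e-12)
  }
  E2 <- runif(500, 0.05, 0.95)
  above <- dynamic_shift(E2, 1 - E2 + 0.05)
  below <- dynamic_shift(E2, 1 - E2 - 0.05)
  expect_true(all(above > 0)); expect_true(all(below < 0))
  expect_true(all(dynamic_shift(E2, 1 - E2 + 0.05, "perpendicular") > 0))
  expect_true(all(dynamic_shift(E2, 1 - E2 - 0.05, "perpendicular") < 0))
})

test_that("shift distributions summarise usable bursts", {
  df <- data.frame(E_intensity = c(0.4, 0.6, 0.7), tau_norm = c(0.6, 0.4, 0.3),
                   usable = TRUE)
  sh <- shift_distribution(df)
  expect_equal(sh$mu, 0); expect_equal(sh$sigma, 0); expect_equal(sh$n, 3)
  expect_error(shift_distribution(df[0, ]), "empty|bursts")
  # mean and sd recomputable from the stored values
  df2 <- data.frame(E_intensity = runif(50, 0.3, 0.9),
                    tau_norm = runif(50, 0.3, 0.9), usable = TRUE)
  sh2 <- shift_distribution(df2)
  expect_equal(sh2$mu, mean(sh2$delta))
  expect_equal(sh2$sigma, sd(sh2$delta))
})

test_that("moment-difference projection matches a dense-grid oracle", {
  set.seed(402)
  pts <- cbind(runif(25), runif(25, -0.2, 0.45))
  tg <- seq(-1.5, 2.5, length.out = 1e6)
  curve_y <- tg * (1 - tg)
  for (i in seq_len(nrow(pts))) {
    x0 <- pts[i, 1]; y0 <- pts[i, 2]
    d_grid <- sqrt(min((tg - x0)^2 + (curve_y - y0)^2))
    d_fn <- fretsim:::.parabola_signed_distance(x0, y0)
    expect_equal(abs(d_fn), d_grid, tolerance = 1e-6)
    expect_equal(sign(d_fn), sign(y0 - x0 * (1 - x0)))
  }
})

test_that("static coordinates have zero moment difference; mixing is negative", {
  df <- data.frame(E_I = c(0.3, 0.5, 0.8), E_tau = c(0.3, 0.5, 0.8))
  expect_equal(moment_difference_shift(df), rep(0, 3), tolerance = 1e-8)
  set.seed(403)
  ts <- two_state_reference(0.25, 0.75, lambda = 2e-4, n_bursts = 300,
                            n_events = 400)
  md <- moment_difference_shift(data.frame(E_I = ts$bursts$E_intensity,
                                           E_tau = 1 - ts$bursts$tau_norm))
  expect_lt(mean(md, na.rm = TRUE), 0)
})

test_that("Jensen bounds order the mixture lifetimes", {
  jb <- jensen_bounds(c(1, 3), c(0.5, 0.5))
  expect_equal(jb$mean_lifetime, 2 / 3)
  expect_equal(jb$lifetime_of_mean_rate, 1 / 2)
  expect_equal(jb$gap, 1 / 6)
  expect_equal(jensen_bounds(c(2, 2, 2))$gap, 0)
  set.seed(404)
  for (i in 1:1e4) {
    m <- sample(2:5, 1)
    w <- rexp(m); w <- w / sum(w)
    expect_gte(jensen_bounds(rexp(m) + 0.01, w)$gap, -1e-12)
  }
})

test_that("two-state bursts travel the mixing arc as exchange accelerates", {
  set.seed(405)
  E1 <- 0.3; E2 <- 0.8
  tau1 <- 1 - E1; tau2 <- 1 - E2
  # slow exchange: bursts concentrate at the two static points
  slow <- two_state_reference(E1, E2, lambda = 1e-9, n_bursts = 200,
                              n_events = 400)
  d1 <- sqrt((slow$bursts$E_intensity - E1)^2 + (slow$bursts$tau_norm - tau1)^2)
  d2 <- sqrt((slow$bursts$E_intensity - E2)^2 + (slow$bursts$tau_norm - tau2)^2)
  expect_gt(mean(pmin(d1, d2) < 0.1, na.rm = TRUE), 0.95)
  expect_gt(sum(d1 < d2, na.rm = TRUE), 20)
  expect_gt(sum(d2 < d1, na.rm = TRUE), 20)
  # fast exchange: a point mass off the static line at the arc maximum
  fast <- two_state_reference(E1, E2, lambda = 1, n_bursts = 200,
                              n_events = 400)
  expect_lt(sd(fast$bursts$E_intensity), 0.05)
  expect_within_se(mean(fast$bursts$E_intensity), (E1 + E2) / 2,
                   sd(fast$bursts$E_intensity) / sqrt(200), 4)
  expect_within_se(mean(fast$bursts$tau_norm, na.rm = TRUE),
                   (tau1^2 + tau2^2) / (tau1 + tau2),
                   sd(fast$bursts$tau_norm) / sqrt(200), 4)
  expect_gt(mean(dynamic_shift(fast$bursts$E_intensity,
                               fast$bursts$tau_norm)), 0.05)
  # every mixing degree lies on the closed-form arc (the ensemble mean
  # point is compared on-arc; per-burst residuals carry shot noise plus a
  # small curvature bias of the check itself)
  for (lam in c(2e-4, 1e-3)) {
    mid <- two_state_reference(E1, E2, lambda = lam, n_bursts = 300,
                               n_events = 400)
    expect_equal(mean(mid$bursts$E_intensity),
                 mid$arc(mean(mid$bursts$tau_norm, na.rm = TRUE)),
                 tolerance = 0.02)
    resid <- mid$bursts$E_intensity - mid$arc(mid$bursts$tau_norm)
    expect_lt(abs(mean(resid, na.rm = TRUE)), 0.025)
  }
  # arc endpoints are the static points
  expect_equal(slow$arc(tau1), E1, tolerance = 1e-12)
  expect_equal(slow$arc(tau2), E2, tolerance = 1e-12)
})

test_that("kappa^2 path ensembles reproduce the rotational-regime contrasts", {
  D_tr <- 1e-4   # angular scale of the dye's translational diffusion
  fast <- simulate_kappa_paths(4000, 1, D_donor = 1000 * D_tr, seed = 406)
  slow <- simulate_kappa_paths(2000, 1, D_donor = 10 * D_tr, seed = 407)
  sf <- kappa_path_statistics(fast)
  ss <- kappa_path_statistics(slow)
  # the grand mean stays at the dynamic-averaging value in every regime
  for (s in list(sf, ss))
    expect_within_se(s$global_mean, 2 / 3, sd(s$path_mean) / sqrt(s$n_paths), 3)
  # fast-fast: clustered oscillations give a multi-modal path-average
  # distribution whose principal mode sits below 2/3
  expect_gte(sf$n_modes, 2L)
  expect_lt(sf$mode, 2 / 3)
  # slower rotation keeps temporal correlation at every lag up to 1 ns
  expect_true(all(ss$acf$correlation[-1] > sf$acf$correlation[-1]))
})

test_that("kappa_path lists are accepted and path means are exact averages", {
  p1 <- kappa_path(seq(0, 1, by = 0.01), rep(0.5, 101), 50)
  p2 <- kappa_path(seq(0, 1, by = 0.01), seq(0, 2, length.out = 101), 50)
  st <- kappa_path_statistics(c(replicate(60, p1, simplify = FALSE),
                                replicate(60, p2, simplify = FALSE)))
  expect_equal(st$global_mean, (0.5 + 1) / 2, tolerance = 1e-6)
})
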