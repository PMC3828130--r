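test_that("bound-pair detection applies the energy threshold and matching", {
  st <- pair_system(c(0, 0, 2^(1 / 6) * 0.75), epsilon = 5)
  expect_equal(nrow(detect_bound_pairs(st)), 1)        # V = -eps < -eps/2
  st <- pair_system(c(0, 0, 2.5))
  expect_equal(nrow(detect_bound_pairs(st)), 0)        # beyond r_cut
  expect_error(detect_bound_pairs(st, 1.5), "threshold")
})

test_that("a ligand within reach of two receptors binds exactly one", {
  species <- list(L = species_spec("L", 0.5, diffusion = 0.1),
                  R = species_spec("R", 1, diffusion = 0,
                                   domain = "membrane2d"))
  interactions <- list(list(
    a = "L", b = "R",
    spec = interaction_spec("angular_lj", epsilon = 5, sigma_pair = 0.75,
                            n_geom = 0)))
  # ligand midway above two receptors 1.2 sigma apart: both within r_cut
  pos <- rbind(c(5.6, 5, 0.8), c(5, 5, 0), c(6.2, 5, 0))
  st <- cg_system(pos, species_index = c(1L, 2L, 2L), species = species,
                  interactions = interactions, box = box_spec(10, 10, 6))
  # oracle: both pair energies below threshold, detection must pick the lower
  e2 <- angular_lj(pos[1, ] - pos[2, ], c(0, 0, 1), interactions[[1]]$spec)$energy
  e3 <- angular_lj(pos[1, ] - pos[3, ], c(0, 0, 1), interactions[[1]]$spec)$energy
  expect_lt(max(e2, e3), -2.5)
  bp <- detect_bound_pairs(st)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$receptor, c(2, 3)[which.min(c(e2, e3))])
})

test_that("complex time series track scripted binding events", {
  set.seed(3)
  traj <- make_scripted_trajectory(n_complexes = 6,
                                   unbind_at = c(`1` = 2, `2` = 4, `3` = 4),
                                   n_frames = 6)
  s <- complex_timeseries(traj, times = 0:5)
  expect_equal(s$count, c(6, 5, 5, 3, 3, 3))
  expect_error(complex_timeseries(list()), "empty")
  expect_error(complex_timeseries(traj[1]), "2 frames")
})

test_that("koff is recovered exactly from a noise-free exponential", {
  s <- make_decay_series(koff = 0.05, C0 = 200,
                         times = seq(0, 60, length.out = 80))
  est <- estimate_koff(s)
  expect_equal(est$value, 0.05, tolerance = 1e-6)
  expect_gt(est$gof, 0.9999)
  expect_equal(est$fit_model, "exp_decay")
})

test_that("koff of a constant series is zero, with a warning", {
  s <- cgligand:::new_series(0:10, rep(50, 11),
                             matrix(rep(50, 11), ncol = 1), 1L)
  expect_warning(est <- estimate_koff(s), "does not decay")
  expect_equal(est$value, 0)
  expect_error(estimate_koff(cgligand:::new_series(0:3, rep(0, 4),
                                                   matrix(0, 4, 1), 1L)),
               "all-zero")
})

test_that("koff from noisy Markov ensembles lands within two standard errors", {
  set.seed(17)
  for (k_true in c(0.02, 0.1)) {
    s <- make_decay_series(koff = k_true, C0 = 200,
                           times = seq(0, 3 / k_true, length.out = 60),
                           noise = "markov", n_replicates = 20)
    est <- estimate_koff(s)
    expect_lt(abs(est$value - k_true), 2.5 * max(est$stderr, 0.02 * k_true))
  }
})

test_that("kon short-time estimator inverts the linear growth exactly", {
  conc <- 2e-3; r_tot <- 100; kon_true <- 0.4
  slope <- kon_true * conc * r_tot
  s <- make_linear_series(slope, times = seq(0, 100, length.out = 40))
  est <- estimate_kon_short_time(s, conc, r_tot)
  expect_equal(est$value, kon_true, tolerance = 1e-10)
  # zero slope
  s0 <- make_linear_series(0)
  expect_equal(estimate_kon_short_time(s0, conc, r_tot)$value, 0)
  expect_error(estimate_kon_short_time(
    cgligand:::new_series(0:1, c(0, 50), matrix(c(0, 50), ncol = 1), 1L),
    conc, r_tot), "3 points")
})

test_that("the short-time window stops at 20% occupancy on saturating data", {
  conc <- 5e-3; r_tot <- 50; kon_true <- 0.5
  for (koff_true in c(0, 0.002, 0.005)) {
    s <- make_saturating_series(kon_true, koff_true, conc, r_tot,
                                times = seq(0, 600, length.out = 600))
    est <- estimate_kon_short_time(s, conc, r_tot)
    expect_equal(est$value, kon_true, tolerance = 0.05)
    expect_lte(max(s$count[s$time <= est$fit_window[2]]), 0.2 * r_tot + 1e-9)
  }
  # the uncorrected line carries the documented truncation bias
  s <- make_saturating_series(kon_true, 0, conc, r_tot,
                              times = seq(0, 600, length.out = 600))
  raw <- estimate_kon_short_time(s, conc, r_tot, curvature = FALSE)
  expect_lt(raw$value, 0.95 * kon_true)
})

test_that("equilibrium kon matches the mass-action oracle", {
  conc <- 4e-3; r_tot <- 80; kon_true <- 0.3; koff_true <- 2e-3
  # independent oracle: numerical integration of the mass-action ODE
  ode <- function(t0, t1, n = 20000) {
    dt <- (t1 - t0) / n; C <- 0; out <- numeric(n + 1)
    for (i in seq_len(n))
      out[i + 1] <- C <- C + dt * (kon_true * conc * (r_tot - C) -
                                     koff_true * C)
    out[seq(1, n + 1, by = n / 200)]
  }
  tt <- seq(0, 4000, length.out = 201)
  y <- ode(0, 4000)
  s <- cgligand:::new_series(tt, y, matrix(y, ncol = 1), 1L)
  est <- estimate_kon_equilibrium(s, koff_true, conc, r_tot)
  expect_equal(est$value, kon_true, tolerance = 0.01)
  # half-occupancy identity: C_eq = R/2 => kon = koff / [L]
  yh <- c(seq(0, 40, length.out = 50), rep(40, 150))
  sh <- cgligand:::new_series(seq_along(yh), yh, matrix(yh, ncol = 1), 1L)
  esth <- estimate_kon_equilibrium(sh, koff_true, conc, r_tot)
  expect_equal(esth$value, koff_true / conc, tolerance = 1e-10)
  # no plateau -> error
  sr <- make_linear_series(1, times = seq(0, 50, length.out = 60))
  expect_error(estimate_kon_equilibrium(sr, koff_true, conc, r_tot),
               "plateau")
  # zero equilibrium count -> zero rate
  s0 <- cgligand:::new_series(0:20, rep(0, 21), matrix(0, 21, 1), 1L)
  expect_equal(estimate_kon_equilibrium(s0, koff_true, conc, r_tot)$value, 0)
})

test_that("rate-versus-diffusion fits recover linear structure", {
  df <- tibble::tibble(D = c(0.05, 0.1, 0.15, 0.2),
                       value = 2.5 * D + 0.01)
  fit <- rate_vs_diffusion(df)
  expect_equal(fit$slope, 2.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  flat <- rate_vs_diffusion(tibble::tibble(D = 1:4 / 10, value = rep(3, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(rate_vs_diffusion(df[1:2, ]), "3 distinct")
  # transport composition k_meas = k_int k_T / (k_int + k_T), k_T = c D:
  # in the diffusion-limited regime the fitted slope approaches c
  cc <- 5; k_int <- 100
  D <- seq(0.02, 0.2, length.out = 6)
  k_meas <- k_int * cc * D / (k_int + cc * D)
  fit2 <- rate_vs_diffusion(tibble::tibble(D = D, value = k_meas))
  expect_equal(fit2$slope, cc, tolerance = 0.02)
})

test_that("transport decomposition inverts the rate composition", {
  expect_equal(transport_decomposition(0.3, 1e12), 0.3, tolerance = 1e-6)
  expect_equal(transport_decomposition(0.5, 1), 1)     # k_meas = k_T/2
  k <- transport_decomposition(0.999, 1)
  expect_gt(k, 500)                                    # diffusion-limited blow-up
  expect_gte(transport_decomposition(0.2, 0.5), 0.2)   # k_int >= k_meas
  expect_error(transport_decomposition(1.2, 1), "unphysical")
  expect_error(transport_decomposition(0, 1), "positive")
})

test_that("rate estimates expose broom-style summaries", {
  est <- rate_estimate(0.05, 0.002, "exp_decay", c(0, 100), 0.99, 50L)
  td <- generics::tidy(est)
  expect_equal(td$estimate, 0.05)
  gl <- generics::glance(est)
  expect_equal(gl$r.squared, 0.99)
  expect_equal(gl$fit.model, "exp_decay")
})

test_that("simulated dissociation is statistically a two-state Markov process", {
  # isotropic patch: the bound state mixes fast, so after thermalization
  # escape must be a memoryless two-state process under the -eps/2
  # binding criterion
  spec <- experiment_spec("dissociation", n_receptors = 100,
                          surface_density = 0.01, box_height = 20,
                          epsilon = 5, n_geom = 0, n_replicates = 4,
                          seed = 55, n_steps = 2e4, sample_interval = 100)
  out <- simulate_dissociation(spec)
  s <- out$series
  # restrict to the fit window: beyond the shot-noise floor the count is
  # dominated by transient background contacts, not surviving complexes
  t_max <- out$koff$fit_window[2]
  keep <- s$time <= t_max
  surv_md <- s$count[keep] / s$count[1]
  n_md <- round(s$count[1] * spec$n_replicates)  # complexes alive at t = 0
  # two-state Markov oracle: survival of independent complexes with the
  # fitted rate, on the same time grid
  set.seed(56)
  n_mk <- 4000
  lifetimes <- rexp(n_mk, out$koff$value)
  surv_mk <- vapply(s$time[keep], function(t) mean(lifetimes > t),
                    numeric(1))
  # Kolmogorov-Smirnov distance between the survival curves against the
  # two-sample critical value at alpha = 0.01
  D <- max(abs(surv_md - surv_mk))
  D_crit <- 1.628 * sqrt(1 / n_md + 1 / n_mk)
  expect_lt(D, D_crit)
})
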