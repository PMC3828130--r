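test_that("WCA potential matches its closed form and is purely repulsive", {
  sp <- interaction_spec("wca", epsilon = 1, sigma_pair = 1)
  rc <- 2^(1 / 6)
  expect_equal(wca(rc, sp)$energy, 0)
  expect_equal(wca(rc, sp)$force, 0, tolerance = 1e-12)
  expect_equal(wca(1, sp)$energy, 1)            # 4(1-1) + eps
  expect_equal(wca(1.2 * rc, sp)$energy, 0)
  r <- seq(0.8, 1.5, by = 0.01)
  expect_true(all(wca(r, sp)$energy >= 0))
  # continuity at the cutoff
  expect_lt(wca(rc - 1e-8, sp)$energy, 1e-6)
  expect_error(wca(0, sp), "positive")
  expect_error(wca(-1, sp), "positive")
})

test_that("steric cross-repulsion uses the mixed diameter", {
  sp <- interaction_spec("wca", epsilon = 1, sigma_pair = 0.7)
  r <- seq(0.5, 1.1, by = 0.05)
  expect_equal(steric_cross(r, 0.7, 0.7)$energy, wca(r, sp)$energy)
  sij <- (0.5 + 1) / 2
  expect_equal(steric_cross(2^(1 / 6) * sij, 0.5, 1)$energy, 0)
  expect_equal(steric_cross(0.75, 0.5, 1)$energy, 1)   # r = sigma_ij
  expect_true(all(steric_cross(seq(0.4, 2, 0.05), 0.5, 1)$energy >= 0))
})

test_that("angular LJ reproduces the on-axis well, cone and cutoff contracts", {
  sigLR <- 0.75
  sp <- interaction_spec("angular_lj", epsilon = 5, sigma_pair = sigLR,
                         n_geom = 2, theta_cut = pi / 3)
  rmin <- 2^(1 / 6) * sigLR
  # on-axis minimum: -eps up to the cutoff shift
  e0 <- angular_lj(c(0, 0, rmin), c(0, 0, 1), sp)$energy
  shift <- 4 * 5 * ((sigLR / sp$r_cut)^6 - (sigLR / sp$r_cut)^12)
  expect_equal(e0, -5 + shift, tolerance = 1e-12)
  expect_equal(e0, -5, tolerance = 0.02)
  # outside the cone: repulsive only, at any distance
  for (r in c(0.7, rmin, 1.5, 1.8)) {
    th <- sp$theta_cut + 0.1
    v <- angular_lj(r * c(sin(th), 0, cos(th)), c(0, 0, 1), sp)
    expect_gte(v$energy, 0)
  }
  # zero at the cutoff for every angle
  for (th in c(0, 0.4, 1.0, 2.0)) {
    v <- angular_lj(sp$r_cut * c(sin(th), 0, cos(th)), c(0, 0, 1), sp)
    expect_equal(v$energy, 0)
  }
  # continuity approaching the cutoff
  e_in <- angular_lj(c(0, 0, sp$r_cut - 1e-9), c(0, 0, 1), sp)$energy
  expect_lt(abs(e_in), 1e-6)
  # doubling n at theta = theta_c / 2 weakens the attraction
  th <- sp$theta_cut / 2
  rv <- rmin * c(sin(th), 0, cos(th))
  sp4 <- interaction_spec("angular_lj", epsilon = 5, sigma_pair = sigLR,
                          n_geom = 4, theta_cut = pi / 3)
  expect_gt(angular_lj(rv, c(0, 0, 1), sp4)$energy,
            angular_lj(rv, c(0, 0, 1), sp)$energy)
  # errors
  expect_error(angular_lj(c(0, 0, 0), c(0, 0, 1), sp), "zero-length")
  expect_error(angular_lj(c(0, 0, 1), c(0, 0, 2), sp), "unit")
})

test_that("isotropic convention reduces the angular potential to shifted LJ", {
  sigLR <- 0.75; eps <- 3
  sp <- interaction_spec("angular_lj", epsilon = eps, sigma_pair = sigLR,
                         n_geom = 0, theta_cut = pi / 2)
  shifted_lj <- function(r) {
    4 * eps * ((sigLR / r)^12 - (sigLR / r)^6) -
      4 * eps * ((sigLR / sp$r_cut)^12 - (sigLR / sp$r_cut)^6)
  }
  set.seed(7)
  for (k in 1:20) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    r <- runif(1, 0.7, sp$r_cut - 1e-6)
    expect_equal(angular_lj(r * u, c(0, 0, 1), sp)$energy, shifted_lj(r),
                 tolerance = 1e-12)
  }
})

test_that("angular weight narrows monotonically with theta and sharpens with n", {
  thc <- pi / 2
  th <- seq(0, thc - 1e-9, length.out = 50)
  g2 <- cgligand:::ang_weight(th, 2, thc)
  expect_equal(g2[1], 1)
  expect_true(all(diff(g2) < 0))
  g6 <- cgligand:::ang_weight(th, 6, thc)
  expect_true(all(g6[-1] < g2[-1]))
  expect_equal(cgligand:::ang_weight(c(thc, thc + 0.3), 2, thc), c(0, 0))
})

test_that("WLC tension matches the interpolation formula and its cap", {
  lk <- linker_spec(n_monomers = 10, monomer_size = 1, persistence_length = 2)
  expect_equal(lk$L0, 10)
  expect_equal(wlc_force(0, lk), 0)
  expect_equal(wlc_force(5, lk), 1.25 * 1 / 2)     # 1.25 kBT / lp
  r <- seq(0, 0.98 * lk$L0, length.out = 100)
  expect_true(all(diff(wlc_force(r, lk)) > 0))
  f_cap <- wlc_force(0.99 * lk$L0, lk)
  expect_equal(wlc_force(0.999 * lk$L0, lk), f_cap)
  expect_warning(fo <- wlc_force(lk$L0 + 1, lk), "over-stretch")
  expect_true(is.finite(fo))
  expect_equal(fo, f_cap)
})

test_that("Kratky-Porod interpolation hits its closed-form values and limits", {
  lk11 <- linker_spec(1, 1, 1)
  expect_equal(wlc_mean_extension(lk11, "kratky-porod"), sqrt(2 / exp(1)),
               tolerance = 1e-12)
  stiff <- linker_spec(10, 1, 1e4)
  expect_equal(wlc_mean_extension(stiff, "kratky-porod") / stiff$L0, 1,
               tolerance = 1e-3)
  floppy <- linker_spec(1000, 1, 0.05)
  expect_equal(wlc_mean_extension(floppy, "kratky-porod"),
               sqrt(2 * 0.05 * 1000), tolerance = 1e-3)
})

test_that("Boltzmann mean extension agrees with Monte-Carlo sampling", {
  lk <- linker_spec(20, 0.5, 1)
  m <- wlc_mean_extension(lk)
  expect_gt(m, 0); expect_lt(m, lk$L0)
  # independent rejection-sampling oracle on the same force law
  set.seed(42)
  U <- function(r) {
    x <- r / lk$L0
    (lk$kBT * lk$L0 / lk$lp) * (0.25 / (1 - x) - 0.25 - 0.25 * x + 0.5 * x^2)
  }
  grid <- seq(1e-6, lk$L0 * (1 - 1e-6), length.out = 4000)
  wmax <- max(grid^2 * exp(-U(grid)))
  samp <- c()
  while (length(samp) < 20000) {
    r <- runif(40000, 0, lk$L0)
    keep <- runif(40000) < r^2 * exp(-U(r)) / wmax
    samp <- c(samp, r[keep])
  }
  expect_equal(m, mean(samp), tolerance = 0.01)
  # the simulated dimer mean is well below the free-chain interpolation
  expect_lt(m, wlc_mean_extension(lk, "kratky-porod"))
})

test_that("interaction specs enforce their invariants", {
  expect_equal(interaction_spec("wca", sigma_pair = 2)$r_cut, 2^(1 / 6) * 2)
  expect_error(interaction_spec("angular_lj", theta_cut = 0), "theta_cut")
  expect_error(interaction_spec("angular_lj", theta_cut = 2), "theta_cut")
  expect_error(interaction_spec("angular_lj", n_geom = 0.5,
                                theta_cut = pi / 4), "n_geom")
  # V(r_cut) = 0 to machine precision for a generic spec
  sp <- interaction_spec("angular_lj", epsilon = 7, sigma_pair = 1.3,
                         n_geom = 3, theta_cut = 1.1)
  expect_equal(angular_lj_energy(sp$r_cut, 0.2, sp)$energy, 0)
})

test_that("forces are exact negative gradients of the energies", {
  # central-difference check across random ligand positions (angular pair)
  set.seed(11)
  for (k in 1:60) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2)); u[3] <- abs(u[3])
    r <- runif(1, 0.72, 1.6)
    st <- pair_system(r * u, epsilon = 5, n_geom = sample(c(0, 1, 2, 4), 1),
                      theta_cut = sample(c(pi / 2, pi / 3), 1))
    f <- compute_forces(st, "brute")$forces[1, ]
    fn <- num_force(st, 1)
    expect_equal(f, fn, tolerance = 1e-5)
  }
  # WCA pair
  spec <- experiment_spec("dissociation", n_receptors = 4,
                          surface_density = 0.01, seed = 1)
  set.seed(2)
  st <- build_dissociation(spec)
  st$pos[1, ] <- st$pos[2, ] + c(0.4, 0.1, 0.05)  # overlapping ligands
  f <- compute_forces(st, "brute")$forces[1, ]
  expect_equal(f, num_force(st, 1), tolerance = 1e-5)
})

test_that("Langevin sampling reproduces the Boltzmann bound-state population", {
  # single ligand-receptor pair in a small box: the fraction of time the
  # pair is bound (V < -eps/2) must match direct quadrature of exp(-V/kBT)
  eps <- 3.5
  st <- pair_system(c(0, 0, 0.9), epsilon = eps, n_geom = 2,
                    box = box_spec(6, 6, 4))
  sp <- st$interactions[[1]]$spec
  # quadrature oracle over the box (receptor at the origin, axis +z;
  # ligand z confined to [sigma_L/2, lz - sigma_L/2] by the walls)
  nx <- 180
  xs <- seq(-3, 3, length.out = nx)
  zs <- seq(0.25, 3.75, length.out = nx)
  g <- expand.grid(x = xs, y = xs, z = zs)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  th <- acos(pmin(pmax(g$z / r, -1), 1))
  v <- angular_lj_energy(r, th, sp)$energy
  w <- exp(-v)
  p_bound_exact <- sum(w[v < -eps / 2]) / sum(w)
  # MD estimate
  run <- run_dynamics(st, n_steps = 4e5, sample_every = 50, seed = 77)
  p_md <- mean(run$samples$bound_L_R)
  # agreement within generous Monte-Carlo error of the correlated series
  expect_equal(p_md, p_bound_exact, tolerance = 0.15)
  expect_lt(abs(p_md - p_bound_exact), 0.05)
})
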