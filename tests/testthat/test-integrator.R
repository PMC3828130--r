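test_that("cell-list and all-pairs forces agree to machine precision", {
  set.seed(5)
  st <- make_random_state(50, box = box_spec(12, 12, 6))
  fc <- compute_forces(st, "cell")
  fb <- compute_forces(st, "brute")
  expect_identical(fc$forces, fb$forces)
  expect_identical(fc$potential, fb$potential)
  # Newton's third law: pair forces sum to zero
  expect_equal(colSums(fb$forces), c(0, 0, 0), tolerance = 1e-10)
})

test_that("forces vanish beyond the cutoff and at the stationary point", {
  st <- pair_system(c(0, 0, 3))               # beyond r_cut = 2.5 * 0.75
  expect_equal(compute_forces(st)$forces, matrix(0, 2, 3))
  st <- pair_system(c(0, 0, 2^(1 / 6) * 0.75)) # on-axis LJ minimum
  expect_equal(max(abs(compute_forces(st)$forces)), 0, tolerance = 1e-9)
})

test_that("overlapping particles trigger a hard error", {
  st <- pair_system(c(0, 0, 1))
  st$pos[1, ] <- st$pos[2, ] + c(0, 0, 1e-8)
  expect_error(compute_forces(st), "overlap")
})

test_that("trajectories are deterministic given the seed", {
  spec <- experiment_spec("dissociation", n_receptors = 10, seed = 3)
  set.seed(3); st <- build_dissociation(spec)
  r1 <- run_dynamics(st, n_steps = 500, sample_every = 100, seed = 99)
  r2 <- run_dynamics(st, n_steps = 500, sample_every = 100, seed = 99)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$samples, r2$samples)
})

test_that("membrane receptors stay exactly in the plane while diffusing", {
  spec <- experiment_spec("chimera", n_aer = 6, n_ter = 6,
                          ligand_conc = 2e-3, surface_density = 0.02,
                          box_height = 6, seed = 8)
  set.seed(8); st <- build_chimera(spec)
  r <- run_dynamics(st, n_steps = 2000, sample_every = 500, seed = 8)
  rec <- which(names(st$species)[st$species_index] %in% c("AER", "TER"))
  expect_true(all(r$state$pos[rec, 3] == 0))
  expect_true(all(r$state$vel[rec, 3] == 0))
  # and they did diffuse
  expect_gt(max(abs(r$state$pos[rec, 1:2] - st$pos[rec, 1:2])), 1e-3)
})

test_that("bulk species stay between the membrane and the ceiling", {
  spec <- experiment_spec("association", n_receptors = 9,
                          ligand_conc = 5e-3, surface_density = 0.01,
                          box_height = 5, seed = 4)
  set.seed(4); st <- build_association(spec)
  r <- run_dynamics(st, n_steps = 5000, sample_every = 1000, seed = 4)
  lig <- which(names(st$species)[st$species_index] == "L")
  expect_true(all(r$state$pos[lig, 3] >= 0.5 * 0.5 - 1e-9))
  expect_true(all(r$state$pos[lig, 3] <= 5 - 0.5 * 0.5 + 1e-9))
  # x, y wrapped into the primary box
  expect_true(all(r$state$pos[, 1] >= 0 & r$state$pos[, 1] < st$box$lx))
})

test_that("vanishing friction conserves energy to O(dt^2)", {
  # enormous diffusion coefficient => gamma -> 0 and no thermal noise
  drift <- sapply(c(0.002, 0.001), function(dt) {
    st <- pair_system(c(0.1, 0, 0.95), epsilon = 5, n_geom = 0,
                      d_receptor = 0)
    st$species$L$diffusion <- 1e12
    st$vel[1, ] <- c(0.05, -0.02, 0.03)
    r <- run_dynamics(st, n_steps = round(20 / dt), dt = dt,
                      sample_every = 100, seed = 1)
    etot <- r$samples$potential + r$samples$kinetic
    max(abs(etot - etot[1]))
  })
  expect_lt(drift[1], 0.02)          # small in absolute terms (E ~ eps = 5)
  expect_lt(drift[2], drift[1] / 2)  # and shrinking ~ dt^2
})

test_that("the thermostat holds the target temperature", {
  spec <- experiment_spec("association", n_receptors = 16,
                          ligand_conc = 5e-3, surface_density = 0.02,
                          box_height = 8, epsilon = 4, seed = 12)
  set.seed(12); st <- build_association(spec)
  r <- run_dynamics(st, n_steps = 3e4, sample_every = 100, seed = 12)
  temps <- r$samples$temperature[-(1:50)]   # discard equilibration
  expect_equal(mean(temps), 1, tolerance = 0.02)
})

test_that("large timesteps are flagged", {
  st <- pair_system(c(0, 0, 1.2))
  expect_warning(run_dynamics(st, n_steps = 10, dt = 0.01, sample_every = 10,
                              seed = 1), "dt")
})
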