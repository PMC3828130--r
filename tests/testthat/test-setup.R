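test_that("dissociation builds start fully bound", {
  spec <- experiment_spec("dissociation", n_receptors = 200, seed = 1)
  set.seed(1); st <- build_dissociation(spec)
  expect_equal(nrow(st$pos), 400)
  bp <- detect_bound_pairs(st)
  expect_equal(nrow(bp), 200)
  expect_true(all(bp$energy < -0.5 * spec$epsilon))
  # lateral box size from the surface density
  expect_equal(st$box$lx, sqrt(200 / 0.01))
  # no free ligands: every ligand is matched
  expect_setequal(bp$ligand, 1:200)
})

test_that("an empty dissociation build is valid", {
  spec <- experiment_spec("dissociation", n_receptors = 0, seed = 1)
  set.seed(1); st <- build_dissociation(spec)
  expect_equal(nrow(st$pos), 0)
})

test_that("association builds start unbound at the requested concentration", {
  spec <- experiment_spec("association", n_receptors = 100,
                          ligand_conc = 2.5e-3, seed = 2)
  set.seed(2); st <- build_association(spec)
  # V = 100 x 100 x 10 => 250 ligands
  expect_equal(nrow(st$pos), 350)
  expect_equal(nrow(detect_bound_pairs(st)), 0)
  # every ligand clears the interaction cutoff of every receptor
  lig <- st$pos[1:250, ]; rec <- st$pos[251:350, ]
  rcut <- 2.5 * 0.75
  for (i in sample(250, 20)) {
    dx <- abs(rec[, 1] - lig[i, 1]); dx <- pmin(dx, st$box$lx - dx)
    dy <- abs(rec[, 2] - lig[i, 2]); dy <- pmin(dy, st$box$ly - dy)
    expect_gte(min(sqrt(dx^2 + dy^2 + lig[i, 3]^2)), rcut)
  }
})

test_that("builds are reproducible from the seed", {
  spec <- experiment_spec("association", n_receptors = 20,
                          ligand_conc = 2e-3, seed = 7)
  s1 <- build_experiment(spec)
  s2 <- build_experiment(spec)
  expect_identical(s1$pos, s2$pos)
  expect_identical(s1$vel, s2$vel)
})

test_that("chimera builds wire the full multi-species system", {
  # 300 receptors and 500 chimeras -> 1300 particles
  spec <- experiment_spec("chimera", n_aer = 150, n_ter = 150,
                          ligand_conc = 500 / (150 / 0.02 * 10),
                          surface_density = 0.02, box_height = 10, seed = 5)
  set.seed(5); st <- build_chimera(spec)
  expect_equal(nrow(st$pos), 1300)
  expect_equal(nrow(st$bonds), 500)
  tab <- table(names(st$species)[st$species_index])
  expect_equal(as.integer(tab[c("AE", "TE", "AER", "TER")]),
               c(500, 500, 150, 150))
  # complementary pairs are angular, cross pairs steric
  kinds <- sapply(st$interactions, function(e)
    paste(sort(c(e$a, e$b)), collapse = "-"))
  ang <- sapply(st$interactions, function(e) e$spec$kind) == "angular_lj"
  expect_setequal(kinds[ang], c("AE-AER", "TE-TER"))
  # bond lengths start at the linker mean extension (minimum-image in x, y)
  b <- st$bonds
  dx <- abs(st$pos[b$i, 1] - st$pos[b$j, 1]); dx <- pmin(dx, st$box$lx - dx)
  dy <- abs(st$pos[b$i, 2] - st$pos[b$j, 2]); dy <- pmin(dy, st$box$ly - dy)
  dz <- st$pos[b$i, 3] - st$pos[b$j, 3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  ext <- wlc_mean_extension(spec$linker)
  # TE z-clamping at the walls can only shorten the separation
  expect_true(all(d <= ext + 1e-9))
  expect_gt(mean(abs(d - ext) < 1e-9), 0.8)
})

test_that("zero-TER chimera reduces to a monovalent system plus inert beads", {
  spec <- experiment_spec("chimera", n_aer = 20, n_ter = 0,
                          ligand_conc = 4e-3, surface_density = 0.02,
                          box_height = 8, seed = 9)
  set.seed(9); st <- build_chimera(spec)
  expect_equal(sum(names(st$species)[st$species_index] == "TER"), 0)
  r <- run_dynamics(st, n_steps = 500, sample_every = 250, seed = 9)
  expect_true(all(r$samples$bound_TE_TER == 0))
})

test_that("initial configurations have no overlaps", {
  for (seed in 1:3) {
    spec <- experiment_spec("chimera", n_aer = 12, n_ter = 12,
                            ligand_conc = 6e-3, surface_density = 0.02,
                            box_height = 8, seed = seed)
    set.seed(seed); st <- build_chimera(spec)
    expect_gte(min_pair_distance(st), 0.9 * 0.5)  # 0.9 * smallest sigma_ij
  }
})

test_that("impossible placements fail loudly", {
  spec <- experiment_spec("dissociation", n_receptors = 100,
                          surface_density = 2, seed = 1)
  set.seed(1)
  expect_error(build_dissociation(spec), "placement failed")
  expect_error(
    experiment_spec("chimera", n_aer = 4, ligand_conc = 1e-3,
                    linker = linker_spec(1, 0.2, 1)) |> build_chimera(),
    "overlap")
})

test_that("te_prebound builds anchor every chimera on a TER", {
  spec <- experiment_spec("chimera", n_aer = 8, n_ter = 8,
                          surface_density = 0.02, box_height = 8,
                          te_prebound = TRUE, seed = 13)
  set.seed(13); st <- build_chimera(spec)
  expect_equal(nrow(st$bonds), 8)
  bp <- detect_bound_pairs(st)
  expect_equal(sum(bp$pair == "TE-TER"), 8)
})

test_that("config files round-trip an experiment and reject unknown keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "units: {energy: eps0, length: sigma_R, time: tau}",
    "experiment:",
    "  protocol: dissociation",
    "  n_receptors: 10",
    "  epsilon: 4.5",
    "  seed: 3"), cfg)
  spec <- read_config(cfg)
  expect_s3_class(spec, "cg_experiment")
  expect_equal(spec$epsilon, 4.5)
  expect_equal(spec$n_receptors, 10)
  writeLines(c(
    "units: {energy: eps0, length: sigma_R, time: tau}",
    "experiment: {protocol: dissociation, bogus_knob: 1}"), cfg)
  expect_error(read_config(cfg), "unknown experiment key")
  writeLines("experiment: {protocol: dissociation}", cfg)
  expect_error(read_config(cfg), "units")
})
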