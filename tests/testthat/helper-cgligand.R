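# shared helpers for the test suite

# tiny monovalent pair system: one receptor at the origin (frozen unless
# d_receptor > 0), one ligand at the given position
pair_system <- function(lig_pos, epsilon = 5, n_geom = 2, theta_cut = pi / 2,
                        box = box_spec(8, 8, 8), d_receptor = 0,
                        sigma_ligand = 0.5, temperature = 1) {
  species <- list(
    L = species_spec("L", sigma = sigma_ligand, diffusion = 0.1),
    R = species_spec("R", sigma = 1, diffusion = d_receptor,
                     domain = "membrane2d"))
  sigLR <- (sigma_ligand + 1) / 2
  interactions <- list(
    list(a = "L", b = "R",
         spec = interaction_spec("angular_lj", epsilon = epsilon,
                                 sigma_pair = sigLR, n_geom = n_geom,
                                 theta_cut = theta_cut)))
  pos <- rbind(lig_pos, c(box$lx / 2, box$ly / 2, 0))
  pos[1, 1:2] <- pos[1, 1:2] + c(box$lx / 2, box$ly / 2)
  cg_system(pos, species_index = c(1L, 2L), species = species,
            interactions = interactions, box = box,
            temperature = temperature)
}

# numerical gradient of the system potential w.r.t. particle i
num_force <- function(state, i, h = 1e-6) {
  f <- numeric(3)
  for (d in 1:3) {
    sp <- state; sm <- state
    sp$pos[i, d] <- sp$pos[i, d] + h
    sm$pos[i, d] <- sm$pos[i, d] - h
    f[d] <- -(compute_forces(sp, "brute")$potential -
                compute_forces(sm, "brute")$potential) / (2 * h)
  }
  f
}

# minimum-image pair distances of a state (x, y periodic)
min_pair_distance <- function(state) {
  n <- nrow(state$pos)
  if (n < 2) return(Inf)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    dx <- abs(state$pos[(i + 1):n, 1] - state$pos[i, 1])
    dx <- pmin(dx, state$box$lx - dx)
    dy <- abs(state$pos[(i + 1):n, 2] - state$pos[i, 2])
    dy <- pmin(dy, state$box$ly - dy)
    dz <- state$pos[(i + 1):n, 3] - state$pos[i, 3]
    dmin <- min(dmin, sqrt(dx^2 + dy^2 + dz^2))
  }
  dmin
}
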