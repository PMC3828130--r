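#' Synthetic bound-complex time series with known rates
#'
#' Test substrates for the rate estimators: exponential decays (noise-free,
#' Poisson-noised, or exact two-state Markov survival counts), linear
#' growth, and saturating mass-action association curves.
#'
#' @name fixtures
NULL

#' @rdname fixtures
#' @param koff True dissociation rate (1/tau).
#' @param C0 Initial complex count.
#' @param times Sample times.
#' @param noise `"none"`, `"poisson"` (per-time-point Poisson counts) or
#'   `"markov"` (survival counts of C0 independent two-state trajectories,
#'   the exact stochastic dissociation process without rebinding).
#' @param n_replicates Number of replicate series to average.
#' @return A `cg_series`.
#' @export
make_decay_series <- function(koff, C0, times = seq(0, 5 / koff, length.out = 60),
                              noise = c("none", "poisson", "markov"),
                              n_replicates = 1) {
  noise <- match.arg(noise)
  mu <- C0 * exp(-koff * times)
  reps <- switch(noise,
    none = matrix(mu, ncol = 1),
    poisson = vapply(seq_len(n_replicates), function(k) rpois(length(mu), mu),
                     numeric(length(mu))),
    markov = vapply(seq_len(n_replicates), function(k) {
      lifetimes <- rexp(C0, rate = koff)
      vapply(times, function(t) sum(lifetimes > t), numeric(1))
    }, numeric(length(mu))))
  reps <- matrix(reps, nrow = length(times))
  new_series(times, rowMeans(reps), reps, ncol(reps))
}

#' @rdname fixtures
#' @param slope Linear growth rate (complexes per tau).
#' @export
make_linear_series <- function(slope, times = seq(0, 10, length.out = 50)) {
  new_series(times, pmax(slope * times, 0), matrix(slope * times, ncol = 1), 1L)
}

#' @rdname fixtures
#' @param kon Affinity rate (sigma^3/tau).
#' @param ligand_conc Ligand concentration (held constant; no depletion).
#' @param r_total Total receptors.
#' @return For `make_saturating_series`: the closed-form mass-action
#'   solution `C(t) = C_eq (1 - exp(-(kon [L] + koff) t))` as a
#'   `cg_series`.
#' @export
make_saturating_series <- function(kon, koff, ligand_conc, r_total,
                                   times = seq(0, 10, length.out = 100)) {
  lam <- kon * ligand_conc + koff
  c_eq <- r_total * kon * ligand_conc / lam
  y <- c_eq * (1 - exp(-lam * times))
  new_series(times, y, matrix(y, ncol = 1), 1L)
}

#' @rdname fixtures
#' @param n Particle count for a random test state.
#' @param box A `cg_box` (default 8 x 8 x 8).
#' @param epsilon,n_geom Monovalent interaction parameters.
#' @param frac_receptors Fraction of particles that are membrane receptors.
#' @return For `make_random_state`: a small monovalent `cg_system` with
#'   randomly placed, non-overlapping particles.
#' @export
make_random_state <- function(n, box = box_spec(8, 8, 8), epsilon = 5,
                              n_geom = 2, frac_receptors = 0.5) {
  n_r <- round(n * frac_receptors)
  n_l <- n - n_r
  spec <- experiment_spec("association", n_receptors = max(n_r, 1),
                          ligand_conc = 1e-9, epsilon = epsilon,
                          n_geom = n_geom)
  mp <- monovalent_parts(spec)
  rpts <- place_in_plane(n_r, box, min_sep = 1)
  lpts <- place_in_bulk(n_l, box, z_range = c(0.3, box$lz - 0.3),
                        plane_pts = rpts, plane_clear = 0.8,
                        self_clear = 0.5)
  pos <- rbind(lpts, if (n_r > 0) cbind(rpts, 0) else NULL)
  idx <- c(rep(1L, n_l), rep(2L, n_r))
  vel <- mb_velocities(mp$species, idx, 1)
  cg_system(pos, vel, idx, mp$species, mp$interactions, box = box)
}

#' @rdname fixtures
#' @param unbind_at Named integer vector: frame index at which each listed
#'   ligand (by index) is teleported away from its receptor.
#' @param n_frames Number of frames.
#' @return For `make_scripted_trajectory`: a list of `cg_system` snapshots
#'   in which bound ligands detach exactly at the scripted frames.
#' @export
make_scripted_trajectory <- function(n_complexes, unbind_at, n_frames) {
  spec <- experiment_spec("dissociation", n_receptors = n_complexes,
                          surface_density = 0.01, box_height = 20)
  st <- build_dissociation(spec)
  frames <- vector("list", n_frames)
  cur <- st
  for (f in seq_len(n_frames)) {
    leave <- as.integer(names(unbind_at))[unbind_at == f]
    for (i in leave) cur$pos[i, 3] <- cur$box$lz / 2   # teleport into the bulk
    frames[[f]] <- cur
  }
  frames
}

#' @rdname fixtures
#' @param kind One of `"decay"`, `"markov"`, `"linear"`, `"saturating"`,
#'   `"state"`, `"scripted"`.
#' @param seed Integer seed.
#' @param ... Passed to the specific generator.
#' @export
make_fixtures <- function(kind = c("decay", "markov", "linear", "saturating",
                                   "state", "scripted"),
                          seed = 1, ...) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
         decay = make_decay_series(...),
         markov = make_decay_series(noise = "markov", ...),
         linear = make_linear_series(...),
         saturating = make_saturating_series(...),
         state = make_random_state(...),
         scripted = make_scripted_trajectory(...))
}
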