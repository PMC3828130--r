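#' Create a simulation system state
#'
#' The single source of truth for the integrator: particle positions,
#' velocities, species assignments, pair interactions, linker bonds, box and
#' time. Positions are wrapped into the primary box in x, y; membrane
#' species sit exactly at z = 0 with zero z-velocity.
#'
#' @param pos N x 3 matrix of positions.
#' @param vel N x 3 matrix of velocities (defaults to zeros).
#' @param species_index Integer vector mapping each particle to an entry of
#'   `species`.
#' @param species Named list of [species_spec()] objects.
#' @param interactions List of pair interactions, each a list with elements
#'   `a`, `b` (species names), `spec` (a [interaction_spec()]), and for
#'   angular pairs optionally `receptor` (the axis-owning species; defaults
#'   to the membrane-bound one).
#' @param bonds Tibble with columns `i`, `j`, `L0`, `lp` describing WLC
#'   linker bonds (may be empty).
#' @param box A [box_spec()].
#' @param temperature kBT in units of eps0.
#' @param time Current time (tau units).
#' @return An object of class `cg_system`.
#' @export
cg_system <- function(pos, vel = NULL, species_index, species, interactions,
                      bonds = NULL, box, temperature = 1, time = 0) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, length(species_index) == nrow(pos))
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  if (is.null(bonds))
    bonds <- tibble(i = integer(), j = integer(), L0 = numeric(),
                    lp = numeric())
  st <- structure(
    list(pos = pos, vel = as.matrix(vel), species_index = as.integer(species_index),
         species = species, interactions = interactions, bonds = bonds,
         box = box, temperature = temperature, time = time),
    class = "cg_system")
  validate_system(st)
  st
}

validate_system <- function(st) {
  is2d <- vapply(st$species, function(s) s$domain == "membrane2d", logical(1))
  idx2d <- which(is2d[st$species_index])
  if (length(idx2d) && any(abs(st$pos[idx2d, 3]) > 1e-12))
    abort("membrane species must have z = 0")
  cuts <- vapply(st$interactions, function(e) e$spec$r_cut, numeric(1))
  if (length(cuts) && max(cuts) > min(st$box$lx, st$box$ly) / 2)
    abort("pair cutoffs must not exceed half the smallest periodic box dimension")
  invisible(st)
}

#' @export
print.cg_system <- function(x, ...) {
  tabs <- table(names(x$species)[x$species_index])
  cat(sprintf("<cg_system> %d particles (%s), box %.3g x %.3g x %.3g, t = %.4g\n",
              nrow(x$pos),
              paste(sprintf("%s: %d", names(tabs), tabs), collapse = ", "),
              x$box$lx, x$box$ly, x$box$lz, x$time))
  if (nrow(x$bonds)) cat(sprintf("  %d WLC bonds\n", nrow(x$bonds)))
  invisible(x)
}

# --- encoding for the compiled kernel -------------------------------------

kind_code <- c(wca = 1L, steric = 1L, angular_lj = 2L)

encode_system <- function(st) {
  spn <- names(st$species)
  nsp <- length(spn)
  sp_sigma <- vapply(st$species, `[[`, numeric(1), "sigma")
  sp_mass <- vapply(st$species, `[[`, numeric(1), "mass")
  sp_diff <- vapply(st$species, `[[`, numeric(1), "diffusion")
  sp_is2d <- vapply(st$species, function(s) s$domain == "membrane2d", logical(1))
  sp_frozen <- sp_diff == 0
  sp_gamma <- ifelse(sp_frozen, 0, st$temperature / (sp_mass * pmax(sp_diff, 1e-300)))
  np <- nsp * nsp
  pk <- integer(np); peps <- psig <- prc <- pn <- pthc <- numeric(np)
  precsp <- rep(-1L, np)
  pidx <- function(a, b) (a - 1) * nsp + b
  for (e in st$interactions) {
    a <- match(e$a, spn); b <- match(e$b, spn)
    if (is.na(a) || is.na(b)) abort(sprintf("unknown species in interaction: %s-%s", e$a, e$b))
    sp <- e$spec
    k <- kind_code[[sp$kind]]
    rec <- -1L
    if (sp$kind == "angular_lj") {
      rname <- e$receptor %||% c(e$a, e$b)[which(sp_is2d[c(a, b)])[1]]
      if (is.null(rname) || is.na(rname))
        abort(sprintf("angular pair %s-%s: no membrane species; give `receptor`", e$a, e$b))
      rec <- match(rname, spn) - 1L
    }
    for (p in c(pidx(a, b), pidx(b, a))) {
      pk[p] <- k; peps[p] <- sp$epsilon; psig[p] <- sp$sigma_pair
      prc[p] <- sp$r_cut; pn[p] <- sp$n_geom; pthc[p] <- sp$theta_cut
      precsp[p] <- rec
    }
  }
  bonds <- st$bonds
  list(species = st$species_index - 1L,
       sp_sigma = unname(sp_sigma), sp_mass = unname(sp_mass),
       sp_gamma = unname(sp_gamma), sp_is2d = unname(sp_is2d),
       sp_frozen = unname(sp_frozen),
       pair_kind = pk, pair_eps = peps, pair_sigma = psig, pair_rcut = prc,
       pair_n = pn, pair_thetac = pthc, pair_recsp = precsp,
       bond_idx = matrix(as.integer(c(bonds$i - 1L, bonds$j - 1L)),
                         ncol = 2),
       bond_L0 = as.numeric(bonds$L0), bond_lp = as.numeric(bonds$lp),
       spn = spn)
}

#' Total forces and potential energy of a system
#'
#' Assembles all pair interactions (WCA, angular LJ, steric) and WLC linker
#' bonds with the minimum-image convention in x, y. Forces obey Newton's
#' third law pairwise; the cell-list and all-pairs evaluations agree to
#' machine precision.
#'
#' @param state A `cg_system`.
#' @param method `"cell"` (linked-cell neighbour search) or `"brute"`
#'   (all-pairs reference).
#' @return A list with `forces` (N x 3 matrix) and `potential` (scalar).
#' @export
compute_forces <- function(state, method = c("cell", "brute")) {
  method <- match.arg(method)
  en <- encode_system(state)
  cg_forces_cpp(state$pos, en$species, en$sp_sigma, en$sp_mass, en$sp_gamma,
                en$sp_is2d, en$sp_frozen,
                en$pair_kind, en$pair_eps, en$pair_sigma, en$pair_rcut,
                en$pair_n, en$pair_thetac, en$pair_recsp,
                en$bond_idx, en$bond_L0, en$bond_lp,
                state$box$lx, state$box$ly, state$box$lz,
                state$temperature, method == "cell")
}

#' Propagate a system with Langevin dynamics
#'
#' Velocity-Verlet with BAOAB Langevin splitting at constant temperature.
#' Friction per species is `gamma = kBT / (mass * diffusion)`; species with
#' `diffusion = 0` are frozen in place. Membrane species propagate in x, y
#' only; bulk species reflect elastically off the membrane plane and the box
#' ceiling. Trajectories are deterministic given the R random seed.
#'
#' @param state A `cg_system`.
#' @param n_steps Number of timesteps.
#' @param dt Timestep (tau units); default 0.002.
#' @param sample_every Sampling interval in steps.
#' @param bind_threshold Bound-pair energy threshold as a fraction of the
#'   pair epsilon (a pair is bound when V < -bind_threshold * epsilon).
#' @param record_frames If > 0, store a position frame every
#'   `record_frames`-th sample.
#' @param frames_unwrapped Record unwrapped coordinates (for mean-squared
#'   displacements) instead of wrapped ones.
#' @param record_bonds Record per-sample WLC bond extensions.
#' @param method Neighbour search, `"cell"` or `"brute"`.
#' @param seed Optional integer seed (`set.seed` is called if given).
#' @return An object of class `cg_run`: a list with `samples` (tibble of
#'   time, energies, temperature and per-pair-type bound counts), the final
#'   `state`, and optional `frames` / `bond_r` arrays.
#' @export
run_dynamics <- function(state, n_steps, dt = 0.002, sample_every = 100,
                         bind_threshold = 0.5, record_frames = 0,
                         frames_unwrapped = FALSE, record_bonds = FALSE,
                         method = c("cell", "brute"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(n_steps >= 1, dt > 0, sample_every >= 1)
  if (dt > 0.005)
    warn("dt > 0.005 tau exceeds the recommended stability bound")
  if (!is.null(seed)) set.seed(seed)
  en <- encode_system(state)
  res <- cg_run_cpp(state$pos, state$vel, en$species, en$sp_sigma, en$sp_mass,
                    en$sp_gamma, en$sp_is2d, en$sp_frozen,
                    en$pair_kind, en$pair_eps, en$pair_sigma, en$pair_rcut,
                    en$pair_n, en$pair_thetac, en$pair_recsp,
                    en$bond_idx, en$bond_L0, en$bond_lp,
                    state$box$lx, state$box$ly, state$box$lz,
                    state$temperature, dt, as.integer(n_steps),
                    as.integer(sample_every), bind_threshold,
                    as.integer(record_frames), frames_unwrapped, record_bonds,
                    method == "cell")
  spn <- en$spn
  samples <- tibble(time = state$time + res$time,
                    potential = res$potential, kinetic = res$kinetic,
                    temperature = if (res$ndof > 0) 2 * res$kinetic / res$ndof else NA_real_)
  cm <- res$counts
  pair_types <- tibble(ligand = spn[res$type_ligand + 1],
                       receptor = spn[res$type_receptor + 1])
  if (ncol(cm) > 0) {
    cn <- paste0("bound_", pair_types$ligand, "_", pair_types$receptor)
    colnames(cm) <- cn
    samples <- dplyr::bind_cols(samples, as_tibble(cm))
  }
  newstate <- state
  newstate$pos <- res$pos
  newstate$vel <- res$vel
  newstate$time <- state$time + n_steps * dt
  frames <- NULL
  if (record_frames > 0) {
    frames <- aperm(res$frames, c(2, 1, 3)) # N x 3 x nframes
    if (res$n_overstretch > 0)
      warn(sprintf("%d WLC over-stretch event(s) during run", res$n_overstretch))
  } else if (res$n_overstretch > 0) {
    warn(sprintf("%d WLC over-stretch event(s) during run", res$n_overstretch))
  }
  structure(
    list(samples = samples, pair_types = pair_types, counts = cm,
         frames = frames,
         frame_times = if (record_frames > 0)
           samples$time[seq(1, nrow(samples), by = record_frames)] else NULL,
         bond_r = if (record_bonds) res$bond_r else NULL,
         state = newstate, ndof = res$ndof, dt = dt,
         sample_every = sample_every,
         n_overstretch = res$n_overstretch, max_bond_x = res$max_bond_x),
    class = "cg_run")
}

#' @export
print.cg_run <- function(x, ...) {
  cat(sprintf("<cg_run> %d samples, t in [%.4g, %.4g], %d particles\n",
              nrow(x$samples), min(x$samples$time), max(x$samples$time),
              nrow(x$state$pos)))
  invisible(x)
}

#' Advance a system by a few Langevin steps
#'
#' Thin wrapper around [run_dynamics()] returning only the updated state.
#'
#' @inheritParams run_dynamics
#' @return The propagated `cg_system`.
#' @export
langevin_step <- function(state, dt = 0.002, n_steps = 1, seed = NULL) {
  run_dynamics(state, n_steps = n_steps, dt = dt, sample_every = n_steps,
               seed = seed)$state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
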