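#' Experiment descriptor
#'
#' High-level description of one simulation experiment, from which the
#' builders create initial configurations:
#'
#' * `"dissociation"` — all receptors start bound (C(0) = N_R), no free
#'   ligands, tall box and low receptor density to avoid rebinding.
#' * `"association"` — all receptors start unbound (C(0) = 0), free ligands
#'   placed uniformly in the bulk at concentration `ligand_conc`.
#' * `"chimera"` — two receptor species (AER, TER) diffusing in the membrane
#'   and bivalent AE-TE ligands joined by a WLC linker, free in the bulk.
#'
#' All quantities are in reduced units (energy eps0, length sigma_R, time
#' tau, kBT in eps0). Unspecified parameters take the package defaults
#' documented below.
#'
#' @param protocol `"dissociation"`, `"association"` or `"chimera"`.
#' @param n_receptors Receptor count N_R (monovalent protocols).
#' @param n_aer,n_ter Receptor counts per species (chimera protocol).
#' @param ligand_conc Ligand (or chimera) number concentration, 1/sigma^3.
#'   For monovalent protocols the free-ligand count is
#'   `round(ligand_conc * lx*ly*lz)`.
#' @param surface_density Receptor surface density rho_s (1/sigma^2); sets
#'   the lateral box size `lx = ly = sqrt(N_receptors_total / rho_s)`.
#' @param box_height Box height lz.
#' @param epsilon,n_geom,theta_cut Monovalent ligand-receptor interaction
#'   strength (kBT units since kBT = 1 eps0), geometric factor, cone width.
#' @param eps_ae,eps_te,n_ae,n_te Chimera subunit interaction parameters.
#' @param linker A [linker_spec()] (chimera protocol).
#' @param sigma_ligand,sigma_receptor Particle diameters; defaults 0.5 and 1
#'   (epidermal-growth-factor-like ligand/receptor size ratio).
#' @param mass_ligand,mass_receptor Particle masses.
#' @param d_ligand,d_receptor Diffusion coefficients. `d_receptor = 0`
#'   (default for the monovalent protocols) freezes receptors; the chimera
#'   protocol defaults to 0.01 so both receptor species diffuse.
#' @param temperature kBT (eps0 units).
#' @param bind_threshold Bound-pair energy threshold fraction.
#' @param n_replicates Number of independent replicate simulations.
#' @param seed Base integer seed; replicate k uses `seed + k - 1`.
#' @param n_steps,sample_interval Run length and sampling interval (steps).
#' @param equilibration Thermalization steps run and discarded before the
#'   measured trajectory (time is re-zeroed afterwards). Defaults to 2500
#'   steps (5 tau) for the dissociation protocol — complexes are built at
#'   the exact potential minimum, and the bound ensemble needs a few tau to
#'   reach its thermal width before C(0) is meaningful — and 0 for the
#'   association and chimera protocols, which must start strictly unbound.
#' @param dt Timestep.
#' @param te_prebound Chimera option: start every chimera with its TE
#'   subunit bound to a TER (surface-only binding control; no free chimeras
#'   in solution).
#' @return An object of class `cg_experiment`.
#' @export
experiment_spec <- function(protocol = c("dissociation", "association", "chimera"),
                            n_receptors = NULL, n_aer = NULL, n_ter = NULL,
                            ligand_conc = NULL, surface_density = NULL,
                            box_height = NULL,
                            epsilon = 5, n_geom = 2, theta_cut = pi / 2,
                            eps_ae = 12, eps_te = 10, n_ae = 2, n_te = 2,
                            linker = NULL,
                            sigma_ligand = 0.5, sigma_receptor = 1,
                            mass_ligand = 1, mass_receptor = 1,
                            d_ligand = 0.1, d_receptor = NULL,
                            temperature = 1, bind_threshold = 0.5,
                            n_replicates = 4, seed = 1,
                            n_steps = 1e5, sample_interval = 500,
                            equilibration = NULL,
                            dt = 0.002, te_prebound = FALSE) {
  protocol <- match.arg(protocol)
  if (is.null(equilibration))
    equilibration <- if (protocol == "dissociation") 2500L else 0L
  if (protocol == "dissociation") {
    n_receptors <- n_receptors %||% 200
    surface_density <- surface_density %||% 0.01
    box_height <- box_height %||% 20
    d_receptor <- d_receptor %||% 0
  } else if (protocol == "association") {
    n_receptors <- n_receptors %||% 100
    surface_density <- surface_density %||% 0.01
    box_height <- box_height %||% 10
    d_receptor <- d_receptor %||% 0
    if (is.null(ligand_conc)) abort("association protocol needs ligand_conc")
  } else {
    if (is.null(n_aer)) abort("chimera protocol needs n_aer")
    n_ter <- n_ter %||% 0
    surface_density <- surface_density %||% 0.01
    box_height <- box_height %||% 10
    d_receptor <- d_receptor %||% 0.01
    if (is.null(linker))
      linker <- linker_spec(n_monomers = 20, monomer_size = 0.5,
                            persistence_length = 1, temperature = temperature)
    if (!te_prebound && is.null(ligand_conc))
      abort("chimera protocol needs ligand_conc (or te_prebound = TRUE)")
  }
  structure(
    list(protocol = protocol, n_receptors = n_receptors, n_aer = n_aer,
         n_ter = n_ter, ligand_conc = ligand_conc,
         surface_density = surface_density, box_height = box_height,
         epsilon = epsilon, n_geom = n_geom, theta_cut = theta_cut,
         eps_ae = eps_ae, eps_te = eps_te, n_ae = n_ae, n_te = n_te,
         linker = linker, sigma_ligand = sigma_ligand,
         sigma_receptor = sigma_receptor, mass_ligand = mass_ligand,
         mass_receptor = mass_receptor, d_ligand = d_ligand,
         d_receptor = d_receptor, temperature = temperature,
         bind_threshold = bind_threshold, n_replicates = n_replicates,
         seed = seed, n_steps = n_steps, sample_interval = sample_interval,
         equilibration = as.integer(equilibration),
         dt = dt, te_prebound = te_prebound),
    class = "cg_experiment")
}

#' @export
print.cg_experiment <- function(x, ...) {
  cat(sprintf("<cg_experiment> %s protocol, seed %d, %d replicate(s)\n",
              x$protocol, x$seed, x$n_replicates))
  invisible(x)
}

# Maxwell-Boltzmann velocities respecting domain/frozen constraints
mb_velocities <- function(species, species_index, kBT) {
  n <- length(species_index)
  v <- matrix(rnorm(3 * n), n, 3)
  for (k in seq_along(species)) {
    sel <- species_index == k
    s <- species[[k]]
    if (!any(sel)) next
    if (s$diffusion == 0) v[sel, ] <- 0
    else {
      v[sel, ] <- v[sel, ] * sqrt(kBT / s$mass)
      if (s$domain == "membrane2d") v[sel, 3] <- 0
    }
  }
  v
}

# sequential rejection sampling of receptor positions in the plane with a
# minimum pair separation (periodic in x, y)
place_in_plane <- function(n, box, min_sep, max_tries = 1e4) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, 0, box$lx), runif(1, 0, box$ly))
      if (i == 1) { ok <- TRUE; break }
      dx <- abs(pts[seq_len(i - 1), 1] - p[1]); dx <- pmin(dx, box$lx - dx)
      dy <- abs(pts[seq_len(i - 1), 2] - p[2]); dy <- pmin(dy, box$ly - dy)
      if (min(dx^2 + dy^2) >= min_sep^2) { ok <- TRUE; break }
    }
    if (!ok) abort("receptor placement failed: density too high for rejection sampling")
    pts[i, ] <- p
  }
  pts
}

# uniform bulk placement keeping a clearance from given plane points
# (periodic x,y) and from previously placed bulk points
place_in_bulk <- function(n, box, z_range, plane_pts = NULL, plane_clear = 0,
                          self_clear = 0, max_tries = 1e4) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, 0, box$lx), runif(1, 0, box$ly),
             runif(1, z_range[1], z_range[2]))
      good <- TRUE
      if (!is.null(plane_pts) && nrow(plane_pts) > 0 && plane_clear > 0) {
        dx <- abs(plane_pts[, 1] - p[1]); dx <- pmin(dx, box$lx - dx)
        dy <- abs(plane_pts[, 2] - p[2]); dy <- pmin(dy, box$ly - dy)
        if (min(dx^2 + dy^2 + p[3]^2) < plane_clear^2) good <- FALSE
      }
      if (good && i > 1 && self_clear > 0) {
        prev <- pts[seq_len(i - 1), , drop = FALSE]
        dx <- abs(prev[, 1] - p[1]); dx <- pmin(dx, box$lx - dx)
        dy <- abs(prev[, 2] - p[2]); dy <- pmin(dy, box$ly - dy)
        if (min(dx^2 + dy^2 + (prev[, 3] - p[3])^2) < self_clear^2) good <- FALSE
      }
      if (good) { ok <- TRUE; break }
    }
    if (!ok) abort("bulk placement failed: volume too crowded for rejection sampling")
    pts[i, ] <- p
  }
  pts
}

monovalent_parts <- function(spec) {
  kBT <- spec$temperature
  sigL <- spec$sigma_ligand; sigR <- spec$sigma_receptor
  species <- list(
    L = species_spec("L", sigma = sigL, mass = spec$mass_ligand,
                     diffusion = spec$d_ligand, domain = "bulk3d"),
    R = species_spec("R", sigma = sigR, mass = spec$mass_receptor,
                     diffusion = spec$d_receptor, domain = "membrane2d"))
  sigLR <- (sigL + sigR) / 2
  interactions <- list(
    list(a = "L", b = "R",
         spec = interaction_spec("angular_lj", epsilon = spec$epsilon,
                                 sigma_pair = sigLR, n_geom = spec$n_geom,
                                 theta_cut = spec$theta_cut)),
    list(a = "L", b = "L", spec = interaction_spec("wca", epsilon = 1, sigma_pair = sigL)),
    list(a = "R", b = "R", spec = interaction_spec("wca", epsilon = 1, sigma_pair = sigR)))
  list(species = species, interactions = interactions, sigLR = sigLR, kBT = kBT)
}

#' Build the dissociation initial configuration
#'
#' Receptors are placed uniformly at random in the z = 0 plane with minimum
#' separation sigma_R; one ligand per receptor sits at the on-axis potential
#' minimum (all complexes bound at t = 0, no free ligands). Initial
#' velocities are Maxwell-Boltzmann at the target temperature.
#'
#' @param spec A `cg_experiment` with `protocol = "dissociation"`.
#' @return A `cg_system` (with the experiment stored as attribute
#'   `"experiment"`).
#' @export
build_dissociation <- function(spec) {
  stopifnot(inherits(spec, "cg_experiment"), spec$protocol == "dissociation")
  mp <- monovalent_parts(spec)
  nR <- spec$n_receptors
  box <- if (nR > 0) box_from_density(nR, spec$surface_density, spec$box_height)
         else box_spec(10, 10, spec$box_height)
  rpts <- place_in_plane(nR, box, min_sep = spec$sigma_receptor)
  zmin <- 2^(1 / 6) * mp$sigLR
  pos <- rbind(
    if (nR > 0) cbind(rpts, zmin) else NULL,           # ligands, bound on-axis
    if (nR > 0) cbind(rpts, 0) else NULL)              # receptors
  if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
  species_index <- c(rep(1L, nR), rep(2L, nR))
  vel <- mb_velocities(mp$species, species_index, mp$kBT)
  st <- cg_system(pos, vel, species_index, mp$species, mp$interactions,
                  box = box, temperature = mp$kBT)
  attr(st, "experiment") <- spec
  st
}

#' Build the association initial configuration
#'
#' Receptors as in [build_dissociation()]; ligands are placed uniformly at
#' random in the bulk, all farther than the interaction cutoff from every
#' receptor, so C(0) = 0. The ligand count is
#' `round(ligand_conc * lx * ly * lz)`.
#'
#' @param spec A `cg_experiment` with `protocol = "association"`.
#' @return A `cg_system`.
#' @export
build_association <- function(spec) {
  stopifnot(inherits(spec, "cg_experiment"), spec$protocol == "association")
  mp <- monovalent_parts(spec)
  nR <- spec$n_receptors
  box <- if (nR > 0) box_from_density(nR, spec$surface_density, spec$box_height)
         else box_spec(10, 10, spec$box_height)
  rpts <- place_in_plane(nR, box, min_sep = spec$sigma_receptor)
  nL <- round(spec$ligand_conc * box$lx * box$ly * box$lz)
  rcut <- 2.5 * mp$sigLR
  sigL <- spec$sigma_ligand
  lpts <- place_in_bulk(nL, box, z_range = c(0.5 * sigL, box$lz - 0.5 * sigL),
                        plane_pts = rpts, plane_clear = rcut,
                        self_clear = 0.95 * sigL)
  pos <- rbind(lpts, if (nR > 0) cbind(rpts, 0) else NULL)
  if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
  species_index <- c(rep(1L, nL), rep(2L, nR))
  vel <- mb_velocities(mp$species, species_index, mp$kBT)
  st <- cg_system(pos, vel, species_index, mp$species, mp$interactions,
                  box = box, temperature = mp$kBT)
  attr(st, "experiment") <- spec
  st
}

chimera_parts <- function(spec) {
  sigL <- spec$sigma_ligand; sigR <- spec$sigma_receptor
  species <- list(
    AE = species_spec("AE", sigma = sigL, mass = spec$mass_ligand,
                      diffusion = spec$d_ligand, domain = "bulk3d"),
    TE = species_spec("TE", sigma = sigL, mass = spec$mass_ligand,
                      diffusion = spec$d_ligand, domain = "bulk3d"),
    AER = species_spec("AER", sigma = sigR, mass = spec$mass_receptor,
                       diffusion = spec$d_receptor, domain = "membrane2d"),
    TER = species_spec("TER", sigma = sigR, mass = spec$mass_receptor,
                       diffusion = spec$d_receptor, domain = "membrane2d"))
  sigLR <- (sigL + sigR) / 2
  ster <- function(si, sj)
    interaction_spec("steric", epsilon = 1, sigma_pair = (si + sj) / 2)
  interactions <- list(
    list(a = "AE", b = "AER",
         spec = interaction_spec("angular_lj", epsilon = spec$eps_ae,
                                 sigma_pair = sigLR, n_geom = spec$n_ae,
                                 theta_cut = spec$theta_cut)),
    list(a = "TE", b = "TER",
         spec = interaction_spec("angular_lj", epsilon = spec$eps_te,
                                 sigma_pair = sigLR, n_geom = spec$n_te,
                                 theta_cut = spec$theta_cut)),
    # same-type repulsion
    list(a = "AE", b = "AE", spec = interaction_spec("wca", sigma_pair = sigL)),
    list(a = "TE", b = "TE", spec = interaction_spec("wca", sigma_pair = sigL)),
    list(a = "AER", b = "AER", spec = interaction_spec("wca", sigma_pair = sigR)),
    list(a = "TER", b = "TER", spec = interaction_spec("wca", sigma_pair = sigR)),
    list(a = "AER", b = "TER", spec = interaction_spec("wca", sigma_pair = sigR)),
    # non-complementary cross pairs: purely steric
    list(a = "AE", b = "TE", spec = ster(sigL, sigL)),
    list(a = "AE", b = "TER", spec = ster(sigL, sigR)),
    list(a = "TE", b = "AER", spec = ster(sigL, sigR)))
  list(species = species, interactions = interactions, sigLR = sigLR)
}

#' Build the chimeric-ligand initial configuration
#'
#' `n_aer + n_ter` receptors (both species mobile in the membrane) are
#' placed in the plane; chimeras are AE-TE particle pairs joined by a WLC
#' bond, initially separated by the linker's mean extension and placed at
#' random in the bulk. Complementary pairs (AE-AER, TE-TER) interact through
#' the angular potential, all non-complementary cross pairs sterically.
#' With `te_prebound = TRUE` each TER instead starts with a chimera bound by
#' its TE subunit and no chimeras remain in solution.
#'
#' @param spec A `cg_experiment` with `protocol = "chimera"`.
#' @return A `cg_system`.
#' @export
build_chimera <- function(spec) {
  stopifnot(inherits(spec, "cg_experiment"), spec$protocol == "chimera")
  cp <- chimera_parts(spec)
  linker <- spec$linker
  if (linker$L0 < spec$sigma_ligand)
    abort("contour length shorter than the subunit diameter: subunits overlap")
  n_aer <- spec$n_aer; n_ter <- spec$n_ter
  n_rec <- n_aer + n_ter
  # lateral size from the activity-receptor density, so sweeping the TER
  # abundance changes receptor counts at fixed membrane area
  box <- box_from_density(max(n_aer, 1), spec$surface_density, spec$box_height)
  rpts <- place_in_plane(n_rec, box, min_sep = spec$sigma_receptor)
  # interleave receptor species assignment deterministically
  rec_species <- c(rep(3L, n_aer), rep(4L, n_ter))
  sigL <- spec$sigma_ligand
  ext0 <- min(wlc_mean_extension(linker), 0.95 * linker$L0)
  zmin <- 2^(1 / 6) * cp$sigLR
  if (spec$te_prebound) {
    n_chim <- n_ter
    ter_pts <- rpts[rec_species == 4L, , drop = FALSE]
    te <- cbind(ter_pts, zmin)
    # AE straight above its TE at the linker mean extension (capped by box)
    ae <- te
    ae[, 3] <- pmin(te[, 3] + ext0, box$lz - 0.5 * sigL)
  } else {
    n_chim <- round(spec$ligand_conc * box$lx * box$ly * box$lz)
    zr <- c(0.5 * sigL + 1e-9, box$lz - 0.5 * sigL)
    # sequential placement of AE-TE dimers: AE uniform in the bulk, TE at
    # the linker mean extension in a random direction; both must clear the
    # receptors and every previously placed subunit
    ae <- matrix(NA_real_, n_chim, 3)
    te <- matrix(NA_real_, n_chim, 3)
    placed <- matrix(numeric(0), 0, 3)
    clear_ok <- function(p, clear_plane, clear_self) {
      if (nrow(rpts) > 0) {
        dx <- abs(rpts[, 1] - p[1]); dx <- pmin(dx, box$lx - dx)
        dy <- abs(rpts[, 2] - p[2]); dy <- pmin(dy, box$ly - dy)
        if (min(dx^2 + dy^2 + p[3]^2) < clear_plane^2) return(FALSE)
      }
      if (nrow(placed) > 0) {
        dx <- abs(placed[, 1] - p[1]); dx <- pmin(dx, box$lx - dx)
        dy <- abs(placed[, 2] - p[2]); dy <- pmin(dy, box$ly - dy)
        if (min(dx^2 + dy^2 + (placed[, 3] - p[3])^2) < clear_self^2)
          return(FALSE)
      }
      TRUE
    }
    for (k in seq_len(n_chim)) {
      ok <- FALSE
      for (try in seq_len(1e4)) {
        pa <- c(runif(1, 0, box$lx), runif(1, 0, box$ly),
                runif(1, zr[1], zr[2]))
        if (!clear_ok(pa, 2.5 * cp$sigLR, 0.95 * sigL)) next
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        pt <- pa + ext0 * u
        pt[1] <- pt[1] %% box$lx; pt[2] <- pt[2] %% box$ly
        if (pt[3] < zr[1] || pt[3] > zr[2]) next
        if (!clear_ok(pt, 2.5 * cp$sigLR, 0.95 * sigL)) next
        ae[k, ] <- pa; te[k, ] <- pt
        placed <- rbind(placed, pa, pt)
        ok <- TRUE
        break
      }
      if (!ok) abort("chimera placement failed: volume too crowded for rejection sampling")
    }
  }
  pos <- rbind(ae, te, if (n_rec > 0) cbind(rpts, 0) else NULL)
  species_index <- c(rep(1L, n_chim), rep(2L, n_chim), rec_species)
  bonds <- tibble(i = seq_len(n_chim), j = n_chim + seq_len(n_chim),
                  L0 = linker$L0, lp = linker$lp)
  vel <- mb_velocities(cp$species, species_index, spec$temperature)
  st <- cg_system(pos, vel, species_index, cp$species, cp$interactions,
                  bonds = bonds, box = box, temperature = spec$temperature)
  attr(st, "experiment") <- spec
  st
}

#' Build the initial configuration for any protocol
#'
#' Dispatches to [build_dissociation()], [build_association()] or
#' [build_chimera()] according to `spec$protocol`.
#'
#' @param spec A `cg_experiment`.
#' @param seed Optional seed applied before building (defaults to
#'   `spec$seed`).
#' @return A `cg_system`.
#' @export
build_experiment <- function(spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  switch(spec$protocol,
         dissociation = build_dissociation(spec),
         association = build_association(spec),
         chimera = build_chimera(spec))
}
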