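#' Pair interaction specification
#'
#' Defines one pair interaction of the model. Three kinds are supported:
#' `"wca"` (purely repulsive excluded volume between particles of the same
#' type), `"angular_lj"` (the directional ligand-receptor binding potential:
#' a Lennard-Jones attraction modulated by the angle between the
#' receptor-to-ligand separation and the receptor binding axis), and
#' `"steric"` (cross-species excluded volume between non-complementary
#' particles, a WCA form evaluated at the mixed diameter).
#'
#' For `"angular_lj"` the potential is
#' \deqn{V(r,\theta) = V_{rep}(r) + g(\theta)\,V_{att}(r)}
#' with \eqn{V_{rep} = 4\epsilon[(\sigma/r)^{12} - (\sigma/r_c)^{12}]},
#' \eqn{V_{att} = -4\epsilon[(\sigma/r)^6 - (\sigma/r_c)^6]} and angular
#' weight \eqn{g(\theta) = \cos(\pi\theta/2\theta_c)^{2n}} inside the binding
#' cone (\eqn{\theta < \theta_c}) and 0 outside, so the interaction is purely
#' repulsive outside the cone and vanishes at the cutoff for every angle.
#' The geometric factor `n_geom` sharpens the binding patch; `n_geom = 0`
#' with `theta_cut = pi/2` is the isotropic convention (`g == 1` everywhere).
#'
#' @param kind One of `"wca"`, `"angular_lj"`, `"steric"`.
#' @param epsilon Interaction strength in units of the system energy eps0.
#' @param sigma_pair Pair length scale (sigma_LR or sigma_ij), reduced units.
#' @param n_geom Dimensionless geometric factor (angular specificity), >= 0.
#'   For an anisotropic patch (`theta_cut < pi/2`) it must be >= 1 so the
#'   angular weight is C1 at the cone edge.
#' @param theta_cut Binding-cone half width in radians, in (0, pi/2].
#' @param r_cut Cutoff radius. Defaults: `2^(1/6)*sigma_pair` for `"wca"` and
#'   `"steric"` (forced for `"wca"`), `2.5*sigma_pair` for `"angular_lj"`.
#' @return An object of class `cg_interaction`.
#' @export
#' @examples
#' iv <- interaction_spec("angular_lj", epsilon = 6, sigma_pair = 0.75, n_geom = 2)
#' wca_spec <- interaction_spec("wca", epsilon = 1, sigma_pair = 1)
interaction_spec <- function(kind = c("wca", "angular_lj", "steric"),
                             epsilon = 1, sigma_pair = 1,
                             n_geom = 0, theta_cut = pi / 2, r_cut = NULL) {
  kind <- match.arg(kind)
  stopifnot(epsilon >= 0, sigma_pair > 0)
  if (kind %in% c("wca", "steric")) {
    r_cut <- 2^(1 / 6) * sigma_pair
  } else {
    if (is.null(r_cut)) r_cut <- 2.5 * sigma_pair
    if (theta_cut <= 0 || theta_cut > pi / 2)
      abort("theta_cut must lie in (0, pi/2]")
    if (n_geom < 0) abort("n_geom must be >= 0")
    if (n_geom > 0 && n_geom < 1 && theta_cut < pi / 2)
      abort("n_geom must be 0 (isotropic) or >= 1 for an anisotropic patch")
  }
  if (r_cut <= 0) abort("r_cut must be positive")
  # shifts making V(r_cut, theta) = 0 for every theta
  sr <- sigma_pair / r_cut
  structure(
    list(kind = kind, epsilon = epsilon, sigma_pair = sigma_pair,
         n_geom = n_geom, theta_cut = theta_cut, r_cut = r_cut,
         shift_rep = -4 * epsilon * sr^12, shift_att = 4 * epsilon * sr^6),
    class = "cg_interaction")
}

#' @export
print.cg_interaction <- function(x, ...) {
  cat(sprintf("<cg_interaction> %s  eps=%.3g  sigma=%.3g  r_cut=%.4g",
              x$kind, x$epsilon, x$sigma_pair, x$r_cut))
  if (x$kind == "angular_lj")
    cat(sprintf("  n=%.3g  theta_c=%.4g", x$n_geom, x$theta_cut))
  cat("\n")
  invisible(x)
}

#' Worm-like-chain linker specification
#'
#' Parameterizes the flexible polypeptide linker joining the two subunits of
#' a chimeric ligand. The contour length is `L0 = n_monomers * monomer_size`.
#'
#' @param n_monomers Number of monomers in the chain.
#' @param monomer_size Monomer size b (reduced length units).
#' @param persistence_length Persistence length lp (reduced length units).
#' @param temperature kBT in units of eps0.
#' @return An object of class `cg_linker` with fields `L0`, `lp`, `kBT`.
#' @export
linker_spec <- function(n_monomers, monomer_size, persistence_length,
                        temperature = 1) {
  stopifnot(n_monomers > 0, monomer_size > 0, persistence_length > 0,
            temperature > 0)
  structure(
    list(n_monomers = n_monomers, monomer_size = monomer_size,
         persistence_length = persistence_length, temperature = temperature,
         L0 = n_monomers * monomer_size, lp = persistence_length,
         kBT = temperature),
    class = "cg_linker")
}

#' @export
print.cg_linker <- function(x, ...) {
  cat(sprintf("<cg_linker> N=%g b=%.3g -> L0=%.3g, lp=%.3g, kBT=%.3g\n",
              x$n_monomers, x$monomer_size, x$L0, x$lp, x$kBT))
  invisible(x)
}

#' WCA (Weeks-Chandler-Andersen) repulsive potential
#'
#' Purely repulsive excluded-volume interaction between particles of the same
#' type: the Lennard-Jones potential truncated at its minimum
#' \eqn{2^{1/6}\sigma} and shifted up by \eqn{\epsilon}, so the energy is
#' non-negative and both energy and force are continuous at the cutoff.
#'
#' @param r Pair distance(s), > 0.
#' @param spec A `cg_interaction` of kind `"wca"` or `"steric"`, or any spec
#'   whose `epsilon`/`sigma_pair` should be used in the WCA form.
#' @return A tibble with columns `r`, `energy`, `force` (force is the scalar
#'   radial force \eqn{-dV/dr}; positive = repulsive).
#' @export
#' @examples
#' wca(seq(0.9, 1.3, by = 0.1), interaction_spec("wca", epsilon = 1, sigma_pair = 1))
wca <- function(r, spec) {
  if (any(r <= 0)) abort("r must be positive")
  eps <- spec$epsilon; sig <- spec$sigma_pair
  rc <- 2^(1 / 6) * sig
  sr6 <- (sig / r)^6
  inside <- r < rc
  energy <- ifelse(inside, 4 * eps * (sr6^2 - sr6) + eps, 0)
  force <- ifelse(inside, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  tibble(r = r, energy = energy, force = force)
}

#' Steric cross-repulsion between non-complementary species
#'
#' WCA form evaluated at the mixed diameter
#' \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2}; never attractive.
#'
#' @param r Pair distance(s), > 0.
#' @param sigma_i,sigma_j Diameters of the two species.
#' @param eps0 Repulsion strength (energy units), default 1.
#' @return A tibble with columns `r`, `energy`, `force`.
#' @export
steric_cross <- function(r, sigma_i, sigma_j, eps0 = 1) {
  stopifnot(sigma_i > 0, sigma_j > 0)
  wca(r, interaction_spec("steric", epsilon = eps0,
                          sigma_pair = (sigma_i + sigma_j) / 2))
}

# angular weight g(theta); n = 0 with theta_cut = pi/2 is the isotropic case
ang_weight <- function(theta, n_geom, theta_cut) {
  if (n_geom == 0 && theta_cut >= pi / 2 - 1e-12) return(rep(1, length(theta)))
  out <- numeric(length(theta))
  inside <- theta < theta_cut
  out[inside] <- cos(pi * theta[inside] / (2 * theta_cut))^(2 * n_geom)
  out
}

#' Anisotropic (patchy) ligand-receptor potential
#'
#' Evaluates the directional Lennard-Jones binding interaction for one
#' ligand-receptor pair. The separation vector `r_vec` points from the
#' receptor to the ligand and `axis` is the receptor binding axis (a unit
#' vector, `c(0, 0, 1)` for a membrane receptor whose patch faces the bulk).
#' The returned force acts on the ligand; the receptor feels the opposite
#' force.
#'
#' @param r_vec Numeric length-3 vector, receptor-to-ligand separation.
#' @param axis Receptor binding axis (unit 3-vector).
#' @param spec A `cg_interaction` of kind `"angular_lj"`.
#' @return A list with `energy` (scalar) and `force` (length-3 numeric,
#'   force on the ligand).
#' @export
#' @examples
#' sp <- interaction_spec("angular_lj", epsilon = 5, sigma_pair = 0.75, n_geom = 2)
#' angular_lj(c(0, 0, 2^(1/6) * 0.75), c(0, 0, 1), sp)
angular_lj <- function(r_vec, axis = c(0, 0, 1), spec) {
  stopifnot(length(r_vec) == 3, length(axis) == 3)
  r <- sqrt(sum(r_vec^2))
  an <- sqrt(sum(axis^2))
  if (r <= 0) abort("zero-length separation vector")
  if (abs(an - 1) > 1e-8) abort("axis must be a unit vector")
  if (spec$kind != "angular_lj") abort("spec must have kind 'angular_lj'")
  if (r >= spec$r_cut) return(list(energy = 0, force = c(0, 0, 0)))
  eps <- spec$epsilon; sig <- spec$sigma_pair; rc <- spec$r_cut
  sr6 <- (sig / r)^6; src6 <- (sig / rc)^6
  A <- 4 * eps * (sr6^2 - src6^2)
  B <- -4 * eps * (sr6 - src6)
  dA <- -48 * eps * sr6^2 / r
  dB <- 24 * eps * sr6 / r
  cth <- max(-1, min(1, sum(r_vec * axis) / r))
  th <- acos(cth)
  n <- spec$n_geom; thc <- spec$theta_cut
  iso <- (n == 0 && thc >= pi / 2 - 1e-12)
  if (iso) {
    g <- 1; dgdc <- 0
  } else if (th >= thc) {
    g <- 0; dgdc <- 0
  } else {
    a <- pi / (2 * thc)
    cc <- cos(a * th)
    g <- cc^(2 * n)
    ratio <- if (sin(th) > 1e-8) sin(a * th) / sin(th) else a
    dgdc <- 2 * n * a * cc^(2 * n - 1) * ratio
  }
  energy <- A + g * B
  rhat <- r_vec / r
  # force on ligand = -(A' + g B') rhat - B dg/dcos * (axis - cth*rhat)/r
  force <- -(dA + g * dB) * rhat - B * dgdc * (axis - cth * rhat) / r
  list(energy = energy, force = force)
}

#' Angular Lennard-Jones energy profile
#'
#' Vectorized energy evaluation of the patchy ligand-receptor potential at
#' given distances and polar angles (receptor axis at theta = 0). Convenient
#' for plotting and for tabulating the binding well.
#'
#' @param r Distances (vector).
#' @param theta Polar angles in radians (vector, recycled against `r`).
#' @param spec A `cg_interaction` of kind `"angular_lj"`.
#' @return A tibble with columns `r`, `theta`, `energy`.
#' @export
angular_lj_energy <- function(r, theta, spec) {
  stopifnot(spec$kind == "angular_lj")
  d <- tibble(r = r, theta = theta)
  eps <- spec$epsilon; sig <- spec$sigma_pair; rc <- spec$r_cut
  sr6 <- (sig / d$r)^6; src6 <- (sig / rc)^6
  A <- 4 * eps * (sr6^2 - src6^2)
  B <- -4 * eps * (sr6 - src6)
  g <- ang_weight(d$theta, spec$n_geom, spec$theta_cut)
  d$energy <- ifelse(d$r < rc, A + g * B, 0)
  d
}

#' Worm-like-chain tension
#'
#' Interpolated force-extension law of a worm-like chain with contour length
#' `L0` and persistence length `lp`:
#' \deqn{F(r) = \frac{k_B T}{l_p}\left[\frac{1}{4(1 - r/L_0)^2} -
#'   \frac{1}{4} + \frac{r}{L_0}\right].}
#' The divergence at full extension is an artifact of the continuum law at a
#' finite timestep, so the tension is capped at its value at
#' `cap_fraction * L0`; extensions at or beyond `L0` trigger a warning
#' (over-stretch event) and return the capped force, never a non-finite
#' value.
#'
#' @param r Extension(s), >= 0.
#' @param linker A `cg_linker`.
#' @param cap_fraction Fraction of `L0` beyond which the force is clamped.
#' @return Numeric vector of tensions (energy/length units).
#' @export
wlc_force <- function(r, linker, cap_fraction = 0.99) {
  stopifnot(inherits(linker, "cg_linker"), all(r >= 0))
  if (any(r >= linker$L0))
    warn(sprintf("%d over-stretch event(s): extension >= L0, force capped",
                 sum(r >= linker$L0)))
  x <- pmin(r / linker$L0, cap_fraction)
  (linker$kBT / linker$lp) * (0.25 / (1 - x)^2 - 0.25 + x)
}

# potential energy of the WLC tension (integral of wlc_force from 0), with
# linear continuation beyond the cap
wlc_energy <- function(r, linker, cap_fraction = 0.99) {
  x <- pmin(r / linker$L0, cap_fraction)
  u <- (linker$kBT * linker$L0 / linker$lp) *
    (0.25 / (1 - x) - 0.25 - 0.25 * x + 0.5 * x^2)
  over <- r > cap_fraction * linker$L0
  if (any(over)) {
    fc <- wlc_force(cap_fraction * linker$L0 * (1 - 1e-12), linker, cap_fraction)
    u[over] <- u[over] + fc * (r[over] - cap_fraction * linker$L0)
  }
  u
}

#' Mean end-to-end distance of the worm-like-chain linker
#'
#' Two conventions are provided. The default, `"boltzmann"`, is the
#' self-consistent equilibrium mean of the implemented tension law: the
#' Boltzmann average \eqn{\langle r\rangle = \int r^3 e^{-U(r)/k_BT} dr /
#' \int r^2 e^{-U(r)/k_BT} dr} over \eqn{[0, L_0)} with
#' \eqn{U(r) = \int_0^r F}, which is what a simulated linker-tethered dimer
#' actually samples. `"kratky-porod"` returns the textbook interpolation
#' \eqn{\sqrt{\langle r^2\rangle}} with
#' \eqn{\langle r^2\rangle = 2 l_p L_0 [1 - (l_p/L_0)(1 - e^{-L_0/l_p})]};
#' it describes the free discrete chain rather than the effective dimer and
#' typically exceeds the Boltzmann mean by 20-30% for flexible linkers.
#'
#' @param linker A `cg_linker`.
#' @param method `"boltzmann"` (default) or `"kratky-porod"`.
#' @return Mean end-to-end distance, in (0, L0).
#' @export
wlc_mean_extension <- function(linker,
                               method = c("boltzmann", "kratky-porod")) {
  method <- match.arg(method)
  L0 <- linker$L0; lp <- linker$lp; kBT <- linker$kBT
  if (method == "kratky-porod") {
    r2 <- 2 * lp * L0 * (1 - (lp / L0) * (1 - exp(-L0 / lp)))
    return(sqrt(r2))
  }
  U <- function(r) {
    x <- r / L0
    (kBT * L0 / lp) * (0.25 / (1 - x) - 0.25 - 0.25 * x + 0.5 * x^2)
  }
  w <- function(r) r^2 * exp(-U(r) / kBT)
  hi <- L0 * (1 - 1e-9)
  num <- integrate(function(r) r * w(r), 0, hi, rel.tol = 1e-10)$value
  den <- integrate(w, 0, hi, rel.tol = 1e-10)$value
  num / den
}
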