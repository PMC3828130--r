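#' Particle species specification
#'
#' @param name Species identifier (e.g. `"L"`, `"R"`, `"AE"`, `"TER"`).
#' @param sigma Particle diameter (reduced length units).
#' @param mass Particle mass (reduced units).
#' @param diffusion Diffusion coefficient D (sigma^2/tau). `0` freezes the
#'   species in place (used when receptor diffusion is neglected).
#' @param domain `"bulk3d"` for ligands diffusing in the volume or
#'   `"membrane2d"` for receptors confined to the z = 0 plane.
#' @return An object of class `cg_species`.
#' @export
#' @examples
#' species_spec("L", sigma = 0.5, mass = 1, diffusion = 0.1, domain = "bulk3d")
species_spec <- function(name, sigma, mass = 1, diffusion = 0.1,
                         domain = c("bulk3d", "membrane2d")) {
  domain <- match.arg(domain)
  stopifnot(sigma > 0, mass > 0, diffusion >= 0)
  structure(list(name = name, sigma = sigma, mass = mass,
                 diffusion = diffusion, domain = domain),
            class = "cg_species")
}

#' @export
print.cg_species <- function(x, ...) {
  cat(sprintf("<cg_species> %s  sigma=%.3g m=%.3g D=%.3g  [%s]\n",
              x$name, x$sigma, x$mass, x$diffusion, x$domain))
  invisible(x)
}

#' Simulation box
#'
#' Periodic in x and y; bounded in z by the membrane plane (z = 0) and a
#' reflective ceiling at `lz`.
#'
#' @param lx,ly,lz Box edge lengths (reduced units).
#' @return An object of class `cg_box`.
#' @export
box_spec <- function(lx, ly, lz) {
  stopifnot(lx > 0, ly > 0, lz > 0)
  structure(list(lx = lx, ly = ly, lz = lz), class = "cg_box")
}

#' Box from a surface receptor density
#'
#' Lateral dimensions follow from the requested number of receptors and their
#' surface density: `lx = ly = sqrt(n_receptors / density)`.
#'
#' @param n_receptors Total receptors to place in the plane.
#' @param density Surface density rho_s (receptors per sigma_R^2).
#' @param lz Box height.
#' @return A `cg_box`.
#' @export
box_from_density <- function(n_receptors, density, lz) {
  stopifnot(n_receptors > 0, density > 0)
  l <- sqrt(n_receptors / density)
  box_spec(l, l, lz)
}
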