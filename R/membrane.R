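#' Lattice membrane leaflet
#'
#' The membrane model used throughout: a planar 2D lattice of lipid sites in
#' the `z = 0` plane (outward normal `+z`), each site covering
#' `lattice_spacing^2` Angstrom^2.  One species is the laterally mobile
#' anionic lipid (PS: -1 e, PIP2: -4 e per headgroup); its local area
#' fraction is the density field `phi(x, y)`.  For the mean-field solver the
#' lattice is tiled periodically over the lateral simulation box, so a
#' uniform `phi` represents an infinite uniformly charged membrane.
#'
#' @param nx,ny lattice dimensions (sites).
#' @param lattice_spacing site edge length, Angstrom (default `sqrt(65)`,
#'   one lipid of 65 A^2 per site).
#' @param species data frame with columns `name`, `headgroup_charge` (e) and
#'   `mole_fraction`; fractions must sum to 1.
#' @param anionic name of the mobile anionic species (default: the species
#'   with the most negative headgroup charge).
#' @param phi initial anionic area-fraction field (`nx` x `ny` matrix or a
#'   scalar); defaults to the anionic mole fraction everywhere.
#' @param area_per_lipid Angstrom^2 per lipid (default 65).
#' @param plane_origin 3-vector, a point on the membrane plane.
#' @param site_occupancy optional character matrix (`nx` x `ny`) of species
#'   names for discrete bilayer realizations.
#' @return object of class `lattice_membrane`.
#' @export
lattice_membrane <- function(nx, ny, lattice_spacing = sqrt(65),
                             species = default_membrane_species(),
                             anionic = NULL, phi = NULL,
                             area_per_lipid = 65,
                             plane_origin = c(0, 0, 0),
                             site_occupancy = NULL) {
  species <- as.data.frame(species)
  if (abs(sum(species$mole_fraction) - 1) > 1e-9) {
    stop("lattice_membrane: species mole fractions must sum to 1")
  }
  if (is.null(anionic)) {
    anionic <- species$name[which.min(species$headgroup_charge)]
  }
  if (!anionic %in% species$name) stop("unknown anionic species: ", anionic)
  fa <- species$mole_fraction[species$name == anionic]
  if (is.null(phi)) phi <- fa
  if (length(phi) == 1) phi <- matrix(phi, nx, ny)
  phi <- as.matrix(phi)
  if (!all(dim(phi) == c(nx, ny))) stop("phi must be an nx x ny matrix")
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  structure(list(
    nx = nx, ny = ny,
    lattice_spacing = lattice_spacing,
    area_per_lipid = area_per_lipid,
    species = species,
    anionic = anionic,
    phi = phi,
    plane_origin = plane_origin,
    normal = c(0, 0, 1),
    site_occupancy = site_occupancy
  ), class = "lattice_membrane")
}

#' Default four-species plasma-membrane-like composition
#'
#' 44:23:23:10 POPC:POPE:cholesterol:anionic, the donor-vesicle composition
#' used for the membrane simulations; the anionic slot defaults to PS (-1 e).
#' Use `anionic_charge = -4` for a PIP2 membrane.
#'
#' @param anionic_name,anionic_charge identity of the 10% anionic component.
#' @return species data frame.
#' @export
default_membrane_species <- function(anionic_name = "POPS", anionic_charge = -1) {
  data.frame(
    name = c("POPC", "POPE", "CHOL", anionic_name),
    headgroup_charge = c(0, 0, 0, anionic_charge),
    mole_fraction = c(0.44, 0.23, 0.23, 0.10),
    stringsAsFactors = FALSE
  )
}

#' @export
print.lattice_membrane <- function(x, ...) {
  cat(sprintf("<lattice_membrane> %d x %d sites, spacing %.2f A, anionic '%s' (z=%+g e)\n",
              x$nx, x$ny, x$lattice_spacing, x$anionic,
              x$species$headgroup_charge[x$species$name == x$anionic]))
  cat(sprintf("  mean phi %.4f, anionic amount %.3f lipids\n",
              mean(x$phi), anionic_amount(x)))
  invisible(x)
}

#' Total mobile anionic lipid content of a leaflet
#'
#' `sum(phi) * site_area / area_per_lipid`, in lipid molecules.  This amount
#' is conserved exactly by every density update.
#'
#' @param membrane a [lattice_membrane()].
#' @return number of anionic lipids represented by the `phi` field.
#' @export
anionic_amount <- function(membrane) {
  sum(membrane$phi) * membrane$lattice_spacing^2 / membrane$area_per_lipid
}

# headgroup charge of the mobile anionic species, e
.anionic_charge <- function(membrane) {
  membrane$species$headgroup_charge[membrane$species$name == membrane$anionic]
}

# surface charge density field sigma(x, y) in e / A^2 for given phi
.surface_charge_density <- function(membrane, phi = membrane$phi) {
  .anionic_charge(membrane) * phi / membrane$area_per_lipid
}

# site x/y centers (used for maps and placement export)
.membrane_site_table <- function(membrane) {
  s <- membrane$lattice_spacing
  expand.grid(ix = seq_len(membrane$nx), iy = seq_len(membrane$ny),
              KEEP.OUT.ATTRS = FALSE)[, c("ix", "iy")] |>
    transform(x = (ix - 0.5) * s + membrane$plane_origin[1],
              y = (iy - 0.5) * s + membrane$plane_origin[2])
}
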