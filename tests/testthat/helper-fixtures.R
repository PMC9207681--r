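# Shared fixture builders.  Everything is generated in code; no data files.

# small solver setup used across the mean-field tests (h = lambda/2 at 0.15 M)
small_cfg <- function(...) {
  memfield_config(box_edge_A = 128, grid_points = 32, ...)
}

small_membrane <- function(anionic_charge = -1) {
  # spacing 8 A = 2 grid cells of the small solver box: sites commensurate
  # with the grid, so a uniform phi is an exactly uniform surface charge
  lattice_membrane(16, 16, lattice_spacing = 8,
                   species = default_membrane_species(anionic_charge = anionic_charge))
}

# place a structure centered laterally at (cx, cy) with its lowest atom at
# height z_min
place_at <- function(x, cx, cy, z_min) {
  xyz <- as.matrix(x)
  xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + cx
  xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + cy
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + z_min
  st <- x
  st$atoms[, c("x", "y", "z")] <- xyz
  st
}

# a bare structure from a coordinate matrix (all atoms one segment)
coords_structure <- function(xyz, charge = 0, segment = "other",
                             name = "CA", residue_name = "ALA",
                             element = "C", residue_id = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  charged_structure(data.frame(
    atom_id = seq_len(n), name = name, residue_name = residue_name,
    residue_id = residue_id %||% seq_len(n), segment = segment,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), element = element,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small charged structure for IO round-trips
random_structure <- function(seed, n = 30) {
  set.seed(seed)
  coords_structure(matrix(runif(3 * n, -40, 40), ncol = 3),
                   charge = sample(c(-1, 0, 0, 1), n, replace = TRUE))
}

# ideal CA helix along +z
ideal_helix <- function(n = 22, rise = 1.5, twist = 100, radius = 2.3) {
  i <- seq_len(n) - 1
  cbind(radius * cos(i * twist * pi / 180),
        radius * sin(i * twist * pi / 180),
        i * rise)
}

# two-cluster probe used by the embedding tests: an omega1-loop pad and a
# beta/cterm pad at slightly different heights, over a bead slab membrane
embedding_probe <- function() {
  pad <- function(x0, y0, z0, nx = 4, ny = 4, s = 2.2) {
    g <- expand.grid(x = x0 + s * seq_len(nx), y = y0 + s * seq_len(ny))
    cbind(g$x, g$y, z0)
  }
  omega <- pad(0, 0, 0)
  beta <- pad(14, 0, 1.2)
  atoms <- rbind(
    data.frame(name = "CA", residue_name = "GLY", residue_id = 90 + seq_len(nrow(omega)),
               segment = "omega1_loop", x = omega[, 1], y = omega[, 2], z = omega[, 3],
               charge = 0, element = "C", stringsAsFactors = FALSE),
    data.frame(name = "CA", residue_name = "VAL", residue_id = 150 + seq_len(nrow(beta)),
               segment = "beta_sheet", x = beta[, 1], y = beta[, 2], z = beta[, 3],
               charge = 0, element = "C", stringsAsFactors = FALSE))
  atoms$atom_id <- seq_len(nrow(atoms))
  charged_structure(atoms)
}

# descend a protein stepwise toward the membrane plane of a trajectory
descend_trajectory <- function(protein, membrane, heights, tilt = 0) {
  sched <- data.frame(tilt = rep(tilt, length(heights)),
                      rotation = rep(0, length(heights)))
  tr <- make_trajectory(protein, membrane, sched, n_frames = length(heights),
                        height = max(heights) + 1)
  prot_rows <- seq_len(nrow(protein$atoms))
  for (f in seq_along(heights)) {
    dz <- min(tr$coords[prot_rows, 3, f]) - heights[f]
    tr$coords[prot_rows, 3, f] <- tr$coords[prot_rows, 3, f] - dz
  }
  tr
}
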