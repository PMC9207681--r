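# Seeded synthetic-data generators: lattice bilayers at the study
# composition, bead proteins with labeled segments and charged sites,
# trajectories with planted orientations and lipid-binding events, and
# noisy single-exponential FRET traces.  All generators are deterministic
# under a fixed seed.

#' Largest-remainder (Hamilton) allocation of counts to fractions
#' @param n total count.
#' @param fractions percentage fractions (must sum to 100).
#' @return integer counts summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  if (abs(sum(fractions) - 100) > 1e-9) stop("fractions must sum to 100")
  exact <- n * fractions / 100
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# most-square factorization nx * ny = n with nx <= ny
.factor_lattice <- function(n) {
  nx <- floor(sqrt(n))
  while (nx > 1 && n %% nx != 0) nx <- nx - 1
  c(nx, n / nx)
}

#' Build a symmetric lattice bilayer
#'
#' Allocates per-leaflet species counts by largest remainder from the
#' composition (default 44:23:23:10 POPC:POPE:cholesterol:anionic, i.e. 200
#' lipids per leaflet give 88/46/46/20 and a 400-lipid bilayer), assigns
#' species to lattice sites by a seeded permutation (or proportionally to a
#' supplied density map), and mirrors the leaflet.
#'
#' @param n_per_leaflet lipids per leaflet (default 200).
#' @param composition percentage fractions, must sum to 100.
#' @param species_names names matching `composition`.
#' @param anionic_species name of the anionic species (charge
#'   `anionic_charge`).
#' @param anionic_charge headgroup charge of the anionic species, e.
#' @param lattice_spacing site edge, Angstrom.
#' @param seed RNG seed for site placement.
#' @param density_map optional matrix (lattice-shaped) of anionic placement
#'   weights (e.g. a mean-field steady-state map).
#' @return a [lattice_membrane()] for the upper leaflet carrying
#'   `site_occupancy`; attributes `counts` (per-leaflet species counts) and
#'   `total_lipids` (both leaflets).
#' @export
make_bilayer <- function(n_per_leaflet = 200,
                         composition = c(44, 23, 23, 10),
                         species_names = c("POPC", "POPE", "CHOL", "POPS"),
                         anionic_species = NULL,
                         anionic_charge = -1,
                         lattice_spacing = sqrt(65),
                         seed = 1,
                         density_map = NULL) {
  if (length(composition) != length(species_names)) {
    stop("composition and species_names lengths differ")
  }
  counts <- largest_remainder(n_per_leaflet, composition)
  if (is.null(anionic_species)) anionic_species <- species_names[length(species_names)]
  dims <- .factor_lattice(n_per_leaflet)
  nx <- dims[1]; ny <- dims[2]
  species <- data.frame(name = species_names,
                        headgroup_charge = ifelse(species_names == anionic_species,
                                                  anionic_charge, 0),
                        mole_fraction = composition / 100,
                        stringsAsFactors = FALSE)
  set.seed(seed)
  pool <- rep(species_names, counts)
  if (is.null(density_map)) {
    occ <- matrix(sample(pool), nx, ny)
  } else {
    if (length(density_map) != n_per_leaflet) stop("density map size mismatch")
    n_an <- counts[species_names == anionic_species]
    an_sites <- export_density_and_place(matrix(density_map, nx, ny),
                                         lattice_membrane(nx, ny, lattice_spacing,
                                                          species,
                                                          anionic = anionic_species),
                                         n_an, seed = seed)
    occ <- matrix("", nx, ny)
    occ[cbind(an_sites$ix, an_sites$iy)] <- anionic_species
    rest <- sample(rep(species_names[species_names != anionic_species],
                       counts[species_names != anionic_species]))
    occ[occ == ""] <- rest
  }
  phi <- matrix(as.numeric(occ == anionic_species), nx, ny)
  mem <- lattice_membrane(nx, ny, lattice_spacing, species,
                          anionic = anionic_species, phi = phi,
                          site_occupancy = occ)
  attr(mem, "counts") <- setNames(counts, species_names)
  attr(mem, "total_lipids") <- 2L * n_per_leaflet
  mem
}

#' Bead-protein specification
#'
#' An idealized stand-in for a membrane-binding StarT-domain protein: a
#' C-terminal helix built as an ideal CA helix, an Omega1-loop bead cluster
#' (the rotation reference), a beta-sheet bead cluster, and named charged
#' sites (e.g. `R46`, `R58`, `S215`, `R218`) carrying the basic-patch
#' charges.
#'
#' @param helix list with `n_residues` (>= 4), `rise` (Angstrom/residue,
#'   default 1.5), `twist` (deg/residue, default 100), `radius` (Angstrom,
#'   default 2.3), `start_residue` (default 203).
#' @param loop,sheet bead layouts: list with `offsets` (N x 3 matrix) and
#'   `residues` (ids).
#' @param charged_sites data frame with columns `label`, `x`, `y`, `z`,
#'   `charge`.
#' @return list of class `bead_protein_spec`.
#' @export
bead_protein_spec <- function(helix = list(), loop = NULL, sheet = NULL,
                              charged_sites = NULL) {
  helix <- modifyList(list(n_residues = 22, rise = 1.5, twist = 100,
                           radius = 2.3, start_residue = 203), helix)
  if (helix$n_residues < 4) stop("helix needs at least 4 residues")
  if (is.null(loop)) {
    loop <- list(offsets = cbind(x = c(-6, -7, -6, -5, -6),
                                 y = c(-1, 0, 1, 0, 0),
                                 z = c(2, 3, 4, 3, 3)),
                 residues = 90:94)
  }
  if (is.null(sheet)) {
    sheet <- list(offsets = cbind(x = c(4, 5, 6, 4, 5, 6),
                                  y = c(5, 5, 5, 6, 6, 6),
                                  z = c(6, 6, 6, 8, 8, 8)),
                  residues = 30:35)
  }
  if (is.null(charged_sites)) {
    charged_sites <- data.frame(
      label = c("R46", "R58", "S215", "R218"),
      x = c(7, 13, -3, -3), y = c(0, 0, 4, -4), z = c(2, 2, 0, 0),
      charge = c(1, 1, 0, 1), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(charged_sites$label)) stop("duplicate charged-site labels")
  structure(list(helix = helix, loop = loop, sheet = sheet,
                 charged_sites = charged_sites), class = "bead_protein_spec")
}

.site_residue_info <- function(label) {
  type <- substr(label, 1, 1)
  id <- as.integer(sub("^[A-Za-z]+", "", label))
  rn <- switch(type, R = "ARG", K = "LYS", S = "SER", H = "HIS", D = "ASP",
               E = "GLU", "ALA")
  an <- switch(rn, ARG = "NH1", LYS = "NZ", SER = "OG", HIS = "NE2",
               ASP = "OD1", GLU = "OE1", "CB")
  el <- substr(an, 1, 1)
  list(residue_name = rn, residue_id = id, atom_name = an, element = el)
}

#' Build a bead protein from a specification
#'
#' The helix CA trace follows the ideal geometry (rise/twist/radius) along
#' `+z` starting at the origin; loop, sheet and charged-site beads are
#' placed at their specified offsets.  Deterministic; `seed` only matters
#' when `jitter_sd > 0`.
#'
#' @param spec a [bead_protein_spec()].
#' @param seed RNG seed for optional coordinate jitter.
#' @param jitter_sd Gaussian jitter applied to all beads (default 0).
#' @return a [charged_structure()].
#' @export
make_bead_protein <- function(spec = bead_protein_spec(), seed = 1,
                              jitter_sd = 0) {
  h <- spec$helix
  i <- seq_len(h$n_residues) - 1
  hx <- cbind(h$radius * cos(i * h$twist * pi / 180),
              h$radius * sin(i * h$twist * pi / 180),
              i * h$rise)
  rows <- data.frame(
    name = "CA", residue_name = "ALA",
    residue_id = h$start_residue + i, segment = "cterm_helix",
    x = hx[, 1], y = hx[, 2], z = hx[, 3], charge = 0, element = "C",
    stringsAsFactors = FALSE)
  add <- function(rows, offs, resids, seg, resname) {
    rbind(rows, data.frame(name = "CA", residue_name = resname,
                           residue_id = resids, segment = seg,
                           x = offs[, 1], y = offs[, 2], z = offs[, 3],
                           charge = 0, element = "C", stringsAsFactors = FALSE))
  }
  rows <- add(rows, spec$loop$offsets, spec$loop$residues, "omega1_loop", "GLY")
  rows <- add(rows, spec$sheet$offsets, spec$sheet$residues, "beta_sheet", "VAL")
  cs <- spec$charged_sites
  for (s in seq_len(nrow(cs))) {
    info <- .site_residue_info(cs$label[s])
    rows <- rbind(rows, data.frame(
      name = info$atom_name, residue_name = info$residue_name,
      residue_id = info$residue_id, segment = "other",
      x = cs$x[s], y = cs$y[s], z = cs$z[s], charge = cs$charge[s],
      element = info$element, stringsAsFactors = FALSE))
  }
  if (jitter_sd > 0) {
    set.seed(seed)
    rows[, c("x", "y", "z")] <- rows[, c("x", "y", "z")] +
      matrix(rnorm(3 * nrow(rows), sd = jitter_sd), ncol = 3)
  }
  rows$atom_id <- seq_len(nrow(rows))
  charged_structure(rows)
}

#' Binding plan for planted residue-lipid contacts
#'
#' `events` lists the frames in which a (residue, lipid) pair is bound; any
#' planned pair is held at `unbound_distance` in its other frames.  Rows
#' sharing (lipid, frame) across several residues produce a shared-site
#' placement (the oxygen bead sits at the midpoint of the residues' polar
#' atoms).
#'
#' @param events data frame with columns `residue` (id), `lipid` (lipid
#'   residue id), `frame` (1-based frame index).
#' @param bound_distance planted bound O-to-atom distance (default 3.5).
#' @param unbound_distance planted unbound distance (default 5.5).
#' @param cutoff the contact criterion the plan must be consistent with
#'   (default 4): requires `bound < cutoff <= unbound`.
#' @return list of class `binding_plan`.
#' @export
binding_plan <- function(events = data.frame(residue = integer(0),
                                             lipid = integer(0),
                                             frame = integer(0)),
                         bound_distance = 3.5, unbound_distance = 5.5,
                         cutoff = 4) {
  if (!(bound_distance < cutoff && cutoff <= unbound_distance)) {
    stop("binding plan must satisfy bound < cutoff <= unbound")
  }
  events <- as.data.frame(events)
  structure(list(events = events, bound_distance = bound_distance,
                 unbound_distance = unbound_distance, cutoff = cutoff),
            class = "binding_plan")
}

# sample an orientation schedule from a law specification
.sample_schedule <- function(law, n_frames) {
  draw1 <- function(n, l) {
    tl <- rnorm(n, l$tilt_mean, l$tilt_sd %||% 0)
    tl <- abs(tl); tl[tl > 180] <- 360 - tl[tl > 180]   # reflect into [0, 180]
    rt <- rnorm(n, l$rotation_mean, l$rotation_sd %||% 0)
    rt <- ((rt + 180) %% 360) - 180                     # wrap into [-180, 180)
    data.frame(tilt = tl, rotation = rt)
  }
  if (!is.null(law$components)) {
    w <- vapply(law$components, function(c) c$weight %||% 1, numeric(1))
    pick <- sample.int(length(w), n_frames, replace = TRUE, prob = w / sum(w))
    out <- draw1(n_frames, law$components[[1]])
    for (ci in seq_along(law$components)[-1]) {
      sel <- pick == ci
      if (any(sel)) out[sel, ] <- draw1(sum(sel), law$components[[ci]])
    }
    out
  } else draw1(n_frames, law)
}

#' Generate a trajectory with planted orientations and binding events
#'
#' Each frame poses the bead protein above the membrane at the scheduled
#' (tilt, rotation) -- measured exactly as [orientation_angles()] measures
#' them -- and realizes the binding plan by moving the planned lipids'
#' headgroup-oxygen beads to the bound (or unbound) distance from the named
#' residues' polar atoms.  All other lipids sit at their lattice sites with
#' a P bead in the plane and an O bead 1 Angstrom above it.
#'
#' @param protein a bead [charged_structure()] (canonical build from
#'   [make_bead_protein()], helix along +z).
#' @param membrane a [lattice_membrane()] (e.g. from [make_bilayer()]).
#' @param orientation_schedule data frame with `tilt`/`rotation` columns
#'   (`n_frames` rows), or a law list (`tilt_mean`, `tilt_sd`,
#'   `rotation_mean`, `rotation_sd`, or `components` list of such with
#'   `weight`s) sampled under `seed`.
#' @param binding_plan a [binding_plan()] (default: empty).
#' @param n_frames number of frames.
#' @param stride_ns time between frames, ns.
#' @param seed RNG seed (schedule sampling).
#' @param height minimum protein bead height above the plane, Angstrom
#'   (default 8, keeping unplanned lipid contacts impossible under a 4
#'   Angstrom criterion).
#' @return an [mf_trajectory()] whose topology is protein + lipid beads.
#' @export
make_trajectory <- function(protein, membrane, orientation_schedule,
                            binding_plan = NULL, n_frames = NULL,
                            stride_ns = 0.1, seed = 1, height = 8) {
  if (is.null(binding_plan)) binding_plan <- memfield::binding_plan()
  if (is.data.frame(orientation_schedule)) {
    sched <- orientation_schedule
    if (is.null(n_frames)) n_frames <- nrow(sched)
    if (nrow(sched) != n_frames) stop("schedule length must match n_frames")
  } else {
    if (is.null(n_frames)) stop("n_frames required with a sampling law")
    set.seed(seed)
    sched <- .sample_schedule(orientation_schedule, n_frames)
  }
  # lipid beads: P at the site center in-plane, O1 one Angstrom above
  st <- .membrane_site_table(membrane)
  nsite <- nrow(st)
  occ <- membrane$site_occupancy
  lip_name <- if (is.null(occ)) rep("LIP", nsite) else occ[cbind(st$ix, st$iy)]
  lip_res <- 1000L + seq_len(nsite)
  np <- nrow(protein$atoms)
  lip <- data.frame(
    atom_id = np + seq_len(2 * nsite),
    name = rep(c("P", "O1"), nsite),
    residue_name = rep(lip_name, each = 2),
    residue_id = rep(lip_res, each = 2),
    segment = "other",
    x = rep(st$x, each = 2), y = rep(st$y, each = 2),
    z = rep(c(0, 1), nsite),
    charge = 0, element = rep(c("P", "O"), nsite),
    stringsAsFactors = FALSE)
  topo <- charged_structure(rbind(protein$atoms, lip))
  o_row <- np + 2 * match(lip_res, lip_res)   # O1 row per lipid (in topo)
  names(o_row) <- as.character(lip_res)
  xyz_lip <- as.matrix(lip[, c("x", "y", "z")])
  xyz0 <- .structure_coords(protein)
  ctr_xy <- c(mean(st$x), mean(st$y))
  hel_p <- which(protein$atoms$segment == "cterm_helix" & protein$atoms$name == "CA")
  loop_p <- which(protein$atoms$segment == "omega1_loop")
  plane <- list(origin = c(0, 0, 0), normal = c(0, 0, 1))
  ev <- binding_plan$events
  planned_lipids <- unique(ev$lipid)
  coords <- array(NA_real_, dim = c(nrow(topo$atoms), 3, n_frames))
  for (f in seq_len(n_frames)) {
    th <- sched$tilt[f]; rho <- sched$rotation[f]
    Rt <- rotation_matrix(c(0, 1, 0), th)
    xyz <- xyz0 %*% t(Rt)
    if (th > 1e-9 && th < 180 - 1e-9) {
      ax <- helix_axis(xyz[hel_p, , drop = FALSE])
      ang0 <- orientation_angles(xyz[hel_p, , drop = FALSE],
                                 colMeans(xyz[loop_p, , drop = FALSE]), plane)
      xyz <- .rotate_coords(xyz, rotation_matrix(ax, rho - ang0$rotation),
                            colMeans(xyz))
    }
    xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + ctr_xy[1]
    xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + ctr_xy[2]
    xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + height
    frame <- rbind(xyz, xyz_lip)
    prot_ctr <- colMeans(xyz)
    for (lid in planned_lipids) {
      here <- ev$frame == f & ev$lipid == lid
      o_i <- o_row[[as.character(lid)]]
      if (any(here)) {
        rids <- unique(ev$residue[here])
        frame[o_i, ] <- .planted_o_position(topo, frame, rids, lid, prot_ctr,
                                            binding_plan)
      } else {
        rid <- ev$residue[ev$lipid == lid][1]
        atom_i <- .residue_polar_row(topo, rid)
        u <- .unit(frame[atom_i, ] - prot_ctr)
        frame[o_i, ] <- frame[atom_i, ] + binding_plan$unbound_distance * u
      }
    }
    coords[, , f] <- frame
  }
  mf_trajectory(topo, coords, times = (seq_len(n_frames) - 1) * stride_ns,
                membrane = membrane)
}

# polar (charged-site) atom row for a protein residue id
.residue_polar_row <- function(topo, rid) {
  a <- topo$atoms
  i <- which(a$residue_id == rid & a$segment == "other" & a$residue_id < 1000)
  if (!length(i)) i <- which(a$residue_id == rid & a$residue_id < 1000)
  if (!length(i)) stop("binding plan references unknown residue ", rid)
  i[1]
}

# bound O-bead position for one or several target residues
.planted_o_position <- function(topo, frame, rids, lid, prot_ctr, plan) {
  rows <- vapply(rids, function(r) .residue_polar_row(topo, r), integer(1))
  if (length(rows) == 1) {
    base <- frame[rows, ]
    u <- .unit(base - prot_ctr)
    # vary the direction by lipid id so several lipids can bind one residue
    perp <- .unit(.cross(u, if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
    ang <- (lid %% 7) * 137.5
    R <- rotation_matrix(u, ang)
    dir <- .unit(u + 0.35 * as.vector(R %*% perp))
    pos <- base + plan$bound_distance * dir
    d <- .vnorm(pos - base)
    if (d >= plan$cutoff) stop("planted bound distance >= cutoff; fixture unverifiable")
    return(pos)
  }
  pos <- colMeans(frame[rows, , drop = FALSE])
  d <- max(sqrt(rowSums(sweep(frame[rows, , drop = FALSE], 2, pos)^2)))
  if (d >= plan$cutoff) {
    stop("shared-site placement cannot satisfy the cutoff for residues ",
         paste(rids, collapse = ", "))
  }
  pos
}

#' Generate a single-exponential FRET trace
#'
#' \eqn{F(t) = F_\infty + (F_0 - F_\infty)e^{-kt}} plus Gaussian noise.
#'
#' @param F0,F_inf initial and plateau signal.
#' @param k rate constant, 1/min (>= 0).
#' @param t_grid times, minutes (strictly increasing).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed RNG seed.
#' @param metadata forwarded to [fret_trace()].
#' @return a [fret_trace()].
#' @export
make_fret_trace <- function(F0, F_inf, k, t_grid, noise_sd = 0, seed = 1,
                            metadata = list()) {
  if (k < 0) stop("rate constant must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  y <- F_inf + (F0 - F_inf) * exp(-k * t_grid)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(t_grid), sd = noise_sd)
  }
  fret_trace(t_grid, y, metadata = metadata)
}

#' Aggregate simulation-plan bookkeeping
#'
#' Total sampled time per loading state: `n_traj * per_traj_duration_us`
#' (e.g. 12 trajectories of 2.2 us give 26.4 us).
#'
#' @param n_traj number of trajectories.
#' @param per_traj_duration_us duration of each, microseconds.
#' @return aggregate duration in microseconds.
#' @export
plan_totals <- function(n_traj, per_traj_duration_us) {
  if (n_traj <= 0 || per_traj_duration_us <= 0) stop("inputs must be positive")
  n_traj * per_traj_duration_us
}
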