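# Orientation scan: probe the protein approaching the membrane from a set
# of directions, relax the mobile anionic lipids for each pose, and rank
# poses by adsorption free energy (most negative first).

#' Scan protein orientations against the membrane
#'
#' For each pose (Fibonacci-sphere approach direction x azimuth grid) the
#' protein is rotated so the approach direction faces the membrane, spun by
#' the azimuth about the membrane normal, translated so its lowest atom sits
#' at the clearance height, and the anionic lipid density is relaxed to
#' self-consistency.  The adsorption energy is the relaxed free energy
#' relative to the protein-at-infinity uniform-membrane reference.  The best
#' orientation is the pose with the strongest (most negative) adsorption
#' energy.
#'
#' @param protein a [charged_structure()] (any position; it is centered).
#' @param membrane a [lattice_membrane()].
#' @param cfg configuration (grid, ionic conditions, mixing...).
#' @param n_directions,n_azimuths orientation set size (defaults from `cfg`).
#' @param clearance minimum atom height above the membrane plane, Angstrom.
#' @return object of class `orientation_scan`: `poses` data frame (one row
#'   per pose, ranked ascending by adsorption energy, ties broken by
#'   direction then azimuth index), `best_phi` the relaxed density map of
#'   the best pose, `best_structure` the posed protein, `reference`.
#' @export
scan_orientations <- function(protein, membrane, cfg = memfield_config(),
                              n_directions = NULL, n_azimuths = NULL,
                              clearance = NULL) {
  sc <- if (inherits(cfg, "solver_config")) cfg else solver_config(cfg)
  if (is.null(n_directions)) n_directions <- if (inherits(cfg, "solver_config")) 72 else as.integer(cfg$n_directions)
  if (is.null(n_azimuths)) n_azimuths <- if (inherits(cfg, "solver_config")) 12 else as.integer(cfg$n_azimuths)
  if (is.null(clearance)) clearance <- sc$clearance
  if (n_directions < 1 || n_azimuths < 1) stop("orientation set must be non-empty")
  xyz0 <- sweep(.structure_coords(protein), 2, .structure_centroid(protein))
  dirs <- fibonacci_sphere(n_directions)
  az <- (seq_len(n_azimuths) - 1) * 360 / n_azimuths
  reference <- mfm_reference(membrane, sc)
  membrane$phi <- reference$phi   # start every pose from the reference state
  rows <- NULL
  best <- NULL
  for (d in seq_len(n_directions)) {
    R1 <- .rotation_to_minus_z(dirs[d, ])
    for (ai in seq_len(n_azimuths)) {
      Rz <- rotation_matrix(c(0, 0, 1), az[ai])
      xyz <- xyz0 %*% t(R1) %*% t(Rz)
      pose <- .place_pose(protein, xyz, sc, clearance)
      res <- tryCatch(
        relax_densities(pose, membrane, sc, reference = reference),
        error = function(e) e
      )
      ok <- !inherits(res, "error")
      rows <- rbind(rows, data.frame(
        direction = d, azimuth = az[ai],
        dx = dirs[d, 1], dy = dirs[d, 2], dz = dirs[d, 3],
        adsorption_energy = if (ok) res$free_energy$F_total else NA_real_,
        F_el = if (ok) res$free_energy$F_el else NA_real_,
        F_ion = if (ok) res$free_energy$F_ion else NA_real_,
        F_lip = if (ok) res$free_energy$F_lip else NA_real_,
        iterations = if (ok) res$iterations else NA_integer_,
        converged = ok
      ))
      if (ok && (is.null(best) || res$free_energy$F_total < best$energy - 0 ||
                 (res$free_energy$F_total == best$energy && FALSE))) {
        if (is.null(best) || res$free_energy$F_total < best$energy) {
          best <- list(energy = res$free_energy$F_total, phi = res$phi,
                       structure = pose, direction = d, azimuth = az[ai])
        }
      }
    }
  }
  ord <- order(rows$adsorption_energy, rows$direction, rows$azimuth,
               na.last = TRUE)
  ranked <- rows[ord, ]
  rownames(ranked) <- NULL
  structure(list(poses = ranked, best_phi = best$phi,
                 best_structure = best$structure, reference = reference,
                 clearance = clearance),
            class = "orientation_scan")
}

#' @export
print.orientation_scan <- function(x, ...) {
  p <- x$poses
  cat(sprintf("<orientation_scan> %d poses (%d converged)\n",
              nrow(p), sum(p$converged)))
  cat(sprintf("  best: direction %d, azimuth %g deg, F = %.4g kT\n",
              p$direction[1], p$azimuth[1], p$adsorption_energy[1]))
  invisible(x)
}

# rotation taking unit vector v to (0, 0, -1); azimuth convention fixed by
# rotating about the axis v x (-z)
.rotation_to_minus_z <- function(v) {
  v <- .unit(v)
  tgt <- c(0, 0, -1)
  cth <- sum(v * tgt)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) return(rotation_matrix(c(1, 0, 0), 180))
  axis <- .cross(v, tgt)
  rotation_matrix(axis, acos(cth) * 180 / pi)
}

# center laterally in the box, lift to the clearance height
.place_pose <- function(protein, xyz, sc, clearance) {
  xyz[, 1] <- xyz[, 1] - mean(xyz[, 1]) + sc$box_edge / 2
  xyz[, 2] <- xyz[, 2] - mean(xyz[, 2]) + sc$box_edge / 2
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + clearance
  .set_structure_coords(protein, xyz)
}

#' Place anionic lipids according to a steady-state density map
#'
#' Draws exactly `n_anionic` distinct lattice sites with inclusion
#' probability proportional to `phi` (systematic probability-proportional-
#' to-size sampling over a seeded random site order), the recipe used to
#' transfer the mean-field steady-state lipid density map into a discrete
#' membrane build.  Writes the density map and the placement as long-format
#' CSV when `out_density`/`out_placement` are given.
#'
#' @param phi density map (matrix, e.g. `scan$best_phi`).
#' @param membrane the [lattice_membrane()] the map lives on.
#' @param n_anionic number of anionic lipids to place.
#' @param seed RNG seed (placement is reproducible given the seed).
#' @param out_density,out_placement optional CSV paths.
#' @return data frame of selected sites (`ix`, `iy`, `x`, `y`, `phi`).
#' @export
export_density_and_place <- function(phi, membrane, n_anionic, seed = 1,
                                     out_density = NULL, out_placement = NULL) {
  phi <- as.matrix(phi)
  nsite <- length(phi)
  if (n_anionic > nsite) stop("more anionic lipids than lattice sites")
  tot <- sum(phi)
  if (tot <= 0) stop("density map is identically zero")
  pii <- n_anionic * as.vector(phi) / tot
  if (any(pii > 1 + 1e-9)) {
    stop("density map too concentrated: a site would need inclusion probability > 1 ",
         sprintf("(max %.3f); reduce n_anionic or spread the map", max(pii)))
  }
  set.seed(seed)
  ord <- sample.int(nsite)
  cum <- cumsum(pii[ord])
  u <- runif(1)
  ticks <- u + 0:(n_anionic - 1)
  sel_ord <- findInterval(ticks, cum) + 1L
  sel <- ord[pmin(sel_ord, nsite)]
  if (length(unique(sel)) != n_anionic) {
    # numerical tie at a cumulative boundary; fall back to sequential draw
    sel <- unique(sel)
    remaining <- setdiff(seq_len(nsite), sel)
    need <- n_anionic - length(sel)
    if (need > 0) {
      w <- pii[remaining]
      sel <- c(sel, remaining[sample.int(length(remaining), need,
                                         prob = pmax(w, 1e-300))])
    }
  }
  st <- .membrane_site_table(membrane)
  st$phi <- as.vector(phi)
  out <- st[sel, c("ix", "iy", "x", "y", "phi")]
  rownames(out) <- NULL
  if (!is.null(out_density)) {
    write_table_artifact(table_artifact(st[, c("x", "y", "phi")],
                                        command = "memfield dock density",
                                        seed = seed), out_density)
  }
  if (!is.null(out_placement)) {
    write_table_artifact(table_artifact(out, command = "memfield dock placement",
                                        seed = seed), out_placement)
  }
  out
}
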