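# Solvent-accessible surface areas (Shrake-Rupley) and buried contact area
# between a protein selection and the membrane.  The buried contact area is
# half the solvent-accessible area lost on forming the complex:
# (A_P + A_M - A_PM) / 2.

# golden-spiral points on the unit sphere (deterministic)
.sphere_points <- function(n) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * (i - 0.5)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.default_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8,
                    X = 1.7)

.atom_radii <- function(elements, radii = .default_radii) {
  r <- radii[elements]
  r[is.na(r)] <- radii["X"]
  if (any(r <= 0)) stop("zero or negative atom radius")
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param xyz N x 3 coordinates, Angstrom.
#' @param radii per-atom radii, Angstrom.
#' @param probe probe radius (default 1.4, water).
#' @param n_points test points per atom sphere (default 960).
#' @return total SASA in Angstrom^2.
#' @export
sasa <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (length(radii) != n) stop("radii length must match atom count")
  if (any(radii <= 0)) stop("zero or negative atom radius")
  sp <- .sphere_points(n_points)
  rr <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    ri <- rr[i]
    d <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(d^2)
    nb <- which(d2 < (ri + rr)^2 & seq_len(n) != i)
    pts <- sweep(sp * ri, 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- sweep(pts, 2, xyz[j, ])
        acc <- acc & (rowSums(dj^2) > rr[j]^2)
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    total <- total + frac * 4 * pi * ri^2
  }
  total
}

#' Buried contact area between two atom selections
#'
#' Computes SASA for each selection alone and for the complex and returns
#' `(A_P + A_M - A_PM) / 2` -- half the accessible area buried at the
#' interface, the quantity used by the membrane-embedding criterion.
#' Symmetric in the two selections; zero (to numerical noise) when they are
#' far apart.
#'
#' @param xyz_a,xyz_b coordinate matrices of the two selections.
#' @param radii_a,radii_b per-atom radii.
#' @param probe probe radius, Angstrom.
#' @param n_points sphere test points per atom.
#' @return buried contact area, Angstrom^2.
#' @export
buried_contact_area <- function(xyz_a, xyz_b, radii_a, radii_b,
                                probe = 1.4, n_points = 960) {
  if (!nrow(matrix(xyz_a, ncol = 3)) || !nrow(matrix(xyz_b, ncol = 3))) {
    stop("both selections must be non-empty")
  }
  a_p <- sasa(xyz_a, radii_a, probe, n_points)
  a_m <- sasa(xyz_b, radii_b, probe, n_points)
  a_pm <- sasa(rbind(matrix(xyz_a, ncol = 3), matrix(xyz_b, ncol = 3)),
               c(radii_a, radii_b), probe, n_points)
  (a_p + a_m - a_pm) / 2
}

#' Membrane-embedding criterion
#'
#' A frame counts as membrane-embedded when the buried contact area between
#' the Omega1 loop and the membrane exceeds `area_omega1_min` (strictly) AND
#' the buried contact area between the beta9 & C-terminal-helix selection
#' and the membrane exceeds `area_beta9_cterm_min` (strictly).
#'
#' @param area_omega1_min Angstrom^2, default 200 (strict >).
#' @param area_beta9_cterm_min Angstrom^2, default 150 (strict >).
#' @param omega1_segments,beta9_cterm_segments segment labels selecting the
#'   two protein regions.
#' @return list of class `embedding_criterion`.
#' @export
embedding_criterion <- function(area_omega1_min = 200,
                                area_beta9_cterm_min = 150,
                                omega1_segments = "omega1_loop",
                                beta9_cterm_segments = c("beta_sheet", "cterm_helix")) {
  if (area_omega1_min <= 0 || area_beta9_cterm_min <= 0) {
    stop("area thresholds must be positive")
  }
  structure(list(area_omega1_min = area_omega1_min,
                 area_beta9_cterm_min = area_beta9_cterm_min,
                 omega1_segments = omega1_segments,
                 beta9_cterm_segments = beta9_cterm_segments),
            class = "embedding_criterion")
}

# membrane atom rows of a topology (lipid residue names)
.membrane_rows <- function(topology,
                           lipid_resnames = c("POPC", "POPE", "CHOL", "POPS",
                                              "PIP2", "LIP")) {
  which(topology$atoms$residue_name %in% lipid_resnames)
}

#' Detect membrane embedding along a trajectory
#'
#' Evaluates the two buried-contact-area conditions per frame (strict
#' inequalities, no hysteresis) and reports the per-frame flag and the first
#' embedding time.
#'
#' @param trajectory an [mf_trajectory()].
#' @param criterion an [embedding_criterion()].
#' @param probe,n_points SASA parameters.
#' @param lipid_resnames residue names forming the membrane selection.
#' @return list of class `embedding_result`: `timeline` data frame
#'   (`frame`, `time_ns`, `area_omega1`, `area_beta9_cterm`, `embedded`),
#'   `first_embedding_time` (ns or NA), `first_embedding_frame`.
#' @export
detect_embedding <- function(trajectory, criterion = embedding_criterion(),
                             probe = 1.4, n_points = 960,
                             lipid_resnames = c("POPC", "POPE", "CHOL",
                                                "POPS", "PIP2", "LIP")) {
  a <- trajectory$topology$atoms
  mem <- .membrane_rows(trajectory$topology, lipid_resnames)
  if (!length(mem)) stop("no membrane atoms in topology")
  sel1 <- which(a$segment %in% criterion$omega1_segments)
  sel2 <- which(a$segment %in% criterion$beta9_cterm_segments)
  if (!length(sel1)) stop("missing segment labels for the Omega1 selection")
  if (!length(sel2)) stop("missing segment labels for the beta9/C-term selection")
  rmem <- .atom_radii(a$element[mem])
  r1 <- .atom_radii(a$element[sel1])
  r2 <- .atom_radii(a$element[sel2])
  nf <- n_frames(trajectory)
  tl <- data.frame(frame = seq_len(nf), time_ns = trajectory$times,
                   area_omega1 = NA_real_, area_beta9_cterm = NA_real_,
                   embedded = FALSE)
  for (f in seq_len(nf)) {
    xyz <- trajectory$coords[, , f]
    a1 <- buried_contact_area(xyz[sel1, , drop = FALSE], xyz[mem, , drop = FALSE],
                              r1, rmem, probe, n_points)
    a2 <- buried_contact_area(xyz[sel2, , drop = FALSE], xyz[mem, , drop = FALSE],
                              r2, rmem, probe, n_points)
    tl$area_omega1[f] <- a1
    tl$area_beta9_cterm[f] <- a2
    tl$embedded[f] <- (a1 > criterion$area_omega1_min) &&
      (a2 > criterion$area_beta9_cterm_min)
  }
  first <- which(tl$embedded)[1]
  structure(list(timeline = tl,
                 first_embedding_frame = if (is.na(first)) NA_integer_ else first,
                 first_embedding_time = if (is.na(first)) NA_real_ else tl$time_ns[first]),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  ne <- sum(x$timeline$embedded)
  cat(sprintf("<embedding_result> %d/%d frames embedded; first at %s\n",
              ne, nrow(x$timeline),
              if (is.na(x$first_embedding_time)) "never"
              else sprintf("%.3f ns (frame %d)", x$first_embedding_time,
                           x$first_embedding_frame)))
  invisible(x)
}
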