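# Orientation analytics: membrane plane fit, helix axis, (tilt, rotation)
# angles and their 2D probability maps.

#' Fit the membrane plane from headgroup reference atoms
#'
#' Least-squares plane through the selected points (principal-component
#' fit); the outward normal is oriented toward `toward` (e.g. the protein
#' centroid), or `+z` when no reference is given.
#'
#' @param points N x 3 matrix of headgroup atom positions (N >= 3).
#' @param toward optional 3-vector the normal should point toward.
#' @return list with `origin` (point on plane) and `normal` (outward unit).
#' @export
fit_membrane_plane <- function(points, toward = NULL) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 3) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  pc <- prcomp(points, center = TRUE)
  if (pc$sdev[2] < 1e-9) stop("degenerate (collinear) points: no unique plane")
  normal <- pc$rotation[, 3]
  if (!is.null(toward)) {
    if (sum((toward - ctr) * normal) < 0) normal <- -normal
  } else if (normal[3] < 0) normal <- -normal
  list(origin = ctr, normal = .unit(normal))
}

#' Helix axis from CA positions
#'
#' The local rotation axis of the helix, estimated from cross products of
#' successive second differences of the CA trace (exact for an ideal helix,
#' needs >= 4 CA atoms), oriented N-terminal to C-terminal.  `method =
#' "pca"` falls back to the principal axis of the CA point set.
#'
#' @param ca N x 3 matrix of CA coordinates in sequence order (N >= 4).
#' @param method `"rotation"` (default) or `"pca"`.
#' @return unit 3-vector.
#' @export
helix_axis <- function(ca, method = c("rotation", "pca")) {
  method <- match.arg(method)
  ca <- matrix(ca, ncol = 3)
  n <- nrow(ca)
  if (n < 4) stop("helix axis needs at least 4 CA atoms")
  nc <- ca[n, ] - ca[1, ]
  if (method == "pca") {
    ax <- prcomp(ca, center = TRUE)$rotation[, 1]
  } else {
    v <- diff(ca)            # bond vectors
    w <- diff(v)             # second differences point inward, normal to axis
    acc <- c(0, 0, 0)
    ref <- NULL
    for (i in seq_len(nrow(w) - 1)) {
      u <- .cross(w[i, ], w[i + 1, ])
      nu <- .vnorm(u)
      if (nu < 1e-12) next
      u <- u / nu
      if (is.null(ref)) ref <- u
      if (sum(u * ref) < 0) u <- -u
      acc <- acc + u
    }
    if (.vnorm(acc) < 1e-9) {
      ax <- prcomp(ca, center = TRUE)$rotation[, 1]   # degenerate: fall back
    } else {
      ax <- acc / .vnorm(acc)
    }
  }
  if (sum(ax * nc) < 0) ax <- -ax
  .unit(ax)
}

#' Tilt and rotation of the reference helix relative to the membrane
#'
#' `tilt` is the angle (degrees, 0..180) between the helix axis and the
#' outward membrane normal: 0 means the helix points straight away from the
#' membrane, larger tilt means the helix leans down toward the membrane
#' plane.  `rotation` (degrees, -180..180) is the spin of the protein about
#' the helix axis: the signed angle, measured about the helix axis, from the
#' projection of the outward normal to the projection of the vector from the
#' helix centroid to the reference selection centroid (default: the Omega1
#' loop).  When the helix axis is (anti)parallel to the normal the rotation
#' is undefined and reported as 0 with `degenerate = TRUE`.
#'
#' @param helix_ca CA coordinates of the reference helix (sequence order).
#' @param reference_centroid centroid of the rotation reference selection.
#' @param plane membrane plane from [fit_membrane_plane()] (or a list with a
#'   unit `normal`).
#' @return list `tilt`, `rotation` (degrees), `degenerate` flag.
#' @export
orientation_angles <- function(helix_ca, reference_centroid, plane) {
  nrm <- .unit(plane$normal)
  ax <- helix_axis(helix_ca)
  ct <- max(-1, min(1, sum(ax * nrm)))
  tilt <- acos(ct) * 180 / pi
  hctr <- colMeans(matrix(helix_ca, ncol = 3))
  vref <- reference_centroid - hctr
  rot <- .signed_angle(nrm, vref, ax)
  degen <- is.na(rot) || abs(ct) > 1 - 1e-12
  if (is.na(rot)) rot <- 0
  list(tilt = tilt, rotation = rot, degenerate = degen)
}

#' Per-frame orientation samples of a trajectory
#'
#' Applies [orientation_angles()] to every frame: the helix is the
#' `cterm_helix` segment's CA trace, the rotation reference the
#' `omega1_loop` centroid (configurable via `reference_segment`), and the
#' membrane plane is fit per frame from the lipid headgroup selection
#' (atoms named in `plane_atoms` among residues in `lipid_resnames`), or
#' taken as the stored membrane plane when the trajectory carries one.
#'
#' @param trajectory an [mf_trajectory()].
#' @param reference_segment segment label for the rotation reference.
#' @param plane_atoms atom names defining the leaflet plane (default "P").
#' @param lipid_resnames residue names treated as lipids.
#' @return data frame with `frame_time`, `tilt`, `rotation`, `degenerate`.
#' @export
orientation_samples <- function(trajectory, reference_segment = "omega1_loop",
                                plane_atoms = "P",
                                lipid_resnames = c("POPC", "POPE", "CHOL",
                                                   "POPS", "PIP2", "LIP")) {
  a <- trajectory$topology$atoms
  hel <- which(a$segment == "cterm_helix" & a$name == "CA")
  if (length(hel) < 4) stop("cterm_helix segment needs >= 4 CA atoms")
  refsel <- which(a$segment == reference_segment)
  if (!length(refsel)) stop("empty rotation reference segment: ", reference_segment)
  lip <- which(a$residue_name %in% lipid_resnames & a$name %in% plane_atoms)
  prot <- which(!a$residue_name %in% lipid_resnames)
  out <- data.frame(frame_time = trajectory$times, tilt = NA_real_,
                    rotation = NA_real_, degenerate = FALSE)
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- trajectory$coords[, , f]
    plane <- if (length(lip) >= 3) {
      fit_membrane_plane(xyz[lip, , drop = FALSE],
                         toward = colMeans(xyz[prot, , drop = FALSE]))
    } else if (!is.null(trajectory$membrane)) {
      list(origin = trajectory$membrane$plane_origin,
           normal = trajectory$membrane$normal)
    } else stop("no membrane representation to fit a plane from")
    ang <- orientation_angles(xyz[hel, , drop = FALSE],
                              colMeans(xyz[refsel, , drop = FALSE]), plane)
    out$tilt[f] <- ang$tilt
    out$rotation[f] <- ang$rotation
    out$degenerate[f] <- ang$degenerate
  }
  out
}

#' 2D orientation probability map
#'
#' Normalized 2D histogram of (tilt, rotation) samples; bin masses sum to 1.
#'
#' @param samples data frame with `tilt` and `rotation` columns (degrees).
#' @param tilt_bins,rotation_bins bin counts over 0..180 and -180..180.
#' @return object of class `orientation_map`: `density` matrix
#'   (tilt x rotation), `tilt_edges`, `rotation_edges`, `n_samples`.
#' @export
orientation_map <- function(samples, tilt_bins = 36, rotation_bins = 36) {
  tl <- samples$tilt[!is.na(samples$tilt)]
  rt <- samples$rotation[!is.na(samples$rotation)]
  if (!length(tl) || length(tl) != length(rt)) {
    stop("orientation_map: need at least one valid (tilt, rotation) sample")
  }
  te <- seq(0, 180, length.out = tilt_bins + 1)
  re <- seq(-180, 180, length.out = rotation_bins + 1)
  ti <- pmin(pmax(findInterval(tl, te, rightmost.closed = TRUE), 1), tilt_bins)
  ri <- pmin(pmax(findInterval(rt, re, rightmost.closed = TRUE), 1), rotation_bins)
  dens <- matrix(0, tilt_bins, rotation_bins)
  for (i in seq_along(ti)) dens[ti[i], ri[i]] <- dens[ti[i], ri[i]] + 1
  dens <- dens / length(ti)
  structure(list(density = dens, tilt_edges = te, rotation_edges = re,
                 n_samples = length(ti)), class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("<orientation_map> %d x %d bins over %d samples; peak mass %.4f\n",
              nrow(x$density), ncol(x$density), x$n_samples, max(x$density)))
  invisible(x)
}

#' Write an orientation map as long-format CSV
#' @param x an [orientation_map()].
#' @param path output CSV.
#' @param ... provenance arguments passed to [table_artifact()].
#' @return `path`, invisibly.
#' @export
write_orientation_map <- function(x, path, ...) {
  tb <- expand.grid(tilt_bin = seq_len(nrow(x$density)),
                    rotation_bin = seq_len(ncol(x$density)),
                    KEEP.OUT.ATTRS = FALSE)
  tb$tilt_mid <- (x$tilt_edges[tb$tilt_bin] + x$tilt_edges[tb$tilt_bin + 1]) / 2
  tb$rotation_mid <- (x$rotation_edges[tb$rotation_bin] +
                        x$rotation_edges[tb$rotation_bin + 1]) / 2
  tb$probability <- x$density[cbind(tb$tilt_bin, tb$rotation_bin)]
  write_table_artifact(table_artifact(tb, command = "memfield analyze orientation", ...),
                       path)
  invisible(path)
}
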