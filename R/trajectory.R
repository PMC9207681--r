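#' Trajectory container
#'
#' Ordered frames over a fixed topology.  `coords` is an
#' `n_atoms x 3 x n_frames` array in Angstrom; `times` are in ns and must be
#' strictly increasing.
#'
#' @param topology a [charged_structure()] describing every atom.
#' @param coords `n_atoms x 3 x n_frames` numeric array.
#' @param times frame times, ns.
#' @param membrane optional [lattice_membrane()] reference.
#' @return object of class `mf_trajectory`.
#' @export
mf_trajectory <- function(topology, coords, times, membrane = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(topology$atoms)) {
    stop("coords atom count does not match topology")
  }
  if (dim(coords)[3] != length(times)) stop("times length != frame count")
  if (length(times) && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), membrane = membrane),
            class = "mf_trajectory")
}

#' @export
print.mf_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf("<mf_trajectory> %d frames, %d atoms, t = %.3f .. %.3f ns\n",
              nf, dim(x$coords)[1],
              if (nf) x$times[1] else NA, if (nf) x$times[nf] else NA))
  invisible(x)
}

#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.mf_trajectory <- function(x) dim(x$coords)[3]

#' Extract one frame as a charged_structure
#' @param trajectory an [mf_trajectory()].
#' @param i frame index.
#' @return [charged_structure()] with that frame's coordinates.
#' @export
trajectory_frame <- function(trajectory, i) {
  .set_structure_coords(trajectory$topology, trajectory$coords[, , i])
}

#' Read a trajectory from a multi-model PDB
#'
#' Frame atom order must match the topology; times come from a fixed stride
#' (ns/frame) starting at 0.
#'
#' @param topology_path PDB file defining the topology (first model is used
#'   if multi-model), or a [charged_structure()].
#' @param traj_path multi-model PDB with MODEL/ENDMDL records.
#' @param stride_ns time between frames, ns.
#' @param charges,segments forwarded to [read_structure()] for the topology.
#' @return an [mf_trajectory()].
#' @export
read_trajectory <- function(topology_path, traj_path, stride_ns = 0.1,
                            charges = NULL, segments = NULL) {
  topo <- if (inherits(topology_path, "charged_structure")) topology_path
          else read_structure(topology_path, charges = charges, segments = segments)
  lines <- readLines(traj_path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) {
    # single-model file: treat the whole file as one frame
    sel <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(sel)) stop("trajectory file contains zero frames")
    starts <- 0; ends <- length(lines) + 1
  }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records")
  na <- nrow(topo$atoms)
  nf <- length(starts)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    seg <- lines[(starts[f] + 1):(ends[f] - 1)]
    seg <- seg[grepl("^(ATOM  |HETATM)", seg)]
    if (length(seg) != na) {
      stop(sprintf("frame %d has %d atoms, topology has %d", f, length(seg), na))
    }
    at <- .parse_pdb_atoms(seg)
    coords[, , f] <- as.matrix(at[, c("x", "y", "z")])
  }
  mf_trajectory(topo, coords, times = (seq_len(nf) - 1) * stride_ns)
}

#' Write a trajectory as a multi-model PDB
#' @param trajectory an [mf_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  a <- trajectory$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL %8d", f), con)
    af <- a
    af[, c("x", "y", "z")] <- trajectory$coords[, , f]
    writeLines(vapply(seq_len(nrow(af)),
                      function(i) .format_pdb_atom(af[i, ], af$atom_id[i]),
                      character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Restrict a trajectory to its final analysis window
#'
#' Keeps the last `last_ns` nanoseconds of the trajectory (the analysis
#' window; production runs of 2.2 us are analyzed over their last 720 ns, so
#' frames with t > 1480 ns are retained).  Frames strictly after
#' `t_end - last_ns` are kept; when the trajectory duration equals `last_ns`
#' exactly, every frame is kept.
#'
#' @param trajectory an [mf_trajectory()].
#' @param last_ns window length in ns (default 720).
#' @return the windowed [mf_trajectory()].
#' @export
analysis_window <- function(trajectory, last_ns = 720) {
  tms <- trajectory$times
  dur <- tms[length(tms)] - tms[1]
  if (dur < last_ns - 1e-9) {
    stop(sprintf("trajectory duration %.3f ns is shorter than the %.3f ns window",
                 dur, last_ns))
  }
  if (abs(dur - last_ns) <= 1e-9) {
    keep <- rep(TRUE, length(tms))
  } else {
    keep <- tms > tms[length(tms)] - last_ns + 1e-12
  }
  mf_trajectory(trajectory$topology,
                trajectory$coords[, , keep, drop = FALSE],
                tms[keep], trajectory$membrane)
}

#' Pool replica trajectories into one frame set
#'
#' Replicas are pooled with equal frame weights (probabilities over the pool
#' equal probabilities over the concatenation).  Times are renumbered
#' sequentially to keep them strictly increasing.
#'
#' @param ... [mf_trajectory()] objects sharing a topology.
#' @return pooled [mf_trajectory()].
#' @export
pool_trajectories <- function(...) {
  trs <- list(...)
  if (length(trs) == 1 && is.list(trs[[1]]) && !inherits(trs[[1]], "mf_trajectory")) {
    trs <- trs[[1]]
  }
  na <- dim(trs[[1]]$coords)[1]
  for (tr in trs) {
    if (dim(tr$coords)[1] != na) stop("replicas must share a topology")
  }
  coords <- do.call(abind3, lapply(trs, function(t) t$coords))
  nf <- dim(coords)[3]
  dt <- if (length(trs[[1]]$times) > 1) diff(trs[[1]]$times[1:2]) else 1
  mf_trajectory(trs[[1]]$topology, coords, times = (seq_len(nf) - 1) * dt,
                membrane = trs[[1]]$membrane)
}

# bind 3d arrays along the third dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, dim = c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], 0))))
  at <- 0
  for (x in xs) {
    nf <- dim(x)[3]
    if (nf) out[, , at + seq_len(nf)] <- x
    at <- at + nf
  }
  out
}
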