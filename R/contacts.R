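# Residue-lipid contact statistics: a lipid binds a residue when any of its
# headgroup oxygens lies within the cutoff of any sidechain N/O atom of the
# residue (4 Angstrom, inclusive, by default).

#' Contact criterion
#'
#' @param cutoff distance cutoff in Angstrom (inclusive; default 4).
#' @param lipid_oxygen_atoms named list, per lipid species, of headgroup
#'   oxygen atom names (default covers the bead fixtures and common
#'   PS/PIP headgroup oxygens).
#' @param residue_polar_atoms named list, per residue type, of sidechain
#'   N/O atom names considered (backbone excluded).
#' @return list of class `contact_criterion`.
#' @export
contact_criterion <- function(cutoff = 4,
                              lipid_oxygen_atoms = NULL,
                              residue_polar_atoms = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(lipid_oxygen_atoms)) {
    lipid_oxygen_atoms <- list(
      POPS = c("O1", "O13A", "O13B", "OP32", "OP33", "OP34"),
      PIP2 = c("O1", "OP42", "OP43", "OP44", "OP52", "OP53", "OP54"),
      POPC = c("O1", "OP32", "OP33", "OP34"),
      POPE = c("O1", "OP32", "OP33", "OP34"),
      CHOL = c("O1", "O3"),
      LIP = "O1"
    )
  }
  if (is.null(residue_polar_atoms)) {
    residue_polar_atoms <- list(
      ARG = c("NE", "NH1", "NH2"),
      LYS = c("NZ"),
      SER = c("OG"),
      HIS = c("ND1", "NE2")
    )
  }
  if (any(!vapply(lipid_oxygen_atoms, length, 0L)) ||
      any(!vapply(residue_polar_atoms, length, 0L))) {
    stop("atom-name lists must be non-empty")
  }
  structure(list(cutoff = cutoff,
                 lipid_oxygen_atoms = lipid_oxygen_atoms,
                 residue_polar_atoms = residue_polar_atoms),
            class = "contact_criterion")
}

# resolve the polar-atom rows for a residue id and the O-atom rows per lipid
.contact_selections <- function(topology, criterion, residues, lipid_species) {
  a <- topology$atoms
  res_sel <- list()
  for (r in residues) {
    rows <- which(a$residue_id == r &
                    !a$residue_name %in% names(criterion$lipid_oxygen_atoms))
    if (!length(rows)) stop("residue id ", r, " not found in topology")
    cand <- unique(a$residue_name[rows])
    rn <- cand[cand %in% names(criterion$residue_polar_atoms)][1]
    if (is.na(rn)) {
      stop("no sidechain polar-atom list for residue type(s) ",
           paste(cand, collapse = "/"))
    }
    pol <- criterion$residue_polar_atoms[[rn]]
    sel <- rows[a$residue_name[rows] == rn & a$name[rows] %in% pol]
    if (!length(sel)) {
      stop("residue ", r, " (", rn, ") has none of the atoms: ",
           paste(pol, collapse = ", "))
    }
    res_sel[[as.character(r)]] <- sel
  }
  lip_sel <- list()
  for (sp in lipid_species) {
    ox <- criterion$lipid_oxygen_atoms[[sp]]
    if (is.null(ox)) stop("no headgroup oxygen list for lipid species ", sp)
    rows <- which(a$residue_name == sp & a$name %in% ox)
    if (!length(rows)) next
    for (lid in unique(a$residue_id[rows])) {
      lip_sel[[as.character(lid)]] <- rows[a$residue_id[rows] == lid]
    }
  }
  list(residues = res_sel, lipids = lip_sel)
}

#' Lipids bound to each residue in one frame
#'
#' A lipid molecule is bound to a residue iff the minimum distance between
#' its headgroup oxygens and the residue's sidechain N/O atoms is at most
#' the cutoff.
#'
#' @param frame a [charged_structure()] (one trajectory frame).
#' @param criterion a [contact_criterion()].
#' @param residues residue ids to analyze.
#' @param lipid_species lipid residue names to consider.
#' @return named list: per residue id, integer vector of bound lipid
#'   residue ids.
#' @export
residue_lipid_contacts <- function(frame, criterion, residues, lipid_species) {
  sel <- .contact_selections(frame, criterion, residues, lipid_species)
  xyz <- .structure_coords(frame)
  out <- list()
  for (r in names(sel$residues)) {
    rp <- xyz[sel$residues[[r]], , drop = FALSE]
    bound <- integer(0)
    for (lid in names(sel$lipids)) {
      lp <- xyz[sel$lipids[[lid]], , drop = FALSE]
      d2 <- outer(rowSums(rp^2), rowSums(lp^2), "+") - 2 * rp %*% t(lp)
      if (min(d2) <= criterion$cutoff^2 + 1e-12) {
        bound <- c(bound, as.integer(lid))
      }
    }
    out[[r]] <- bound
  }
  out
}

#' Residue-lipid binding probability table over a trajectory
#'
#' Per residue: the probability (fraction of frames) of at least one bound
#' lipid, of two or more simultaneously bound lipids, and the mean number of
#' bound lipids.  Per residue pair in `shared_pairs`: the probability that
#' at least one lipid is simultaneously bound to both residues (a shared
#' site, such as the R46/R58 groove where every R58-bound lipid is also
#' engaged by R46).
#'
#' @param trajectory an [mf_trajectory()].
#' @param criterion a [contact_criterion()].
#' @param residues residue ids.
#' @param lipid_species lipid residue names.
#' @param shared_pairs list of 2-vectors of residue ids.
#' @return object of class `contact_table`: `residues` data frame
#'   (`residue`, `p_bound`, `p_two_or_more`, `mean_multiplicity`, and the
#'   same probabilities as percent occurrence), `shared` data frame,
#'   `n_frames`.
#' @export
binding_probability_table <- function(trajectory, criterion, residues,
                                      lipid_species,
                                      shared_pairs = list()) {
  nf <- n_frames(trajectory)
  if (nf < 1) stop("empty trajectory")
  rk <- as.character(residues)
  nb <- matrix(0L, nf, length(rk), dimnames = list(NULL, rk))
  two <- matrix(FALSE, nf, length(rk), dimnames = list(NULL, rk))
  shared_hits <- matrix(FALSE, nf, length(shared_pairs))
  for (f in seq_len(nf)) {
    contacts <- residue_lipid_contacts(trajectory_frame(trajectory, f),
                                       criterion, residues, lipid_species)
    for (r in rk) {
      nb[f, r] <- length(contacts[[r]])
      two[f, r] <- length(contacts[[r]]) >= 2
    }
    for (p in seq_along(shared_pairs)) {
      pr <- as.character(shared_pairs[[p]])
      shared_hits[f, p] <- length(intersect(contacts[[pr[1]]], contacts[[pr[2]]])) > 0
    }
  }
  res <- data.frame(
    residue = residues,
    p_bound = colMeans(nb >= 1),
    p_two_or_more = colMeans(two),
    mean_multiplicity = colMeans(nb)
  )
  res$pct_bound <- 100 * res$p_bound
  res$pct_two_or_more <- 100 * res$p_two_or_more
  rownames(res) <- NULL
  shr <- if (length(shared_pairs)) data.frame(
    residue_a = vapply(shared_pairs, `[`, numeric(1), 1),
    residue_b = vapply(shared_pairs, `[`, numeric(1), 2),
    p_shared = colMeans(matrix(shared_hits, nf)),
    pct_shared = 100 * colMeans(matrix(shared_hits, nf))
  ) else data.frame(residue_a = numeric(0), residue_b = numeric(0),
                    p_shared = numeric(0), pct_shared = numeric(0))
  structure(list(residues = res, shared = shr, n_frames = nf),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("<contact_table> %d frames\n", x$n_frames))
  print(x$residues, row.names = FALSE)
  if (nrow(x$shared)) print(x$shared, row.names = FALSE)
  invisible(x)
}

#' Write a contact table as provenance-stamped CSV
#' @param x a `contact_table`.
#' @param path output CSV (residue table; shared pairs are appended with a
#'   `pair` marker column when present).
#' @param ... provenance arguments for [table_artifact()].
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(x, path, ...) {
  df <- x$residues
  df$n_frames <- x$n_frames
  write_table_artifact(table_artifact(df, command = "memfield analyze contacts", ...),
                       path)
  if (nrow(x$shared)) {
    write_table_artifact(table_artifact(x$shared,
                                        command = "memfield analyze contacts shared", ...),
                         sub("(\\.[^.]+)$", "_shared\\1", path))
  }
  invisible(path)
}
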