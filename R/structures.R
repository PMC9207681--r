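#' Charged molecular structure
#'
#' A `charged_structure` is the package's protein container: a data frame of
#' atoms with Cartesian coordinates (Angstrom), partial charges (elementary
#' charges) and a coarse segment label used by the orientation and embedding
#' analyses.  Valid segments are `cterm_helix`, `omega1_loop`, `beta_sheet`
#' and `other`.
#'
#' @param atoms data frame with columns `atom_id` (integer), `name`,
#'   `residue_name`, `residue_id` (integer), `segment`, `x`, `y`, `z`,
#'   `charge`, `element`.
#' @return object of class `charged_structure`.
#' @export
charged_structure <- function(atoms) {
  req <- c("atom_id", "name", "residue_name", "residue_id", "segment",
           "x", "y", "z", "charge", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("charged_structure: missing columns: ",
                         paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("charged_structure: non-finite coordinates")
  }
  bad <- !atoms$segment %in% c("cterm_helix", "omega1_loop", "beta_sheet", "other")
  if (any(bad)) stop("charged_structure: invalid segment label(s): ",
                     paste(unique(atoms$segment[bad]), collapse = ", "))
  atoms$charge[is.na(atoms$charge)] <- 0
  if (!all(is.finite(atoms$charge))) stop("charged_structure: non-finite charges")
  structure(list(atoms = atoms), class = "charged_structure")
}

#' @export
print.charged_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<charged_structure> %d atoms, %d residues, net charge %+.2f e\n",
              nrow(a), length(unique(a$residue_id)), sum(a$charge)))
  tb <- table(a$segment)
  cat("  segments:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.matrix.charged_structure <- function(x, ...) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

.structure_coords <- function(x) as.matrix.charged_structure(x)

.set_structure_coords <- function(x, xyz) {
  x$atoms[, c("x", "y", "z")] <- xyz
  x
}

.structure_centroid <- function(x) colMeans(.structure_coords(x))

# parse "a-b" / c("a-b","c-d") / numeric vector into a residue-id set
.parse_residue_ranges <- function(spec) {
  if (is.null(spec) || (is.character(spec) && !nzchar(paste(spec, collapse = "")))) {
    return(integer(0))
  }
  if (is.numeric(spec)) return(as.integer(spec))
  out <- integer(0)
  for (s in unlist(strsplit(spec, ","))) {
    s <- trimws(s)
    if (!nzchar(s)) next
    if (grepl("^-?[0-9]+\\s*-\\s*-?[0-9]+$", s)) {
      ab <- as.integer(strsplit(s, "-")[[1]][1:2])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", s)) {
      out <- c(out, as.integer(s))
    } else {
      stop("cannot parse residue range: '", s, "'")
    }
  }
  out
}

#' Assign segment labels from residue ranges
#'
#' Segment definitions are residue-range based (e.g. the C-terminal helix of
#' StarD4 spans residues 203-224 in the crystal numbering).  Residues not
#' covered by any range are labeled `other`.
#'
#' @param x a [charged_structure()].
#' @param segments named list; names among `cterm_helix`, `omega1_loop`,
#'   `beta_sheet`; values residue ranges like `"203-224"`.
#' @return the structure with updated segment labels.
#' @export
assign_segments <- function(x, segments) {
  a <- x$atoms
  a$segment <- "other"
  for (seg in names(segments)) {
    if (!seg %in% c("cterm_helix", "omega1_loop", "beta_sheet")) {
      stop("unknown segment name: ", seg)
    }
    ids <- .parse_residue_ranges(segments[[seg]])
    a$segment[a$residue_id %in% ids] <- seg
  }
  x$atoms <- a
  x
}

# default coarse charge rule when no table is given: unit charges on the
# charge-bearing group centers of ionizable sidechains (His neutral).
.default_charge_rule <- function(atoms) {
  ch <- numeric(nrow(atoms))
  key <- paste(atoms$residue_name, atoms$name)
  ch[key %in% c("ARG CZ", "LYS NZ")] <- 1
  ch[key %in% c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2")] <- -0.5
  ch
}

.apply_charge_table <- function(atoms, tab, strict = FALSE) {
  if (is.character(tab)) tab <- read.csv(tab, stringsAsFactors = FALSE)
  tab <- as.data.frame(tab)
  ch <- rep(NA_real_, nrow(atoms))
  if ("atom_id" %in% names(tab)) {
    m <- match(atoms$atom_id, tab$atom_id)
    ch[!is.na(m)] <- tab$charge[m[!is.na(m)]]
  } else {
    if (!all(c("residue_name", "charge") %in% names(tab))) {
      stop("charge table needs columns (residue_name[, atom_name], charge) or (atom_id, charge)")
    }
    if (!"atom_name" %in% names(tab)) tab$atom_name <- "*"
    for (i in seq_len(nrow(tab))) {
      hit <- atoms$residue_name == tab$residue_name[i] &
        (tab$atom_name[i] == "*" | atoms$name == tab$atom_name[i])
      ch[hit] <- tab$charge[i]
    }
  }
  if (strict && anyNA(ch)) {
    stop("strict charge assignment: ", sum(is.na(ch)),
         " atom(s) missing from the charge table")
  }
  ch[is.na(ch)] <- 0
  ch
}

#' Read a protein structure from a PDB file
#'
#' Parses `ATOM`/`HETATM` records.  Charges come from a charge-table CSV
#' (columns `residue_name`, optional `atom_name` (`"*"` wildcard), `charge`,
#' or `atom_id`/`charge`), from the occupancy-style charge column of a
#' PQR-flavoured file (`charges = "pqr"`), or from a coarse built-in rule
#' (Arg/Lys +1 at the terminal sidechain N-group center, Asp/Glu -1 split
#' over the carboxylate oxygens, His 0).
#'
#' @param path PDB file.
#' @param charges `NULL` (default rule), a data frame / CSV path, or `"pqr"`.
#' @param segments optional segment-definition list, see [assign_segments()].
#' @param strict error if a charge-table atom lookup fails.
#' @return a [charged_structure()].
#' @export
read_structure <- function(path, charges = NULL, segments = NULL, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  atoms <- .parse_pdb_atoms(lines[sel], which(sel))
  if (identical(charges, "pqr")) {
    atoms$charge <- atoms$occupancy
  } else if (is.null(charges)) {
    atoms$charge <- .default_charge_rule(atoms)
  } else {
    atoms$charge <- .apply_charge_table(atoms, charges, strict = strict)
  }
  atoms$segment <- "other"
  x <- charged_structure(atoms[, c("atom_id", "name", "residue_name",
                                   "residue_id", "segment", "x", "y", "z",
                                   "charge", "element")])
  if (!is.null(segments)) x <- assign_segments(x, segments)
  x
}

.parse_pdb_atoms <- function(lines, line_numbers = seq_along(lines)) {
  sub_num <- function(l, a, b, what, ln) {
    v <- suppressWarnings(as.numeric(substr(l, a, b)))
    bad <- is.na(v)
    if (any(bad)) {
      stop(sprintf("malformed PDB %s field at line %d: '%s'",
                   what, ln[bad][1], lines[bad][1]))
    }
    v
  }
  data.frame(
    atom_id = as.integer(sub_num(lines, 7, 11, "serial", line_numbers)),
    name = trimws(substr(lines, 13, 16)),
    residue_name = trimws(substr(lines, 18, 21)),
    residue_id = as.integer(sub_num(lines, 23, 26, "resSeq", line_numbers)),
    x = sub_num(lines, 31, 38, "x", line_numbers),
    y = sub_num(lines, 39, 46, "y", line_numbers),
    z = sub_num(lines, 47, 54, "z", line_numbers),
    occupancy = {
      v <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
      v[is.na(v)] <- 0
      v
    },
    element = {
      e <- trimws(substr(lines, 77, 78))
      nm <- trimws(substr(lines, 13, 16))
      e[!nzchar(e)] <- substr(gsub("[0-9]", "", nm[!nzchar(e)]), 1, 1)
      e
    },
    stringsAsFactors = FALSE
  )
}

.format_pdb_atom <- function(a, serial, charge_in_b = TRUE) {
  nm <- a$name
  nm <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
  sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, substr(a$residue_name, 1, 4), a$residue_id %% 10000,
          a$x, a$y, a$z, 1.0,
          if (charge_in_b) a$charge else 0.0,
          substr(a$element, 1, 2))
}

#' Write a structure as a PDB file
#'
#' Coordinates are written at PDB precision (1e-3 Angstrom); the partial
#' charge is stored in the B-factor column for reference (the authoritative
#' charge channel is the CSV charge table).
#'
#' @param x a [charged_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  lines <- vapply(seq_len(nrow(a)),
                  function(i) .format_pdb_atom(a[i, ], a$atom_id[i]),
                  character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
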