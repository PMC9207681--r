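# Run configuration: a validated flat key-value list with physical units in
# the key names.  Files are a flat YAML subset ("key: value" lines, '#'
# comments) or JSON; unknown keys are rejected.

.config_schema <- function() {
  num <- function(default, lo = -Inf, hi = Inf, unit = "") {
    list(default = default, type = "numeric", lo = lo, hi = hi, unit = unit)
  }
  chr <- function(default, unit = "") list(default = default, type = "character", unit = unit)
  lgl <- function(default) list(default = default, type = "logical", unit = "")
  list(
    # mean-field solver
    box_edge_A           = num(256, lo = 1e-6, unit = "Angstrom"),
    grid_points          = num(64, lo = 8, unit = "nodes per axis"),
    ionic_strength_M     = num(0.15, lo = 1e-12, unit = "mol/L"),
    temperature_K        = num(310, lo = 1e-6, unit = "K"),
    relative_permittivity = num(80, lo = 1e-6, unit = "dimensionless"),
    convergence_tol      = num(1e-6, lo = 0, unit = "relative dF"),
    phi_tol              = num(1e-9, lo = 0, unit = "max |dphi|"),
    max_iter             = num(1000, lo = 1, unit = "iterations"),
    mixing               = num(0.5, lo = 1e-9, hi = 1, unit = "damping in (0,1]"),
    area_per_lipid_A2    = num(65, lo = 1e-6, unit = "Angstrom^2"),
    clearance_A          = num(2, lo = 0, unit = "Angstrom"),
    n_directions         = num(72, lo = 1, unit = "count"),
    n_azimuths           = num(12, lo = 1, unit = "count"),
    nonlinear_ions       = lgl(FALSE),
    # trajectory analysis
    contact_cutoff_A     = num(4, lo = 1e-6, unit = "Angstrom"),
    probe_A              = num(1.4, lo = 0, unit = "Angstrom"),
    n_sphere_points      = num(960, lo = 16, unit = "count"),
    window_last_ns       = num(720, lo = 1e-9, unit = "ns"),
    area_omega1_min_A2   = num(200, lo = 1e-9, unit = "Angstrom^2"),
    area_beta9_cterm_min_A2 = num(150, lo = 1e-9, unit = "Angstrom^2"),
    cterm_helix_range    = chr("203-224", unit = "residue ids"),
    omega1_loop_range    = chr("", unit = "residue ids"),
    beta_sheet_range     = chr("", unit = "residue ids"),
    # kinetics
    f_eq                 = num(0.5, lo = 1e-12, hi = 1, unit = "fraction"),
    time_unit            = chr("min", unit = "min|s")
  )
}

#' Build a validated run configuration
#'
#' @param ... configuration overrides by key (see `names(memfield_config())`
#'   for the full key set; units are part of the key names).
#' @return a named list of class `memfield_config`.
#' @export
memfield_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  .validate_config(over)
}

.validate_config <- function(over) {
  schema <- .config_schema()
  unknown <- setdiff(names(over), names(schema))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- lapply(schema, function(s) s$default)
  for (k in names(over)) {
    s <- schema[[k]]
    v <- over[[k]]
    if (s$type == "numeric") {
      v <- suppressWarnings(as.numeric(v))
      if (is.na(v)) stop("key '", k, "' must be numeric")
      if (v < s$lo || v > s$hi) {
        stop(sprintf("key '%s' = %g out of range [%g, %g] (%s)", k, v, s$lo, s$hi, s$unit))
      }
    } else if (s$type == "logical") {
      v <- as.logical(v)
      if (is.na(v)) stop("key '", k, "' must be logical")
    } else {
      v <- as.character(v)
    }
    cfg[[k]] <- v
  }
  structure(cfg, class = "memfield_config")
}

#' Load a configuration file
#'
#' Accepts a flat `key: value` file ('#' comments; a YAML subset) or JSON.
#' An empty file yields the full default configuration; unknown keys and
#' out-of-range values (e.g. a negative ionic strength) are errors.
#'
#' @param path configuration file.
#' @return a `memfield_config`.
#' @export
load_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    over <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(memfield_config(over))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (l in lines) {
    if (!grepl(":", l, fixed = TRUE)) stop("cannot parse config line: '", l, "'")
    k <- trimws(sub(":.*$", "", l))
    v <- trimws(sub("^[^:]*:", "", l))
    v <- gsub('^"|"$', "", v)
    over[[k]] <- v
  }
  memfield_config(over)
}

#' Write a configuration file (normalized form)
#'
#' `load_config(dump_config(cfg))` reproduces `cfg` exactly; dumping the
#' load of any valid file yields its normalized form.
#'
#' @param cfg a `memfield_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  writeLines(.config_text(cfg), path)
  invisible(path)
}

.config_text <- function(cfg) {
  vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    vs <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    sprintf("%s: %s", k, vs)
  }, character(1))
}

#' Hash of a configuration (provenance)
#' @param cfg a `memfield_config`.
#' @return md5 hex string of the normalized config text.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(.config_text(cfg), f)
  unname(tools::md5sum(f))
}

#' Solver configuration derived from a run configuration
#'
#' Collects the mean-field solver parameters and the derived Debye length;
#' warns when the grid spacing exceeds half the Debye length (under-resolved
#' screening).
#'
#' @param cfg a `memfield_config` (default: all defaults).
#' @return list of class `solver_config` with fields `box_edge`,
#'   `grid_points`, `h`, `lambda`, `bjerrum`, `ionic_strength`, `temperature`,
#'   `relative_permittivity`, `mixing`, `phi_tol`, `max_iter`, `clearance`.
#' @export
solver_config <- function(cfg = memfield_config()) {
  lam <- debye_length(cfg$ionic_strength_M, cfg$temperature_K,
                      cfg$relative_permittivity)
  n <- as.integer(cfg$grid_points)
  h <- cfg$box_edge_A / n
  if (h > lam / 2 + 1e-12) {
    warning(sprintf("grid spacing %.3f A exceeds lambda/2 = %.3f A; screening under-resolved",
                    h, lam / 2))
  }
  structure(list(
    box_edge = cfg$box_edge_A, grid_points = n, h = h,
    lambda = lam,
    bjerrum = bjerrum_length(cfg$temperature_K, cfg$relative_permittivity),
    ionic_strength = cfg$ionic_strength_M,
    temperature = cfg$temperature_K,
    relative_permittivity = cfg$relative_permittivity,
    mixing = cfg$mixing, phi_tol = cfg$phi_tol,
    max_iter = as.integer(cfg$max_iter),
    convergence_tol = cfg$convergence_tol,
    clearance = cfg$clearance_A,
    area_per_lipid = cfg$area_per_lipid_A2
  ), class = "solver_config")
}
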