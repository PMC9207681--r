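# Linearized Poisson-Boltzmann (Debye-Hueckel) solver for a fixed-charge
# protein above a planar membrane carrying a mobile anionic surface charge.
#
# Geometry: the membrane is an impermeable plane at z = 0 carrying surface
# charge sigma(x, y); ions occupy only z > 0.  The potential (in kT/e units)
# obeys  lap(psi) - psi/lambda^2 = -4 pi lB rho  with the flux condition
# d(psi)/dz|_{0+} = -4 pi lB sigma and psi -> 0 far away.  The lateral
# directions are periodic (an infinite membrane); the top face is Dirichlet.
#
# Numerics: singularity splitting.  The protein point charges contribute
# their free-space screened-Coulomb (Yukawa) field analytically; the grid
# only carries the smooth remainder (membrane charge + the flux correction
# that builds the protein's image response).  The grid operator is a compact
# fourth-order (Mehrstellen) discretization, diagonalized by lateral FFT and
# solved exactly by a tridiagonal sweep in z, with an exponentially fitted
# screening mass so a uniformly charged plane reproduces the Gouy-Chapman
# profile to machine precision.

.pb_cache <- new.env(parent = emptyenv())

# factorized operator pieces for a given (L, n, nz, lambda)
.pb_operator <- function(L, n, nz, lambda) {
  key <- sprintf("%.10g_%d_%d_%.10g", L, n, nz, lambda)
  if (!is.null(.pb_cache[[key]])) return(.pb_cache[[key]])
  h <- L / n
  kap2 <- 1 / lambda^2
  M <- 2 * (cosh(h / lambda) - 1) / h^2      # fitted screening mass
  rhsf <- 1 + h^2 * kap2 / 12
  idx <- 0:(n - 1)
  ca <- cos(2 * pi * idx / n)
  CA <- outer(ca, rep(1, n)); CB <- outer(rep(1, n), ca)
  T1 <- (2 + 2 * CA + 2 * CB) / (6 * h^2)
  T0 <- (-24 + 4 * CA + 4 * CB + 4 * CA * CB) / (6 * h^2) - M
  S0 <- rhsf + (-6 + 2 * CA + 2 * CB) / 12
  T1s <- ifelse(abs(T1) < 1e-300, 1, T1)
  disc <- sqrt(as.complex(T0^2 - 4 * T1^2))
  mu_a <- (-T0 - disc) / (2 * T1s); mu_b <- (-T0 + disc) / (2 * T1s)
  mu <- Re(ifelse(Mod(mu_a) <= Mod(mu_b), mu_a, mu_b))
  mu[abs(T1) < 1e-300] <- 0
  m2 <- ifelse(idx > n / 2, idx - n, idx)
  qcont <- sqrt(kap2 + outer((2 * pi * m2 / L)^2, (2 * pi * m2 / L)^2, "+"))
  mus <- ifelse(mu == 0, 1, mu)
  cbc <- (1 / mus - mus) / (2 * qcont * h)   # exact-flux BC factor per mode
  cbc[mu == 0] <- 1
  op <- list(L = L, n = n, nz = nz, h = h, lambda = lambda,
             T0 = T0, T1 = T1, S0 = S0, cbc = cbc)
  .pb_cache[[key]] <- op
  op
}

# exact solve of the discrete operator: src n x n x nz (4 pi lB rho terms),
# gsurf n x n with d(psi)/dz|0 = -gsurf.  Returns psi on the grid.
.pb_grid_solve <- function(op, src, gsurf) {
  n <- op$n; nz <- op$nz; h <- op$h
  T0 <- op$T0; T1 <- op$T1; S0 <- op$S0
  Sf <- array(0+0i, dim = c(n, n, nz))
  if (!is.null(src)) for (k in seq_len(nz)) Sf[, , k] <- fft(src[, , k])
  Gf <- fft(gsurf)
  nu <- nz - 1                       # unknown planes; psi[, , nz] = 0 (top)
  B <- array(0+0i, dim = c(n, n, nu))
  for (k in seq_len(nu)) {
    sm1 <- if (k > 1) Sf[, , k - 1] else 0 * Sf[, , 1]
    B[, , k] <- -(S0 * Sf[, , k] + (sm1 + Sf[, , k + 1]) / 12)
  }
  B[, , 1] <- B[, , 1] - T1 * 2 * h * Gf * op$cbc
  cvec <- vector("list", nu)
  for (k in seq_len(nu)) {
    cc <- if (k == 1) 2 * T1 else T1
    if (k > 1) {
      denom <- T0 - T1 * cvec[[k - 1]]
      B[, , k] <- B[, , k] - T1 * B[, , k - 1]
    } else denom <- T0
    cvec[[k]] <- cc / denom
    B[, , k] <- B[, , k] / denom
  }
  psi <- array(0, dim = c(n, n, nz))
  X <- B[, , nu]
  psi[, , nu] <- Re(fft(X, inverse = TRUE)) / n^2
  for (k in (nu - 1):1) {
    X <- B[, , k] - cvec[[k]] * X
    psi[, , k] <- Re(fft(X, inverse = TRUE)) / n^2
  }
  psi
}

# minimum-image lateral displacement for period L
.wrap_l <- function(d, L) d - L * round(d / L)

#' Screened-Coulomb (Yukawa) potential of a set of point charges
#'
#' \eqn{\psi(r) = l_B \sum_i z_i e^{-r_i/\lambda} / r_i} in kT/e units.
#' Lateral displacements use the minimum image for period `L` when given.
#'
#' @param points N x 3 matrix of evaluation points (Angstrom).
#' @param charge_pos M x 3 matrix of charge positions.
#' @param charge M charges, e.
#' @param lambda Debye length, Angstrom.
#' @param bjerrum Bjerrum length, Angstrom.
#' @param L lateral period (NULL: free space).
#' @return potential at each point, kT/e.
#' @export
yukawa_potential <- function(points, charge_pos, charge, lambda, bjerrum,
                             L = NULL) {
  points <- matrix(points, ncol = 3)
  charge_pos <- matrix(charge_pos, ncol = 3)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(charge_pos))) {
    dx <- points[, 1] - charge_pos[i, 1]
    dy <- points[, 2] - charge_pos[i, 2]
    if (!is.null(L)) { dx <- .wrap_l(dx, L); dy <- .wrap_l(dy, L) }
    r <- sqrt(dx^2 + dy^2 + (points[, 3] - charge_pos[i, 3])^2)
    r <- pmax(r, 1e-9)
    out <- out + charge[i] * bjerrum * exp(-r / lambda) / r
  }
  out
}

# singular-field bundle for a posed protein on a given solver grid
.singular_fields <- function(protein, sc) {
  a <- protein$atoms
  keep <- a$charge != 0
  q <- a$charge[keep]
  qpos <- as.matrix(a[keep, c("x", "y", "z")])
  n <- sc$grid_points; nz <- n + 1; h <- sc$h; L <- sc$box_edge
  lam <- sc$lambda; lB <- sc$bjerrum
  out <- list(q = q, qpos = qpos, n_charges = length(q))
  if (length(q) == 0) {
    out$psi_s <- array(0, dim = c(n, n, nz))
    out$flux <- matrix(0, n, n)
    out$below_sq <- 0
    out$pair_sum <- 0
    out$rmin <- NULL
    return(out)
  }
  if (any(qpos[, 3] < 0)) stop("protein charges must lie above the membrane plane (z >= 0)")
  gx <- (0:(n - 1)) * h
  zs <- (0:(nz - 1)) * h
  psi_s <- array(0, dim = c(n, n, nz))
  rmin <- array(Inf, dim = c(n, n, nz))
  flux <- matrix(0, n, n)
  for (i in seq_along(q)) {
    dx <- .wrap_l(gx - qpos[i, 1], L)
    dy <- .wrap_l(gx - qpos[i, 2], L)
    lat2 <- outer(dx^2, dy^2, "+")
    for (k in seq_len(nz)) {
      r <- sqrt(lat2 + (zs[k] - qpos[i, 3])^2)
      rmin[, , k] <- pmin(rmin[, , k], r)
      r <- pmax(r, 1e-9)
      psi_s[, , k] <- psi_s[, , k] + q[i] * lB * exp(-r / lam) / r
    }
    r0 <- sqrt(lat2 + qpos[i, 3]^2)
    flux <- flux + q[i] * lB * (-qpos[i, 3]) / r0 *
      (-exp(-r0 / lam)) * (1 / r0^2 + 1 / (lam * r0))
  }
  # ion-cloud integral of psi_s^2 below the membrane plane (protein-at-
  # infinity reference keeps this part of its screening cloud)
  kmax <- ceiling(8 * lam / h)
  below <- 0
  for (k in seq_len(kmax)) {
    pts <- cbind(rep(gx, n), rep(gx, each = n), -k * h)
    v <- yukawa_potential(pts, qpos, q, lam, lB, L = L)
    below <- below + sum(v^2) * h^3
  }
  # pairwise self energy  sum_{i<j} z_i z_j lB e^{-r/lam}/r  (pose invariant)
  pair <- 0
  if (length(q) > 1) {
    for (i in seq_len(length(q) - 1)) {
      d <- sweep(qpos[(i + 1):length(q), , drop = FALSE], 2, qpos[i, ])
      r <- sqrt(rowSums(d^2))
      pair <- pair + sum(q[i] * q[(i + 1):length(q)] * lB * exp(-r / lam) / r)
    }
  }
  out$psi_s <- psi_s
  out$flux <- flux
  out$below_sq <- below
  out$pair_sum <- pair
  out$rmin <- rmin
  out
}

# map membrane lattice sites onto grid columns by periodic tiling; returns
# the site index (column-major in the phi matrix) per grid column plus the
# node count per site.  Each site's surface charge (z phi spacing^2 / a) is
# spread over its nodes so the discrete energy sees the exact site area --
# this keeps the field energy, the Langmuir update and the conservation law
# mutually consistent.
.site_index_for_grid <- function(membrane, sc) {
  n <- sc$grid_points; h <- sc$h
  s <- membrane$lattice_spacing
  gx <- (0:(n - 1)) * h
  ix <- (floor((gx - membrane$plane_origin[1]) / s)) %% membrane$nx
  iy <- (floor((gx - membrane$plane_origin[2]) / s)) %% membrane$ny
  idx <- outer(ix + 1L, iy * membrane$nx, "+")   # phi[ix, iy] column-major index
  nsite <- membrane$nx * membrane$ny
  w <- tabulate(as.vector(idx), nbins = nsite)
  if (any(w == 0)) {
    warning("some membrane sites are not sampled by the solver grid; ",
            "their density is frozen (increase grid_points or spacing)")
  }
  list(index = idx, weight = w)
}

#' Solve the linearized PB potential for a protein pose over the membrane
#'
#' Returns the total potential field (analytic protein Yukawa part + grid
#' part carrying the membrane charge and the protein's image response), in
#' kT/e units, plus the linearized ion concentration fields
#' \eqn{c_\pm = c_0 (1 \mp e\psi/kT)}.
#'
#' @param protein a posed [charged_structure()] with all atoms at z >= 0, or
#'   NULL for a membrane-only solve.
#' @param membrane a [lattice_membrane()]; its `phi` field sets the surface
#'   charge.
#' @param cfg a `memfield_config` or [solver_config()].
#' @param phi optional override of the membrane `phi` field.
#' @param sing precomputed singular-field bundle (internal reuse across the
#'   self-consistency loop).
#' @return object of class `field_solution` with elements `psi` (total, kT/e,
#'   `n x n x (n+1)` with z layer 1 at the membrane), `psi_grid`, `c_plus`,
#'   `c_minus` (mol/L), `converged`, `iterations`, grid metadata and cached
#'   singular-field terms.
#' @export
solve_potential <- function(protein, membrane, cfg = memfield_config(),
                            phi = NULL, sing = NULL) {
  sc <- if (inherits(cfg, "solver_config")) cfg else solver_config(cfg)
  if (!inherits(cfg, "solver_config") && isTRUE(cfg$nonlinear_ions)) {
    stop("nonlinear ion treatment is not implemented; use the linearized model")
  }
  n <- sc$grid_points; nz <- n + 1
  op <- .pb_operator(sc$box_edge, n, nz, sc$lambda)
  if (is.null(phi)) phi <- membrane$phi
  if (any(phi < 0 | phi > 1)) stop("phi outside [0, 1]")
  if (is.null(sing)) {
    sing <- if (is.null(protein)) .singular_fields(charged_structure(
      data.frame(atom_id = integer(0), name = character(0),
                 residue_name = character(0), residue_id = integer(0),
                 segment = character(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), charge = numeric(0), element = character(0))), sc)
    else .singular_fields(protein, sc)
  }
  # protein image response (phi-independent): solved once per pose
  if (is.null(sing$psi_g_prot)) {
    sing$psi_g_prot <- if (sing$n_charges > 0) {
      .pb_grid_solve(op, NULL, sing$flux)
    } else array(0, dim = c(n, n, nz))
  }
  smap <- .site_index_for_grid(membrane, sc)
  sidx <- smap$index
  # per-node surface charge: site total charge spread over its grid nodes
  site_sigma <- .surface_charge_density(membrane, phi) *
    membrane$lattice_spacing^2 / (pmax(smap$weight, 1) * sc$h^2)
  sigma_grid <- matrix(site_sigma[sidx], n, n)
  psi_g_mem <- .pb_grid_solve(op, NULL, 4 * pi * sc$bjerrum * sigma_grid)
  psi_grid <- psi_g_mem + sing$psi_g_prot
  psi <- psi_grid + sing$psi_s
  c0 <- sc$ionic_strength
  structure(list(
    psi = psi, psi_grid = psi_grid, psi_g_mem = psi_g_mem,
    c_plus = c0 * (1 - psi), c_minus = c0 * (1 + psi),
    converged = TRUE, iterations = 1L,
    solver = sc, phi = phi, sigma_grid = sigma_grid, site_index = sidx,
    sing = sing, protein = protein
  ), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d^2 x %d grid, h = %.3f A, lambda = %.3f A\n",
              x$solver$grid_points, dim(x$psi)[3], x$solver$h, x$solver$lambda))
  cat(sprintf("  psi range [%.4g, %.4g] kT/e at the membrane plane\n",
              min(x$psi[, , 1]), max(x$psi[, , 1])))
  invisible(x)
}

# mean grid-node potential per membrane site at the membrane plane
.site_surface_potential <- function(field) {
  psi0 <- field$psi[, , 1]
  idx <- as.vector(field$site_index)
  nsite <- max(idx)
  sums <- vapply(seq_len(nsite), function(i) 0, numeric(1))
  sums <- as.vector(tapply(as.vector(psi0), idx, mean))
  full <- numeric(nsite)
  full[sort(unique(idx))] <- sums
  full
}

#' Langmuir (lattice-gas) density update with conserved lipid amount
#'
#' The minimizer of the mean-field free energy at fixed potential:
#' \eqn{\phi'/(1-\phi') = \exp(-(z_l \psi - \mu))} with the chemical
#' potential \eqn{\mu} chosen so the total anionic amount is conserved,
#' followed by damped mixing \eqn{\phi_{next} = (1-m)\phi + m\phi'}.
#'
#' @param psi_site surface potential per site, kT/e.
#' @param phi current area fractions per site.
#' @param z_l headgroup charge of the mobile species, e.
#' @param mixing damping factor in (0, 1].
#' @return updated phi (same shape as `phi`).
#' @export
langmuir_update <- function(psi_site, phi, z_l, mixing = 0.5) {
  target <- mean(phi)
  if (target <= 0 || target >= 1) stop("mean phi must be in (0, 1)")
  en <- z_l * as.vector(psi_site)
  f <- function(mu) mean(1 / (1 + exp(en - mu))) - target
  lo <- min(en) + log(target / (1 - target)) - 30
  hi <- max(en) + log(target / (1 - target)) + 30
  if (f(lo) > 0 || f(hi) < 0) stop("lipid conservation bisection failed to bracket")
  mu <- uniroot(f, c(lo, hi), tol = 1e-15)$root
  # Newton polish: conservation to the rounding floor without leaving (0, 1)
  for (it in 1:20) {
    p <- 1 / (1 + exp(en - mu))
    g <- mean(p) - target
    dg <- mean(p * (1 - p))
    if (abs(g) < 1e-16 * max(1, target) || dg <= 0) break
    mu <- mu - g / dg
  }
  phi_new <- 1 / (1 + exp(en - mu))
  out <- (1 - mixing) * as.vector(phi) + mixing * phi_new
  if (is.matrix(phi)) out <- matrix(out, nrow(phi), ncol(phi))
  out
}

#' One self-consistency step of the lipid density field
#'
#' @param field a [solve_potential()] result for the current `phi`.
#' @param membrane the [lattice_membrane()].
#' @param cfg configuration (for the mixing damping).
#' @return updated phi matrix; total anionic amount is conserved exactly.
#' @export
update_lipid_densities <- function(field, membrane, cfg = memfield_config()) {
  sc <- if (inherits(cfg, "solver_config")) cfg else solver_config(cfg)
  psi_site <- .site_surface_potential(field)
  matrix(langmuir_update(psi_site, as.vector(field$phi),
                         .anionic_charge(membrane), mixing = sc$mixing),
         membrane$nx, membrane$ny)
}

# entropy density of a lattice-gas site, with 0 log 0 = 0
.site_entropy <- function(phi) {
  s <- numeric(length(phi))
  p <- phi > 0
  s[p] <- s[p] + phi[p] * log(phi[p])
  p <- phi < 1
  s[p] <- s[p] + (1 - phi[p]) * log(1 - phi[p])
  s
}

#' Reference (protein-at-infinity) state for free-energy differences
#'
#' Membrane-only state with the anionic density relaxed to its own fixed
#' point starting from uniform (for solver grids commensurate with the lipid
#' lattice the uniform field is exactly that fixed point; otherwise the
#' relaxation absorbs a small grid-quantization texture).  All adsorption
#' free energies are measured against this state plus the protein-in-bulk
#' self energy.
#'
#' @param membrane a [lattice_membrane()].
#' @param cfg configuration.
#' @return list with the reference field, relaxed `phi`, and raw component
#'   values used by [free_energy()].
#' @export
mfm_reference <- function(membrane, cfg = memfield_config()) {
  sc <- if (inherits(cfg, "solver_config")) cfg else solver_config(cfg)
  phi_bar <- mean(membrane$phi)
  phi <- matrix(phi_bar, membrane$nx, membrane$ny)
  z_l <- .anionic_charge(membrane)
  field <- solve_potential(NULL, membrane, sc, phi = phi)
  for (it in seq_len(sc$max_iter)) {
    psi_site <- .site_surface_potential(field)
    phi_star <- matrix(langmuir_update(psi_site, as.vector(phi), z_l,
                                       mixing = 1), membrane$nx, membrane$ny)
    if (max(abs(phi_star - phi)) < sc$phi_tol) break
    phi <- (1 - sc$mixing) * phi + sc$mixing * phi_star
    field <- solve_potential(NULL, membrane, sc, phi = phi)
  }
  h <- sc$h
  e_chg <- 0.5 * sum(field$sigma_grid * field$psi[, , 1]) * h^2
  c0A3 <- .conc_to_A3(sc$ionic_strength)
  ion_sq <- c0A3 * sum(field$psi^2) * h^3
  lip_sum <- (membrane$lattice_spacing^2 / membrane$area_per_lipid) *
    sum(.site_entropy(as.vector(phi)))
  list(field = field, phi = phi, phi_bar = phi_bar, e_chg = e_chg,
       ion_sq = ion_sq, lip_sum = lip_sum, solver = sc)
}

#' Mean-field free energy breakdown
#'
#' Components in kT, relative to the protein-at-infinity, uniform-membrane
#' reference when `reference` is supplied (as in all docking energies):
#' \itemize{
#'   \item `F_el`: electrostatic field energy \eqn{(\varepsilon/2)\int |\nabla\psi|^2},
#'     evaluated via the equilibrium identity \eqn{F_{el} = \frac12\sum q\psi - F_{ion}}.
#'   \item `F_ion`: translational-entropy penalty of the mobile ions,
#'     \eqn{kT\sum_\pm\int[c\ln(c/c_0)-(c-c_0)]}, to second order
#'     \eqn{kTc_0\int (e\psi/kT)^2}.
#'   \item `F_lip`: lipid mixing entropy
#'     \eqn{(kT/a)\int[\phi\ln\phi + (1-\phi)\ln(1-\phi)]}.
#' }
#' `F_total = F_el + F_ion + F_lip` holds to machine precision, and equals
#' the charging free energy \eqn{\frac12\sum q\psi + F_{lip}} that the
#' self-consistent lipid relaxation descends on.
#'
#' @param field a [solve_potential()] result.
#' @param membrane the [lattice_membrane()].
#' @param cfg configuration.
#' @param reference a [mfm_reference()] result; NULL gives raw (absolute)
#'   values whose reference terms have not been subtracted.
#' @return list of class `free_energy_breakdown` with `F_total`, `F_el`,
#'   `F_ion`, `F_lip` (kT).
#' @export
free_energy <- function(field, membrane, cfg = memfield_config(),
                        reference = NULL) {
  sc <- field$solver
  h <- sc$h
  phi <- field$phi
  if (any(phi <= 0 | phi >= 1)) {
    if (any(phi < 0 | phi > 1)) stop("phi outside [0, 1]")
  }
  c0A3 <- .conc_to_A3(sc$ionic_strength)
  sing <- field$sing
  a <- membrane$area_per_lipid
  site_area <- membrane$lattice_spacing^2
  # charge energy.  The protein<->membrane cross term is counted once,
  # through the surface-side path (membrane charge in the protein's direct +
  # image field); this makes the Langmuir update the exact gradient of the
  # discrete functional, so the self-consistency loop descends on F_total.
  e_mem <- 0.5 * sum(field$sigma_grid * field$psi_g_mem[, , 1]) * h^2
  e_cross <- 0
  e_protself <- 0
  psig_at <- numeric(0)
  if (sing$n_charges > 0) {
    e_cross <- sum(field$sigma_grid *
                     (sing$psi_s[, , 1] + sing$psi_g_prot[, , 1])) * h^2
    psig_at <- .interp_grid(field$psi_grid, sing$qpos, sc)
    e_protself <- 0.5 * sum(sing$q * .interp_grid(sing$psi_g_prot, sing$qpos, sc)) +
      sing$pair_sum
  }
  e_chg <- e_mem + e_cross + e_protself
  # ion term: c0 int psi^2, near-charge cells handled by an equal-volume
  # analytic ball around each charge
  if (sing$n_charges > 0) {
    mask <- sing$rmin < 0.6 * sc$h
    cross <- 2 * sing$psi_s * field$psi_grid + field$psi_grid^2
    cross[mask] <- field$psi_grid[mask]^2
    nmask <- sum(mask)
    ball <- 0
    if (nmask > 0) {
      req <- (3 * nmask * h^3 / (4 * pi * sing$n_charges))^(1 / 3)
      lam <- sc$lambda
      ball_int <- 4 * pi * sc$bjerrum * lam^2 *
        (1 - exp(-req / lam) * (1 + req / lam))
      ball <- sum(2 * sing$q * psig_at) * ball_int
    }
    ion_rel_part <- c0A3 * (sum(cross) * h^3 + ball)
    sing_sq <- c0A3 * (sum(sing$psi_s[!mask]^2) * h^3)
  } else {
    ion_rel_part <- c0A3 * sum(field$psi_grid^2) * h^3
    sing_sq <- 0
  }
  F_lip_raw <- (site_area / a) * sum(.site_entropy(as.vector(phi)))
  if (is.null(reference)) {
    ion <- ion_rel_part + sing_sq
    out <- list(F_total = e_chg + F_lip_raw, F_el = e_chg - ion,
                F_ion = ion, F_lip = F_lip_raw)
  } else {
    # relative: pose minus (uniform membrane + protein in bulk)
    ion <- ion_rel_part - reference$ion_sq - c0A3 * sing$below_sq
    e_rel <- e_chg - sing$pair_sum - reference$e_chg
    F_lip <- F_lip_raw - reference$lip_sum
    out <- list(F_total = e_rel + F_lip, F_el = e_rel - ion,
                F_ion = ion, F_lip = F_lip)
  }
  structure(out, class = "free_energy_breakdown")
}

#' @export
print.free_energy_breakdown <- function(x, ...) {
  cat(sprintf("F_total = %.6g kT  (F_el %.6g, F_ion %.6g, F_lip %.6g)\n",
              x$F_total, x$F_el, x$F_ion, x$F_lip))
  invisible(x)
}

#' Evaluate the total potential at arbitrary points
#'
#' The smooth grid part is interpolated trilinearly; the protein point-charge
#' (Yukawa) part is evaluated analytically, so accuracy does not degrade
#' near the fixed charges.
#'
#' @param field a [solve_potential()] result.
#' @param points N x 3 matrix, Angstrom (z >= 0).
#' @return potential at each point, kT/e.
#' @export
potential_at <- function(field, points) {
  points <- matrix(points, ncol = 3)
  out <- .interp_grid(field$psi_grid, points, field$solver)
  if (field$sing$n_charges > 0) {
    out <- out + yukawa_potential(points, field$sing$qpos, field$sing$q,
                                  field$solver$lambda, field$solver$bjerrum,
                                  L = field$solver$box_edge)
  }
  out
}

# trilinear interpolation of a grid field at arbitrary points
.interp_grid <- function(arr, points, sc) {
  n <- sc$grid_points; h <- sc$h
  nz <- dim(arr)[3]
  points <- matrix(points, ncol = 3)
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    fx <- (points[p, 1] %% sc$box_edge) / h
    fy <- (points[p, 2] %% sc$box_edge) / h
    fz <- points[p, 3] / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    k0 <- max(0, min(nz - 2, k0))
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    v <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
        (if (dk) wz else 1 - wz)
      v <- v + w * arr[(i0 + di) %% n + 1, (j0 + dj) %% n + 1, k0 + dk + 1]
    }
    out[p] <- v
  }
  out
}

#' Relax the anionic lipid density to self-consistency for a fixed pose
#'
#' Alternates the linear field solve with the conserved Langmuir update
#' until the density field is a fixed point (`max |dphi| < phi_tol`).  The
#' free energy is recorded at every iteration; it is non-increasing along
#' the path.
#'
#' @param protein posed [charged_structure()] (or NULL).
#' @param membrane [lattice_membrane()]; `phi` is the starting field.
#' @param cfg configuration.
#' @param reference optional precomputed [mfm_reference()].
#' @return list with `field`, `phi`, `free_energy` (final breakdown),
#'   `trace` (data frame of components per iteration), `iterations`,
#'   `converged`.
#' @export
relax_densities <- function(protein, membrane, cfg = memfield_config(),
                            reference = NULL) {
  sc <- if (inherits(cfg, "solver_config")) cfg else solver_config(cfg)
  if (is.null(reference)) reference <- mfm_reference(membrane, sc)
  sing <- if (is.null(protein)) NULL else .singular_fields(protein, sc)
  phi <- membrane$phi
  z_l <- .anionic_charge(membrane)
  solve1 <- function(phi) {
    f <- solve_potential(protein, membrane, sc, phi = phi, sing = sing)
    sing <<- f$sing
    f
  }
  field <- solve1(phi)
  fe <- free_energy(field, membrane, sc, reference = reference)
  trace <- data.frame(iteration = 1L, F_total = fe$F_total, F_el = fe$F_el,
                      F_ion = fe$F_ion, F_lip = fe$F_lip)
  residual <- Inf
  m_cur <- sc$mixing   # adaptive damping: grows while F keeps descending
  phi_prev <- NULL; r_prev <- NULL
  for (it in seq_len(sc$max_iter)) {
    # full (undamped) Langmuir target; residual measures the fixed point
    psi_site <- .site_surface_potential(field)
    phi_star <- matrix(langmuir_update(psi_site, as.vector(phi), z_l,
                                       mixing = 1), nrow(phi), ncol(phi))
    r <- phi_star - phi
    residual <- max(abs(r))
    if (residual < sc$phi_tol) {
      membrane$phi <- phi
      return(list(field = field, phi = phi, membrane = membrane,
                  free_energy = fe, trace = trace, iterations = it,
                  converged = TRUE, residual = residual))
    }
    accepted <- FALSE
    # depth-1 Anderson (secant) acceleration; mixing weights sum to one so
    # the anionic amount stays conserved.  Accept only if F decreases and
    # the accelerated iterate stays strictly inside (0, 1).
    if (!is.null(phi_prev)) {
      dr <- r - r_prev
      den <- sum(dr^2)
      if (den > 0) {
        th <- sum(r * dr) / den
        phi_mix <- phi + th * (phi_prev - phi)
        r_mix <- r + th * (r_prev - r)
        phi_try <- phi_mix + min(1, m_cur * 2) * r_mix
        if (all(phi_try > 0 & phi_try < 1)) {
          field_try <- solve1(phi_try)
          fe_try <- free_energy(field_try, membrane, sc, reference = reference)
          if (fe_try$F_total <= fe$F_total + 1e-12) accepted <- TRUE
        }
      }
    }
    if (!accepted) {
      # damped step with backtracking so the free energy never increases;
      # the step direction is a descent direction of the discrete
      # functional, so a small enough step always makes progress
      m <- m_cur
      repeat {
        phi_try <- phi + m * r
        field_try <- solve1(phi_try)
        fe_try <- free_energy(field_try, membrane, sc, reference = reference)
        if (fe_try$F_total <= fe$F_total + 1e-12 || m < 1e-7) break
        m <- m / 2
      }
      m_cur <- min(1, m * 1.5)
    }
    phi_prev <- phi; r_prev <- r
    phi <- phi_try; field <- field_try; fe <- fe_try
    trace <- rbind(trace, data.frame(iteration = it + 1L, F_total = fe$F_total,
                                     F_el = fe$F_el, F_ion = fe$F_ion,
                                     F_lip = fe$F_lip))
  }
  stop(sprintf("density relaxation did not converge in %d iterations (residual %.3g)",
               sc$max_iter, residual))
}
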