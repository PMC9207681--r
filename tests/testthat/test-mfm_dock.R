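test_that("debye_length reproduces the closed form and its scalings", {
  expect_equal(debye_length(0.15, 310, 80), 8.09, tolerance = 0.01 / 8.09)
  expect_equal(debye_length(0.15, 298.15, 78.5), 7.86, tolerance = 0.01 / 7.86)
  # lambda ~ I^(-1/2): quadrupling I halves lambda
  expect_equal(debye_length(0.6, 310, 80), debye_length(0.15, 310, 80) / 2,
               tolerance = 1e-12)
  expect_error(debye_length(-0.1), "positive")
  expect_error(debye_length(0.15, 0), "positive")
})

test_that("solver_config derives lambda and warns on coarse grids", {
  sc <- solver_config(memfield_config())
  expect_equal(sc$lambda, debye_length(0.15, 310, 80))
  expect_equal(sc$h, 4)
  expect_warning(solver_config(memfield_config(grid_points = 16)),
                 "under-resolved")
})

test_that("all charges zero gives an identically zero potential", {
  mem <- lattice_membrane(16, 16,
                          species = data.frame(name = c("POPC", "POPS"),
                                               headgroup_charge = c(0, -1),
                                               mole_fraction = c(0.9, 0.1)),
                          phi = 0.5)
  mem$species$headgroup_charge <- c(0, 0)   # neutral headgroups everywhere
  f <- solve_potential(NULL, mem, small_cfg())
  expect_equal(max(abs(f$psi)), 0)
  expect_equal(f$c_plus, f$c_minus)
})

test_that("uniformly charged plane reproduces the Gouy-Chapman profile", {
  cfg <- small_cfg()
  sc <- solver_config(cfg)
  mem <- small_membrane()
  f <- solve_potential(NULL, mem, cfg)
  z <- (0:sc$grid_points) * sc$h
  sigma <- -0.1 / 65
  truth <- 4 * pi * sc$bjerrum * sigma * sc$lambda * exp(-z / sc$lambda)
  sel <- z <= 4 * sc$lambda
  expect_lt(max(abs(f$psi[3, 9, sel] / truth[sel] - 1)), 0.02)
  # linearized ion fields
  expect_equal(f$c_plus, sc$ionic_strength * (1 - f$psi))
})

test_that("point charge over an uncharged plane matches the Yukawa form", {
  cfg <- small_cfg()
  sc <- solver_config(cfg)
  mem <- small_membrane()
  mem$phi[] <- 1e-9   # essentially uncharged
  prot <- coords_structure(rbind(c(64, 64, 64)), charge = 1)
  f <- solve_potential(prot, mem, cfg)
  yuk <- function(r) sc$bjerrum * exp(-r / sc$lambda) / r
  set.seed(7)
  for (i in 1:50) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    d <- runif(1, sc$lambda, 4 * sc$lambda)
    p <- c(64, 64, 64) + d * u
    expect_lt(abs(potential_at(f, rbind(p)) / yuk(d) - 1), 0.02)
  }
})

test_that("charge + wall image response converges to the exact closed form", {
  # a charge above an uncharged impermeable plane has the exact solution
  # yukawa(direct) + yukawa(image); the image part is computed by the grid,
  # so its error measures real discretization error and shrinks with h
  mem <- small_membrane()
  mem$phi[] <- 1e-9
  err_for <- function(n) {
    cfg <- memfield_config(box_edge_A = 128, grid_points = n)
    sc <- solver_config(cfg)
    z0 <- 12
    prot <- coords_structure(rbind(c(64, 64, z0)), charge = 1)
    f <- solve_potential(prot, mem, cfg)
    yuk <- function(r) sc$bjerrum * exp(-r / sc$lambda) / r
    set.seed(11)
    errs <- numeric(0)
    while (length(errs) < 60) {
      p <- c(runif(1, 40, 88), runif(1, 40, 88), runif(1, 0, 40))
      rd <- sqrt(sum((p - c(64, 64, z0))^2))
      if (rd < sc$lambda || rd > 4 * sc$lambda) next
      ri <- sqrt(sum((p - c(64, 64, -z0))^2))
      truth <- yuk(rd) + yuk(ri)
      errs <- c(errs, abs(potential_at(f, rbind(p)) / truth - 1))
    }
    max(errs)
  }
  e32 <- err_for(32)   # h = lambda/2
  e64 <- err_for(64)   # h = lambda/4
  expect_lt(e32, 0.02)
  expect_lt(e64, e32)  # error decreases under refinement
})

test_that("langmuir update matches a brute-force two-site minimization", {
  # two sites, known potentials; oracle: direct constrained minimization of
  # z*psi*phi + phi log phi + (1-phi) log(1-phi) per site at fixed total
  psi <- c(-1.3, 0.4)
  phi0 <- c(0.1, 0.1)
  z <- -1
  oracle <- optimize(function(p1) {
    p2 <- sum(phi0) - p1
    z * psi[1] * p1 + z * psi[2] * p2 +
      p1 * log(p1) + (1 - p1) * log(1 - p1) +
      p2 * log(p2) + (1 - p2) * log(1 - p2)
  }, interval = c(1e-6, sum(phi0) - 1e-6), tol = 1e-12)$minimum
  upd <- langmuir_update(psi, phi0, z, mixing = 1)
  expect_equal(upd[1], oracle, tolerance = 1e-6)
  expect_equal(sum(upd), sum(phi0), tolerance = 1e-12)
  # psi == 0 relaxes to the uniform mean
  upd0 <- langmuir_update(c(0, 0, 0, 0), c(0.4, 0.1, 0.05, 0.25), z, mixing = 1)
  expect_equal(upd0, rep(0.2, 4), tolerance = 1e-12)
})

test_that("density updates conserve the anionic amount exactly", {
  cfg <- small_cfg()
  mem <- small_membrane()
  bp <- place_at(make_bead_protein(), 64, 64, 2)
  f <- solve_potential(bp, mem, cfg)
  total0 <- anionic_amount(mem)
  for (i in 1:5) {
    mem$phi <- update_lipid_densities(f, mem, cfg)
    f <- solve_potential(bp, mem, cfg, sing = f$sing)
    expect_lt(abs(anionic_amount(mem) / total0 - 1), 1e-10)
  }
})

test_that("free energy components sum exactly and vanish at the reference", {
  cfg <- small_cfg()
  mem <- small_membrane()
  ref <- mfm_reference(mem, cfg)
  # uncharged protein over the reference membrane: all components zero
  prot0 <- coords_structure(rbind(c(60, 64, 10), c(70, 64, 18)), charge = 0)
  mem$phi <- ref$phi
  fe0 <- free_energy(solve_potential(prot0, mem, cfg), mem, cfg, reference = ref)
  expect_equal(fe0$F_total, 0, tolerance = 1e-9)
  expect_equal(fe0$F_el, 0, tolerance = 1e-9)
  expect_equal(fe0$F_ion, 0, tolerance = 1e-9)
  expect_equal(fe0$F_lip, 0, tolerance = 1e-9)
  # sum identity on a charged pose
  bp <- place_at(make_bead_protein(), 64, 64, 2)
  res <- relax_densities(bp, mem, cfg, reference = ref)
  fe <- res$free_energy
  expect_equal(fe$F_total, fe$F_el + fe$F_ion + fe$F_lip, tolerance = 1e-9)
})

test_that("planted non-uniform phi reproduces the direct F_lip lattice sum", {
  cfg <- small_cfg()
  mem <- small_membrane()
  phibar <- mean(mem$phi)
  phi <- matrix(rep(c(2 * phibar, 1e-12), length.out = 16 * 16), 16, 16)
  a <- mem$area_per_lipid
  s2 <- mem$lattice_spacing^2
  ent <- function(p) ifelse(p > 0, p * log(p), 0) +
    ifelse(p < 1, (1 - p) * log(1 - p), 0)
  direct <- (s2 / a) * sum(ent(as.vector(phi)))
  mem$species$headgroup_charge[] <- 0    # kill the field: pure entropy test
  mem$phi <- phi
  fe <- free_energy(solve_potential(NULL, mem, cfg), mem, cfg)
  expect_equal(fe$F_lip, direct, tolerance = 1e-12)
})

test_that("self-consistent relaxation descends monotonically to a fixed point", {
  cfg <- small_cfg()
  mem <- small_membrane()
  ref <- mfm_reference(mem, cfg)
  set.seed(99)
  for (s in 1:4) {
    cs <- data.frame(label = sprintf("R%d", sample(1:80, 4)),
                     x = runif(4, -8, 8), y = runif(4, -8, 8),
                     z = runif(4, 0, 8), charge = sample(c(1, 1, 2, -1), 4))
    bp <- place_at(make_bead_protein(bead_protein_spec(charged_sites = cs)),
                   64, 64, 2)
    mem$phi <- ref$phi
    res <- relax_densities(bp, mem, cfg, reference = ref)
    expect_true(res$converged)
    expect_lt(max(diff(res$trace$F_total)), 1e-8)
    phi_next <- update_lipid_densities(res$field, res$membrane, cfg)
    expect_lt(max(abs(phi_next - res$phi)), 1e-8)
  }
})

test_that("adsorption energy decays to zero at large separation", {
  cfg <- memfield_config(box_edge_A = 128, grid_points = 64,
                         ionic_strength_M = 0.6)   # lambda ~ 4 A
  sc <- suppressWarnings(solver_config(cfg))
  mem <- small_membrane()
  ref <- mfm_reference(mem, sc)
  mem$phi <- ref$phi
  bp <- place_at(make_bead_protein(), 64, 64, 12 * sc$lambda)
  res <- relax_densities(bp, mem, sc, reference = ref)
  expect_lt(abs(res$free_energy$F_total), 1e-4)
})

test_that("dipole scan ranks poses like brute-force re-evaluation", {
  cfg <- small_cfg()
  mem <- small_membrane()
  dip <- coords_structure(rbind(c(0, 0, 0), c(0, 0, 20)), charge = c(2, -2))
  scan <- scan_orientations(dip, mem, cfg, n_directions = 4, n_azimuths = 3)
  expect_true(all(scan$poses$converged))
  # best pose puts the positive bead proximal to the anionic membrane
  best <- scan$best_structure$atoms
  expect_lt(best$z[best$charge > 0], best$z[best$charge < 0])
  # brute force: independently rebuild and evaluate every pose
  sc <- solver_config(cfg)
  ref <- mfm_reference(mem, sc)
  mem$phi <- ref$phi
  dirs <- fibonacci_sphere(4)
  az <- c(0, 120, 240)
  xyz0 <- sweep(as.matrix(dip), 2, colMeans(as.matrix(dip)))
  brute <- NULL
  for (d in 1:4) {
    v <- dirs[d, ] / sqrt(sum(dirs[d, ]^2))
    cth <- -v[3]
    R1 <- if (cth > 1 - 1e-12) diag(3) else if (cth < -1 + 1e-12) {
      rotation_matrix(c(1, 0, 0), 180)
    } else rotation_matrix(c(v[2] * (-1) - 0, 0 - v[1] * (-1), 0), # v x (0,0,-1)
                           acos(cth) * 180 / pi)
    for (ai in seq_along(az)) {
      xyz <- xyz0 %*% t(R1) %*% t(rotation_matrix(c(0, 0, 1), az[ai]))
      pose <- place_at(coords_structure(xyz, charge = c(2, -2)), 64, 64, 2)
      # keep the exact lateral centering used by the scan
      res <- relax_densities(pose, mem, sc, reference = ref)
      brute <- rbind(brute, data.frame(direction = d, azimuth = az[ai],
                                       energy = res$free_energy$F_total))
    }
  }
  brute <- brute[order(brute$energy, brute$direction, brute$azimuth), ]
  expect_equal(scan$poses$direction, brute$direction)
  expect_equal(scan$poses$azimuth, brute$azimuth)
  expect_equal(scan$poses$adsorption_energy, brute$energy, tolerance = 1e-9)
})

test_that("on-axis charge distributions are azimuth-degenerate", {
  cfg <- small_cfg()
  mem <- small_membrane()
  mono <- coords_structure(rbind(c(0, 0, 0)), charge = 3)
  scan <- scan_orientations(mono, mem, cfg, n_directions = 2, n_azimuths = 4)
  for (d in 1:2) {
    e <- scan$poses$adsorption_energy[scan$poses$direction == d]
    expect_lt(diff(range(e)), 1e-6)
  }
})

test_that("neutral protein scan is energy-degenerate at zero", {
  cfg <- small_cfg()
  mem <- small_membrane()
  prot <- coords_structure(ideal_helix(8), charge = 0)
  scan <- scan_orientations(prot, mem, cfg, n_directions = 2, n_azimuths = 2)
  expect_lt(max(abs(scan$poses$adsorption_energy)), 1e-6)
})

test_that("density placement draws the right sites, reproducibly", {
  mem <- small_membrane()
  phi <- matrix(1, 16, 16)
  out <- export_density_and_place(phi, mem, 40, seed = 4)
  expect_equal(nrow(out), 40)
  expect_equal(anyDuplicated(out[, c("ix", "iy")]), 0)
  out2 <- export_density_and_place(phi, mem, 40, seed = 4)
  expect_identical(out, out2)
  # all mass on a 10-site patch
  phi0 <- matrix(0, 16, 16)
  phi0[1:10] <- 1
  expect_error(export_density_and_place(phi0, mem, 40, seed = 1),
               "concentrated")
  sel <- export_density_and_place(phi0, mem, 10, seed = 1)
  expect_setequal(sel$ix + (sel$iy - 1) * 16, 1:10)
  expect_error(export_density_and_place(matrix(0, 16, 16), mem, 5, seed = 1),
               "zero")
  # density CSV export
  f <- tempfile(fileext = ".csv")
  export_density_and_place(phi, mem, 5, seed = 2, out_density = f)
  expect_equal(nrow(read_table_artifact(f)$data), 256)
})

test_that("placement frequencies follow the density map (chi-square)", {
  mem <- lattice_membrane(10, 5, species = default_membrane_species())
  set.seed(21)
  phi <- matrix(runif(50, 0.2, 1), 10, 5)
  p <- as.vector(phi) / sum(phi)
  n_draw <- 3
  reps <- 20000
  counts <- numeric(50)
  for (r in seq_len(reps)) {
    sel <- export_density_and_place(phi, mem, n_draw, seed = r)
    idx <- sel$ix + (sel$iy - 1) * 10
    counts[idx] <- counts[idx] + 1
  }
  expected <- reps * n_draw * p
  stat <- sum((counts - expected)^2 / expected)
  pval <- stats::pchisq(stat, df = 49, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})
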