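all_species <- c("POPS", "POPC", "POPE", "CHOL", "LIP")

# one-frame topology: a Lys NZ atom plus one single-oxygen lipid at distance d
lys_lipid_frame <- function(d) {
  atoms <- data.frame(
    atom_id = 1:2,
    name = c("NZ", "O1"),
    residue_name = c("LYS", "LIP"),
    residue_id = c(7L, 1001L),
    segment = "other",
    x = c(0, d), y = 0, z = 0,
    charge = 0, element = c("N", "O"),
    stringsAsFactors = FALSE)
  charged_structure(atoms)
}

test_that("the 4 Angstrom criterion boundary is inclusive", {
  crit <- contact_criterion()
  inside <- residue_lipid_contacts(lys_lipid_frame(3.99), crit, 7, "LIP")
  expect_equal(inside[["7"]], 1001L)
  at_cut <- residue_lipid_contacts(lys_lipid_frame(4.00), crit, 7, "LIP")
  expect_equal(at_cut[["7"]], 1001L)          # "within 4 A" read as <= 4.0
  outside <- residue_lipid_contacts(lys_lipid_frame(4.01), crit, 7, "LIP")
  expect_length(outside[["7"]], 0)
})

test_that("contact detection errors on unresolvable names", {
  crit <- contact_criterion()
  expect_error(residue_lipid_contacts(lys_lipid_frame(3), crit, 99, "LIP"),
               "not found")
  expect_error(residue_lipid_contacts(lys_lipid_frame(3), crit, 7, "XXX"),
               "oxygen list")
})

test_that("contact detection equals the all-pairs distance oracle", {
  crit <- contact_criterion()
  for (seed in 1:100) {
    set.seed(seed)
    # random frame: 3 residues with 1-3 polar atoms, 6 lipids with 1-2 oxygens
    rows <- NULL
    for (r in 1:3) {
      np <- sample(1:3, 1)
      nm <- c("NE", "NH1", "NH2")[seq_len(np)]
      rows <- rbind(rows, data.frame(
        name = nm, residue_name = "ARG", residue_id = r,
        x = runif(np, 0, 30), y = runif(np, 0, 30), z = runif(np, 0, 30)))
    }
    for (l in 1:6) {
      no <- sample(1:2, 1)
      rows <- rbind(rows, data.frame(
        name = c("O1", "O3")[seq_len(no)], residue_name = "CHOL",
        residue_id = 1000 + l,
        x = runif(no, 0, 30), y = runif(no, 0, 30), z = runif(no, 0, 30)))
    }
    rows$atom_id <- seq_len(nrow(rows))
    rows$segment <- "other"; rows$charge <- 0
    rows$element <- substr(rows$name, 1, 1)
    frame <- charged_structure(rows)
    got <- residue_lipid_contacts(frame, crit, 1:3, "CHOL")
    # brute force: explicit double loop over every (polar atom, oxygen) pair
    a <- frame$atoms
    for (r in 1:3) {
      pa <- a[a$residue_id == r & a$name %in% c("NE", "NH1", "NH2"), ]
      bound <- integer(0)
      for (l in 1000 + 1:6) {
        ox <- a[a$residue_id == l & a$name %in% c("O1", "O3"), ]
        hit <- FALSE
        for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(ox))) {
          d <- sqrt((pa$x[i] - ox$x[j])^2 + (pa$y[i] - ox$y[j])^2 +
                      (pa$z[i] - ox$z[j])^2)
          if (d <= 4) hit <- TRUE
        }
        if (hit) bound <- c(bound, l)
      }
      expect_identical(sort(got[[as.character(r)]]), sort(as.integer(bound)))
    }
  }
})

test_that("planted occupancies yield exact probabilities and multiplicities", {
  bp <- make_bead_protein()
  mem <- make_bilayer(100, seed = 3)
  crit <- contact_criterion()
  # 30/100 frames bound at R46; two lipids simultaneously at R218 in 70/100
  ev <- rbind(data.frame(residue = 46, lipid = 1007, frame = 1:30),
              data.frame(residue = 218, lipid = 1011, frame = 1:70),
              data.frame(residue = 218, lipid = 1013, frame = 1:70))
  tr <- make_trajectory(bp, mem, data.frame(tilt = rep(45, 100), rotation = 30),
                        binding_plan = binding_plan(ev), n_frames = 100)
  tb <- binding_probability_table(tr, crit, c(46, 58, 218), all_species)
  res <- tb$residues
  expect_equal(res$p_bound[res$residue == 46], 0.30)
  expect_equal(res$p_bound[res$residue == 58], 0)
  expect_equal(res$p_two_or_more[res$residue == 218], 0.70)
  expect_equal(res$mean_multiplicity[res$residue == 218], 1.4)
  expect_equal(res$pct_two_or_more[res$residue == 218], 70)
  # table invariants
  expect_true(all(res$p_two_or_more <= res$p_bound + 1e-12))
  expect_true(all(res$p_bound >= 0 & res$p_bound <= 1))
})

test_that("occluded shared site: every R58 lipid is shared with R46", {
  bp <- make_bead_protein()
  mem <- make_bilayer(100, seed = 3)
  crit <- contact_criterion()
  # every lipid that binds R58 binds R46 in the same frame
  ev <- rbind(data.frame(residue = 58, lipid = 1020, frame = 1:40),
              data.frame(residue = 46, lipid = 1020, frame = 1:40),
              data.frame(residue = 46, lipid = 1030, frame = 41:55))
  tr <- make_trajectory(bp, mem, data.frame(tilt = rep(45, 100), rotation = 30),
                        binding_plan = binding_plan(ev), n_frames = 100)
  tb <- binding_probability_table(tr, crit, c(46, 58), all_species,
                                  shared_pairs = list(c(46, 58)))
  res <- tb$residues
  expect_equal(tb$shared$p_shared, res$p_bound[res$residue == 58])
  # no frame has R58-only binding
  expect_equal(res$p_bound[res$residue == 58], 0.40)
  expect_equal(res$p_bound[res$residue == 46], 0.55)
  # invariant: shared probability bounded by both members
  expect_lte(tb$shared$p_shared,
             min(res$p_bound) + 1e-12)
})

test_that("empty trajectories and empty plans behave", {
  bp <- make_bead_protein()
  mem <- make_bilayer(100, seed = 3)
  crit <- contact_criterion()
  tr <- make_trajectory(bp, mem, data.frame(tilt = rep(45, 5), rotation = 0),
                        n_frames = 5)
  tb <- binding_probability_table(tr, crit, c(46, 58, 218), all_species)
  expect_true(all(tb$residues$p_bound == 0))
  expect_error(binding_probability_table(
    mf_trajectory(tr$topology, tr$coords[, , 0, drop = FALSE], numeric(0)),
    crit, 46, all_species), "empty")
})

test_that("contact tables write and read as percent-occurrence CSV", {
  bp <- make_bead_protein()
  mem <- make_bilayer(100, seed = 3)
  ev <- data.frame(residue = 46, lipid = 1007, frame = 1:3)
  tr <- make_trajectory(bp, mem, data.frame(tilt = rep(45, 10), rotation = 30),
                        binding_plan = binding_plan(ev), n_frames = 10)
  tb <- binding_probability_table(tr, contact_criterion(), 46, all_species,
                                  shared_pairs = list(c(46, 58)))
  f <- tempfile(fileext = ".csv")
  write_contact_table(tb, f, seed = 1)
  back <- read_table_artifact(f)$data
  expect_equal(back$pct_bound, 30)
  expect_true(file.exists(sub("\\.csv$", "_shared.csv", f)))
})
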