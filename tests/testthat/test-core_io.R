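test_that("read_structure builds charged structures from PDB + charge table", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  NH1 ARG A  12      10.000  11.000  12.000  1.00  0.00           N",
    "ATOM      2  NH2 ARG A  12      10.500  11.500  12.500  1.00  0.00           N",
    "ATOM      3  CA  GLY A  13       1.000   2.000   3.000  1.00  0.00           C",
    "END"), pdb)
  tab <- data.frame(residue_name = "ARG", atom_name = c("NH1", "NH2"),
                    charge = 0.33)
  x <- read_structure(pdb, charges = tab)
  expect_equal(nrow(x$atoms), 3)
  expect_equal(x$atoms$charge, c(0.33, 0.33, 0))
  expect_equal(x$atoms$residue_id, c(12L, 12L, 13L))
  # strict mode errors on uncovered atoms
  expect_error(read_structure(pdb, charges = tab, strict = TRUE), "strict")
  # segment labels propagate from residue-range config
  y <- read_structure(pdb, segments = list(cterm_helix = "12-12"))
  expect_equal(y$atoms$segment, c("cterm_helix", "cterm_helix", "other"))
})

test_that("malformed PDB records error with the line number", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A  13       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  14       xxxxx   2.000   3.000  1.00  0.00           C"),
    pdb)
  expect_error(read_structure(pdb), "line 2")
})

test_that("structure writer/reader round-trips coordinates to PDB precision", {
  for (seed in 1:100) {
    x <- random_structure(seed, n = 12)
    f <- tempfile(fileext = ".pdb")
    write_structure(x, f)
    y <- read_structure(f)
    expect_lt(max(abs(as.matrix(x) - as.matrix(y))), 1e-3 + 1e-12)
  }
})

test_that("default charge rule places unit charges on ionizable sidechains", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CZ  ARG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  NZ  LYS A   2       5.000   0.000   0.000  1.00  0.00           N",
    "ATOM      3  OD1 ASP A   3      10.000   0.000   0.000  1.00  0.00           O",
    "ATOM      4  OD2 ASP A   3      11.000   0.000   0.000  1.00  0.00           O",
    "ATOM      5  ND1 HIS A   4      15.000   0.000   0.000  1.00  0.00           N"),
    pdb)
  x <- read_structure(pdb)
  expect_equal(sum(x$atoms$charge), 1)  # +1 +1 -1 +0
  expect_equal(x$atoms$charge[5], 0)    # His neutral
})

test_that("trajectory reader handles multi-model PDB, stride and errors", {
  bp <- make_bead_protein()
  mem <- make_bilayer(100, seed = 1)
  tr <- make_trajectory(bp, mem, data.frame(tilt = rep(20, 5), rotation = rep(5, 5)),
                        n_frames = 5)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(tr$topology, f, stride_ns = 0.1)
  expect_equal(n_frames(tr2), 5)
  expect_equal(tr2$times, c(0, 0.1, 0.2, 0.3, 0.4))
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-3 + 1e-12)
  # zero-frame file errors
  f0 <- tempfile(fileext = ".pdb")
  writeLines("END", f0)
  expect_error(read_trajectory(tr$topology, f0), "zero frames")
  # atom-count mismatch errors with the frame index
  lines <- readLines(f)
  drop <- which(grepl("^ATOM", lines))[nrow(tr$topology$atoms) + 3]
  writeLines(lines[-drop], f0)
  expect_error(read_trajectory(tr$topology, f0), "frame 2")
})

test_that("trajectory invariants are enforced", {
  bp <- make_bead_protein()
  co <- array(0, dim = c(nrow(bp$atoms), 3, 2))
  expect_error(mf_trajectory(bp, co, times = c(1, 1)), "strictly increasing")
  expect_error(mf_trajectory(bp, co[-1, , , drop = FALSE], times = c(1, 2)),
               "atom count")
})

test_that("configuration loads, validates and round-trips", {
  f <- tempfile(fileext = ".yaml")
  writeLines(character(0), f)
  cfg <- load_config(f)                      # empty file -> full defaults
  expect_s3_class(cfg, "memfield_config")
  expect_equal(cfg$box_edge_A, 256)
  expect_equal(cfg$ionic_strength_M, 0.15)
  writeLines("ionic_strength_M: -1", f)
  expect_error(load_config(f), "out of range")
  writeLines("no_such_key: 3", f)
  expect_error(load_config(f), "unknown configuration key")
  # dump(load(x)) == normalize(x)
  writeLines(c("# comment", "grid_points: 48", 'time_unit: "min"'), f)
  cfg <- load_config(f)
  f2 <- tempfile(); f3 <- tempfile()
  dump_config(cfg, f2)
  dump_config(load_config(f2), f3)
  expect_identical(readLines(f2), readLines(f3))
  expect_equal(load_config(f2)$grid_points, 48)
})

test_that("table artifacts round-trip losslessly with provenance", {
  df <- data.frame(x = c(pi, exp(1), 1 / 3), n = c(1L, 2L, 3L),
                   s = c("a", "b", "c"), b = c(TRUE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_table_artifact(table_artifact(df, command = "test", seed = 11), f)
  art <- read_table_artifact(f)
  expect_identical(art$data$x, df$x)   # full double precision
  expect_identical(art$data$n, df$n)
  expect_identical(art$data$s, df$s)
  expect_identical(art$data$b, df$b)
  expect_equal(art$provenance$command, "test")
  expect_equal(art$provenance$seed, "11")
  # identical config+seed reruns are byte-identical
  f2 <- tempfile(fileext = ".csv")
  cfg <- memfield_config()
  write_table_artifact(table_artifact(df, command = "t", seed = 1, config = cfg), f)
  write_table_artifact(table_artifact(df, command = "t", seed = 1, config = cfg), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("CLI runs synth -> kinetics fit -> fold change end to end", {
  td <- file.path(tempdir(), "cli_test")
  expect_equal(memfield_cli(c("synth", "fret", "--seed", "3", "--k", "0.6087",
                              "--out-dir", td)), 0L)
  expect_equal(memfield_cli(c("kinetics", "fit", "--trace",
                              file.path(td, "fret.csv"), "--dhe-um", "23",
                              "--stard4-um", "1", "--out-dir", td)), 0L)
  j <- jsonlite::read_json(file.path(td, "fit.json"))
  expect_equal(j$rate$molecules_per_stard4_per_min, 7.00005, tolerance = 1e-6)
  expect_true(!is.null(j$provenance$config_hash))
  # bilayer synth writes one row per site
  expect_equal(memfield_cli(c("synth", "bilayer", "--seed", "5",
                              "--out-dir", td)), 0L)
  b <- read_table_artifact(file.path(td, "bilayer.csv"))
  expect_equal(nrow(b$data), 200)
  expect_equal(sum(b$data$species == "POPS"), 20)
})

test_that("CLI analyze orientation recovers a planted peak", {
  td <- file.path(tempdir(), "cli_an")
  dir.create(td, showWarnings = FALSE)
  bp <- make_bead_protein()
  mem <- make_bilayer(100, seed = 2)
  tr <- make_trajectory(bp, mem, data.frame(tilt = rep(45, 6), rotation = rep(30, 6)),
                        n_frames = 6)
  write_structure(trajectory_frame(tr, 1), file.path(td, "top.pdb"))
  write_trajectory(tr, file.path(td, "traj.pdb"))
  # segments come from the config (residue ranges of the bead protein)
  cfgf <- file.path(td, "cfg.yaml")
  writeLines(c("cterm_helix_range: 203-224", "omega1_loop_range: 90-94"), cfgf)
  expect_equal(memfield_cli(c("analyze", "orientation", "--top",
                              file.path(td, "top.pdb"), "--traj",
                              file.path(td, "traj.pdb"), "--config", cfgf,
                              "--out-dir", td)), 0L)
  m <- read_table_artifact(file.path(td, "orientation.csv"))$data
  expect_equal(sum(m$probability), 1, tolerance = 1e-12)
  peak <- m[which.max(m$probability), ]
  expect_equal(peak$probability, 1)
  expect_lt(abs(peak$tilt_mid - 45), 5 + 1e-9)
  expect_lt(abs(peak$rotation_mid - 30), 10 + 1e-9)
})
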