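test_that("read_pdb echoes fields of a hand-written file and flags HETATM", {
  txt <- c(
    "ATOM      1  N   ALA A   1      11.104  13.207   2.100  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      12.560  13.300   2.000  0.50 30.50           C",
    "HETATM    3 NI    NI A 301       1.000   2.000   3.000  1.00 50.00          NI")
  f <- withr::local_tempfile(lines = txt, fileext = ".pdb")
  s <- read_pdb(f)
  expect_s3_class(s, "Structure")
  expect_equal(n_atoms(s), 3L)
  expect_equal(s$atoms$x, c(11.104, 12.560, 1.000))
  expect_equal(s$atoms$b, c(20, 30.5, 50))
  expect_equal(s$atoms$occ, c(1, 0.5, 1))
  expect_equal(s$atoms$atom, c("N", "CA", "NI"))
  expect_equal(s$atoms$het, c(FALSE, FALSE, TRUE))
  expect_equal(s$atoms$element, c("N", "C", "NI"))

  expect_error(read_pdb(withr::local_tempfile(lines = "REMARK none")),
               "zero atoms")
  bad <- sub("11.104", "xx.xxx", txt[1])
  expect_error(read_pdb(withr::local_tempfile(lines = bad, fileext = ".pdb")),
               "line 1")
})

test_that("multi-MODEL files come back as ensembles", {
  block <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00 10.00           C")
  block2 <- sub("0.000   0.000   0.000", "9.000   0.000   0.000", block)
  f <- withr::local_tempfile(
    lines = c("MODEL        1", block, "ENDMDL",
              "MODEL        2", block2, "ENDMDL", "END"), fileext = ".pdb")
  e <- read_pdb(f)
  expect_s3_class(e, "Ensemble")
  expect_length(e$frames, 2L)
  expect_equal(e$frames[[2]][1, 1], 9)
  expect_equal(e$frames[[1]][1, 1], 0)
})

test_that("altloc policies resolve duplicates as documented", {
  txt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CB ALA  A   1       2.000   0.000   0.000  1.00 10.00           C")
  txt[3] <- "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00 10.00           C"
  f <- withr::local_tempfile(lines = txt, fileext = ".pdb")
  hi <- read_pdb(f, "highest-occupancy")
  expect_equal(n_atoms(hi), 2L)
  expect_equal(hi$atoms$altloc[hi$atoms$atom == "CA"], "A")
  expect_equal(n_atoms(read_pdb(f, "keep-all")), 3L)
  only_b <- read_pdb(f, "B")
  expect_equal(only_b$atoms$altloc[only_b$atoms$atom == "CA"], "B")
  # occupancy tie: label order breaks it, 'A' first
  tie <- sub("0.40", "0.60", txt)
  ft <- withr::local_tempfile(lines = tie, fileext = ".pdb")
  expect_equal(read_pdb(ft)$atoms$altloc[1], "A")
})

test_that("write/read round trip preserves coordinates and identities", {
  h <- make_helix(12, sequence = c("ALA", "GLY", "LYS"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  h2 <- read_pdb(f)
  # exact at the PDB field precision of 3 decimals
  expect_equal(coords(h2), round(coords(h), 3), tolerance = 1e-12)
  expect_equal(h2$atoms$resname, h$atoms$resname)
  expect_equal(h2$atoms$atom, h$atoms$atom)
  expect_equal(h2$atoms$resseq, h$atoms$resseq)
  # ensemble round trip
  me <- make_mode_ensemble(make_helix(20), mode_index = 7, n_frames = 3,
                           seed = 4, cutoff = 12)
  fe <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(me$ensemble, fe)
  e2 <- read_pdb(fe)
  expect_length(e2$frames, 3L)
  expect_equal(e2$frames[[2]], round(unname(me$ensemble$frames[[2]]), 3),
               tolerance = 1e-12)
})

test_that("kabsch recovers exact transforms and refuses degenerate input", {
  set.seed(7)
  P <- matrix(rnorm(30), 10)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(P, P)$rotation, diag(3), tolerance = 1e-9)

  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  f <- kabsch_superpose(P, P %*% Rz)
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  expect_equal(f$rotation, Rz, tolerance = 1e-9)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "3 points")
  expect_error(kabsch_superpose(P, P[1:5, ]), "mismatch")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line[5:1, ]), "collinear")
})

test_that("kabsch matches a brute-force rotation-search oracle", {
  set.seed(11)
  for (rep in 1:3) {
    P <- matrix(rnorm(30), 10); Q <- matrix(rnorm(30), 10)
    expect_equal(kabsch_superpose(P, Q)$rmsd, brute_force_rmsd(P, Q),
                 tolerance = 1e-8)
  }
})

test_that("kabsch rmsd is rigid-invariant with proper rotations only", {
  set.seed(21)
  P <- matrix(rnorm(45), 15); Q <- matrix(rnorm(45), 15)
  base <- kabsch_superpose(P, Q)$rmsd
  for (rep in 1:20) {
    R <- random_rotation(); t <- rnorm(3, 0, 5)
    f <- kabsch_superpose(sweep(P %*% R, 2, t, `+`), Q)
    expect_equal(f$rmsd, base, tolerance = 1e-9)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  }
})

test_that("rmsd_between handles identity, translation, and mismatches", {
  h <- make_helix(15)
  expect_equal(rmsd_between(h, h), 0, tolerance = 1e-12)
  ht <- set_coords(h, sweep(coords(h), 2, c(1, 0, 0), `+`))
  expect_equal(rmsd_between(h, ht, superpose = FALSE), 1.0, tolerance = 1e-12)
  expect_equal(rmsd_between(h, ht, superpose = TRUE), 0, tolerance = 1e-9)
  # symmetry
  hr <- apply_random_rigid(h)
  expect_equal(rmsd_between(h, hr), rmsd_between(hr, h), tolerance = 1e-9)
  # unmatched atoms are loud, not silently intersected
  h_short <- subset_structure(h, sel(resseq = 1:12))
  expect_error(rmsd_between(h, h_short), "unmatched")
  expect_equal(rmsd_between(h, h_short, on_unmatched = "exclude"), 0,
               tolerance = 1e-9)
})

test_that("bfactor_stats: closed form, degenerate input, z-score invariant", {
  rows <- do.call(rbind, lapply(1:3, function(i)
    atom_row("A", i, "ALA", "CA", i, 0, 0, "C", b = c(10, 20, 30)[i])))
  s <- Structure(rows)
  st <- bfactor_stats(s)
  expect_equal(st$mean, 20)
  stn <- bfactor_stats(s, normalize = TRUE)
  expect_equal(as.numeric(stn$per_atom), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_error(bfactor_stats(subset_structure(s, sel(resseq = 1)),
                             normalize = TRUE), "zero")
  # normalized B has mean 0 and (population) sd 1 within any structure
  set.seed(3)
  h <- make_helix(20)
  h$atoms$b <- runif(n_atoms(h), 5, 80)
  z <- bfactor_stats(h, normalize = TRUE)$per_atom
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
})
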