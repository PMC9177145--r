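test_that("toy structures round-trip every descriptor exactly at zero noise", {
  m <- toy_model(d77 = 5.0, d_nterm = 2.8, d_val76 = 3.5, omega = 170,
                 psi = -40)
  expect_equal(d77_pOmega1(m), 5.0, tolerance = 1e-6)
  expect_equal(d_tyr171_nterm(m), 2.8, tolerance = 1e-6)
  expect_equal(mindist_side_chains(m), 3.5, tolerance = 1e-6)
  tor <- terminal_torsion(m)
  expect_equal(unname(tor["omega_term"]), 170, tolerance = 1e-6)
  expect_equal(unname(tor["psi_pOmega1"]), -40, tolerance = 1e-6)
})

test_that("ideal trans and cis terminal bonds give omega 180 and 0", {
  expect_equal(unname(terminal_torsion(toy_model(omega = 180))["omega_term"]),
               180, tolerance = 1e-6)
  expect_equal(unname(terminal_torsion(toy_model(omega = 0))["omega_term"]),
               0, tolerance = 1e-6)
})

test_that("10mer-bound structures are measured at p9 (pOmega-1)", {
  m <- toy_model(d77 = 4.6, peptide_length = 10)
  expect_identical(length(m$pep_resnos), 10L)
  expect_equal(d77_pOmega1(m), 4.6, tolerance = 1e-6)
  expect_equal(mindist_side_chains(m), 3.5, tolerance = 1e-6)
})

test_that("PDB-format fixtures round-trip to coordinate precision", {
  m <- toy_model(d77 = 5.0, d_nterm = 2.8, ext = ".pdb")
  expect_equal(d77_pOmega1(m), 5.0, tolerance = 2e-3)
  expect_equal(d_tyr171_nterm(m), 2.8, tolerance = 2e-3)
})

test_that("the dihedral matches an analytic 60-degree construction and bio3d", {
  # four points engineered for a +60 dihedral about the x-axis
  a <- c(0, 1, 0); b <- c(0, 0, 0); c3 <- c(1, 0, 0)
  d <- c(1, cos(pi / 3), sin(pi / 3))
  expect_equal(dihedral_angle(a, b, c3, d), 60, tolerance = 1e-6)
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- matrix(rnorm(12), 4, byrow = TRUE)
      mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
      ref <- bio3d::torsion.xyz(as.vector(t(p)))
      expect_equal(abs(mine), abs(as.numeric(ref)), tolerance = 1e-6)
    }
  })
})

test_that("side-chain minimum distance excludes backbone atoms", {
  # decoy: backbone pair at 3.0 A, closest true side-chain pair at 3.5 A
  atoms <- rbind(
    atom_row("P", 8, "N", "SER", 0, 3.0, 0),     # backbone decoy
    atom_row("P", 8, "CA", "SER", 1, 3.0, 0),
    atom_row("P", 8, "CB", "SER", 0, 0, 0),
    atom_row("P", 8, "OG", "SER", 0, -1.4, 0),
    atom_row("P", 9, "CA", "ALA", 5, 3.0, 0),
    atom_row("A", 76, "N", "VAL", 0, 6.0, 0),    # backbone decoy partner
    atom_row("A", 76, "CA", "VAL", 1, 6.0, 0),
    atom_row("A", 76, "CB", "VAL", 0, 3.5, 0),
    atom_row("A", 76, "CG1", "VAL", 0, 5.0, 0))
  m <- fake_model(atoms)
  expect_equal(mindist_side_chains(m, pep_resno = 8), 3.5, tolerance = 1e-9)
})

test_that("side-chain minimum equals the brute-force all-pairs minimum", {
  withr::with_seed(13, {
    for (i in 1:10) {
      pa <- matrix(rnorm(15, sd = 3), 5)
      pb <- matrix(rnorm(15, mean = 4, sd = 3), 5)
      atoms <- rbind(
        do.call(rbind, lapply(1:5, function(j)
          atom_row("P", 8, c("CB", "CG", "CD", "CE", "CZ")[j], "LYS",
                   pa[j, 1], pa[j, 2], pa[j, 3]))),
        atom_row("P", 9, "CA", "ALA", 20, 0, 0),
        do.call(rbind, lapply(1:5, function(j)
          atom_row("A", 76, c("CB", "CG1", "CG2", "CD1", "CD2")[j], "ILE",
                   pb[j, 1], pb[j, 2], pb[j, 3]))))
      brute <- min(as.matrix(stats::dist(rbind(pa, pb)))[1:5, 6:10])
      expect_equal(mindist_side_chains(fake_model(atoms), pep_resno = 8),
                   brute, tolerance = 1e-12)
    }
  })
})

test_that("glycine at a contact position is reported as undefined", {
  atoms <- rbind(atom_row("P", 8, "N", "GLY", 0, 1, 0),
                 atom_row("P", 8, "CA", "GLY", 0, 0, 0),
                 atom_row("P", 9, "CA", "ALA", 4, 0, 0),
                 atom_row("A", 76, "CB", "VAL", 0, 4, 0))
  expect_error(mindist_side_chains(fake_model(atoms), pep_resno = 8),
               "no side chain")
})

test_that("all descriptors are invariant under rigid-body transforms", {
  m <- toy_model(d77 = 4.7, d_nterm = 2.7, d_val76 = 3.6, omega = 165,
                 psi = -35)
  ref <- c(d77_pOmega1(m), d_tyr171_nterm(m), mindist_side_chains(m),
           terminal_torsion(m))
  for (seed in 1:5) {
    R <- random_rotation(seed)
    t <- withr::with_seed(seed + 100, rnorm(3, sd = 50))
    mt <- transform_model(m, R, t)
    got <- c(d77_pOmega1(mt), d_tyr171_nterm(mt), mindist_side_chains(mt),
             terminal_torsion(mt))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("mirror reflection flips dihedral signs and preserves magnitude", {
  m <- toy_model(omega = 150, psi = -40)
  ref <- terminal_torsion(m)
  mm <- m
  mm$atoms$x <- -mm$atoms$x
  got <- terminal_torsion(mm)
  expect_equal(unname(got), unname(-ref), tolerance = 1e-9)
  expect_equal(abs(unname(got)), abs(unname(ref)), tolerance = 1e-9)
})

test_that("chain auto-detection agrees with explicit ids and flags ties", {
  f <- tempfile(fileext = ".cif")
  build_toy_structure(toy_structure_spec(heavy_length = 180L), f)
  auto <- suppressMessages(load_structure(f))
  explicit <- suppressMessages(load_structure(f, heavy_chain = "A",
                                              peptide_chain = "P"))
  expect_identical(auto$heavy_chain, "A")
  expect_identical(auto$peptide_chain, "P")
  expect_equal(d77_pOmega1(auto), d77_pOmega1(explicit))

  # duplicate the peptide chain under a new id: ambiguity must be an error
  fp <- tempfile(fileext = ".pdb")
  build_toy_structure(toy_structure_spec(heavy_length = 180L), fp)
  lines <- readLines(fp)
  pep <- grepl("^ATOM", lines) & substr(lines, 22, 22) == "P"
  dup <- lines[pep]
  substr(dup, 22, 22) <- "Q"
  writeLines(c(lines[lines != "END"], dup, "END"), fp)
  expect_error(suppressWarnings(suppressMessages(load_structure(fp))),
               "equally short")
})

test_that("missing atoms and a non-Tyr 171 produce named errors", {
  f <- tempfile(fileext = ".pdb")
  build_toy_structure(toy_structure_spec(heavy_length = 180L), f)
  lines <- readLines(f)
  noCB <- lines[!(grepl("^ATOM", lines) & substr(lines, 14, 16) == "CB " &
                    substr(lines, 22, 22) == "A" &
                    trimws(substr(lines, 23, 26)) == "77")]
  f2 <- write_tmp_lines(noCB, ".pdb")
  m2 <- suppressMessages(load_structure(f2))
  expect_error(d77_pOmega1(m2), "CB")

  swapped <- sub("TYR A 171", "PHE A 171", lines)
  f3 <- write_tmp_lines(swapped, ".pdb")
  m3 <- suppressMessages(load_structure(f3))
  expect_error(d_tyr171_nterm(m3), "not Tyr")
})

test_that("group statistics recover the generating means with Welch separation", {
  withr::with_seed(55, {
    t1 <- rnorm(5, 4.6, 0.1)
    t2 <- rnorm(7, 5.7, 0.2)
  })
  records <- do.call(rbind, c(
    lapply(t1, function(d) measure_groove_geometry(
      toy_model(d77 = round(d, 3), group = "C1"))),
    lapply(t2, function(d) measure_groove_geometry(
      toy_model(d77 = round(d, 3), group = "C2")))))
  stats <- group_geometry_stats(records, descriptors = "d77_pOmega1")
  expect_lt(abs(stats$mean_c1 - 4.6), 3 * 0.1 / sqrt(5))
  expect_lt(abs(stats$mean_c2 - 5.7), 3 * 0.2 / sqrt(7))
  expect_lt(stats$p_welch, 0.001)
  ref <- stats::t.test(round(t1, 3), round(t2, 3))
  expect_equal(stats$p_welch, ref$p.value, tolerance = 1e-6)
})

test_that("degenerate and undersized geometry panels are rejected", {
  rec <- function(g, v) data.frame(id = "x", group = g, d77_pOmega1 = v)
  const <- rbind(rec("C1", 1), rec("C1", 1), rec("C2", 1), rec("C2", 1))
  expect_error(group_geometry_stats(const, "d77_pOmega1"), "constant")
  small <- rbind(rec("C1", 1), rec("C2", 1), rec("C2", 2))
  expect_error(group_geometry_stats(small, "d77_pOmega1"), "fewer than 2")
})
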