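# Toy peptide-MHC coordinate fixtures.
#
# The heavy chain is a geometric stub, not a folded MHC model: only the
# atoms the groove descriptors touch (Val76, Ser77 and Tyr171 side chains,
# the peptide terminus) are placed meaningfully; the remaining backbone sits
# on a non-clashing lattice far from the peptide. Descriptor tests need
# geometry, not physics.

#' Specification for a toy peptide-MHC structure
#'
#' Target values for the four groove descriptors, realised exactly (at zero
#' noise) by analytic atom placement.
#'
#' @param d77 Target residue-77 Cbeta to pOmega-1 Calpha distance (angstrom).
#' @param d_nterm Target Tyr171 OH to peptide p1 N distance (angstrom).
#' @param d_val76 Target minimum side-chain distance pOmega-1/Val76
#'   (angstrom).
#' @param omega Target terminal peptide-bond torsion (degrees, (-180, 180]).
#' @param psi Target auxiliary psi(pOmega-1) (degrees).
#' @param peptide_length Peptide residues (8-11).
#' @param heavy_length Heavy-chain residues (default 278).
#' @param noise_sd Isotropic Gaussian displacement applied to every atom
#'   (angstrom); 0 gives exact targets.
#' @param seed Seed for the noise draws.
#' @return List of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(d77 = 5.0, d_nterm = 2.8, d_val76 = 3.5,
                               omega = 180, psi = -40,
                               peptide_length = 9L, heavy_length = 278L,
                               noise_sd = 0, seed = NULL) {
  stopifnot(d77 > 0, d_nterm > 0, d_val76 > 0,
            omega > -180, omega <= 180, psi > -180, psi <= 180,
            peptide_length >= 8L, peptide_length <= 11L,
            heavy_length >= 180L, noise_sd >= 0)
  structure(list(d77 = d77, d_nterm = d_nterm, d_val76 = d_val76,
                 omega = omega, psi = psi,
                 peptide_length = as.integer(peptide_length),
                 heavy_length = as.integer(heavy_length),
                 noise_sd = noise_sd, seed = seed),
            class = "toy_structure_spec")
}

#' Write a toy peptide-MHC coordinate file
#'
#' Builds a PDB file with a heavy-chain stub (chain A, residues 1 to
#' `heavy_length`, full side chains at Val76, Ser77 and Tyr171) and a bound
#' peptide (chain P), positioned so that each groove descriptor equals its
#' target exactly at zero noise.
#'
#' Coordinates are written in PDB format (3-decimal coordinate fields) or,
#' when `path` ends in `.cif`, as mmCIF with full floating-point precision —
#' the format to use when descriptors must round-trip to 1e-6.
#'
#' @param spec A [toy_structure_spec()].
#' @param path Output path (`.pdb` or `.cif`).
#' @return `path`, invisibly.
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".pdb")
#' build_toy_structure(toy_structure_spec(d77 = 4.7), f)
#' m <- load_structure(f, group = "C1")
#' d77_pOmega1(m)  # 4.7
#' }
#' @export
build_toy_structure <- function(spec, path) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  L <- spec$peptide_length
  atoms <- list()
  add <- function(chain, resno, resname, name, xyz) {
    atoms[[length(atoms) + 1L]] <<- list(chain = chain, resno = resno,
                                         resname = resname, name = name,
                                         xyz = xyz)
  }

  ## peptide chain P: residues 1..L-2 glycine backbone along -x,
  ## residue L-1 serine and residue L alanine built with exact torsions
  ca <- function(i) c((i - (L - 1)) * 3.8, 0, 0)
  for (i in seq_len(L - 2L)) {
    add("P", i, "GLY", "N", ca(i) + c(-0.53, 1.36, 0))
    add("P", i, "GLY", "CA", ca(i))
    add("P", i, "GLY", "C", ca(i) + c(1.52, 0, 0))
    add("P", i, "GLY", "O", ca(i) + c(2.05, 1.05, 0))
  }
  nL1 <- ca(L - 1L) + c(-0.53, 1.36, 0)
  caL1 <- ca(L - 1L)
  cPrev <- ca(L - 2L) + c(1.52, 0, 0)
  cL1 <- place_dihedral(cPrev, nL1, caL1, 1.52, 111, -60)
  nL <- place_dihedral(nL1, caL1, cL1, 1.33, 116, spec$psi)
  oL1 <- place_dihedral(nL1, caL1, cL1, 1.23, 121, spec$psi - 180)
  caL <- place_dihedral(caL1, cL1, nL, 1.46, 122, spec$omega)
  cL <- place_dihedral(cL1, nL, caL, 1.52, 110, -120)
  oL <- place_dihedral(nL, caL, cL, 1.23, 121, 60)
  oxt <- place_dihedral(nL, caL, cL, 1.25, 118, -120)
  cbL <- place_dihedral(nL, caL, cL, 1.53, 110, 122)

  # pOmega-1 serine side chain: CB from backbone, OG perpendicular to the
  # CA->CB axis so the Val76 contact below is realised at CB exactly
  cbL1 <- place_dihedral(cL1, nL1, caL1, 1.53, 110, 122)
  u <- cbL1 - caL1
  u <- u / sqrt(sum(u^2))
  w <- cross3(u, c(1, 0, 0))
  if (sqrt(sum(w^2)) < 1e-6) w <- cross3(u, c(0, 1, 0))
  w <- w / sqrt(sum(w^2))
  ogL1 <- cbL1 + 1.41 * w

  add("P", L - 1L, "SER", "N", nL1)
  add("P", L - 1L, "SER", "CA", caL1)
  add("P", L - 1L, "SER", "C", cL1)
  add("P", L - 1L, "SER", "O", oL1)
  add("P", L - 1L, "SER", "CB", cbL1)
  add("P", L - 1L, "SER", "OG", ogL1)
  add("P", L, "ALA", "N", nL)
  add("P", L, "ALA", "CA", caL)
  add("P", L, "ALA", "C", cL)
  add("P", L, "ALA", "O", oL)
  add("P", L, "ALA", "CB", cbL)
  add("P", L, "ALA", "OXT", oxt)

  ## heavy chain A
  # Ser77: CB exactly d77 from CA(pOmega-1), stub backbone hanging below
  cb77 <- caL1 + c(0, 0, -spec$d77)
  ca77 <- cb77 + c(0, -1.54, 0)
  add("A", 77L, "SER", "N", ca77 + c(-1.20, -0.80, 0))
  add("A", 77L, "SER", "CA", ca77)
  add("A", 77L, "SER", "C", ca77 + c(1.30, -0.80, 0))
  add("A", 77L, "SER", "O", ca77 + c(1.30, -2.03, 0))
  add("A", 77L, "SER", "CB", cb77)
  add("A", 77L, "SER", "OG", cb77 + c(0, 1.00, -1.00))

  # Val76: CG1 exactly d_val76 from CB(pOmega-1) along +u; every other
  # side-chain atom placed strictly further so CG1/CB is the minimum pair
  cg1 <- cbL1 + spec$d_val76 * u
  cb76 <- cg1 + 1.54 * u
  cg2 <- cb76 + 1.54 * w
  ca76 <- cb76 + 1.54 * u + 1.0 * w
  add("A", 76L, "VAL", "N", ca76 + 1.46 * u)
  add("A", 76L, "VAL", "CA", ca76)
  add("A", 76L, "VAL", "C", ca76 + 1.52 * u + 0.8 * w)
  add("A", 76L, "VAL", "O", ca76 + 1.52 * u + 2.0 * w)
  add("A", 76L, "VAL", "CB", cb76)
  add("A", 76L, "VAL", "CG1", cg1)
  add("A", 76L, "VAL", "CG2", cg2)

  # Tyr171: OH exactly d_nterm from the peptide p1 backbone N
  n1 <- ca(1L) + c(-0.53, 1.36, 0)
  oh <- n1 + c(0, spec$d_nterm, 0)
  cz <- oh + c(0, 1.38, 0)
  ring <- function(dx, dy) cz + c(dx, dy, 0)
  ca171 <- cz + c(0, 5.9, 0)
  add("A", 171L, "TYR", "N", ca171 + c(-1.20, 0.80, 0))
  add("A", 171L, "TYR", "CA", ca171)
  add("A", 171L, "TYR", "C", ca171 + c(1.30, 0.80, 0))
  add("A", 171L, "TYR", "O", ca171 + c(1.30, 2.03, 0))
  add("A", 171L, "TYR", "CB", ca171 + c(0, -1.53, 0))
  add("A", 171L, "TYR", "CG", cz + c(0, 2.80, 0))
  add("A", 171L, "TYR", "CD1", ring(-1.20, 2.10))
  add("A", 171L, "TYR", "CD2", ring(1.20, 2.10))
  add("A", 171L, "TYR", "CE1", ring(-1.20, 0.70))
  add("A", 171L, "TYR", "CE2", ring(1.20, 0.70))
  add("A", 171L, "TYR", "CZ", cz)
  add("A", 171L, "TYR", "OH", oh)

  # remaining heavy-chain residues: glycine backbone on a lattice well away
  # from the peptide and the placed side chains
  rest <- setdiff(seq_len(spec$heavy_length), c(76L, 77L, 171L))
  for (r in rest) {
    base <- c((r %% 20L) * 4 - 40, (r %/% 20L) * 4 + 15, 18)
    add("A", r, "GLY", "N", base + c(-0.53, 1.36, 0))
    add("A", r, "GLY", "CA", base)
    add("A", r, "GLY", "C", base + c(1.52, 0, 0))
    add("A", r, "GLY", "O", base + c(2.05, 1.05, 0))
  }

  xyz <- do.call(rbind, lapply(atoms, `[[`, "xyz"))
  if (spec$noise_sd > 0) {
    noise <- function() matrix(stats::rnorm(length(xyz), sd = spec$noise_sd),
                               ncol = 3)
    xyz <- xyz + if (is.null(spec$seed)) noise() else
      withr::with_seed(spec$seed, noise())
  }

  as_cif <- tolower(tools::file_ext(path)) == "cif"
  lines <- if (as_cif) cif_lines(atoms, xyz) else pdb_lines(atoms, xyz)
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write toy structure to ", path, call. = FALSE)
  invisible(path)
}

pdb_lines <- function(atoms, xyz) {
  body <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    el <- substr(gsub("[0-9]", "", a$name), 1, 1)
    sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, sprintf(" %-3s", a$name), a$resname, a$chain, a$resno,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.00, 0.00, el)
  }, character(1))
  c(body, "END")
}

cif_lines <- function(atoms, xyz) {
  header <- c(
    "data_toy", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                            "label_alt_id", "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "pdbx_formal_charge", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id", "auth_atom_id",
                            "pdbx_PDB_model_num")))
  body <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    el <- substr(gsub("[0-9]", "", a$name), 1, 1)
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.9f %.9f %.9f 1.00 0.00 ? %d %s %s %s 1",
            i, el, a$name, a$resname, a$chain, a$resno,
            xyz[i, 1], xyz[i, 2], xyz[i, 3],
            a$resno, a$resname, a$chain, a$name)
  }, character(1))
  c(header, body)
}
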