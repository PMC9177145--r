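#' Load a peptide-MHC structure for groove-geometry analysis
#'
#' Reads a PDB or mmCIF coordinate file (via bio3d), keeps the first model,
#' removes hydrogens, resolves alternate locations to the
#' highest-occupancy conformer (ties broken by altloc letter), and
#' identifies the MHC heavy chain and the bound peptide chain. When chain
#' ids are not supplied, the peptide chain is auto-detected as the shortest
#' polypeptide chain of 8-11 residues and the heavy chain as a long chain
#' (>= 100 residues) containing residues 76, 77 and 171 in author
#' numbering, preferring one with Tyr at 171 (conserved in the class I
#' fold); detection is logged.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param heavy_chain,peptide_chain Optional explicit chain ids.
#' @param group Optional C1/C2 group label carried into downstream tables.
#' @param id Structure identifier (defaults to the file name).
#' @param offset Integer added to the canonical heavy-chain residue numbers
#'   (76/77/171) for files whose author numbering is shifted.
#' @return Object of class `groove_structure`.
#' @export
load_structure <- function(path, heavy_chain = NULL, peptide_chain = NULL,
                           group = NA_character_, id = NULL, offset = 0L) {
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") suppressWarnings(bio3d::read.cif(path)) else
    bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # drop hydrogens/deuteriums
  ele <- at$elesy
  hy <- (!is.na(ele) & ele %in% c("H", "D")) |
    (is.na(ele) & grepl("^[0-9]*[HD]", at$elety))
  at <- at[!hy, , drop = FALSE]
  # altloc: keep highest-occupancy conformer per atom, ties -> first letter
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt) | at$alt == "", " ", at$alt)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  res77 <- 77L + offset
  chain_len <- vapply(split(at$resno, at$chain),
                      function(r) length(unique(r)), integer(1))

  if (is.null(peptide_chain)) {
    cand <- names(chain_len)[chain_len >= 8 & chain_len <= 11]
    if (!length(cand)) {
      stop("no candidate peptide chain (8-11 residues) found in ", path,
           call. = FALSE)
    }
    shortest <- cand[chain_len[cand] == min(chain_len[cand])]
    if (length(shortest) > 1L) {
      stop("multiple equally short peptide-chain candidates (",
           paste(shortest, collapse = ", "),
           "); supply peptide_chain explicitly", call. = FALSE)
    }
    peptide_chain <- shortest
  }
  if (is.null(heavy_chain)) {
    need <- c(76L, 77L, 171L) + offset
    cand <- names(chain_len)[vapply(names(chain_len), function(ch) {
      r <- unique(at$resno[at$chain == ch])
      chain_len[ch] >= 100 && all(need %in% r) && ch != peptide_chain
    }, logical(1))]
    if (!length(cand)) {
      stop("no heavy-chain candidate containing residues 76/77/171 in ", path,
           call. = FALSE)
    }
    if (length(cand) > 1L) {
      tyr <- cand[vapply(cand, function(ch) {
        any(at$chain == ch & at$resno == 171L + offset & at$resid == "TYR")
      }, logical(1))]
      if (length(tyr) == 1L) cand <- tyr
      else stop("ambiguous heavy-chain candidates (",
                paste(cand, collapse = ", "),
                "); supply heavy_chain explicitly", call. = FALSE)
    }
    heavy_chain <- cand
  }
  message(sprintf("structure %s: heavy chain %s (%d residues), peptide chain %s (%d residues)",
                  id %||% basename(path), heavy_chain, chain_len[heavy_chain],
                  peptide_chain, chain_len[peptide_chain]))
  structure(list(id = id %||% sub("\\.[^.]*$", "", basename(path)),
                 atoms = at,
                 heavy_chain = heavy_chain,
                 peptide_chain = peptide_chain,
                 pep_resnos = sort(unique(at$resno[at$chain == peptide_chain])),
                 group = group,
                 offset = as.integer(offset)),
            class = "groove_structure")
}

#' @export
print.groove_structure <- function(x, ...) {
  cat(sprintf("<groove_structure %s: heavy %s, peptide %s (%d residues), group %s>\n",
              x$id, x$heavy_chain, x$peptide_chain, length(x$pep_resnos),
              x$group))
  invisible(x)
}

get_atom_xyz <- function(model, chain, resno, elety) {
  i <- which(model$atoms$chain == chain & model$atoms$resno == resno &
               model$atoms$elety == elety)
  if (length(i) != 1L) {
    stop(sprintf("atom %s not found (or not unique) in residue %d of chain %s",
                 elety, resno, chain), call. = FALSE)
  }
  as.numeric(model$atoms[i, c("x", "y", "z")])
}

get_residue <- function(model, chain, resno) {
  model$atoms[model$atoms$chain == chain & model$atoms$resno == resno, ,
              drop = FALSE]
}

pep_pos_resno <- function(model, from_end) {
  r <- model$pep_resnos
  if (length(r) < 2L) stop("peptide chain has fewer than 2 residues", call. = FALSE)
  r[length(r) - from_end]
}

#' Distance from heavy-chain residue 77 Cbeta to the peptide pOmega-1 Calpha
#'
#' The groove-displacement descriptor: Euclidean distance between the first
#' side-chain carbon (Cbeta) of the dimorphic residue 77 and the backbone
#' Calpha of the penultimate peptide residue (p8 of a 9mer, p9 of a 10mer).
#' Larger values indicate the pOmega-1 backbone is lifted out of the groove.
#'
#' @param model A [load_structure()] result.
#' @return Distance in angstroms.
#' @export
d77_pOmega1 <- function(model) {
  stopifnot(inherits(model, "groove_structure"))
  cb <- get_atom_xyz(model, model$heavy_chain, 77L + model$offset, "CB")
  ca <- get_atom_xyz(model, model$peptide_chain, pep_pos_resno(model, 1L), "CA")
  vec_dist(cb, ca)
}

#' Distance from the Tyr171 hydroxyl to the peptide N-terminus
#'
#' The conserved A-pocket contact: distance between the side-chain hydroxyl
#' oxygen of heavy-chain Tyr171 (PDB atom name `OH`, the eta-hydroxyl) and
#' the backbone nitrogen of peptide residue 1. Serves as the
#' groove-anchoring control expected to be identical between C1 and C2
#' structures.
#'
#' @param model A [load_structure()] result.
#' @return Distance in angstroms.
#' @export
d_tyr171_nterm <- function(model) {
  stopifnot(inherits(model, "groove_structure"))
  r171 <- 171L + model$offset
  res <- get_residue(model, model$heavy_chain, r171)
  if (!nrow(res) || res$resid[1] != "TYR") {
    stop("heavy-chain residue 171 is not Tyr", call. = FALSE)
  }
  oh <- get_atom_xyz(model, model$heavy_chain, r171, "OH")
  n1 <- get_atom_xyz(model, model$peptide_chain, model$pep_resnos[1], "N")
  vec_dist(oh, n1)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

side_chain_xyz <- function(model, chain, resno) {
  res <- get_residue(model, chain, resno)
  res <- res[!(res$elety %in% BACKBONE_ATOMS), , drop = FALSE]
  as.matrix(res[, c("x", "y", "z")])
}

#' Minimum side-chain heavy-atom distance between pOmega-1 and residue 76
#'
#' Tests van der Waals contact between the peptide's penultimate side chain
#' and the heavy-chain Val76 side chain: the minimum over all pairs of
#' side-chain heavy atoms (Cbeta and beyond; backbone N/CA/C/O/OXT
#' excluded). Contact range is conventionally 3.3-4.0 angstroms.
#'
#' @param model A [load_structure()] result.
#' @param pep_resno Peptide residue number (default: pOmega-1).
#' @param heavy_res Heavy-chain residue number before offset (default 76).
#' @return Minimum distance in angstroms. Glycine at either position has no
#'   side chain and raises an error; callers report the descriptor as
#'   undefined.
#' @export
mindist_side_chains <- function(model, pep_resno = NULL, heavy_res = 76L) {
  stopifnot(inherits(model, "groove_structure"))
  pep_resno <- pep_resno %||% pep_pos_resno(model, 1L)
  a <- side_chain_xyz(model, model$peptide_chain, pep_resno)
  b <- side_chain_xyz(model, model$heavy_chain, heavy_res + model$offset)
  if (!nrow(a)) stop("peptide residue ", pep_resno, " has no side chain", call. = FALSE)
  if (!nrow(b)) stop("heavy-chain residue ", heavy_res, " has no side chain", call. = FALSE)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Torsion angles of the terminal peptide bond
#'
#' The orientation descriptor for the C-terminal anchor: the omega dihedral
#' of the pOmega-1 to pOmega peptide bond,
#' `Calpha(pOmega-1)-C(pOmega-1)-N(pOmega)-Calpha(pOmega)` (180 for trans, 0
#' for cis), plus the auxiliary psi of pOmega-1,
#' `N(pOmega-1)-Calpha(pOmega-1)-C(pOmega-1)-N(pOmega)`. Both signed, IUPAC
#' convention, in (-180, 180].
#'
#' @param model A [load_structure()] result.
#' @return Named numeric vector `c(omega_term, psi_pOmega1)` in degrees.
#' @export
terminal_torsion <- function(model) {
  stopifnot(inherits(model, "groove_structure"))
  rO <- pep_pos_resno(model, 0L)
  rO1 <- pep_pos_resno(model, 1L)
  ch <- model$peptide_chain
  n1 <- get_atom_xyz(model, ch, rO1, "N")
  ca1 <- get_atom_xyz(model, ch, rO1, "CA")
  c1 <- get_atom_xyz(model, ch, rO1, "C")
  n2 <- get_atom_xyz(model, ch, rO, "N")
  ca2 <- get_atom_xyz(model, ch, rO, "CA")
  c(omega_term = dihedral_angle(ca1, c1, n2, ca2),
    psi_pOmega1 = dihedral_angle(n1, ca1, c1, n2))
}

#' Measure all groove descriptors on one structure
#'
#' @param model A [load_structure()] result.
#' @return One-row data frame: `id`, `group`, `d77_pOmega1`,
#'   `d_tyr171_nterm`, `d_val76_side` (NA with a warning when pOmega-1 is
#'   glycine), `omega_term`, `psi_pOmega1`.
#' @export
measure_groove_geometry <- function(model) {
  tor <- terminal_torsion(model)
  dval <- tryCatch(mindist_side_chains(model), error = function(e) {
    warning(sprintf("structure %s: d_val76_side undefined (%s)",
                    model$id, conditionMessage(e)), call. = FALSE)
    NA_real_
  })
  data.frame(id = model$id,
             group = model$group,
             d77_pOmega1 = d77_pOmega1(model),
             d_tyr171_nterm = d_tyr171_nterm(model),
             d_val76_side = dval,
             omega_term = unname(tor["omega_term"]),
             psi_pOmega1 = unname(tor["psi_pOmega1"]),
             stringsAsFactors = FALSE)
}

#' C1-vs-C2 summary statistics over a panel of geometry records
#'
#' Per descriptor: unweighted group means, sample standard deviations and a
#' two-sided Welch t-test across structures. Records with an undefined
#' descriptor (e.g. a glycine side chain) are excluded pairwise for that
#' descriptor only, with a log message. A descriptor that is constant in
#' both groups has an undefined Welch statistic and raises an error naming
#' the descriptor.
#'
#' @param records Data frame of rows from [measure_groove_geometry()],
#'   with a `group` column over C1/C2.
#' @param descriptors Descriptor columns to summarise.
#' @return Data frame: one row per descriptor with `mean_c1`, `sd_c1`,
#'   `n_c1`, `mean_c2`, `sd_c2`, `n_c2`, `p_welch`.
#' @export
group_geometry_stats <- function(records,
                                 descriptors = c("d77_pOmega1", "d_tyr171_nterm",
                                                 "d_val76_side", "omega_term")) {
  stopifnot(is.data.frame(records), "group" %in% names(records))
  rows <- lapply(descriptors, function(d) {
    if (!d %in% names(records)) stop("descriptor column missing: ", d, call. = FALSE)
    ok <- !is.na(records[[d]])
    if (any(!ok)) {
      message(sum(!ok), " structure(s) excluded from ", d, " (undefined descriptor)")
    }
    x1 <- records[[d]][ok & records$group == "C1"]
    x2 <- records[[d]][ok & records$group == "C2"]
    if (length(x1) < 2L || length(x2) < 2L) {
      stop("fewer than 2 structures per group for descriptor ", d, call. = FALSE)
    }
    tw <- two_sample_t(x1, x2, var_equal = FALSE)
    if (is.na(tw$df) && tw$t == 0) {
      stop("descriptor ", d, " is constant in both groups: Welch p undefined",
           call. = FALSE)
    }
    data.frame(descriptor = d,
               mean_c1 = mean(x1), sd_c1 = stats::sd(x1), n_c1 = length(x1),
               mean_c2 = mean(x2), sd_c2 = stats::sd(x2), n_c2 = length(x2),
               p_welch = tw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Manifest of the published 12-structure HLA-C panel
#'
#' PDB accessions, allotypes and C1/C2 groups of the crystal-structure
#' panel on which the groove descriptors separate C1 from C2 (5 C1 and 7 C2
#' peptide-bound structures, including two 10mer complexes measured at p9).
#' Coordinates are not bundled; fetch them explicitly with
#' [fetch_structures()] when network access is available.
#'
#' @return Data frame read from the bundled manifest CSV.
#' @export
study_structure_manifest <- function() {
  utils::read.csv(system.file("extdata", "study_structure_panel.csv",
                              package = "hlacpep"),
                  stringsAsFactors = FALSE)
}

#' Fetch PDB coordinate files by accession (explicit opt-in)
#'
#' Thin wrapper over `bio3d::get.pdb`. Network access is never exercised by
#' the test suite; analyses of the published panel are reproduced by
#' fetching once and passing local paths to [run_geometry_analysis()].
#'
#' @param ids PDB accessions.
#' @param path Download directory.
#' @return Character vector of file paths.
#' @export
fetch_structures <- function(ids, path = ".") {
  bio3d::get.pdb(ids, path = path)
}
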