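# Synthetic immunopeptidome panels with known ground truth.
#
# The generator emulates the statistical structure of per-allotype eluted
# 9mer sets: a shared baseline motif with HLA-C-like anchors (p2 and a
# hydrophobic C-terminus), a group-level pOmega-Ala rate (C1 > C2), and a
# group-level size tilt at pOmega-1 linking log-frequency to side-chain
# volume (C2 favouring larger residues). Positions are sampled
# independently unless an explicit pOmega-conditional pOmega-1 distribution
# is supplied.

#' Specification for a synthetic peptide panel
#'
#' Defaults are the study conditions of the sequence arm: 14 C1 and 7 C2
#' allotypes, 9mers, group pOmega-Ala rates of 1.45% (C1) and 0.27% (C2),
#' and a pOmega-1 volume coefficient of 0.7 per standard deviation of
#' side-chain volume (so a residue one volume-SD above the mean is about
#' twofold C2-enriched at pOmega-1).
#'
#' @param n_c1,n_c2 Number of C1 and C2 allotypes.
#' @param peptides_per_allotype Peptides sampled per allotype.
#' @param peptide_length Peptide length (9 is the primary analysis stratum).
#' @param baseline 20 x L baseline frequency matrix (default
#'   [default_baseline_pfm()]).
#' @param pOmega_ala_rate Named vector `c(C1 = , C2 = )` of pOmega-Ala
#'   probabilities; the remaining pOmega mass is renormalised.
#' @param size_coef pOmega-1 volume coefficient: C2 frequencies are tilted
#'   by `exp(+coef/2 * vstd)`, C1 by `exp(-coef/2 * vstd)`, `vstd` the
#'   standardised Zamyatnin volume. 0 disables the effect.
#' @param pOmega1_multipliers Optional list `list(C1 = , C2 = )` of named
#'   positive multipliers applied to pOmega-1 frequencies before
#'   renormalisation (used to plant known enrichments).
#' @param pOmega_conditional Optional named list mapping a pOmega residue
#'   to a length-20 pOmega-1 distribution, emulating anchor-conditional
#'   preferences.
#' @param contaminant_fraction Fraction of each allotype's peptides drawn
#'   from the contaminant motif instead of the allotype motif.
#' @param contaminant A [contaminant_motif()] supplying that motif.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return Validated list of class `generator_spec`.
#' @export
generator_spec <- function(n_c1 = 14L, n_c2 = 7L,
                           peptides_per_allotype = 1000L,
                           peptide_length = 9L,
                           baseline = default_baseline_pfm(peptide_length),
                           pOmega_ala_rate = c(C1 = 0.0145, C2 = 0.0027),
                           size_coef = 0.7,
                           pOmega1_multipliers = NULL,
                           pOmega_conditional = NULL,
                           contaminant_fraction = 0,
                           contaminant = NULL,
                           seed = 1L) {
  stopifnot(n_c1 >= 1L, n_c2 >= 1L, peptides_per_allotype >= 1L,
            peptide_length >= 8L, peptide_length <= 15L)
  if (inherits(baseline, "pfm")) baseline <- baseline$freq
  stopifnot(is.matrix(baseline), nrow(baseline) == 20L,
            ncol(baseline) == peptide_length)
  if (any(baseline < 0) || any(!is.finite(baseline))) {
    stop("baseline frequencies must be finite and non-negative", call. = FALSE)
  }
  if (any(pOmega_ala_rate < 0) || any(pOmega_ala_rate > 1)) {
    stop("pOmega-Ala rates must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c("C1", "C2") %in% names(pOmega_ala_rate))) {
    stop("pOmega_ala_rate needs elements C1 and C2", call. = FALSE)
  }
  if (!is.null(pOmega1_multipliers)) {
    for (g in names(pOmega1_multipliers)) {
      m <- pOmega1_multipliers[[g]]
      if (any(m <= 0) || any(!is.finite(m))) {
        stop("pOmega-1 multipliers must be positive and finite", call. = FALSE)
      }
    }
  }
  if (contaminant_fraction < 0 || contaminant_fraction > 1) {
    stop("contaminant_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (contaminant_fraction > 0 && is.null(contaminant)) {
    contaminant <- default_contaminant_motif(peptide_length)
  }
  structure(list(n_c1 = as.integer(n_c1), n_c2 = as.integer(n_c2),
                 peptides_per_allotype = as.integer(peptides_per_allotype),
                 peptide_length = as.integer(peptide_length),
                 baseline = sweep(baseline, 2, colSums(baseline), "/"),
                 pOmega_ala_rate = pOmega_ala_rate,
                 size_coef = size_coef,
                 pOmega1_multipliers = pOmega1_multipliers,
                 pOmega_conditional = pOmega_conditional,
                 contaminant_fraction = contaminant_fraction,
                 contaminant = contaminant,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' HLA-C-like baseline position-frequency matrix
#'
#' A 9mer-shaped motif used as the generator baseline: a p2 anchor
#' favouring Ala/Pro, a hydrophobic C-terminal anchor dominated by
#' Leu/Val/Ile/Phe/Met (together ~86% of pOmega, as in HLA-C eluted
#' ligands), and near-background interior positions.
#'
#' @param length Peptide length (interior positions are replicated for
#'   lengths other than 9).
#' @return 20 x `length` frequency matrix, columns summing to 1.
#' @export
default_baseline_pfm <- function(length = 9L) {
  # approximate proteome background over AA20
  bg <- c(A = 0.08, C = 0.02, D = 0.05, E = 0.06, F = 0.04, G = 0.07,
          H = 0.02, I = 0.05, K = 0.06, L = 0.09, M = 0.02, N = 0.04,
          P = 0.05, Q = 0.04, R = 0.05, S = 0.07, T = 0.06, V = 0.06,
          W = 0.01, Y = 0.03)
  bg <- bg / sum(bg)
  p2 <- bg * 0.35
  p2["A"] <- 0.35; p2["P"] <- 0.20; p2["V"] <- 0.10
  p2 <- p2 / sum(p2)
  pO <- bg * 0.2
  pO["L"] <- 0.50; pO["V"] <- 0.12; pO["I"] <- 0.10; pO["F"] <- 0.09
  pO["M"] <- 0.05
  pO <- pO / sum(pO)
  m <- matrix(rep(bg, length), nrow = 20, dimnames = list(names(bg), NULL))
  m[, 2] <- p2
  m[, length] <- pO
  colnames(m) <- paste0("p", seq_len(length))
  m
}

#' Built-in C1R-background contaminant motif
#'
#' A stand-in for the HLA-B*35:03-like background of C1R-derived datasets:
#' strong Pro at p2 and aromatic pOmega. The default threshold is the
#' expected self log-likelihood minus one self-score standard deviation:
#' roughly 85% of motif-drawn peptides score above it. How many background
#' peptides cross it depends on how similar the background motif is;
#' thresholds should be tuned per dataset when the filter matters.
#'
#' @param length Peptide length.
#' @param threshold Log-likelihood threshold; `NULL` for the default above.
#' @return A [contaminant_motif()].
#' @export
default_contaminant_motif <- function(length = 9L, threshold = NULL) {
  m <- default_baseline_pfm(length)
  p2 <- m[, 2] * 0.1
  p2["P"] <- 0.85
  m[, 2] <- p2 / sum(p2)
  pO <- m[, length] * 0.2
  pO["Y"] <- 0.45; pO["F"] <- 0.30
  m[, length] <- pO / sum(pO)
  if (is.null(threshold)) {
    lp <- log(m)
    mu <- sum(colSums(m * lp))
    v <- sum(colSums(m * lp^2) - colSums(m * lp)^2)
    threshold <- mu - sqrt(v)
  }
  contaminant_motif("B*35:03-like", pfm_from_freq(m), threshold)
}

# Effective per-group frequency matrices implied by a generator spec.
effective_group_pfms <- function(spec) {
  vol <- aa_volumes()
  vstd <- (vol - mean(vol)) / stats::sd(vol)
  out <- list()
  for (g in c("C1", "C2")) {
    m <- spec$baseline
    L <- spec$peptide_length
    # pOmega: pin the Ala rate, renormalise the rest
    rate <- spec$pOmega_ala_rate[[g]]
    others <- setdiff(AA20, "A")
    m["A", L] <- rate
    m[others, L] <- m[others, L] * (1 - rate) / sum(m[others, L])
    # pOmega-1: volume tilt plus planted multipliers
    s <- if (g == "C2") spec$size_coef / 2 else -spec$size_coef / 2
    w <- m[, L - 1L] * exp(s * vstd[AA20])
    mult <- spec$pOmega1_multipliers[[g]]
    if (!is.null(mult)) w[names(mult)] <- w[names(mult)] * mult
    m[, L - 1L] <- w / sum(w)
    out[[g]] <- m
  }
  out
}

#' Sample a synthetic per-allotype peptide panel
#'
#' Draws each allotype's peptides position-independently from its group's
#' effective frequency matrix (baseline modified by the group effects in
#' the spec), optionally mixing in contaminant-motif peptides. Allotypes
#' reuse the 21 study allotype names where possible. Ground-truth matrices
#' are returned for parameter-recovery tests.
#'
#' @param spec A [generator_spec()].
#' @return List with `sets` (named list of [peptide_set()]), `allotypes`
#'   (data frame), `truth` (effective group matrices) and `spec`.
#' @export
sample_peptide_panel <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  eff <- effective_group_pfms(spec)
  panel <- hlac_study_panel()
  mk_names <- function(g, n) {
    have <- panel$name[panel$group == g]
    if (n <= length(have)) have[seq_len(n)]
    else c(have, sprintf("%s-syn%02d", g, seq_len(n - length(have))))
  }
  allo <- data.frame(
    name = c(mk_names("C1", spec$n_c1), mk_names("C2", spec$n_c2)),
    group = c(rep("C1", spec$n_c1), rep("C2", spec$n_c2)),
    stringsAsFactors = FALSE)
  allo$residue77 <- ifelse(allo$group == "C1", "S", "N")
  allo$residue80 <- ifelse(allo$group == "C1", "N", "K")

  withr::with_seed(spec$seed, {
    sets <- lapply(seq_len(nrow(allo)), function(i) {
      m <- eff[[allo$group[i]]]
      n <- spec$peptides_per_allotype
      L <- spec$peptide_length
      chars <- matrix("", nrow = n, ncol = L)
      for (j in seq_len(L)) {
        chars[, j] <- sample(AA20, n, replace = TRUE, prob = m[, j])
      }
      if (!is.null(spec$pOmega_conditional)) {
        for (aa in names(spec$pOmega_conditional)) {
          idx <- which(chars[, L] == aa)
          if (length(idx)) {
            pr <- spec$pOmega_conditional[[aa]]
            chars[idx, L - 1L] <- sample(AA20, length(idx), replace = TRUE,
                                         prob = pr[AA20])
          }
        }
      }
      if (spec$contaminant_fraction > 0) {
        ncont <- round(spec$contaminant_fraction * n)
        if (ncont > 0) {
          cm <- spec$contaminant$pfms[[as.character(L)]]$freq
          for (j in seq_len(L)) {
            chars[seq_len(ncont), j] <- sample(AA20, ncont, replace = TRUE,
                                               prob = cm[, j])
          }
        }
      }
      peps <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
      peptide_set(peps,
                  allotype = allotype_record(allo$name[i], allo$residue77[i],
                                             allo$residue80[i]),
                  source = "synthetic")
    })
  })
  names(sets) <- allo$name
  list(sets = sets, allotypes = allo, truth = eff, spec = spec)
}

#' Assemble a group-enrichment panel from peptide sets
#'
#' Convenience bridge from a list of per-allotype peptide sets to the
#' `(allotype, pfm)` panel consumed by [group_enrichment()].
#'
#' @param sets Named list of [peptide_set()] objects.
#' @param length Length stratum for the frequency matrices.
#' @return List of `list(allotype = , pfm = )` entries.
#' @export
panel_pfms <- function(sets, length = 9L) {
  lapply(sets, function(ps) {
    list(allotype = ps$allotype,
         pfm = position_frequency_matrix(ps, length = length))
  })
}
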