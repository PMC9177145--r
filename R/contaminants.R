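#' Define a contaminant binding motif
#'
#' Eluted-ligand datasets produced in C1R cells carry a background of
#' peptides bound by the cell line's endogenous HLA-B*35:03 and HLA-C*04:01;
#' peptides matching those motifs are removed before analysis. The
#' motif is represented as one position-frequency matrix per peptide length
#' and peptides are scored by log-likelihood; a peptide scoring at or above
#' the threshold under any motif is excluded.
#'
#' @param name Allotype name of the contaminant motif, e.g. `"B*35:03"`.
#' @param pfms A single [position_frequency_matrix()]-style `pfm`, or a list
#'   of them covering the lengths to be filtered.
#' @param threshold Finite log-likelihood threshold (natural log). Peptides
#'   with `score >= threshold` are removed.
#' @return Object of class `contaminant_motif`.
#' @export
contaminant_motif <- function(name, pfms, threshold) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  stopifnot(all(vapply(pfms, inherits, logical(1), "pfm")),
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  names(pfms) <- vapply(pfms, function(p) as.character(p$length), character(1))
  structure(list(name = name, pfms = pfms, threshold = threshold),
            class = "contaminant_motif")
}

#' Log-likelihood of peptides under a position-frequency matrix
#'
#' Sum over positions of the natural log of the matrix frequency of the
#' observed residue; a residue of frequency zero gives `-Inf`.
#'
#' @param peptides Character vector, all of the matrix's length.
#' @param pfm A `pfm` object.
#' @return Numeric vector of scores.
#' @export
score_peptides <- function(peptides, pfm) {
  stopifnot(inherits(pfm, "pfm"))
  if (!length(peptides)) return(numeric(0))
  if (any(nchar(peptides) != pfm$length)) {
    stop("all peptides must have length ", pfm$length, call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(peptides, "")), ncol = pfm$length, byrow = TRUE)
  sc <- numeric(length(peptides))
  for (j in seq_len(pfm$length)) {
    sc <- sc + log(pfm$freq[cbind(match(chars[, j], rownames(pfm$freq)), j)])
  }
  sc
}

#' Remove peptides matching contaminant motifs
#'
#' @param ps A [peptide_set()].
#' @param motifs List of [contaminant_motif()] objects (empty list = no-op).
#' @return Filtered `peptide_set` with attribute `"removal_log"`: a data
#'   frame of each removed peptide, the motif responsible, and its score.
#' @export
filter_contaminant_motifs <- function(ps, motifs = list()) {
  stopifnot(inherits(ps, "peptide_set"))
  if (inherits(motifs, "contaminant_motif")) motifs <- list(motifs)
  if (!length(motifs) || !length(ps)) {
    attr(ps, "removal_log") <- data.frame(peptide = character(0),
                                          motif = character(0),
                                          score = numeric(0))
    return(ps)
  }
  lens <- unique(nchar(ps$peptides))
  removed <- logical(length(ps$peptides))
  log_rows <- list()
  for (m in motifs) {
    miss <- setdiff(as.character(lens), names(m$pfms))
    if (length(miss)) {
      stop(sprintf("contaminant motif '%s' lacks a matrix for length(s) %s",
                   m$name, paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (L in lens) {
      idx <- which(nchar(ps$peptides) == L)
      sc <- score_peptides(ps$peptides[idx], m$pfms[[as.character(L)]])
      hit <- sc >= m$threshold
      if (any(hit)) {
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(peptide = ps$peptides[idx][hit], motif = m$name,
                     score = sc[hit], stringsAsFactors = FALSE)
        removed[idx[hit]] <- TRUE
      }
    }
  }
  out <- ps
  out$peptides <- ps$peptides[!removed]
  out$sources <- ps$sources[!removed]
  rl <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(peptide = character(0), motif = character(0), score = numeric(0))
  attr(out, "removal_log") <- rl
  if (nrow(rl)) message(nrow(rl), " peptide(s) removed by contaminant motifs")
  out
}
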