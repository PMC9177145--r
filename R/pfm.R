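#' Position-specific amino-acid frequency matrix
#'
#' Counts and relative frequencies of the 20 amino acids at every position
#' of an equal-length peptide stratum. This is the per-allotype summary on
#' which all group-level enrichment statistics operate; in the anchor
#' analyses the informative rows are pOmega (the C-terminal position L) and
#' pOmega-1 (position L-1).
#'
#' @param x A [peptide_set()] or character vector of peptides.
#' @param length Peptide length of the stratum. Mandatory when `x` mixes
#'   lengths; defaults to the single length present.
#' @return Object of class `pfm`: list with `freq` and `counts` (20 x L
#'   matrices, rows the alphabetical one-letter codes), `n` (number of
#'   peptides) and `length`.
#' @examples
#' pfm <- position_frequency_matrix(c("GADGVGKSA", "GADGVGKSV"))
#' pfm$freq["G", 1]  # 1
#' @export
position_frequency_matrix <- function(x, length = NULL) {
  peps <- if (inherits(x, "peptide_set")) x$peptides else toupper(as.character(x))
  if (!is.null(length)) peps <- peps[nchar(peps) == length]
  if (!base::length(peps)) {
    stop("empty peptide stratum: no peptides",
         if (!is.null(length)) sprintf(" of length %d", length) else "",
         call. = FALSE)
  }
  L <- unique(nchar(peps))
  if (base::length(L) != 1L) {
    stop("peptides of mixed length; supply `length` to choose a stratum",
         call. = FALSE)
  }
  cm <- Biostrings::consensusMatrix(Biostrings::AAStringSet(peps))
  counts <- matrix(0L, nrow = 20L, ncol = L, dimnames = list(AA20, paste0("p", seq_len(L))))
  common <- intersect(rownames(cm), AA20)
  counts[common, ] <- cm[common, , drop = FALSE]
  n <- base::length(peps)
  structure(list(freq = counts / n, counts = counts, n = n, length = L),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm: %d peptides of length %d>\n", x$n, x$length))
  top <- apply(x$freq, 2, function(f) {
    i <- which.max(f); sprintf("%s %.2f", rownames(x$freq)[i], f[i])
  })
  cat("  top residue per position:", paste(top, collapse = " | "), "\n")
  invisible(x)
}

# Build a pfm object directly from a known frequency matrix (ground truth
# from the synthetic generator, or literature motifs). `n` = 0 marks it as
# count-free.
pfm_from_freq <- function(freq, n = 0L) {
  stopifnot(is.matrix(freq), nrow(freq) == 20L)
  if (is.null(rownames(freq))) rownames(freq) <- AA20
  freq <- freq[AA20, , drop = FALSE]
  freq <- sweep(freq, 2, colSums(freq), "/")
  colnames(freq) <- paste0("p", seq_len(ncol(freq)))
  structure(list(freq = freq, counts = freq * n, n = n, length = ncol(freq)),
            class = "pfm")
}

#' Count and percentage of one residue at one peptide position
#'
#' The quantity behind per-allotype anchor usage summaries, e.g. a
#' pOmega-Ala frequency of 1.5% (30 of 1986 9mers).
#'
#' @param x A [peptide_set()] or character vector.
#' @param length Length stratum.
#' @param position Position within 1..length (`length` itself is pOmega).
#' @param aa One-letter code.
#' @return Named numeric vector `c(count, total, percent)`.
#' @export
residue_frequency <- function(x, length, position, aa) {
  assert_aa_code(aa)
  if (position < 1L || position > length) {
    stop(sprintf("position %d out of range for %d-mers", position, length),
         call. = FALSE)
  }
  pfm <- position_frequency_matrix(x, length = length)
  k <- pfm$counts[aa, position]
  c(count = unname(k), total = pfm$n, percent = unname(100 * k / pfm$n))
}

#' pOmega-1 residue profile stratified by the C-terminal residue
#'
#' Frequency vector at the penultimate position computed only over peptides
#' whose C-terminal residue equals `pOmega_aa` — e.g. to ask whether the
#' preference for small residues at p8 is accentuated in pOmega-Ala
#' peptides relative to pOmega-Leu peptides.
#'
#' @param x A [peptide_set()] or character vector.
#' @param length Length stratum.
#' @param pOmega_aa One-letter code required at the C-terminus.
#' @return Named numeric frequency vector over the 20 amino acids, with
#'   attribute `"n"` (stratum size).
#' @export
stratified_pOmega1_profile <- function(x, length, pOmega_aa) {
  assert_aa_code(pOmega_aa)
  peps <- if (inherits(x, "peptide_set")) x$peptides else toupper(as.character(x))
  peps <- peps[nchar(peps) == length]
  peps <- peps[substr(peps, length, length) == pOmega_aa]
  if (!base::length(peps)) {
    stop(sprintf("no %d-mer peptides with pOmega %s", length, pOmega_aa),
         call. = FALSE)
  }
  pfm <- position_frequency_matrix(peps)
  out <- pfm$freq[, length - 1L]
  attr(out, "n") <- pfm$n
  out
}
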