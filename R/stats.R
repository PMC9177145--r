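#' Fisher's exact test on two anchor-residue counts
#'
#' Exact two-sided test comparing the proportion of peptides carrying a
#' residue in two peptide sets (e.g. pOmega-Ala in C*08:02 vs C*05:01
#' 9mers). Two-sidedness follows the probability-mass convention: the
#' p-value sums the hypergeometric probabilities of every 2x2 table with the
#' same margins whose probability does not exceed that of the observed table
#' (the convention of `stats::fisher.test`). This is documented because
#' mid-p and central-interval conventions differ in the third significant
#' figure.
#'
#' @param k1,n1 Count and total in the first set.
#' @param k2,n2 Count and total in the second set.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_count_test(30, 1986, 1, 732)  # 0.0016
#' @export
fisher_count_test <- function(k1, n1, k2, n2) {
  v <- c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (k1 > n1 || k2 > n2) stop("count exceeds its total", call. = FALSE)
  N <- n1 + n2
  if (N == 0) stop("both totals are zero", call. = FALSE)
  K <- k1 + k2
  lo <- max(0, K - n2)
  hi <- min(K, n1)
  d <- stats::dhyper(lo:hi, K, N - K, n1)
  p_obs <- stats::dhyper(k1, K, N - K, n1)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
}

# Two-sample t on allotype-level frequency vectors with explicit handling of
# degenerate (zero-variance) groups: identical constant groups give t = 0,
# p = 1; constant groups with different means give t = +/-Inf, p = 0.
two_sample_t <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(m1 - m2) * Inf, df = NA_real_, p = 0))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Per-amino-acid C2/C1 enrichment at one peptide position
#'
#' For each of the 20 amino acids, the unweighted mean frequency across C1
#' allotypes and across C2 allotypes at the given position, the C2/C1 fold
#' difference on pseudocounted means (Haldane-Anscombe 0.5 added to every
#' count cell, so folds stay finite when a residue is absent from a group),
#' and two-sided t-test p-values across the allotype-level frequencies —
#' both the equal-variance Student form and the Welch form are reported.
#' Group means are unweighted across allotypes, not pooled across peptides:
#' allotype set sizes differ by more than tenfold and each allotype is one
#' observation.
#'
#' @param panel List whose elements each carry an `allotype`
#'   ([allotype_record()]) and a `pfm` ([position_frequency_matrix()]).
#'   HYBRID allotypes are excluded with a warning; each group needs >= 2.
#' @param position Peptide position (use the peptide length for pOmega,
#'   length - 1 for pOmega-1).
#' @param pseudocount Counts added per cell before forming the means used in
#'   the fold ratio (default 0.5). Raw means are reported alongside.
#' @param test Which p-value drives the `significant` flag:
#'   `"student"` (the volcano default) or `"welch"`.
#' @return Data frame of class `enrichment_table`, one row per amino acid:
#'   raw group means and sds (percent scale), `fold_c2_c1`, `log2_fold`,
#'   `t_stat`, `p_student`, `p_welch`, `p_adj_bh`, `significant`
#'   (fold >= 2 or <= 0.5, and p < 0.05). Attributes record position,
#'   group sizes, pseudocount and flag test.
#' @export
group_enrichment <- function(panel, position, pseudocount = 0.5,
                             test = c("student", "welch")) {
  test <- match.arg(test)
  groups <- vapply(panel, function(e) e$allotype$group, character(1))
  if (any(groups == "HYBRID")) {
    warning(sum(groups == "HYBRID"), " HYBRID allotype(s) excluded from C1/C2 comparison")
    panel <- panel[groups != "HYBRID"]
    groups <- groups[groups != "HYBRID"]
  }
  if (sum(groups == "C1") < 2L || sum(groups == "C2") < 2L) {
    stop("need >= 2 allotypes in each of C1 and C2", call. = FALSE)
  }
  counts <- vapply(panel, function(e) {
    if (position < 1L || position > e$pfm$length) {
      stop("position out of range for allotype ", e$allotype$name, call. = FALSE)
    }
    e$pfm$counts[, position]
  }, numeric(20))                      # 20 x n_allotypes
  ns <- vapply(panel, function(e) e$pfm$n, numeric(1))
  pct <- sweep(counts, 2, ns, "/") * 100
  pseudo <- sweep(counts + pseudocount, 2, ns + 20 * pseudocount, "/")

  i1 <- groups == "C1"; i2 <- groups == "C2"
  mean_ps1 <- rowMeans(pseudo[, i1, drop = FALSE])
  mean_ps2 <- rowMeans(pseudo[, i2, drop = FALSE])
  fold <- mean_ps2 / mean_ps1

  tests <- lapply(AA20, function(a) {
    st <- two_sample_t(pct[a, i2], pct[a, i1], var_equal = TRUE)
    we <- two_sample_t(pct[a, i2], pct[a, i1], var_equal = FALSE)
    c(t = st$t, p_student = st$p, p_welch = we$p)
  })
  tm <- do.call(rbind, tests)

  out <- data.frame(
    aa = AA20,
    mean_c1_pct = rowMeans(pct[, i1, drop = FALSE]),
    sd_c1_pct = apply(pct[, i1, drop = FALSE], 1, stats::sd),
    mean_c2_pct = rowMeans(pct[, i2, drop = FALSE]),
    sd_c2_pct = apply(pct[, i2, drop = FALSE], 1, stats::sd),
    fold_c2_c1 = fold,
    log2_fold = log2(fold),
    t_stat = tm[, "t"],
    p_student = tm[, "p_student"],
    p_welch = tm[, "p_welch"],
    row.names = NULL, stringsAsFactors = FALSE)
  p_flag <- if (test == "student") out$p_student else out$p_welch
  out$p_adj_bh <- stats::p.adjust(p_flag, method = "BH")
  out$significant <- (out$fold_c2_c1 >= 2 | out$fold_c2_c1 <= 0.5) &
    !is.na(p_flag) & p_flag < 0.05
  attr(out, "position") <- position
  attr(out, "n_c1") <- sum(i1)
  attr(out, "n_c2") <- sum(i2)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "test") <- test
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Pearson correlation of two allotypes' residue usage at one position
#'
#' Correlates the 20-element frequency vectors of two position-frequency
#' matrices at a position — the statistic used to compare the positional
#' amino-acid usage of sequences unique to two allotypes.
#'
#' @param pfmA,pfmB `pfm` objects of the same length.
#' @param position Position within 1..length.
#' @return Pearson r in \[-1, 1\].
#' @export
positionwise_correlation <- function(pfmA, pfmB, position) {
  stopifnot(inherits(pfmA, "pfm"), inherits(pfmB, "pfm"))
  if (pfmA$length != pfmB$length) stop("matrices have different lengths", call. = FALSE)
  if (position < 1L || position > pfmA$length) stop("position out of range", call. = FALSE)
  fa <- pfmA$freq[, position]
  fb <- pfmB$freq[, position]
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    stop("zero variance in a frequency vector: correlation undefined", call. = FALSE)
  }
  stats::cor(fa, fb)
}

#' Correlate amino-acid enrichment with side-chain volume
#'
#' Pearson correlation between side-chain volume and log2(C2/C1) enrichment
#' across the 20 amino acids: a positive r means larger residues are
#' favoured by C2 allotypes at the analysed position.
#'
#' @param enrichment An `enrichment_table` from [group_enrichment()].
#' @param volumes Named volume vector (default [aa_volumes()]).
#' @return List of class `volume_correlation`: `r` and `table` (columns
#'   `aa`, `volume`, `log2_fold`) ready for a scatter plot.
#' @export
volume_correlation <- function(enrichment, volumes = aa_volumes()) {
  stopifnot(inherits(enrichment, "enrichment_table"))
  miss <- setdiff(enrichment$aa, names(volumes))
  if (length(miss)) {
    stop("volume table lacks amino acid(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(enrichment$log2_fold))) {
    stop("non-finite fold values; use a positive pseudocount", call. = FALSE)
  }
  tab <- data.frame(aa = enrichment$aa,
                    volume = unname(volumes[enrichment$aa]),
                    log2_fold = enrichment$log2_fold,
                    stringsAsFactors = FALSE)
  structure(list(r = stats::cor(tab$volume, tab$log2_fold), table = tab),
            class = "volume_correlation")
}

#' @export
print.volume_correlation <- function(x, ...) {
  cat(sprintf("<volume_correlation: Pearson r = %.3f over %d amino acids>\n",
              x$r, nrow(x$table)))
  invisible(x)
}
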