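# Internal helpers shared across modules.

# Canonical 20-letter amino-acid alphabet, alphabetical one-letter order.
# B/J/O/U/X/Z are deliberately excluded: ambiguous or non-standard codes are
# rejected at ingestion, never silently dropped.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PEPTIDE_LENGTH_RANGE <- c(8L, 15L)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_aa_code <- function(x) {
  is.character(x) & nchar(x) == 1L & x %in% AA20
}

assert_aa_code <- function(x, what = "amino acid code") {
  bad <- !is_aa_code(x)
  if (any(bad)) {
    stop(sprintf("invalid %s: %s (must be one of %s)",
                 what, paste(unique(x[bad]), collapse = ", "),
                 paste(AA20, collapse = "")), call. = FALSE)
  }
  invisible(x)
}

#' Side-chain volumes of the 20 standard amino acids
#'
#' Residue volumes on the Zamyatnin (1972) scale, in cubic angstroms. Used to
#' relate amino-acid enrichment at the penultimate peptide position
#' (pOmega-1) to side-chain size.
#'
#' @return Named numeric vector over the 20 one-letter codes, with a
#'   `"citation"` attribute. Satisfies Gly < Ala < Trp.
#' @examples
#' aa_volumes()[c("G", "A", "W")]
#' @export
aa_volumes <- function() {
  v <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
         G = 60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
         M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
         S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)
  attr(v, "citation") <-
    "Zamyatnin AA (1972) Protein volume in solution. Prog Biophys Mol Biol 24:107-123"
  v
}

vec_dist <- function(a, b) sqrt(sum((a - b)^2))

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by points p1-p2-p3-p4 about the p2-p3
#' axis, using the IUPAC sign convention (cis = 0, trans = 180). Exported
#' because the structural descriptors and the toy-structure generator are
#' both defined in terms of it.
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors of length 3.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension reference frame placement: position a fourth atom at a
# given bond length from c, bond angle b-c-d, and dihedral a-b-c-d.
place_dihedral <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  theta <- angle_deg * pi / 180
  chi <- dihedral_deg * pi / 180
  d_local <- bond * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  bc <- (c - b) / vec_dist(c, b)
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d_local)
}
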