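#' Classify an HLA-C allotype into the C1/C2 dimorphism groups
#'
#' HLA-C allotypes split into two groups by the dimorphic heavy-chain
#' residues 77 and 80: C1 allotypes carry Ser77/Asn80 and C2 allotypes carry
#' Asn77/Lys80. Any other combination (e.g. engineered point mutants such as
#' C*05:01-N77S, which has Ser77/Lys80) is labelled `HYBRID`.
#'
#' @param residue77,residue80 One-letter amino-acid codes (vectorised).
#' @return Character vector over `{"C1", "C2", "HYBRID"}`.
#' @examples
#' assign_c1c2("S", "N")  # C1
#' assign_c1c2("N", "K")  # C2
#' assign_c1c2("S", "K")  # HYBRID (N77S point mutant of a C2 allotype)
#' @export
assign_c1c2 <- function(residue77, residue80) {
  assert_aa_code(residue77, "residue 77 code")
  assert_aa_code(residue80, "residue 80 code")
  ifelse(residue77 == "S" & residue80 == "N", "C1",
         ifelse(residue77 == "N" & residue80 == "K", "C2", "HYBRID"))
}

#' Construct an allotype record
#'
#' @param name HLA nomenclature string, e.g. `"C*08:02"`.
#' @param residue77,residue80 One-letter codes of the dimorphic residues.
#' @return An object of class `allotype_record` with fields `name`,
#'   `residue77`, `residue80` and the derived `group`.
#' @export
allotype_record <- function(name, residue77, residue80) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name,
         residue77 = residue77,
         residue80 = residue80,
         group = assign_c1c2(residue77, residue80)),
    class = "allotype_record")
}

#' @export
print.allotype_record <- function(x, ...) {
  cat(sprintf("<allotype %s: residue77=%s residue80=%s group=%s>\n",
              x$name, x$residue77, x$residue80, x$group))
  invisible(x)
}

#' The 21-allotype HLA-C study panel
#'
#' The 14 C1 and 7 C2 HLA-C allotypes whose eluted-ligand immunopeptidomes
#' are analysed by the sequence arm of this package, with their dimorphic
#' residues. C1 allotypes carry Ser77/Asn80, C2 allotypes Asn77/Lys80.
#'
#' @return Data frame with columns `name`, `residue77`, `residue80`,
#'   `group`.
#' @export
hlac_study_panel <- function() {
  c1 <- c("C*01:02", "C*03:02", "C*03:03", "C*03:04", "C*07:01", "C*07:02",
          "C*07:04", "C*08:01", "C*08:02", "C*12:02", "C*12:03", "C*14:02",
          "C*14:03", "C*16:01")
  c2 <- c("C*02:02", "C*04:01", "C*04:03", "C*05:01", "C*06:02", "C*15:02",
          "C*17:01")
  data.frame(
    name = c(c1, c2),
    residue77 = c(rep("S", length(c1)), rep("N", length(c2))),
    residue80 = c(rep("N", length(c1)), rep("K", length(c2))),
    group = c(rep("C1", length(c1)), rep("C2", length(c2))),
    stringsAsFactors = FALSE)
}

#' Read an allotype metadata table
#'
#' Expects a CSV with columns `name`, `residue77` (or `res77`), `residue80`
#' (or `res80`); the C1/C2/HYBRID group is derived, never read.
#'
#' @param path CSV file path.
#' @return Data frame with columns `name`, `residue77`, `residue80`, `group`.
#' @export
read_allotype_table <- function(path) {
  if (!file.exists(path)) stop("allotype table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "res77"] <- "residue77"
  names(df)[names(df) == "res80"] <- "residue80"
  need <- c("name", "residue77", "residue80")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("allotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("allotype names must be unique within a panel", call. = FALSE)
  }
  df$residue77 <- toupper(df$residue77)
  df$residue80 <- toupper(df$residue80)
  df$group <- assign_c1c2(df$residue77, df$residue80)
  df[need %in% names(df)]
  df[, c(need, "group")]
}

# Look up an allotype_record by name, from a metadata data frame or from the
# bundled study panel.
lookup_allotype <- function(name, table = hlac_study_panel()) {
  i <- match(name, table$name)
  if (is.na(i)) stop("unknown allotype: ", name, call. = FALSE)
  allotype_record(table$name[i], table$residue77[i], table$residue80[i])
}
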