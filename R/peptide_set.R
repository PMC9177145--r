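#' Construct a deduplicated per-allotype peptide set
#'
#' The container for one allotype's eluted-ligand sequences. Sequences are
#' upper-cased, validated against the 20-letter alphabet, restricted to
#' lengths 8-15 (the class-I eluted-ligand range), deduplicated by exact
#' string equality, and stored sorted so that a peptide set has a single
#' canonical representation regardless of input order.
#'
#' @param peptides Character vector of sequences (may contain duplicates).
#' @param allotype An [allotype_record()], an allotype name (looked up in
#'   [hlac_study_panel()]), or `NULL` for an unattributed set.
#' @param source Single source label, or a vector parallel to `peptides`
#'   (which study/file each sequence came from).
#' @param on_invalid `"error"` rejects the whole input naming the first
#'   offending entry; `"drop"` removes invalid sequences with a logged count.
#' @return Object of class `peptide_set` with fields `allotype`, `peptides`
#'   (sorted unique sequences) and `sources` (";"-joined labels, parallel to
#'   `peptides`).
#' @examples
#' ps <- peptide_set(c("GADGVGKSA", "GADGVGKSAL"), allotype = "C*08:02")
#' length(ps)
#' @export
peptide_set <- function(peptides, allotype = NULL, source = "user",
                        on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (is.character(allotype)) allotype <- lookup_allotype(allotype)
  if (!is.null(allotype) && !inherits(allotype, "allotype_record")) {
    stop("allotype must be an allotype_record, a name, or NULL", call. = FALSE)
  }
  peptides <- toupper(as.character(peptides))
  if (length(source) == 1L) source <- rep(source, length(peptides))
  stopifnot(length(source) == length(peptides))

  keep <- !is.na(peptides) & nzchar(peptides)
  peptides <- peptides[keep]; source <- source[keep]

  bad <- validate_peptide_strings(peptides)
  if (any(bad)) {
    if (on_invalid == "error") {
      i <- which(bad)[1L]
      stop(sprintf("invalid peptide sequence at entry %d: '%s'",
                   i, peptides[i]), call. = FALSE)
    }
    message(sum(bad), " invalid peptide sequence(s) rejected")
    peptides <- peptides[!bad]; source <- source[!bad]
  }

  # exact-string dedup; union source labels for collapsed duplicates
  src <- split(source, peptides)
  uniq <- sort(names(src))
  sources <- vapply(src[uniq],
                    function(s) paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))),
                                      collapse = ";"),
                    character(1))
  structure(list(allotype = allotype,
                 peptides = uniq,
                 sources = unname(sources)),
            class = "peptide_set")
}

# TRUE for sequences that violate the alphabet or the 8-15 length range
validate_peptide_strings <- function(x) {
  bad_alpha <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
  n <- nchar(x)
  bad_alpha | n < PEPTIDE_LENGTH_RANGE[1] | n > PEPTIDE_LENGTH_RANGE[2]
}

#' @export
length.peptide_set <- function(x) length(x$peptides)

#' @export
print.peptide_set <- function(x, ...) {
  nm <- if (is.null(x$allotype)) "<unattributed>" else x$allotype$name
  tab <- table(nchar(x$peptides))
  cat(sprintf("<peptide_set %s: %d unique peptides (%s)>\n", nm, length(x),
              paste(sprintf("%smers: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

allotype_name <- function(ps) {
  if (is.null(ps$allotype)) NA_character_ else ps$allotype$name
}

#' Merge peptide sets of the same allotype
#'
#' Set union with exact-string deduplication, mirroring the merging of
#' allotype-specific sequence lists from independent immunopeptidomics
#' studies. Merging is idempotent and order-independent; source labels of
#' shared sequences are concatenated.
#'
#' @param ... `peptide_set` objects, or a single list of them. All must
#'   reference the same allotype name.
#' @return A merged `peptide_set`.
#' @export
merge_peptide_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "peptide_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "peptide_set")))
  nms <- vapply(sets, allotype_name, character(1))
  if (length(unique(nms)) > 1L) {
    stop("cannot merge peptide sets from different allotypes: ",
         paste(unique(nms), collapse = ", "), call. = FALSE)
  }
  peptide_set(unlist(lapply(sets, `[[`, "peptides")),
              allotype = sets[[1]]$allotype,
              source = unlist(lapply(sets, `[[`, "sources")))
}

#' Extract a length stratum of a peptide set
#'
#' @param ps A `peptide_set`.
#' @param length Peptide length (9 for the default 9mer analysis set).
#' @return `peptide_set` restricted to sequences of that length.
#' @export
stratify_length <- function(ps, length) {
  stopifnot(inherits(ps, "peptide_set"))
  keep <- nchar(ps$peptides) == length
  out <- ps
  out$peptides <- ps$peptides[keep]
  out$sources <- ps$sources[keep]
  out
}

#' Partition two allotypes' peptides into unique and shared sequences
#'
#' Used to compare positional amino-acid usage between sequences unique to
#' one allotype versus another (e.g. uC*08:02 vs uC*05:01) after removing
#' the peptides both allotypes present.
#'
#' @param a,b `peptide_set` objects.
#' @param length Length stratum to compare (default 9).
#' @return List with character vectors `unique_a`, `unique_b`, `shared`;
#'   the three are disjoint and `unique_a` + `shared` reconstructs `a`'s
#'   stratum (likewise for `b`).
#' @export
partition_unique_shared <- function(a, b, length = 9L) {
  pa <- stratify_length(a, length)$peptides
  pb <- stratify_length(b, length)$peptides
  if (!base::length(pa)) {
    stop(sprintf("set '%s' has no %d-mer peptides", allotype_name(a), length),
         call. = FALSE)
  }
  if (!base::length(pb)) {
    stop(sprintf("set '%s' has no %d-mer peptides", allotype_name(b), length),
         call. = FALSE)
  }
  shared <- intersect(pa, pb)
  list(unique_a = setdiff(pa, pb),
       unique_b = setdiff(pb, pa),
       shared = shared)
}
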