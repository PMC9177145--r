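#' Read a peptide list from disk
#'
#' Two plain-text layouts are supported: `lines` (one sequence per line, one
#' allotype per file) and `csv` (columns `allotype,peptide[,source]`,
#' possibly covering several allotypes). Sequences are upper-cased and
#' validated; a sequence containing a character outside the 20-letter
#' alphabet, or outside the 8-15 length range, raises a validation error
#' naming its line number (or is dropped with a logged count when
#' `on_invalid = "drop"`).
#'
#' @param path Input file.
#' @param format `"auto"` (by extension: `.csv` vs anything else), `"lines"`
#'   or `"csv"`.
#' @param allotype Allotype for `lines` input: an [allotype_record()], a
#'   name known to [hlac_study_panel()], or `NULL`.
#' @param source Source label recorded per peptide; defaults to the file
#'   name.
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @return A [peptide_set()] — or, for a `csv` containing several
#'   allotypes, a named list of them.
#' @export
read_peptide_list <- function(path, format = c("auto", "lines", "csv"),
                              allotype = NULL, source = NULL,
                              on_invalid = c("error", "drop")) {
  format <- match.arg(format)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("cannot read peptide list: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "lines"
  }
  source <- source %||% basename(path)

  if (format == "lines") {
    lines <- trimws(readLines(path, warn = FALSE))
    keep <- nzchar(lines)
    if (!any(keep)) {
      warning("empty peptide list: ", path, call. = FALSE)
      return(peptide_set(character(0), allotype = allotype, source = source))
    }
    seqs <- toupper(lines[keep])
    if (on_invalid == "error") {
      bad <- validate_peptide_strings(seqs)
      if (any(bad)) {
        ln <- which(keep)[which(bad)[1L]]
        stop(sprintf("invalid peptide sequence at line %d of %s: '%s'",
                     ln, path, seqs[which(bad)[1L]]), call. = FALSE)
      }
    }
    return(peptide_set(seqs, allotype = allotype, source = source,
                       on_invalid = on_invalid))
  }

  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("allotype", "peptide") %in% names(df))) {
    stop("csv peptide list must have columns allotype,peptide: ", path,
         call. = FALSE)
  }
  if (!nrow(df)) {
    warning("empty peptide list: ", path, call. = FALSE)
    return(peptide_set(character(0), allotype = allotype, source = source))
  }
  df$peptide <- toupper(trimws(df$peptide))
  if (on_invalid == "error") {
    bad <- validate_peptide_strings(df$peptide)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("invalid peptide sequence at line %d of %s: '%s'",
                   i + 1L, path, df$peptide[i]), call. = FALSE)  # +1 header
    }
  }
  src <- if ("source" %in% names(df)) df$source else source
  out <- lapply(split(seq_len(nrow(df)), df$allotype), function(i) {
    al <- tryCatch(lookup_allotype(df$allotype[i[1]]), error = function(e) NULL)
    peptide_set(df$peptide[i], allotype = al,
                source = if (length(src) == 1L) src else src[i],
                on_invalid = on_invalid)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Write a peptide set (or list of sets) to CSV with provenance
#'
#' @param x A `peptide_set` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_csv <- function(x, path) {
  if (inherits(x, "peptide_set")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(ps) {
    data.frame(allotype = allotype_name(ps),
               peptide = ps$peptides,
               source = ps$sources,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
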