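#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent R list) with fields describing
#' inputs and options for [run_peptidome_analysis()] /
#' [run_geometry_analysis()]. All referenced paths are checked up front and
#' every failure is reported in one error.
#'
#' @param config YAML file path or a list.
#' @return Validated list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errs <- character(0)
  for (field in c("peptide_files", "allotype_table", "structure_manifest")) {
    p <- config[[field]]
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      errs <- c(errs, sprintf("%s: file not found: %s", field, p))
    }
  }
  if (!is.null(config$peptide_files) && is.data.frame(config$peptide_files)) {
    bad <- !file.exists(config$peptide_files$path)
    if (any(bad)) {
      errs <- c(errs, paste0("peptide file not found: ",
                             config$peptide_files$path[bad]))
    }
  }
  if (length(errs)) {
    stop("config validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  class(config) <- c("run_config", "list")
  config
}

# manifest column accessor: absent column, NA or "" all mean "not given"
col_or_null <- function(df, col, i) {
  v <- df[[col]]
  if (is.null(v)) return(NULL)
  v <- v[i]
  if (is.na(v) || identical(v, "")) NULL else v
}

load_config_sets <- function(config) {
  if (!is.null(config$sets)) return(config$sets)
  files <- config$peptide_files
  if (is.character(files)) files <- utils::read.csv(files, stringsAsFactors = FALSE)
  if (is.null(files)) stop("config needs either `sets` or `peptide_files`", call. = FALSE)
  allo <- config$allotype_table
  allo <- if (is.null(allo)) hlac_study_panel() else if (is.character(allo))
    read_allotype_table(allo) else allo
  sets <- list()
  for (i in seq_len(nrow(files))) {
    al <- lookup_allotype(files$allotype[i], table = allo)
    ps <- read_peptide_list(files$path[i],
                            format = col_or_null(files, "format", i) %||% "auto",
                            allotype = al,
                            source = col_or_null(files, "source", i) %||%
                              basename(files$path[i]))
    nm <- al$name
    sets[[nm]] <- if (is.null(sets[[nm]])) ps else merge_peptide_sets(sets[[nm]], ps)
  }
  sets
}

#' Run the immunopeptidome analysis arm end-to-end
#'
#' From per-allotype peptide sets (in-memory or described by a file
#' manifest) this produces the full sequence-side report: per-allotype
#' position-frequency matrices, the pOmega residue-frequency table and
#' Fisher comparison for a named allotype pair, C1-vs-C2 volcano tables at
#' pOmega and pOmega-1, the unique/shared partition of the focus pair with
#' position-wise Pearson correlations, the volume correlation at pOmega-1,
#' and a machine-readable run log accounting for every input peptide
#' (kept, deduplicated or filtered).
#'
#' @param config A [read_run_config()] result or a compatible list. Fields:
#'   `sets` (named list of [peptide_set()]) or `peptide_files` +
#'   `allotype_table`; `length` (default 9); `focus_pair` (default
#'   `c("C*08:02", "C*05:01")` when both present); `pseudocount` (0.5);
#'   `test` ("student"); `contaminant_motifs` (optional list); `out_dir`
#'   (optional: write CSV/JSON reports there); `seed` (recorded).
#' @return Invisible list with elements `pfms`, `pomega_freq`, `fisher`,
#'   `volcano_pomega`, `volcano_pomega1`, `partition`, `correlations`,
#'   `volume`, `log`.
#' @export
run_peptidome_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  L <- config$length %||% 9L
  sets <- load_config_sets(config)
  n_input <- vapply(sets, length, integer(1))

  motifs <- config$contaminant_motifs %||% list()
  removed <- integer(length(sets)); names(removed) <- names(sets)
  if (length(motifs)) {
    sets <- lapply(sets, filter_contaminant_motifs, motifs = motifs)
    removed <- vapply(sets, function(s) nrow(attr(s, "removal_log")), integer(1))
  }
  strata <- lapply(sets, stratify_length, length = L)
  kept <- vapply(strata, length, integer(1))

  panel <- panel_pfms(strata[vapply(strata, length, integer(1)) > 0], length = L)
  pfms <- lapply(panel, `[[`, "pfm")
  names(pfms) <- vapply(panel, function(e) e$allotype$name, character(1))

  test <- config$test %||% "student"
  pc <- config$pseudocount %||% 0.5
  volcano_pO <- group_enrichment(panel, position = L, pseudocount = pc, test = test)
  volcano_pO1 <- group_enrichment(panel, position = L - 1L, pseudocount = pc, test = test)
  vol <- volume_correlation(volcano_pO1)

  focus <- config$focus_pair %||%
    intersect(c("C*08:02", "C*05:01"), names(pfms))
  fisher <- pomega_freq <- partition <- correlations <- NULL
  if (length(focus) == 2L && all(focus %in% names(pfms))) {
    fa <- residue_frequency(strata[[focus[1]]], L, L, "A")
    fb <- residue_frequency(strata[[focus[2]]], L, L, "A")
    fisher <- data.frame(allotype = focus,
                         count = c(fa["count"], fb["count"]),
                         total = c(fa["total"], fb["total"]),
                         percent = c(fa["percent"], fb["percent"]),
                         row.names = NULL)
    fisher$p_fisher <- fisher_count_test(fa["count"], fa["total"],
                                         fb["count"], fb["total"])
    pomega_freq <- data.frame(
      aa = AA20,
      pct_a = 100 * pfms[[focus[1]]]$freq[, L],
      pct_b = 100 * pfms[[focus[2]]]$freq[, L],
      row.names = NULL)
    names(pomega_freq)[2:3] <- paste0("pct_", focus)

    part <- partition_unique_shared(sets[[focus[1]]], sets[[focus[2]]], length = L)
    partition <- data.frame(set = c(paste0("u", focus[1]), paste0("u", focus[2]), "shared"),
                            n = c(length(part$unique_a), length(part$unique_b),
                                  length(part$shared)))
    if (length(part$unique_a) && length(part$unique_b)) {
      ua <- position_frequency_matrix(part$unique_a)
      ub <- position_frequency_matrix(part$unique_b)
    } else {
      # identical repertoires leave no unique sequences; correlate the full
      # strata so the report still carries the per-position comparison
      ua <- position_frequency_matrix(strata[[focus[1]]])
      ub <- position_frequency_matrix(strata[[focus[2]]])
    }
    correlations <- data.frame(
      position = seq_len(L),
      pearson_r = vapply(seq_len(L), function(p)
        positionwise_correlation(ua, ub, p), numeric(1)))
    attr(partition, "unique_sets") <- part
  }

  log <- list(package = "hlacpep",
              version = as.character(utils::packageVersion("hlacpep")),
              seed = config$seed %||% NA,
              length = L,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              allotypes = lapply(names(sets), function(nm) {
                list(allotype = nm,
                     input_unique = n_input[[nm]],
                     removed_contaminant = removed[[nm]],
                     outside_stratum = n_input[[nm]] - removed[[nm]] - kept[[nm]],
                     kept = kept[[nm]])
              }))

  out <- list(pfms = pfms, pomega_freq = pomega_freq, fisher = fisher,
              volcano_pomega = volcano_pO, volcano_pomega1 = volcano_pO1,
              partition = partition, correlations = correlations,
              volume = vol, log = log)
  if (!is.null(config$out_dir)) write_peptidome_reports(out, config$out_dir)
  invisible(out)
}

write_peptidome_reports <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(as.data.frame(df), file.path(dir, name), row.names = FALSE)
    }
  }
  for (nm in names(out$pfms)) {
    wr(data.frame(aa = AA20, out$pfms[[nm]]$freq, check.names = FALSE),
       paste0("pfm_", gsub("[*:]", "", nm), ".csv"))
  }
  wr(out$pomega_freq, "pomega_frequency.csv")
  wr(out$fisher, "fisher_pair.csv")
  wr(out$volcano_pomega, "volcano_pomega.csv")
  wr(out$volcano_pomega1, "volcano_pomega1.csv")
  wr(out$partition, "unique_shared_counts.csv")
  wr(out$correlations, "unique_shared_correlation.csv")
  wr(out$volume$table, "volume_correlation.csv")
  jsonlite::write_json(out$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the structure-geometry analysis arm end-to-end
#'
#' Measures the four groove descriptors on every structure in a manifest
#' and, when both groups have at least two structures, the C1-vs-C2 Welch
#' statistics. Rows that fail to parse are recorded as errors and the run
#' continues; the call fails only if every row fails.
#'
#' @param config A [read_run_config()] result or list with fields
#'   `structure_manifest` (CSV path or data frame with columns
#'   `structure_id`, `path`, `group` and optional `heavy_chain`,
#'   `peptide_chain`, `offset`) and optional `out_dir`.
#' @return Invisible list with `records` (per-structure descriptors),
#'   `stats` (group statistics or NULL with a warning), `errors`.
#' @export
run_geometry_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  man <- config$structure_manifest
  if (is.character(man)) man <- utils::read.csv(man, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(man),
            all(c("structure_id", "path", "group") %in% names(man)))
  records <- list(); errors <- list()
  for (i in seq_len(nrow(man))) {
    rec <- tryCatch({
      m <- load_structure(man$path[i],
                          heavy_chain = col_or_null(man, "heavy_chain", i),
                          peptide_chain = col_or_null(man, "peptide_chain", i),
                          group = man$group[i],
                          id = man$structure_id[i],
                          offset = col_or_null(man, "offset", i) %||% 0L)
      measure_groove_geometry(m)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[man$structure_id[i]]] <- conditionMessage(rec)
    } else {
      records[[man$structure_id[i]]] <- rec
    }
  }
  if (!length(records)) {
    stop("all structures failed:\n  ",
         paste(unlist(errors), collapse = "\n  "), call. = FALSE)
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  stats <- NULL
  if (min(table(factor(records$group, levels = c("C1", "C2")))) >= 2L) {
    stats <- group_geometry_stats(records)
  } else {
    warning("fewer than 2 structures per group: group statistics skipped",
            call. = FALSE)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(config$out_dir, "geometry_records.csv"),
                     row.names = FALSE)
    if (!is.null(stats)) {
      utils::write.csv(stats, file.path(config$out_dir, "geometry_group_stats.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(records = records, stats = stats, errors = errors))
}
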