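#' Construct an abundance study
#'
#' Bundles a label-free protein abundance matrix (proteins x samples, missing
#' values allowed and kept distinct from measured zeros) with its sample
#' metadata. This is the container the filtering cascade operates on.
#'
#' @param proteins Character vector of unique protein identifiers.
#' @param samples Data frame of sample metadata with columns `sample_id`,
#'   `group` (`"FT"` or `"HGSOC"`), `source` (`"cell_line"` or `"tissue"`),
#'   `line_or_patient` (the replicate unit: one cell line or one tissue set),
#'   and `replicate_index` (integer >= 1).
#' @param intensities Numeric matrix with `length(proteins)` rows and
#'   `nrow(samples)` columns; non-negative; `NA` encodes "not measured".
#' @return An object of class `abundance_study`.
#' @export
abundance_study <- function(proteins, samples, intensities) {
  proteins <- normalize_ids(proteins)
  if (anyDuplicated(proteins)) {
    dups <- unique(proteins[duplicated(proteins)])
    stop("duplicate protein identifier(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "group", "source", "line_or_patient",
                "replicate_index")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (!all(samples$group %in% c("FT", "HGSOC"))) {
    stop("sample group must be 'FT' or 'HGSOC'", call. = FALSE)
  }
  if (!all(samples$source %in% c("cell_line", "tissue"))) {
    stop("sample source must be 'cell_line' or 'tissue'", call. = FALSE)
  }
  samples$replicate_index <- as.integer(samples$replicate_index)
  if (any(samples$replicate_index < 1L)) {
    stop("replicate_index must be >= 1", call. = FALSE)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != length(proteins) ||
      ncol(intensities) != nrow(samples)) {
    stop("intensity matrix must be length(proteins) x nrow(samples)",
         call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  dimnames(intensities) <- list(proteins, samples$sample_id)
  structure(
    list(proteins = proteins, samples = samples, intensities = intensities),
    class = "abundance_study"
  )
}

#' @export
print.abundance_study <- function(x, ...) {
  cat("<abundance_study> ", length(x$proteins), " proteins x ",
      nrow(x$samples), " samples\n", sep = "")
  tab <- dplyr::count(x$samples, .data$group, .data$source)
  print(tab)
  invisible(x)
}

#' @export
as_tibble.abundance_study <- function(x, ...) {
  long <- as_tibble(x$intensities, rownames = "protein")
  long <- pivot_longer(long, -"protein",
                       names_to = "sample_id", values_to = "intensity")
  left_join(long, x$samples, by = "sample_id")
}

#' Units of an abundance study
#'
#' A *unit* is one cell line or one tissue-explant set, i.e. the grouping
#' level at which the replicate-detection rule applies.
#'
#' @param study An [abundance_study()].
#' @return Tibble with one row per unit: `line_or_patient`, `group`,
#'   `source`, `n_replicates`.
#' @export
study_units <- function(study) {
  stopifnot(inherits(study, "abundance_study"))
  study$samples |>
    group_by(.data$line_or_patient, .data$group, .data$source) |>
    summarise(n_replicates = dplyr::n(), .groups = "drop") |>
    arrange(.data$group, .data$source, .data$line_or_patient)
}

#' Read a protein abundance table with sample metadata
#'
#' The abundance file is delimited text with a header row; the first column
#' holds protein identifiers and the remaining columns one sample each.
#' Empty cells are read as missing (`NA`), which is kept distinct from a
#' measured `0`: both count as "not detected" for presence rules, but only
#' `NA` is excluded from fold-change means.
#'
#' @param path Path to the abundance table (CSV or TSV; delimiter
#'   auto-detected unless `delim` is given).
#' @param meta_path Path to the sample metadata table with columns
#'   `sample_id`, `group`, `source`, `line_or_patient`, `replicate_index`.
#' @param delim Optional explicit delimiter for both files.
#' @return An [abundance_study()].
#' @export
read_abundance <- function(path, meta_path, delim = NULL) {
  if (!file.exists(path)) stop("abundance file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path, call. = FALSE)
  d1 <- delim %||% detect_delim(path)
  d2 <- delim %||% detect_delim(meta_path)
  tab <- readr::read_delim(path, delim = d1, na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_delim(meta_path, delim = d2, na = c("", "NA"),
                            show_col_types = FALSE, progress = FALSE)
  proteins <- normalize_ids(tab[[1]])
  if (anyDuplicated(proteins)) {
    dups <- unique(proteins[duplicated(proteins)])
    stop("duplicate protein identifier(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- names(tab)[-1]
  unknown <- setdiff(sample_ids, meta$sample_id)
  if (length(unknown)) {
    stop("sample(s) in abundance table absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(meta$sample_id, sample_ids)
  if (length(extra)) {
    warning("metadata row(s) without abundance column dropped: ",
            paste(extra, collapse = ", "), call. = FALSE)
    meta <- filter(meta, .data$sample_id %in% sample_ids)
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  mat <- as.matrix(tab[-1])
  abundance_study(proteins, meta, mat)
}

#' Write an abundance study to delimited text
#'
#' Inverse of [read_abundance()]: missing values are written as empty cells
#' so a round trip preserves the missing/zero distinction.
#'
#' @param study An [abundance_study()].
#' @param path,meta_path Output paths for the intensity table and metadata.
#' @param delim Field delimiter (default tab).
#' @return `study`, invisibly.
#' @export
write_abundance <- function(study, path, meta_path, delim = "\t") {
  stopifnot(inherits(study, "abundance_study"))
  tab <- as_tibble(study$intensities, rownames = "protein")
  readr::write_delim(tab, path, delim = delim, na = "")
  readr::write_delim(study$samples, meta_path, delim = delim, na = "")
  invisible(study)
}

#' Read a reference protein list
#'
#' One identifier per line; `#` starts a comment (whole-line or trailing);
#' blank lines are skipped. Identifiers are case-normalized and
#' de-duplicated; the number of duplicates dropped is recorded.
#'
#' @param path Path to the list file.
#' @param name Short name for the list (e.g. `"transmembrane"`).
#' @param provenance Optional free-text provenance note.
#' @return An object of class `reference_list` with fields `name`, `members`
#'   (sorted unique identifiers), `provenance`, `n_duplicates`.
#' @export
read_reference_list <- function(path, name, provenance = "") {
  if (!file.exists(path)) stop("reference list not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  ids <- normalize_ids(lines)
  ids <- ids[nzchar(ids)]
  if (!length(ids)) {
    stop("reference list '", name, "' is empty after parsing: ", path,
         call. = FALSE)
  }
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0) {
    message("reference list '", name, "': dropped ", n_dup, " duplicate id(s)")
  }
  reference_list(name, unique(ids), provenance, n_duplicates = n_dup)
}

#' Construct a reference list in code
#'
#' @param name Short name.
#' @param members Character vector of identifiers (normalized, de-duplicated).
#' @param provenance Free-text provenance.
#' @param n_duplicates Number of duplicates dropped during parsing.
#' @return A `reference_list`.
#' @export
reference_list <- function(name, members, provenance = "", n_duplicates = 0L) {
  members <- sort(unique(normalize_ids(members)))
  if (!length(members)) stop("reference list must be non-empty", call. = FALSE)
  structure(
    list(name = name, members = members, provenance = provenance,
         n_duplicates = as.integer(n_duplicates)),
    class = "reference_list"
  )
}

#' @export
print.reference_list <- function(x, ...) {
  cat("<reference_list> '", x$name, "': ", length(x$members), " members\n",
      sep = "")
  invisible(x)
}

#' Write a reference list to plain text
#'
#' @param x A `reference_list` or character vector.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_reference_list <- function(x, path) {
  readr::write_lines(as_members(x), path)
  invisible(x)
}

#' Read a marker-panel intensity table
#'
#' A samples x markers table of positive fluorescence readouts with a
#' `sample_id` column and a `label` column (case/control or cancer type);
#' all remaining columns are marker intensities.
#'
#' @param path Path to the panel file (CSV or TSV).
#' @param delim Optional explicit delimiter.
#' @param label_col Name of the label column (default `"label"`).
#' @return A tibble with columns `sample_id`, the label column, and one
#'   numeric column per marker.
#' @export
read_marker_panel <- function(path, delim = NULL, label_col = "label") {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  d <- delim %||% detect_delim(path)
  panel <- readr::read_delim(path, delim = d, na = c("", "NA"),
                             show_col_types = FALSE, progress = FALSE)
  validate_marker_panel(panel, label_col = label_col)
  panel
}

#' Write a marker panel to delimited text
#'
#' @param panel Marker-panel tibble.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `panel`, invisibly.
#' @export
write_marker_panel <- function(panel, path, delim = "\t") {
  readr::write_delim(panel, path, delim = delim, na = "")
  invisible(panel)
}

# Validate the samples x markers panel layout; returns marker names.
validate_marker_panel <- function(panel, label_col = "label",
                                  markers = NULL) {
  if (!is.data.frame(panel)) stop("panel must be a data frame", call. = FALSE)
  if (!label_col %in% names(panel)) {
    stop("panel is missing the label column '", label_col, "'", call. = FALSE)
  }
  found <- setdiff(names(panel), c("sample_id", label_col))
  if (is.null(markers)) markers <- found
  missing <- setdiff(markers, found)
  if (length(missing)) {
    stop("panel is missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(unique(panel[[label_col]])) < 2) {
    stop("panel labels must cover at least two classes", call. = FALSE)
  }
  markers
}

#' Write a filter trace
#'
#' Writes the machine-readable trace as JSON lines (one record per stage:
#' stage name, rule parameters, n_in, n_out, dropped identifiers) and a
#' human-readable TSV summary of the stage counts next to it
#' (`<path>.summary.tsv`).
#'
#' @param trace A `filter_trace` from [run_filter_pipeline()].
#' @param path Output path for the JSON-lines trace.
#' @return `path`, invisibly.
#' @export
write_filter_trace <- function(trace, path) {
  stopifnot(inherits(trace, "filter_trace"))
  if (!nrow(trace$stages)) stop("cannot write an empty trace", call. = FALSE)
  records <- lapply(seq_len(nrow(trace$stages)), function(i) {
    row <- trace$stages[i, ]
    jsonlite::toJSON(
      list(stage = row$stage, params = row$params[[1]],
           n_in = row$n_in, n_out = row$n_out,
           dropped = row$dropped[[1]]),
      auto_unbox = TRUE, null = "null", digits = NA
    )
  })
  writeLines(unlist(records), path)
  readr::write_tsv(tidy(trace), paste0(path, ".summary.tsv"))
  invisible(path)
}

#' Read a filter trace written by [write_filter_trace()]
#'
#' @param path Path to the JSON-lines trace.
#' @return Tibble with one row per stage: `stage`, `n_in`, `n_out`,
#'   `n_dropped`, plus list-columns `params` and `dropped`.
#' @export
read_filter_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("trace file is empty: ", path, call. = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble(
    stage = map_chr(recs, "stage"),
    n_in = map_int(recs, ~ as.integer(.x$n_in)),
    n_out = map_int(recs, ~ as.integer(.x$n_out)),
    n_dropped = map_int(recs, ~ length(.x$dropped)),
    params = map(recs, "params"),
    dropped = map(recs, ~ as.character(.x$dropped))
  )
}
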