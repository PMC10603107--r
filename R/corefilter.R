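#' Replicate-detection rule
#'
#' A protein counts as detected in a unit (one cell line or one tissue set)
#' when it has a non-missing, nonzero intensity in at least the required
#' number of that unit's replicates. Defaults follow the discovery design:
#' 2 of 3 biological replicates for HGSOC cell lines, 2 of 2 for FT cell
#' lines, and all replicates for tissue-explant sets.
#'
#' @param min_reps_hgsoc_cell,min_reps_ft_cell Minimum detected replicates
#'   for cell-line units of each lineage.
#' @param tissue_rule Currently only `"all_replicates"`.
#' @return A `detection_rule` list.
#' @export
detection_rule <- function(min_reps_hgsoc_cell = 2L, min_reps_ft_cell = 2L,
                           tissue_rule = "all_replicates") {
  tissue_rule <- match.arg(tissue_rule, "all_replicates")
  stopifnot(min_reps_hgsoc_cell >= 1, min_reps_ft_cell >= 1)
  structure(
    list(min_reps_hgsoc_cell = as.integer(min_reps_hgsoc_cell),
         min_reps_ft_cell = as.integer(min_reps_ft_cell),
         tissue_rule = tissue_rule),
    class = "detection_rule"
  )
}

#' Configuration of the candidate-selection cascade
#'
#' @param detection A [detection_rule()].
#' @param log2fc_threshold Retain proteins with log2 fold change
#'   (carcinoma over healthy lineage) at or above this value; the default
#'   -0.58 keeps proteins present in the healthy lineage that hold steady or
#'   rise with disease. The boundary is inclusive.
#' @param pseudocount Positive value added to both group means before the
#'   log ratio, guarding against zero means. On the total-intensity
#'   normalized scale the default 1 is negligible for detected proteins.
#' @param cell_aggregation How to combine the detected sets of a lineage's
#'   cell lines before intersecting with its tissue set: `"union"`
#'   (default; a protein found in any cell line of the lineage counts) or
#'   `"intersection"`.
#' @param fc_basis Samples used for the fold-change means: `"pooled"`
#'   (default, all samples of each lineage), `"tissue"`, or `"cell_line"`.
#' @param normalize Apply per-sample total-intensity normalization before
#'   fold changes (default `TRUE`).
#' @param tm_list,common_ev_list,exclusion_list [reference_list()]s (or
#'   character vectors): predicted-transmembrane proteins, top common
#'   EV-associated proteins, and manual exclusions.
#' @return A `filter_config` list.
#' @export
filter_config <- function(detection = detection_rule(),
                          log2fc_threshold = -0.58,
                          pseudocount = 1,
                          cell_aggregation = c("union", "intersection"),
                          fc_basis = c("pooled", "tissue", "cell_line"),
                          normalize = TRUE,
                          tm_list = NULL, common_ev_list = NULL,
                          exclusion_list = NULL) {
  stopifnot(pseudocount > 0)
  structure(
    list(detection = detection,
         log2fc_threshold = log2fc_threshold,
         pseudocount = pseudocount,
         cell_aggregation = match.arg(cell_aggregation),
         fc_basis = match.arg(fc_basis),
         normalize = normalize,
         tm_list = tm_list, common_ev_list = common_ev_list,
         exclusion_list = exclusion_list),
    class = "filter_config"
  )
}

#' Per-sample total-intensity normalization
#'
#' Rescales every sample so its total (non-missing) intensity equals the
#' median sample total, removing loading differences before fold-change
#' computation. Missing values stay missing.
#'
#' @param study An [abundance_study()].
#' @return The study with normalized intensities.
#' @export
normalize_total <- function(study) {
  stopifnot(inherits(study, "abundance_study"))
  totals <- colSums(study$intensities, na.rm = TRUE)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(names(totals)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  study$intensities <- sweep(study$intensities, 2, median(totals) / totals, "*")
  study
}

#' Proteins detected in one unit under the replicate rule
#'
#' @param study An [abundance_study()].
#' @param unit A `line_or_patient` value identifying one cell line or one
#'   tissue-explant set.
#' @param rule A [detection_rule()].
#' @return Sorted character vector of detected protein identifiers.
#' @export
detected_set <- function(study, unit, rule = detection_rule()) {
  stopifnot(inherits(study, "abundance_study"))
  idx <- which(study$samples$line_or_patient == unit)
  if (!length(idx)) stop("unit has zero samples: ", unit, call. = FALSE)
  group <- unique(study$samples$group[idx])
  source <- unique(study$samples$source[idx])
  if (length(group) != 1L || length(source) != 1L) {
    stop("unit '", unit, "' mixes groups or sources", call. = FALSE)
  }
  n_reps <- length(idx)
  min_req <- if (source == "tissue") {
    n_reps
  } else if (group == "FT") {
    rule$min_reps_ft_cell
  } else {
    rule$min_reps_hgsoc_cell
  }
  if (min_req > n_reps) {
    stop("detection rule requires ", min_req, " replicates but unit '",
         unit, "' has ", n_reps, call. = FALSE)
  }
  m <- study$intensities[, idx, drop = FALSE]
  hits <- rowSums(!is.na(m) & m > 0)
  sort(study$proteins[hits >= min_req])
}

#' Lineage protein set: cell lines combined, then anchored in tissue
#'
#' The lineage set of a group is the combination of its cell-line detected
#' sets (union by default) intersected with the union of its tissue-explant
#' detected sets (all-replicates rule), so every member has evidence both in
#' culture and in tissue.
#'
#' @param study An [abundance_study()].
#' @param group `"FT"` or `"HGSOC"`.
#' @param rule A [detection_rule()].
#' @param cell_aggregation `"union"` or `"intersection"` across the group's
#'   cell lines.
#' @return Sorted character vector of protein identifiers.
#' @export
lineage_set <- function(study, group, rule = detection_rule(),
                        cell_aggregation = c("union", "intersection")) {
  cell_aggregation <- match.arg(cell_aggregation)
  units <- study_units(study) |> filter(.data$group == !!group)
  cells <- units$line_or_patient[units$source == "cell_line"]
  tissues <- units$line_or_patient[units$source == "tissue"]
  if (!length(cells) || !length(tissues)) {
    stop("group ", group, " needs at least one cell-line and one tissue unit",
         call. = FALSE)
  }
  cell_sets <- lapply(cells, detected_set, study = study, rule = rule)
  cell_combined <- Reduce(
    if (cell_aggregation == "union") union else intersect, cell_sets
  )
  tissue_combined <- Reduce(union,
                            lapply(tissues, detected_set, study = study,
                                   rule = rule))
  sort(intersect(cell_combined, tissue_combined))
}

#' Core proteome: proteins shared by both lineages
#'
#' @param ft_set,hgsoc_set Protein sets from [lineage_set()].
#' @return Sorted intersection; warns if empty.
#' @export
core_proteome <- function(ft_set, hgsoc_set) {
  if (!length(ft_set) || !length(hgsoc_set)) {
    stop("both lineage sets must be non-empty", call. = FALSE)
  }
  out <- sort(intersect(ft_set, hgsoc_set))
  if (!length(out)) warning("core proteome is empty", call. = FALSE)
  out
}

#' Keep only predicted transmembrane proteins
#'
#' @param core Protein set.
#' @param tm A [reference_list()] (or character vector) of known or
#'   predicted transmembrane proteins.
#' @return Sorted intersection.
#' @export
transmembrane_filter <- function(core, tm) {
  members <- as_members(tm)
  if (!length(members)) stop("transmembrane list is empty", call. = FALSE)
  sort(intersect(normalize_ids(core), members))
}

#' Remove ubiquitous EV proteins
#'
#' @param s Protein set.
#' @param common A [reference_list()] (or character vector) of common
#'   EV-associated proteins (e.g. a top-100 list).
#' @return Sorted set difference.
#' @export
subtract_common_ev <- function(s, common) {
  sort(setdiff(normalize_ids(s), as_members(common)))
}

# Vectorized lineage-mean log2 fold change for a set of proteins.
log2_fold_changes <- function(study, proteins, cfg = filter_config()) {
  proteins <- normalize_ids(proteins)
  absent <- setdiff(proteins, study$proteins)
  if (length(absent)) {
    stop("protein(s) absent from study: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(cfg$normalize)) study <- normalize_total(study)
  keep <- if (cfg$fc_basis == "pooled") {
    rep(TRUE, nrow(study$samples))
  } else {
    study$samples$source == cfg$fc_basis
  }
  group_mean <- function(group) {
    cols <- keep & study$samples$group == group
    m <- study$intensities[proteins, cols, drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    mu[is.nan(mu)] <- 0      # all-missing: treat the lineage mean as 0
    mu
  }
  lfc <- log2((group_mean("HGSOC") + cfg$pseudocount) /
              (group_mean("FT") + cfg$pseudocount))
  setNames(lfc, proteins)
}

#' Log2 fold change of one protein between lineages
#'
#' `log2((mean HGSOC + pseudocount) / (mean FT + pseudocount))`, with means
#' over non-missing intensities of the configured sample basis (pooled cell
#' lines and tissues by default), after per-sample total-intensity
#' normalization when `cfg$normalize` is `TRUE`.
#'
#' @param study An [abundance_study()].
#' @param protein Protein identifier.
#' @param cfg A [filter_config()].
#' @return Numeric scalar.
#' @export
log2_fold_change <- function(study, protein, cfg = filter_config()) {
  unname(log2_fold_changes(study, protein, cfg))
}

#' Fold-change filter and ranking
#'
#' Retains proteins whose log2 fold change meets `cfg$log2fc_threshold`
#' (boundary inclusive) and ranks them by decreasing fold change, ties
#' broken lexicographically by identifier.
#'
#' @param s Protein set to evaluate.
#' @param study An [abundance_study()].
#' @param cfg A [filter_config()].
#' @return Tibble with columns `protein`, `log2fc`, sorted by rank.
#' @export
fold_change_filter <- function(s, study, cfg = filter_config()) {
  if (!length(s)) return(tibble(protein = character(), log2fc = double()))
  lfc <- log2_fold_changes(study, s, cfg)
  out <- tibble(protein = names(lfc), log2fc = unname(lfc)) |>
    filter(.data$log2fc >= cfg$log2fc_threshold) |>
    arrange(desc(.data$log2fc), .data$protein)
  out
}

new_filter_trace <- function(stages, final_ranked) {
  stopifnot(all(stages$n_out <= stages$n_in))
  structure(list(stages = stages, final_ranked = final_ranked),
            class = "filter_trace")
}

#' Run the full candidate-selection cascade
#'
#' Executes, in order: per-unit detection, lineage sets (cell lines
#' anchored in tissue), core proteome (FT `\U2229` HGSOC), transmembrane
#' intersection, common-EV subtraction, fold-change filter, and manual
#' exclusion. Every stage is recorded with its parameters, input/output
#' counts, and dropped identifiers.
#'
#' @param study An [abundance_study()].
#' @param cfg A [filter_config()] whose `tm_list` and `common_ev_list` are
#'   set (`exclusion_list` may be `NULL` for no manual exclusions).
#' @return A `filter_trace`: `$stages` (tibble of stage records) and
#'   `$final_ranked` (tibble `protein`, `log2fc` of surviving candidates).
#' @export
run_filter_pipeline <- function(study, cfg = filter_config()) {
  stopifnot(inherits(study, "abundance_study"))
  if (is.null(cfg$tm_list) || is.null(cfg$common_ev_list)) {
    stop("cfg$tm_list and cfg$common_ev_list must be provided", call. = FALSE)
  }
  units <- study_units(study)
  all_proteins <- sort(study$proteins)
  detected_any <- sort(Reduce(union, lapply(
    units$line_or_patient, detected_set, study = study, rule = cfg$detection
  )))
  ft <- lineage_set(study, "FT", cfg$detection, cfg$cell_aggregation)
  hg <- lineage_set(study, "HGSOC", cfg$detection, cfg$cell_aggregation)
  core <- core_proteome(ft, hg)
  tm <- transmembrane_filter(core, cfg$tm_list)
  after_ev <- subtract_common_ev(tm, cfg$common_ev_list)
  ranked <- fold_change_filter(after_ev, study, cfg)
  fc_set <- ranked$protein
  excl <- if (is.null(cfg$exclusion_list)) character() else
    as_members(cfg$exclusion_list)
  final_ranked <- filter(ranked, !.data$protein %in% excl)
  final_set <- final_ranked$protein

  stage <- function(name, params, set_in, set_out) {
    tibble(stage = name, params = list(params),
           n_in = length(set_in), n_out = length(set_out),
           dropped = list(sort(setdiff(set_in, set_out))),
           set_out = list(set_out))
  }
  stages <- bind_rows(
    stage("detected_any_unit",
          list(min_reps_hgsoc_cell = cfg$detection$min_reps_hgsoc_cell,
               min_reps_ft_cell = cfg$detection$min_reps_ft_cell,
               tissue_rule = cfg$detection$tissue_rule),
          all_proteins, detected_any),
    stage("core_proteome",
          list(cell_aggregation = cfg$cell_aggregation,
               n_ft_lineage = length(ft), n_hgsoc_lineage = length(hg)),
          detected_any, core),
    stage("transmembrane", list(list = cfg$tm_list$name %||% "tm"),
          core, tm),
    stage("common_ev_removed",
          list(list = cfg$common_ev_list$name %||% "common_ev"),
          tm, after_ev),
    stage("fold_change",
          list(log2fc_threshold = cfg$log2fc_threshold,
               pseudocount = cfg$pseudocount, basis = cfg$fc_basis,
               normalized = isTRUE(cfg$normalize)),
          after_ev, fc_set),
    stage("manual_exclusion", list(excluded = excl), fc_set, final_set)
  )
  new_filter_trace(stages, final_ranked)
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("<filter_trace> ", nrow(x$stages), " stages, ",
      nrow(x$final_ranked), " final candidates\n", sep = "")
  print(select(x$stages, "stage", "n_in", "n_out"))
  invisible(x)
}

#' Tidy a filter trace into a stage-count tibble
#'
#' @param x A `filter_trace`.
#' @param ... Unused.
#' @return Tibble with `stage`, `n_in`, `n_out`, `n_dropped`.
#' @export
tidy.filter_trace <- function(x, ...) {
  x$stages |>
    mutate(n_dropped = .data$n_in - .data$n_out) |>
    select("stage", "n_in", "n_out", "n_dropped")
}
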