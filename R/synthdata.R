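#' Configuration for the synthetic abundance study
#'
#' Membership is planted first (which proteins survive each stage of the
#' filtering cascade), intensities second, so the cascade's set logic is
#' exactly verifiable. Defaults mirror the discovery study's design and
#' flow: 3 FT cell lines (2 replicates), 6 HGSOC cell lines (3
#' replicates), tissue-explant sets of 6 (FT), 9 (primary tumor) and 6
#' (omental metastasis), lineage sets of 1193 (FT) and 1309 (HGSOC)
#' proteins whose intersection of 985 narrows to 75 transmembrane, 66
#' after common-EV subtraction, 47 past the fold-change filter, and 45
#' after manual exclusion.
#'
#' @param n_shared_core Proteins planted in both lineage sets.
#' @param n_ft_only,n_hgsoc_only Proteins planted in exactly one lineage.
#' @param n_cellline_only_per_group,n_tissue_only_per_group Proteins
#'   detected only in a group's cell lines (resp. tissue), hence excluded
#'   from its lineage set.
#' @param n_tm_in_core Core proteins on the transmembrane list.
#' @param n_common_ev_in_tm Of those, members of the common-EV list.
#' @param n_fc_pass Proteins passing the fold-change filter (subset of the
#'   transmembrane, non-common-EV core).
#' @param n_excluded Fold-change passers placed on the manual exclusion
#'   list.
#' @param detection_dropout Probability that one replicate of a detected
#'   3-replicate cell-line unit is missing; applied only where it cannot
#'   break the planted detection rules.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity
#'   parameters: per-protein base abundance `meanlog` and per-replicate
#'   noise `sdlog`. The default noise (0.25) keeps realized fold changes
#'   within ~0.15 log2 units of their planted targets, far inside the
#'   planted margin around the -0.58 threshold.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An `abundance_sim_config` list.
#' @export
abundance_sim_config <- function(n_shared_core = 985L,
                                 n_ft_only = 208L,
                                 n_hgsoc_only = 324L,
                                 n_cellline_only_per_group = 150L,
                                 n_tissue_only_per_group = 120L,
                                 n_tm_in_core = 75L,
                                 n_common_ev_in_tm = 9L,
                                 n_fc_pass = 47L,
                                 n_excluded = 2L,
                                 detection_dropout = 0.05,
                                 intensity_meanlog = log(1e6),
                                 intensity_sdlog = 0.25,
                                 seed = 1L) {
  cfg <- list(n_shared_core = as.integer(n_shared_core),
              n_ft_only = as.integer(n_ft_only),
              n_hgsoc_only = as.integer(n_hgsoc_only),
              n_cellline_only_per_group = as.integer(n_cellline_only_per_group),
              n_tissue_only_per_group = as.integer(n_tissue_only_per_group),
              n_tm_in_core = as.integer(n_tm_in_core),
              n_common_ev_in_tm = as.integer(n_common_ev_in_tm),
              n_fc_pass = as.integer(n_fc_pass),
              n_excluded = as.integer(n_excluded),
              detection_dropout = detection_dropout,
              intensity_meanlog = intensity_meanlog,
              intensity_sdlog = intensity_sdlog,
              seed = as.integer(seed))
  if (any(unlist(cfg[1:9]) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$n_tm_in_core > cfg$n_shared_core ||
      cfg$n_common_ev_in_tm > cfg$n_tm_in_core ||
      cfg$n_fc_pass > cfg$n_tm_in_core - cfg$n_common_ev_in_tm ||
      cfg$n_excluded > cfg$n_fc_pass) {
    stop("inconsistent nesting of planted stage counts", call. = FALSE)
  }
  if (detection_dropout < 0 || detection_dropout > 1) {
    stop("detection_dropout must be a probability", call. = FALSE)
  }
  structure(cfg, class = "abundance_sim_config")
}

# The fixed sample design of the synthetic study.
synth_sample_design <- function() {
  units <- bind_rows(
    tibble(line_or_patient = c("FT240", "FT246", "FT282"),
           group = "FT", source = "cell_line", n_reps = 2L),
    tibble(line_or_patient = c("OVCAR2", "OVCAR3", "OVCAR4", "OVCAR8",
                               "PEO1", "PEO4"),
           group = "HGSOC", source = "cell_line", n_reps = 3L),
    tibble(line_or_patient = "FT_TISSUE",
           group = "FT", source = "tissue", n_reps = 6L),
    tibble(line_or_patient = c("HGSOC_TUMOR", "HGSOC_OMENTUM"),
           group = "HGSOC", source = "tissue", n_reps = c(9L, 6L))
  )
  samples <- units |>
    dplyr::rowwise() |>
    dplyr::reframe(
      sample_id = paste0(.data$line_or_patient, "_R",
                         seq_len(.data$n_reps)),
      group = .data$group, source = .data$source,
      line_or_patient = .data$line_or_patient,
      replicate_index = seq_len(.data$n_reps)
    )
  samples
}

#' Generate a study-shaped abundance table with planted ground truth
#'
#' Builds an [abundance_study()] over the fixed study design (3 FT cell
#' lines x 2 replicates, 6 HGSOC cell lines x 3, three tissue sets) in
#' which every protein's fate through the filtering cascade is planted:
#' lineage membership by presence/absence, fold-change outcome by lineage
#' mean intensities with a wide margin around the -0.58 log2 threshold
#' (passers drawn in \[0, 3\], failers in \[-3, -1.2\]). Matching
#' transmembrane, common-EV, and exclusion reference lists are emitted.
#' Replicate dropout is applied only to 3-replicate cell-line units, where
#' the 2-of-3 rule tolerates it.
#'
#' @param cfg An [abundance_sim_config()].
#' @return List with `study` (an [abundance_study()]), `truth` (planted
#'   stage sets: `lineage_ft`, `lineage_hgsoc`, `core`, `tm`, `after_ev`,
#'   `fc_pass`, `final`), and the reference lists `tm_list`,
#'   `common_ev_list`, `exclusion_list`.
#' @export
generate_abundance_study <- function(cfg = abundance_sim_config()) {
  stopifnot(inherits(cfg, "abundance_sim_config"))
  set.seed(cfg$seed)
  samples <- synth_sample_design()

  n_core <- cfg$n_shared_core
  categories <- c(rep("core", n_core),
                  rep("ft_only", cfg$n_ft_only),
                  rep("hgsoc_only", cfg$n_hgsoc_only),
                  rep("ft_cell_only", cfg$n_cellline_only_per_group),
                  rep("hgsoc_cell_only", cfg$n_cellline_only_per_group),
                  rep("ft_tissue_only", cfg$n_tissue_only_per_group),
                  rep("hgsoc_tissue_only", cfg$n_tissue_only_per_group))
  n_prot <- length(categories)
  proteins <- sprintf("P%05d", seq_len(n_prot))

  # Planted cascade membership inside the core block.
  core_ids <- proteins[seq_len(n_core)]
  tm_core <- core_ids[seq_len(cfg$n_tm_in_core)]
  common_ev_core <- tm_core[seq_len(cfg$n_common_ev_in_tm)]
  fc_candidates <- setdiff(tm_core, common_ev_core)        # the "66"
  fc_pass <- fc_candidates[seq_len(cfg$n_fc_pass)]
  excluded <- fc_pass[seq_len(cfg$n_excluded)]
  final <- setdiff(fc_pass, excluded)

  # Which units detect which proteins.
  detect_in <- function(cat, group, source) {
    switch(cat,
      core = TRUE,
      ft_only = group == "FT",
      hgsoc_only = group == "HGSOC",
      ft_cell_only = group == "FT" & source == "cell_line",
      hgsoc_cell_only = group == "HGSOC" & source == "cell_line",
      ft_tissue_only = group == "FT" & source == "tissue",
      hgsoc_tissue_only = group == "HGSOC" & source == "tissue")
  }

  # Lineage mean planting: fold-change targets only matter for the 66
  # candidates; everything else gets a mild random lineage shift.
  base_mu <- rnorm(n_prot, cfg$intensity_meanlog, 0.5)
  target_l2fc <- runif(n_prot, -0.5, 0.5)
  target_l2fc[match(fc_pass, proteins)] <-
    runif(length(fc_pass), 0, 3)
  target_l2fc[match(setdiff(fc_candidates, fc_pass), proteins)] <-
    runif(length(fc_candidates) - length(fc_pass), -3, -1.2)
  mu_ft <- base_mu
  mu_hg <- base_mu + target_l2fc * log(2)

  ints <- matrix(NA_real_, n_prot, nrow(samples),
                 dimnames = list(proteins, samples$sample_id))
  unit_tab <- samples |>
    distinct(.data$line_or_patient, .data$group, .data$source)
  for (u in seq_len(nrow(unit_tab))) {
    unit <- unit_tab$line_or_patient[u]
    grp <- unit_tab$group[u]
    src <- unit_tab$source[u]
    cols <- which(samples$line_or_patient == unit)
    n_reps <- length(cols)
    detected <- vapply(categories, detect_in, NA, group = grp, source = src)
    mu <- if (grp == "FT") mu_ft else mu_hg
    for (j in cols) {
      vals <- exp(rnorm(n_prot, mu, cfg$intensity_sdlog))
      vals[!detected] <- NA_real_
      ints[, j] <- vals
    }
    # Sub-threshold presence: a non-detected protein may still appear in
    # min_required - 1 replicates, exercising (not breaking) the rule.
    min_req <- if (src == "tissue") n_reps else 2L
    sub <- which(!detected & runif(n_prot) < 0.3)
    if (length(sub) && min_req >= 2L) {
      reps_present <- sample(cols, min_req - 1L)
      for (j in reps_present) {
        ints[sub, j] <- exp(rnorm(length(sub), mu[sub], cfg$intensity_sdlog))
      }
    }
    # Dropout: only 3-replicate cell-line units can lose one replicate
    # without breaking the 2-of-3 rule.
    if (src == "cell_line" && n_reps >= 3L && cfg$detection_dropout > 0) {
      drop_prot <- which(detected & runif(n_prot) < cfg$detection_dropout)
      if (length(drop_prot)) {
        drop_col <- sample(cols, length(drop_prot), replace = TRUE)
        ints[cbind(drop_prot, drop_col)] <- NA_real_
      }
    }
  }

  study <- abundance_study(proteins, samples, ints)

  ft_only_ids <- proteins[categories == "ft_only"]
  hg_only_ids <- proteins[categories == "hgsoc_only"]
  # Reference lists: planted members plus decoys outside the core.
  tm_extra <- c(head(hg_only_ids, 40), sprintf("TMX%03d", 1:30))
  ev_extra <- sprintf("EVX%03d", seq_len(100 - length(common_ev_core)))
  truth <- list(
    lineage_ft = sort(c(core_ids, ft_only_ids)),
    lineage_hgsoc = sort(c(core_ids, hg_only_ids)),
    core = sort(core_ids),
    tm = sort(tm_core),
    after_ev = sort(fc_candidates),
    fc_pass = sort(fc_pass),
    final = sort(final)
  )
  list(
    study = study,
    truth = truth,
    tm_list = reference_list("transmembrane", c(tm_core, tm_extra),
                             "synthetic predicted-transmembrane list"),
    common_ev_list = reference_list("common_ev",
                                    c(common_ev_core, ev_extra),
                                    "synthetic top-100 common-EV list"),
    exclusion_list = if (length(excluded)) {
      reference_list("manual_exclusion", excluded,
                     "synthetic manual exclusions")
    } else {
      NULL
    }
  )
}

#' Configuration for synthetic marker panels
#'
#' Chip fluorescence intensities are modeled log-normally: controls
#' `exp(N(mu0, sd0))`, cases `exp(N(mu0 + delta, sd1))`, so each marker's
#' true AUC is `Phi(delta / sqrt(sd0^2 + sd1^2))` in closed form. Default
#' markers reproduce the seven-marker panel at its published single-marker
#' AUCs via `delta = sqrt(2) * qnorm(AUC)`; default sizes are 10 cases and
#' 20 controls.
#'
#' @param n_cases,n_controls Group sizes (each >= 2).
#' @param markers Tibble with columns `name`, `delta`, `sd0`, `sd1` (log
#'   scale). Default: the seven-marker panel.
#' @param mu0 Control log-mean fluorescence (default `log(2000)`).
#' @param background_level Nominal background fluorescence recorded with
#'   the panel (default 500, not subtracted).
#' @param n_cancer_types Number of non-ovarian cancer types for
#'   [generate_multicancer_panel()] (default 12, 5 samples each).
#' @param seed Integer seed.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_cases = 10L, n_controls = 20L,
                             markers = default_panel_markers(),
                             mu0 = log(2000), background_level = 500,
                             n_cancer_types = 12L, seed = 1L) {
  markers <- as_tibble(markers)
  stopifnot(all(c("name", "delta", "sd0", "sd1") %in% names(markers)),
            all(markers$sd0 > 0), all(markers$sd1 > 0),
            n_cases >= 2, n_controls >= 2)
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         markers = markers, mu0 = mu0, background_level = background_level,
         n_cancer_types = as.integer(n_cancer_types), seed = as.integer(seed)),
    class = "panel_sim_config"
  )
}

#' Default seven-marker panel definition
#'
#' Log-scale mean shifts chosen so the true AUCs equal the published
#' single-marker values (unit variances in both groups).
#'
#' @return Tibble with columns `name`, `delta`, `sd0`, `sd1`, `true_auc`.
#' @export
default_panel_markers <- function() {
  aucs <- c(IGSF8 = 0.895, ITGA2 = 0.885, MYOF = 0.850, ACSL4 = 0.915,
            ITGB3 = 0.980, ITGA5 = 0.950, FOLR1 = 0.925)
  tibble(name = names(aucs),
         delta = sqrt(2) * qnorm(unname(aucs)),
         sd0 = 1, sd1 = 1,
         true_auc = unname(aucs))
}

#' Generate a synthetic case/control marker panel
#'
#' @param cfg A [panel_sim_config()].
#' @return List with `panel` (tibble: `sample_id`, `label`, one column per
#'   marker) and `truth` (tibble: `marker`, `delta`, `sd0`, `sd1`,
#'   `true_auc` where true AUC = `Phi(delta / sqrt(sd0^2 + sd1^2))`).
#' @export
generate_marker_panel <- function(cfg = panel_sim_config()) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cases + cfg$n_controls
  panel <- tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    label = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  )
  for (i in seq_len(nrow(cfg$markers))) {
    m <- cfg$markers[i, ]
    panel[[m$name]] <- c(
      exp(rnorm(cfg$n_cases, cfg$mu0 + m$delta, m$sd1)),
      exp(rnorm(cfg$n_controls, cfg$mu0, m$sd0))
    )
  }
  truth <- cfg$markers |>
    mutate(true_auc = pnorm(.data$delta / sqrt(.data$sd0^2 + .data$sd1^2))) |>
    select(marker = "name", "delta", "sd0", "sd1", "true_auc")
  list(panel = panel, truth = truth)
}

#' Generate a multi-cancer specificity panel
#'
#' Emulates a cross-cancer specificity experiment: healthy controls and
#' ovarian cases drawn as in [generate_marker_panel()], plus
#' `n_cancer_types` non-ovarian cancer classes (5 samples each) drawn from
#' the control distribution shifted by `nonovarian_shift` (default 0, i.e.
#' non-ovarian cancers look like controls for these lineage markers).
#'
#' @param cfg A [panel_sim_config()].
#' @param nonovarian_shift Log-scale mean shift applied to all non-ovarian
#'   cancer classes (scalar or one per type).
#' @param n_per_type Samples per non-ovarian cancer type (default 5).
#' @return Tibble with `sample_id`, `label` (`"healthy"`, `"ovarian"`, or a
#'   cancer-type name), and one column per marker.
#' @export
generate_multicancer_panel <- function(cfg = panel_sim_config(),
                                       nonovarian_shift = 0,
                                       n_per_type = 5L) {
  stopifnot(inherits(cfg, "panel_sim_config"), cfg$n_cancer_types >= 1)
  set.seed(cfg$seed)
  types <- c("AML", "bladder", "DCIS", "IDC", "cervical", "colorectal",
             "DLBC", "lung", "melanoma", "pancreatic", "thyroid",
             "uterine")[seq_len(cfg$n_cancer_types)]
  if (cfg$n_cancer_types > 12) {
    types <- c(types, sprintf("cancer%02d", 13:cfg$n_cancer_types))
  }
  shift <- rep_len(nonovarian_shift, length(types))
  labels <- c(rep(types, each = n_per_type),
              rep("ovarian", cfg$n_cases),
              rep("healthy", cfg$n_controls))
  n <- length(labels)
  panel <- tibble(sample_id = sprintf("S%03d", seq_len(n)), label = labels)
  for (i in seq_len(nrow(cfg$markers))) {
    m <- cfg$markers[i, ]
    mu <- rep(cfg$mu0, n)
    sdv <- rep(m$sd0, n)
    mu[labels == "ovarian"] <- cfg$mu0 + m$delta
    sdv[labels == "ovarian"] <- m$sd1
    for (t in seq_along(types)) {
      mu[labels == types[t]] <- cfg$mu0 + shift[t]
    }
    panel[[m$name]] <- exp(rnorm(n, mu, sdv))
  }
  panel
}
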