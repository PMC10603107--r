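# Fixtures are built in code; no data files.

# A 4-protein x 6-sample study with deliberate NA (missing) and 0 cells.
make_tiny_study <- function() {
  samples <- tibble::tibble(
    sample_id = c("F1_R1", "F1_R2", "H1_R1", "H1_R2", "H1_R3", "HT_R1"),
    group = c("FT", "FT", "HGSOC", "HGSOC", "HGSOC", "HGSOC"),
    source = c("cell_line", "cell_line", "cell_line", "cell_line",
               "cell_line", "tissue"),
    line_or_patient = c("F1", "F1", "H1", "H1", "H1", "HT"),
    replicate_index = c(1L, 2L, 1L, 2L, 3L, 1L)
  )
  m <- matrix(c(
    10, 12,  20, 22, 18,  30,
    NA,  5,   0,  7,  9,  11,
     3,  0,  NA, NA,  4,   0,
    NA, NA,   6,  8, NA,   9
  ), nrow = 4, byrow = TRUE)
  abundance_study(c("ALPHA", "BETA", "GAMMA", "DELTA"), samples, m)
}

# Build a one-group study in which each unit's detected set is given
# exactly: detected proteins carry values in every replicate, the rest NA.
make_set_study <- function(unit_sets, proteins,
                           sources = NULL, n_reps = NULL, group = "HGSOC") {
  units <- names(unit_sets)
  if (is.null(sources)) sources <- rep("cell_line", length(units))
  if (is.null(n_reps)) n_reps <- rep(3L, length(units))
  samples <- NULL
  cols <- list()
  for (i in seq_along(units)) {
    ids <- paste0(units[i], "_R", seq_len(n_reps[i]))
    samples <- rbind(samples, data.frame(
      sample_id = ids, group = group, source = sources[i],
      line_or_patient = units[i], replicate_index = seq_len(n_reps[i])
    ))
    for (id in ids) {
      v <- rep(NA_real_, length(proteins))
      v[match(unit_sets[[i]], proteins)] <- 100
      cols[[id]] <- v
    }
  }
  m <- do.call(cbind, cols)
  abundance_study(proteins, samples, m)
}

# Small planted-cascade configuration used across tests (120 -> 30 -> 25
# -> 18 -> 16).
small_sim_config <- function(seed = 42L, dropout = 0.05) {
  abundance_sim_config(
    n_shared_core = 120L, n_ft_only = 30L, n_hgsoc_only = 40L,
    n_cellline_only_per_group = 20L, n_tissue_only_per_group = 15L,
    n_tm_in_core = 30L, n_common_ev_in_tm = 5L, n_fc_pass = 18L,
    n_excluded = 2L, detection_dropout = dropout, seed = seed
  )
}

# Fixed two-marker combination model built without fitting.
fixed_model <- function(markers = c("IGSF8", "ITGA5"),
                        coefficients = c(11.299, 14.935)) {
  structure(
    list(markers = markers,
         coefficients = stats::setNames(coefficients, markers),
         intercept = 0, log_likelihood = NA_real_, aic = NA_real_,
         n_obs = 0L, separation = FALSE, positive = "case"),
    class = "combination_model"
  )
}
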