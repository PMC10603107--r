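# Independent oracle: detection by explicit double loop over the matrix.
brute_detected <- function(study, unit, min_req = NULL) {
  idx <- which(study$samples$line_or_patient == unit)
  src <- unique(study$samples$source[idx])
  grp <- unique(study$samples$group[idx])
  if (is.null(min_req)) {
    min_req <- if (src == "tissue") length(idx) else 2L
  }
  out <- character()
  for (p in study$proteins) {
    hits <- 0L
    for (j in idx) {
      v <- study$intensities[p, j]
      if (!is.na(v) && v > 0) hits <- hits + 1L
    }
    if (hits >= min_req) out <- c(out, p)
  }
  sort(out)
}

test_that("detected_set applies the replicate rules and matches a brute-force oracle", {
  study <- make_tiny_study()
  # GAMMA: FT unit F1 has values (3, 0) -> only 1 nonzero of 2 -> excluded
  expect_false("GAMMA" %in% detected_set(study, "F1"))
  # BETA: H1 has (0, 7, 9) -> 2 of 3 nonzero -> included under min 2
  expect_true("BETA" %in% detected_set(study, "H1"))
  # DELTA: H1 has (6, 8, NA) -> 2 of 3 -> included; tissue HT (9) -> included
  expect_true("DELTA" %in% detected_set(study, "H1"))
  # GAMMA in tissue HT is a measured 0 -> not detected (all-replicates rule)
  expect_false("GAMMA" %in% detected_set(study, "HT"))
  expect_error(detected_set(study, "NOPE"), "zero samples")

  set.seed(101)
  proteins <- sprintf("Q%03d", 1:50)
  sim <- generate_abundance_study(small_sim_config(seed = 101))
  for (unit in study_units(sim$study)$line_or_patient) {
    expect_identical(detected_set(sim$study, unit),
                     brute_detected(sim$study, unit))
  }
})

test_that("lineage_set combines cell lines then anchors in tissue, both aggregation modes", {
  proteins <- c("A", "B", "C", "D")
  study <- make_set_study(
    list(CL1 = c("A", "B", "C"), CL2 = c("B", "C"), TIS = c("A", "B", "D")),
    proteins,
    sources = c("cell_line", "cell_line", "tissue"),
    n_reps = c(3L, 3L, 2L), group = "HGSOC"
  )
  expect_identical(lineage_set(study, "HGSOC", cell_aggregation = "union"),
                   c("A", "B"))
  expect_identical(
    lineage_set(study, "HGSOC", cell_aggregation = "intersection"), "B")
  # identical sets everywhere -> that set
  same <- make_set_study(
    list(CL1 = c("A", "B"), TIS = c("A", "B")), proteins,
    sources = c("cell_line", "tissue"), n_reps = c(3L, 2L), group = "FT"
  )
  expect_identical(lineage_set(same, "FT"), c("A", "B"))
  expect_error(lineage_set(study, "FT"), "at least one")
})

test_that("core proteome, transmembrane, and common-EV steps are exact set algebra", {
  expect_identical(core_proteome(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  expect_warning(out <- core_proteome("A", "B"), "empty")
  expect_length(out, 0)
  expect_error(core_proteome(character(), "A"), "non-empty")

  expect_identical(transmembrane_filter(c("A", "B"), c("B", "C")), "B")
  expect_identical(transmembrane_filter(c("A", "B"), c("A", "B", "C")),
                   c("A", "B"))
  expect_identical(subtract_common_ev(c("A", "B"), "B"), "A")
  expect_identical(subtract_common_ev(c("A", "B"), "Z"), c("A", "B"))
})

test_that("log2 fold change has its closed forms and matches direct arithmetic", {
  proteins <- c("X1", "X2")
  samples <- data.frame(
    sample_id = c("F_R1", "F_R2", "FT_T1", "H_R1", "H_R2", "H_R3", "HG_T1"),
    group = c("FT", "FT", "FT", "HGSOC", "HGSOC", "HGSOC", "HGSOC"),
    source = c("cell_line", "cell_line", "tissue",
               "cell_line", "cell_line", "cell_line", "tissue"),
    line_or_patient = c("F", "F", "FT_T", "H", "H", "H", "HG_T"),
    replicate_index = c(1L, 2L, 1L, 1L, 2L, 3L, 1L)
  )
  m <- rbind(c(50, 50, 50, 50, 50, 50, 50),      # equal means -> 0
             c(10, 10, 10, 20, 20, 20, 20))      # doubled -> 1
  study <- abundance_study(proteins, samples, m)
  cfg <- filter_config(pseudocount = 1e-9, normalize = FALSE)
  expect_equal(log2_fold_change(study, "X1", cfg), 0, tolerance = 1e-9)
  expect_equal(log2_fold_change(study, "X2", cfg), 1, tolerance = 1e-9)
  expect_error(log2_fold_change(study, "NOPE", cfg), "NOPE")

  # random fixture vs independent recomputation, with normalization on
  set.seed(7)
  sim <- generate_abundance_study(small_sim_config(seed = 7))
  st <- sim$study
  cfg2 <- filter_config(pseudocount = 1, normalize = TRUE)
  totals <- colSums(st$intensities, na.rm = TRUE)
  norm <- sweep(st$intensities, 2, stats::median(totals) / totals, "*")
  for (p in sample(sim$truth$after_ev, 5)) {
    mh <- mean(norm[p, st$samples$group == "HGSOC"], na.rm = TRUE)
    mf <- mean(norm[p, st$samples$group == "FT"], na.rm = TRUE)
    expect_equal(log2_fold_change(st, p, cfg2),
                 log2((mh + 1) / (mf + 1)), tolerance = 1e-12)
  }
})

test_that("fold-change filter is boundary-inclusive and ranks deterministically", {
  proteins <- c("PASS_HI", "PASS_EDGE", "FAIL_LO", "TIE_A", "TIE_B")
  samples <- data.frame(
    sample_id = c("F_R1", "F_R2", "H_R1", "H_R2"),
    group = c("FT", "FT", "HGSOC", "HGSOC"),
    source = "cell_line",
    line_or_patient = c("F", "F", "H", "H"),
    replicate_index = c(1L, 2L, 1L, 2L)
  )
  ft_val <- 99
  edge_h <- (ft_val + 1) * 2^-0.58 - 1     # exactly log2fc = -0.58
  m <- rbind(
    c(ft_val, ft_val, 300, 300),
    c(ft_val, ft_val, edge_h, edge_h),
    c(ft_val, ft_val, 40, 40),
    c(ft_val, ft_val, 200, 200),
    c(ft_val, ft_val, 200, 200)
  )
  study <- abundance_study(proteins, samples, m)
  cfg <- filter_config(pseudocount = 1, normalize = FALSE)
  edge_lfc <- log2_fold_change(study, "PASS_EDGE", cfg)
  expect_equal(edge_lfc, -0.58, tolerance = 1e-12)
  # boundary inclusive: a protein sitting exactly at the threshold is kept
  cfg <- filter_config(log2fc_threshold = edge_lfc, pseudocount = 1,
                       normalize = FALSE)
  out <- fold_change_filter(proteins, study, cfg)
  expect_identical(out$protein, c("PASS_HI", "TIE_A", "TIE_B", "PASS_EDGE"))
  # all below threshold -> empty
  none <- fold_change_filter("FAIL_LO", study, cfg)
  expect_identical(nrow(none), 0L)
})

test_that("the full cascade matches brute-force set logic on a small fixture", {
  sim <- generate_abundance_study(small_sim_config(seed = 3))
  cfg <- filter_config(tm_list = sim$tm_list,
                       common_ev_list = sim$common_ev_list,
                       exclusion_list = sim$exclusion_list)
  trace <- run_filter_pipeline(sim$study, cfg)

  # brute-force reimplementation by direct set comprehension
  st <- sim$study
  units <- study_units(st)
  dsets <- lapply(units$line_or_patient, brute_detected, study = st)
  names(dsets) <- units$line_or_patient
  lin <- function(grp) {
    cells <- units$line_or_patient[units$group == grp &
                                     units$source == "cell_line"]
    tiss <- units$line_or_patient[units$group == grp &
                                    units$source == "tissue"]
    intersect(Reduce(union, dsets[cells]), Reduce(union, dsets[tiss]))
  }
  core <- sort(intersect(lin("FT"), lin("HGSOC")))
  tm <- sort(intersect(core, sim$tm_list$members))
  after_ev <- sort(setdiff(tm, sim$common_ev_list$members))
  lfc <- vapply(after_ev, function(p) log2_fold_change(st, p, cfg), 0)
  fc <- sort(names(lfc)[lfc >= -0.58])
  final <- sort(setdiff(fc, sim$exclusion_list$members))

  get_set <- function(name) sort(trace$stages$set_out[[
    which(trace$stages$stage == name)]])
  expect_identical(get_set("core_proteome"), core)
  expect_identical(get_set("transmembrane"), tm)
  expect_identical(get_set("common_ev_removed"), after_ev)
  expect_identical(get_set("fold_change"), fc)
  expect_identical(get_set("manual_exclusion"), final)

  # monotone shrinkage along the cascade
  expect_true(all(trace$stages$n_out <= trace$stages$n_in))
  expect_true(all(diff(trace$stages$n_out) <= 0))
})

test_that("the cascade is invariant to row and column permutations", {
  sim <- generate_abundance_study(small_sim_config(seed = 9))
  cfg <- filter_config(tm_list = sim$tm_list,
                       common_ev_list = sim$common_ev_list,
                       exclusion_list = sim$exclusion_list)
  ref <- run_filter_pipeline(sim$study, cfg)

  st <- sim$study
  set.seed(1)
  pr <- sample(length(st$proteins))
  sc <- sample(nrow(st$samples))
  shuffled <- abundance_study(st$proteins[pr], st$samples[sc, ],
                              st$intensities[pr, sc])
  out <- run_filter_pipeline(shuffled, cfg)
  expect_identical(tidy(out), tidy(ref))
  expect_equal(out$final_ranked, ref$final_ranked)
})

test_that("with no exclusion list the last two stages coincide", {
  sim <- generate_abundance_study(small_sim_config(seed = 5))
  cfg <- filter_config(tm_list = sim$tm_list,
                       common_ev_list = sim$common_ev_list,
                       exclusion_list = NULL)
  trace <- run_filter_pipeline(sim$study, cfg)
  ns <- nrow(trace$stages)
  expect_identical(trace$stages$n_out[ns], trace$stages$n_out[ns - 1])
})
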