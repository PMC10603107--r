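new_roc_curve <- function(points, estimator, n_pos, n_neg,
                          bandwidths = NULL) {
  stopifnot(is.data.frame(points), all(c("fpr", "tpr") %in% names(points)))
  structure(
    list(points = as_tibble(points), estimator = estimator,
         n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         bandwidths = bandwidths),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", x$estimator, " estimator, ", nrow(x$points),
      " points (", x$n_pos, " pos / ", x$n_neg, " neg), AUC = ",
      format(roc_auc(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy the points of an ROC curve
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble with columns `fpr`, `tpr`.
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' Empirical ROC curve
#'
#' Step-function ROC over all distinct observed thresholds with the
#' "score at or above threshold is positive" convention. Tied case/control
#' scores produce simultaneous (diagonal) steps, which preserves the exact
#' identity between the trapezoidal AUC and the midrank Mann-Whitney U
#' statistic.
#'
#' @param pos,neg Numeric score vectors for cases and controls.
#' @return A `roc_curve` whose points run from (0,0) to (1,1).
#' @export
empirical_roc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(pos)) || !all(is.finite(neg))) {
    stop("scores must be finite", call. = FALSE)
  }
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- cumsum(vapply(thr, function(t) sum(pos == t), 0)) / length(pos)
  fpr <- cumsum(vapply(thr, function(t) sum(neg == t), 0)) / length(neg)
  points <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  new_roc_curve(points, "empirical", length(pos), length(neg))
}

#' Kernel-smoothed ROC curve
#'
#' Both score distributions are estimated with Gaussian kernel CDFs
#' (bandwidths by Silverman's rule per group unless fixed), and the curve
#' `(1 - F̂_neg(c), 1 - F̂_pos(c))` is traced over a dense grid of
#' thresholds spanning the data plus four bandwidths, yielding a smooth
#' estimate suitable for the arc-length statistic.
#'
#' @param pos,neg Numeric score vectors (at least 3 per group).
#' @param bandwidth Optional fixed bandwidth(s): a single value or
#'   `c(pos = , neg = )`. Default: `stats::bw.nrd0` per group.
#' @param grid_size Number of threshold grid points (default 2001).
#' @return A `roc_curve` with `estimator = "kde_smooth"`. Falls back to the
#'   empirical curve with a warning if either group has zero variance.
#' @export
smooth_roc <- function(pos, neg, bandwidth = NULL, grid_size = 2001L) {
  if (length(pos) < 3 || length(neg) < 3) {
    stop("smooth_roc needs at least 3 scores per group", call. = FALSE)
  }
  if (sd(pos) == 0 || sd(neg) == 0) {
    warning("zero variance in a score group; falling back to empirical ROC",
            call. = FALSE)
    return(empirical_roc(pos, neg))
  }
  if (is.null(bandwidth)) {
    h_pos <- bw.nrd0(pos)
    h_neg <- bw.nrd0(neg)
  } else if (length(bandwidth) == 1L) {
    h_pos <- h_neg <- as.numeric(bandwidth)
  } else {
    h_pos <- as.numeric(bandwidth[["pos"]])
    h_neg <- as.numeric(bandwidth[["neg"]])
  }
  stopifnot(h_pos > 0, h_neg > 0)
  pad <- 4 * max(h_pos, h_neg)
  grid <- seq(max(c(pos, neg)) + pad, min(c(pos, neg)) - pad,
              length.out = grid_size)
  kcdf_surv <- function(grid, x, h) {
    # 1 - mean_i Phi((c - x_i)/h), vectorized over the threshold grid
    rowMeans(pnorm(outer(grid, x, "-") / h, lower.tail = FALSE))
  }
  points <- tibble(
    fpr = c(0, kcdf_surv(grid, neg, h_neg), 1),
    tpr = c(0, kcdf_surv(grid, pos, h_pos), 1)
  )
  new_roc_curve(points, "kde_smooth", length(pos), length(neg),
                bandwidths = c(pos = h_pos, neg = h_neg))
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the curve's ordered points. For the empirical
#' curve this equals `U / (n_pos * n_neg)` with midrank tie handling.
#'
#' @param curve A `roc_curve`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- curve$points$fpr
  tpr <- curve$points$tpr
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Arc length of an ROC curve
#'
#' Polygonal length of the curve in the unit square: 2 for a perfectly
#' separating monotone marker, sqrt(2) for an uninformative diagonal. Large
#' length with near-0.5 AUC flags a non-monotone marker whose case scores
#' sit in both tails of the control distribution.
#'
#' @param curve A `roc_curve`.
#' @return Length in \[sqrt(2), 2\].
#' @export
roc_length <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(sqrt(diff(curve$points$fpr)^2 + diff(curve$points$tpr)^2))
}

#' Standard error and confidence interval for an AUC
#'
#' Hanley-McNeil standard error with a normal 95% interval truncated to
#' \[0, 1\].
#'
#' @param auc Estimated AUC.
#' @param n_pos,n_neg Group sizes (each at least 2).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `se`, `ci_lower`, `ci_upper`.
#' @export
auc_se_ci <- function(auc, n_pos, n_neg, conf_level = 0.95) {
  if (n_pos < 2 || n_neg < 2) {
    stop("auc_se_ci needs at least 2 observations per group", call. = FALSE)
  }
  stopifnot(auc >= 0, auc <= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(se = se,
         ci_lower = max(0, auc - z * se),
         ci_upper = min(1, auc + z * se))
}

#' Mann-Whitney U test
#'
#' U is computed from midranks (so tied pairs count one half) and therefore
#' satisfies `AUC = U / (n_x * n_y)` exactly against the tie-aware empirical
#' ROC curve, with `x` as the case group. P-values come from exact
#' enumeration (via the Wilcoxon distribution) when both groups have at
#' most 8 observations and no ties, and otherwise from the normal
#' approximation with the tie-corrected variance. The one-tailed p-value
#' tests departure from AUC = 0.5 in the observed direction.
#'
#' @param x,y Numeric score vectors (cases, controls).
#' @return Tibble with `U`, `p_two_tailed`, `p_one_tailed`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (nx <= 8 && ny <= 8 && !has_ties) {
    u_min <- min(U, nx * ny - U)
    p_one <- pwilcox(u_min, nx, ny)
    p_two <- min(1, 2 * p_one)
    method <- "exact"
  } else {
    N <- nx + ny
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term))
    z <- if (sigma > 0) (U - nx * ny / 2) / sigma else 0
    p_one <- pnorm(-abs(z))
    p_two <- min(1, 2 * p_one)
    method <- "normal_approx"
  }
  tibble(U = U, p_two_tailed = p_two, p_one_tailed = p_one, method = method)
}

#' Thresholds for monotone / non-monotone marker classification
#'
#' A *monotone* marker attains (numerically) the maximal ROC length of 2
#' with a decisive AUC (> 0.8 or < 0.2); a *non-monotone* marker has a long
#' curve (> 1.6) despite an indeterminate AUC in \[0.35, 0.65\], the
#' signature of case scores falling in both tails of the control
#' distribution.
#'
#' @param monotone_length Target length for monotone markers (2).
#' @param epsilon Tolerance below `monotone_length` granted to smooth
#'   curves, which never attain 2 exactly (default 0.02).
#' @param monotone_auc_hi,monotone_auc_lo AUC thresholds (> hi or < lo).
#' @param nonmono_length Minimum (strict) length for non-monotone markers.
#' @param nonmono_auc_lo,nonmono_auc_hi Inclusive AUC band for non-monotone
#'   markers.
#' @return A `roc_classifier_config` list.
#' @export
roc_classifier_config <- function(monotone_length = 2, epsilon = 0.02,
                                  monotone_auc_hi = 0.8,
                                  monotone_auc_lo = 0.2,
                                  nonmono_length = 1.6,
                                  nonmono_auc_lo = 0.35,
                                  nonmono_auc_hi = 0.65) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  structure(
    list(monotone_length = monotone_length, epsilon = epsilon,
         monotone_auc_hi = monotone_auc_hi, monotone_auc_lo = monotone_auc_lo,
         nonmono_length = nonmono_length, nonmono_auc_lo = nonmono_auc_lo,
         nonmono_auc_hi = nonmono_auc_hi),
    class = "roc_classifier_config"
  )
}

#' Classify a marker as monotone, non-monotone, or neither
#'
#' Monotone takes precedence if both rules fire.
#'
#' @param auc AUC of the marker.
#' @param length ROC arc length of the marker (typically from the smoothed
#'   curve).
#' @param cfg A [roc_classifier_config()].
#' @return One of `"monotone"`, `"non_monotone"`, `"neither"`.
#' @export
classify_marker <- function(auc, length, cfg = roc_classifier_config()) {
  stopifnot(auc >= 0, auc <= 1)
  if (length >= cfg$monotone_length - cfg$epsilon &&
      (auc > cfg$monotone_auc_hi || auc < cfg$monotone_auc_lo)) {
    "monotone"
  } else if (length > cfg$nonmono_length &&
             auc >= cfg$nonmono_auc_lo && auc <= cfg$nonmono_auc_hi) {
    "non_monotone"
  } else {
    "neither"
  }
}

#' Immunohistochemistry H-score
#'
#' `0*a0 + 1*a1 + 2*a2 + 3*a3` over the percent tumor areas staining at
#' intensity levels 0 ("absent") through 3+; the areas must sum to 100.
#'
#' @param area_fractions Numeric vector of four non-negative percent areas
#'   (intensity 0, 1+, 2+, 3+) summing to 100.
#' @return H-score in \[0, 300\].
#' @export
h_score <- function(area_fractions) {
  stopifnot(length(area_fractions) == 4, all(area_fractions >= 0))
  if (abs(sum(area_fractions) - 100) > 1e-6) {
    stop("area fractions must sum to 100", call. = FALSE)
  }
  sum(0:3 * area_fractions)
}

#' Per-marker evaluation table
#'
#' For each marker: empirical AUC (via the tie-aware curve), Hanley-McNeil
#' SE and 95% CI, one-tailed Mann-Whitney p-value against AUC = 0.5,
#' smoothed-ROC arc length, monotone/non-monotone classification,
#' sensitivity at the forced specificity, and PPV at the screening
#' prevalence — one row per marker, mirroring a standard single-marker
#' biomarker evaluation table.
#'
#' @param panel Marker-panel tibble (see [read_marker_panel()]).
#' @param markers Markers to evaluate (default: all non-label columns).
#' @param label_col,positive Label column and the case label value.
#' @param target_spec Forced specificity (default 0.998).
#' @param prevalence Population prevalence for the PPV (default 1/2500).
#' @param classifier A [roc_classifier_config()].
#' @return Tibble with one row per marker.
#' @export
evaluate_markers <- function(panel, markers = NULL, label_col = "label",
                             positive = "case", target_spec = 0.998,
                             prevalence = 1 / 2500,
                             classifier = roc_classifier_config()) {
  markers <- validate_marker_panel(panel, label_col, markers)
  is_pos <- panel[[label_col]] == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("panel must contain both '", positive, "' and non-'", positive,
         "' samples", call. = FALSE)
  }
  rows <- lapply(markers, function(mk) {
    pos <- panel[[mk]][is_pos]
    neg <- panel[[mk]][!is_pos]
    emp <- empirical_roc(pos, neg)
    a <- roc_auc(emp)
    ci <- auc_se_ci(a, length(pos), length(neg))
    mw <- mann_whitney(pos, neg)
    len <- roc_length(smooth_roc(pos, neg))
    sas <- sensitivity_at_specificity(pos, neg, target_spec)
    tibble(
      marker = mk, auc = a, se = ci$se,
      ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
      p_one_tailed = mw$p_one_tailed,
      roc_length = len,
      classification = classify_marker(a, len, classifier),
      sens_at_spec = sas$sensitivity,
      ppv = ppv(sas$sensitivity, target_spec, prevalence)
    )
  })
  list_rbind(rows)
}
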