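new_combination_model <- function(markers, coefficients, intercept,
                                  log_likelihood, n_obs, separation = FALSE,
                                  positive = "case") {
  k <- length(markers) + 1L
  structure(
    list(markers = markers,
         coefficients = setNames(as.numeric(coefficients), markers),
         intercept = as.numeric(intercept),
         log_likelihood = as.numeric(log_likelihood),
         aic = 2 * k - 2 * as.numeric(log_likelihood),
         n_obs = as.integer(n_obs),
         separation = isTRUE(separation),
         positive = positive),
    class = "combination_model"
  )
}

#' @export
print.combination_model <- function(x, ...) {
  cat("<combination_model> ", paste(x$markers, collapse = " + "),
      if (x$separation) "  [separation: ridge-stabilized]" else "", "\n",
      "  score = ",
      paste(sprintf("%.3f x log(%s)", x$coefficients, x$markers),
            collapse = " + "),
      "\n  AIC = ", format(x$aic, digits = 6),
      ", logLik = ", format(x$log_likelihood, digits = 6),
      ", n = ", x$n_obs, "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted marker-combination model
#'
#' @param x A `combination_model`.
#' @param ... Unused.
#' @return Tibble with one row per term (`"(Intercept)"` and each marker)
#'   and its coefficient on the log-intensity scale.
#' @export
tidy.combination_model <- function(x, ...) {
  tibble(term = c("(Intercept)", x$markers),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' One-row model summary of a marker-combination fit
#'
#' @param x A `combination_model`.
#' @param ... Unused.
#' @return Tibble with `n_markers`, `log_likelihood`, `aic`, `n_obs`,
#'   `separation`.
#' @export
glance.combination_model <- function(x, ...) {
  tibble(n_markers = length(x$markers),
         log_likelihood = x$log_likelihood,
         aic = x$aic, n_obs = x$n_obs, separation = x$separation)
}

# Ridge-stabilized logistic fit (penalty lambda on slopes only, never the
# intercept); used when the MLE does not exist under separation.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 200L,
                           tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - pen %*% beta
    hess <- crossprod(X1 * w, X1) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

log_likelihood_bernoulli <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a logistic marker-combination model
#'
#' Maximum-likelihood logistic regression of case status on the natural-log
#' transformed intensities of the requested marker subset. Perfect or
#' quasi-perfect separation (diverging coefficients) is detected and the
#' model refitted with a weak ridge penalty on the slopes
#' (`ridge_lambda`), flagged via `$separation` and a warning.
#'
#' @param panel Marker-panel tibble with positive intensities.
#' @param markers Character vector of marker columns to fit.
#' @param label_col,positive Label column and the case label value.
#' @param ridge_lambda Ridge penalty used only by the separation fallback.
#' @return A `combination_model` with coefficients, intercept,
#'   log-likelihood, and AIC `= 2(k+1) - 2 logLik`.
#' @export
fit_logistic <- function(panel, markers, label_col = "label",
                         positive = "case", ridge_lambda = 1e-4) {
  markers <- validate_marker_panel(panel, label_col, markers)
  if (!length(markers)) stop("marker subset must be non-empty", call. = FALSE)
  y <- as.integer(panel[[label_col]] == positive)
  if (sum(y) < 3 || sum(1 - y) < 3) {
    stop("need at least 3 observations per class", call. = FALSE)
  }
  X <- as.matrix(panel[markers])
  if (any(!is.finite(X)) || any(X <= 0)) {
    stop("marker intensities must be positive and finite", call. = FALSE)
  }
  X <- log(X)
  colnames(X) <- markers
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, X), y, family = binomial())
  )
  beta <- coef(fit)
  separated <- !fit$converged || any(abs(beta[-1]) > 15) ||
    any(!is.finite(beta))
  if (separated) {
    warning("separation detected for subset {",
            paste(markers, collapse = ", "),
            "}; refitting with ridge penalty", call. = FALSE)
    beta <- ridge_logistic(X, y, lambda = ridge_lambda)
    names(beta) <- c("(Intercept)", markers)
  }
  p_hat <- plogis(drop(cbind(1, X) %*% beta))
  ll <- log_likelihood_bernoulli(y, p_hat)
  new_combination_model(markers, beta[-1], beta[1], ll, length(y),
                        separation = separated, positive = positive)
}

#' Exhaustive AIC search over marker subsets
#'
#' Fits a logistic model for every non-empty subset of the candidate
#' markers (`2^k - 1` models) and returns the minimum-AIC fit. Ties are
#' broken in favor of fewer markers, then lexicographic marker names.
#' Individual fit failures are recorded, not fatal.
#'
#' @param panel Marker-panel tibble.
#' @param candidates Candidate marker names (1 to 20).
#' @param label_col,positive Label column and case label value.
#' @param ridge_lambda Passed to [fit_logistic()].
#' @return List with `best` (a `combination_model`) and `models`, a tibble
#'   of all attempted subsets (`markers` list-column, `subset`, `n_markers`,
#'   `aic`, `log_likelihood`, `separation`, `error`).
#' @export
exhaustive_search <- function(panel, candidates, label_col = "label",
                              positive = "case", ridge_lambda = 1e-4) {
  candidates <- validate_marker_panel(panel, label_col, candidates)
  k <- length(candidates)
  if (k < 1 || k > 20) {
    stop("exhaustive_search supports 1 to 20 candidate markers", call. = FALSE)
  }
  subsets <- unlist(
    lapply(seq_len(k), function(m) combn(sort(candidates), m,
                                         simplify = FALSE)),
    recursive = FALSE
  )
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    mk <- subsets[[i]]
    fit <- tryCatch(
      suppressWarnings(
        fit_logistic(panel, mk, label_col, positive, ridge_lambda)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rows[[i]] <- tibble(
        markers = list(mk), subset = paste(mk, collapse = "+"),
        n_markers = length(mk), aic = NA_real_,
        log_likelihood = NA_real_, separation = NA,
        error = conditionMessage(fit)
      )
    } else {
      fits[[i]] <- fit
      rows[[i]] <- tibble(
        markers = list(mk), subset = paste(mk, collapse = "+"),
        n_markers = length(mk), aic = fit$aic,
        log_likelihood = fit$log_likelihood, separation = fit$separation,
        error = NA_character_
      )
    }
  }
  models <- list_rbind(rows)
  ok <- which(!is.na(models$aic))
  if (!length(ok)) stop("every subset fit failed", call. = FALSE)
  ord <- ok[order(models$aic[ok], models$n_markers[ok], models$subset[ok])]
  list(best = fits[[ord[1]]], models = arrange(models, .data$aic))
}

#' Linear combination score of a fitted model
#'
#' The intercept-free linear term `sum_i beta_i * log(x_i)` per sample,
#' used as the combined marker score. Dropping the intercept changes no
#' ranking-based quantity (ROC, sensitivity at specificity, Youden cutoff).
#'
#' @param model A `combination_model`.
#' @param panel Marker-panel tibble containing the model's markers.
#' @return Numeric score vector, one per panel row.
#' @export
linear_score <- function(model, panel) {
  stopifnot(inherits(model, "combination_model"))
  missing <- setdiff(model$markers, names(panel))
  if (length(missing)) {
    stop("panel is missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(panel[model$markers])
  bad <- which(!is.finite(X) | X <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    id <- if ("sample_id" %in% names(panel)) {
      panel$sample_id[bad[1, "row"]]
    } else {
      paste0("row ", bad[1, "row"])
    }
    stop("non-positive intensity for sample ", id, ", marker ",
         model$markers[bad[1, "col"]], call. = FALSE)
  }
  drop(log(X) %*% model$coefficients)
}

new_screening_performance <- function(sensitivity, specificity, cutoff,
                                      ppv, prevalence) {
  tibble(sensitivity = sensitivity, specificity = specificity,
         cutoff = cutoff, youden_j = sensitivity + specificity - 1,
         ppv = ppv, prevalence = prevalence)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate cutoffs
#' placed at midpoints of adjacent distinct scores (plus one beyond each
#' extreme), calling a sample positive when its score exceeds the cutoff.
#' Ties are resolved toward higher specificity, then the lower cutoff.
#'
#' @param scores Numeric score vector.
#' @param labels Class labels aligned with `scores`.
#' @param positive Case label value (default `"case"`).
#' @param prevalence Prevalence used for the reported PPV (default 1/2500).
#' @return One-row tibble: `sensitivity`, `specificity`, `cutoff`,
#'   `youden_j`, `ppv`, `prevalence`.
#' @export
youden_cutoff <- function(scores, labels, positive = "case",
                          prevalence = 1 / 2500) {
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, (head(s, -1) + s[-1]) / 2, s[length(s)] + 1)
  sens <- vapply(cand, function(c) mean(pos > c), 0)
  spec <- vapply(cand, function(c) mean(neg <= c), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-spec[best], cand[best])][1]
  new_screening_performance(sens[best], spec[best], cand[best],
                            ppv(sens[best], spec[best], prevalence),
                            prevalence)
}

#' Sensitivity at a forced specificity
#'
#' Finds the smallest cutoff whose empirical specificity (fraction of
#' controls at or below the cutoff) meets the target, and reports the
#' fraction of cases strictly above it. With fewer than `1 / (1 - target)`
#' controls, any false positive violates the target, so the cutoff lands at
#' the control maximum (empirical specificity 1).
#'
#' @param scores_pos,scores_neg Case and control scores.
#' @param target_spec Target specificity in (0, 1] (default 0.998).
#' @return One-row tibble: `sensitivity`, `cutoff`, `specificity` (the
#'   achieved empirical specificity).
#' @export
sensitivity_at_specificity <- function(scores_pos, scores_neg,
                                       target_spec = 0.998) {
  stopifnot(target_spec > 0, target_spec <= 1)
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  cand <- sort(unique(scores_neg))
  spec <- vapply(cand, function(c) mean(scores_neg <= c), 0)
  i <- which(spec >= target_spec)[1]   # spec is non-decreasing in the cutoff
  cutoff <- cand[i]
  tibble(sensitivity = mean(scores_pos > cutoff),
         cutoff = cutoff, specificity = spec[i])
}

#' Positive predictive value at a population prevalence
#'
#' `PPV = sens * p / (sens * p + (1 - spec) * (1 - p))`: the probability of
#' disease given a positive test when the test operates at the given
#' sensitivity/specificity in a population with prevalence `p`. At the
#' ovarian-screening prevalence of 1/2500 even a near-perfect specificity
#' leaves the PPV far below 1, which is why screening studies force
#' specificity to 0.998 before reading off the PPV.
#'
#' @param sensitivity,specificity Operating point, each in \[0, 1\].
#' @param prevalence Population prevalence in \[0, 1\] (default 1/2500).
#' @return PPV in \[0, 1\]; defined as 0 (with a warning) when both the
#'   true-positive and false-positive rates vanish.
#' @export
ppv <- function(sensitivity, specificity, prevalence = 1 / 2500) {
  stopifnot(all(sensitivity >= 0), all(sensitivity <= 1),
            all(specificity >= 0), all(specificity <= 1),
            all(prevalence >= 0), all(prevalence <= 1))
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  if (any(den == 0)) {
    warning("no positive calls at this operating point; PPV defined as 0",
            call. = FALSE)
  }
  ifelse(den == 0, 0, num / den)
}

#' Apply a fixed combination model to an independent panel
#'
#' Computes the model's linear score on a new panel without refitting, then
#' the sensitivity at the forced specificity and the PPV at the screening
#' prevalence. The caller is responsible for the panel's independence from
#' the fitting data.
#'
#' @param model A `combination_model`.
#' @param panel Marker-panel tibble with the model's markers.
#' @param label_col,positive Label column and case label value.
#' @param target_spec Forced specificity (default 0.998).
#' @param prevalence Screening prevalence (default 1/2500).
#' @return One-row tibble: `sensitivity`, `specificity` (the achieved
#'   empirical specificity, which exceeds the target when the control set
#'   is small), `cutoff`, `youden_j`, `ppv`, `prevalence`. The PPV is
#'   computed at the *nominal* forced specificity, the convention under
#'   which a screening test's operating point is quoted.
#' @export
evaluate_fixed_combination <- function(model, panel, label_col = "label",
                                       positive = "case",
                                       target_spec = 0.998,
                                       prevalence = 1 / 2500) {
  validate_marker_panel(panel, label_col, model$markers)
  scores <- linear_score(model, panel)
  is_pos <- panel[[label_col]] == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  sas <- sensitivity_at_specificity(scores[is_pos], scores[!is_pos],
                                    target_spec)
  new_screening_performance(sas$sensitivity, sas$specificity, sas$cutoff,
                            ppv(sas$sensitivity, target_spec, prevalence),
                            prevalence)
}

#' Average replicate chip measurements per sample
#'
#' Repeated assays of the same samples (e.g. two chip runs) are averaged
#' marker-wise before analysis; panels must share `sample_id` and label
#' columns.
#'
#' @param ... Two or more marker-panel tibbles with identical samples.
#' @param label_col Label column name.
#' @return A single averaged panel.
#' @export
average_marker_panels <- function(..., label_col = "label") {
  panels <- list(...)
  stopifnot(length(panels) >= 2)
  ref <- panels[[1]]
  markers <- validate_marker_panel(ref, label_col)
  for (p in panels[-1]) {
    if (!identical(p$sample_id, ref$sample_id) ||
        !identical(p[[label_col]], ref[[label_col]])) {
      stop("panels must share identical sample_id and labels", call. = FALSE)
    }
    validate_marker_panel(p, label_col, markers)
  }
  out <- ref
  for (mk in markers) {
    out[[mk]] <- Reduce(`+`, lapply(panels, function(p) p[[mk]])) /
      length(panels)
  }
  out
}
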