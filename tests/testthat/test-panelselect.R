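test_that("logistic fit satisfies the AIC identity against recomputed likelihood", {
  set.seed(71)
  pan <- generate_marker_panel(panel_sim_config(
    n_cases = 40, n_controls = 40, seed = 71
  ))$panel
  fit <- fit_logistic(pan, c("IGSF8", "ITGA5"))
  y <- as.integer(pan$label == "case")
  eta <- fit$intercept + log(as.matrix(pan[c("IGSF8", "ITGA5")])) %*%
    fit$coefficients
  p_hat <- plogis(drop(eta))
  ll <- sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
  expect_lt(abs(fit$log_likelihood - ll), 1e-8)
  expect_lt(abs(fit$aic - (2 * 3 - 2 * ll)), 1e-8)

  # agrees with stats::glm on the same design
  g <- glm(y ~ log(IGSF8) + log(ITGA5), data = pan, family = binomial())
  expect_equal(unname(coef(g)),
               unname(c(fit$intercept, fit$coefficients)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(g), tolerance = 1e-6)

  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "IGSF8", "ITGA5"))
  expect_identical(glance(fit)$n_obs, 80L)
})

test_that("an uninformative marker yields a near-zero slope", {
  cfg <- panel_sim_config(
    n_cases = 500, n_controls = 500,
    markers = tibble::tibble(name = "FLAT", delta = 0, sd0 = 1, sd1 = 1),
    seed = 72
  )
  pan <- generate_marker_panel(cfg)$panel
  fit <- fit_logistic(pan, "FLAT")
  expect_lt(abs(fit$coefficients[["FLAT"]]), 0.3)
  expect_false(fit$separation)
})

test_that("generative coefficients are recovered on a large simulated panel", {
  set.seed(73)
  n <- 2000
  b <- c(-0.5, 1.2, 0.8)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(b[1] + b[2] * x1 + b[3] * x2))
  pan <- tibble::tibble(
    sample_id = sprintf("S%04d", 1:n),
    label = ifelse(y == 1, "case", "control"),
    M1 = exp(x1), M2 = exp(x2)
  )
  fit <- fit_logistic(pan, c("M1", "M2"))
  expect_lt(abs(fit$coefficients[["M1"]] - b[2]) / b[2], 0.15)
  expect_lt(abs(fit$coefficients[["M2"]] - b[3]) / b[3], 0.15)
})

test_that("separation is flagged and ridge-stabilized to finite coefficients", {
  set.seed(80)
  pan <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    label = rep(c("case", "control"), each = 6),
    SEP = c(rexp(6) + 10, rexp(6) + 0.1)
  )
  expect_warning(fit <- fit_logistic(pan, "SEP"), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(unlist(fit$coefficients))))
  expect_true(is.finite(fit$aic))
})

test_that("exhaustive search fits 2^k - 1 subsets and orders ties sensibly", {
  pan <- generate_marker_panel(panel_sim_config(
    n_cases = 15, n_controls = 15, seed = 74
  ))$panel
  out <- suppressWarnings(
    exhaustive_search(pan, c("IGSF8", "ITGA5"))
  )
  expect_identical(nrow(out$models), 3L)
  expect_setequal(out$models$subset, c("IGSF8", "ITGA5", "IGSF8+ITGA5"))
  expect_lte(out$best$aic, min(out$models$aic, na.rm = TRUE) + 1e-12)

  out3 <- suppressWarnings(
    exhaustive_search(pan, c("IGSF8", "ITGA5", "MYOF"))
  )
  expect_identical(nrow(out3$models), 7L)
  expect_error(exhaustive_search(pan, character()), "1 to 20")
})

test_that("linear score is the intercept-free coefficient-weighted log sum", {
  model <- fixed_model()
  pan <- tibble::tibble(
    sample_id = "S1", label = "case",
    IGSF8 = exp(1), ITGA5 = exp(1)
  )
  expect_equal(linear_score(model, pan), 11.299 + 14.935, tolerance = 1e-12)

  zero <- fixed_model(coefficients = c(0, 0))
  many <- tibble::tibble(
    sample_id = sprintf("S%d", 1:5), label = "case",
    IGSF8 = runif(5, 1, 9), ITGA5 = runif(5, 1, 9)
  )
  expect_equal(linear_score(zero, many), rep(0, 5))

  missing_col <- many[setdiff(names(many), "ITGA5")]
  expect_error(linear_score(model, missing_col), "ITGA5")
  bad <- many
  bad$ITGA5[3] <- 0
  expect_error(linear_score(model, bad), "S3.*ITGA5")
})

test_that("Youden cutoff equals the exhaustive-sweep argmax", {
  brute_youden <- function(scores, labels) {
    pos <- scores[labels == "case"]
    neg <- scores[labels != "case"]
    s <- sort(unique(scores))
    cand <- c(s[1] - 1, (head(s, -1) + s[-1]) / 2, s[length(s)] + 1)
    best <- -Inf
    for (c in cand) {
      j <- mean(pos > c) + mean(neg <= c) - 1
      if (j > best) best <- j
    }
    best
  }
  set.seed(75)
  for (i in 1:25) {
    scores <- round(rnorm(30), 1)            # ties included
    labels <- rep(c("case", "control"), 15)
    out <- youden_cutoff(scores, labels)
    expect_equal(out$youden_j, brute_youden(scores, labels),
                 tolerance = 1e-12)
  }
  # perfect separation
  perf <- youden_cutoff(c(5, 6, 1, 2), c("case", "case", "control", "control"))
  expect_equal(perf$youden_j, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  # identical score multisets -> J = 0
  degen <- youden_cutoff(c(1, 2, 3, 1, 2, 3),
                         rep(c("case", "control"), each = 3))
  expect_equal(degen$youden_j, 0)
})

test_that("sensitivity at forced specificity matches a brute-force sweep", {
  # separation: 20 controls, target 0.998 forces the cutoff to the control max
  out <- sensitivity_at_specificity(runif(10, 21, 30), 1:20, 0.998)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$cutoff, 20)
  expect_equal(out$specificity, 1)
  # cases all below controls
  low <- sensitivity_at_specificity(runif(10), 2:21, 0.998)
  expect_equal(low$sensitivity, 0)

  brute <- function(pos, neg, target) {
    best <- NULL
    for (c in sort(unique(neg))) {
      spec <- sum(neg <= c) / length(neg)
      if (spec >= target) { best <- c; break }
    }
    c(sensitivity = sum(pos > best) / length(pos), cutoff = best)
  }
  set.seed(76)
  for (i in 1:25) {
    pos <- rnorm(12, 0.7)
    neg <- rnorm(18)
    out <- sensitivity_at_specificity(pos, neg, 0.8)
    ref <- brute(pos, neg, 0.8)
    expect_equal(out$sensitivity, unname(ref["sensitivity"]))
    expect_equal(out$cutoff, unname(ref["cutoff"]))
  }
})

test_that("PPV closed form, boundaries, and monotonicity", {
  expect_equal(ppv(1, 1, 0.3), 1)
  expect_equal(ppv(0.5, 1, 0.0004), 1)    # perfect specificity -> PPV 1
  expect_warning(z <- ppv(0, 1, 0.0004), "PPV defined as 0")
  expect_equal(z, 0)
  # strictly increasing in each argument
  s <- seq(0.05, 1, length.out = 30)
  expect_true(all(diff(ppv(s, 0.99, 0.001)) > 0))
  q <- seq(0.5, 0.999, length.out = 30)
  expect_true(all(diff(ppv(0.8, q, 0.001)) > 0))
})

test_that("a fixed combination applied to its own training panel reproduces training sensitivity", {
  pan <- generate_marker_panel(panel_sim_config(seed = 77))$panel
  fit <- suppressWarnings(fit_logistic(pan, c("IGSF8", "ITGA5")))
  scores <- linear_score(fit, pan)
  is_case <- pan$label == "case"
  train <- sensitivity_at_specificity(scores[is_case], scores[!is_case])
  perf <- evaluate_fixed_combination(fit, pan)
  expect_equal(perf$sensitivity, train$sensitivity)
  expect_equal(perf$cutoff, train$cutoff)
  expect_equal(perf$ppv, ppv(train$sensitivity, 0.998, 1 / 2500))

  no_col <- pan[setdiff(names(pan), "ITGA5")]
  expect_error(evaluate_fixed_combination(fit, no_col), "ITGA5")
})

test_that("replicate chip panels average marker-wise", {
  p1 <- generate_marker_panel(panel_sim_config(seed = 78))$panel
  p2 <- p1
  p2$IGSF8 <- p2$IGSF8 * 3
  avg <- average_marker_panels(p1, p2)
  expect_equal(avg$IGSF8, p1$IGSF8 * 2)
  expect_equal(avg$ITGA5, p1$ITGA5)
  p3 <- p1[nrow(p1):1, ]
  expect_error(average_marker_panels(p1, p3), "identical sample_id")
})
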