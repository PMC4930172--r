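test_that("naive Bayes posteriors match a hand-computed Bayes rule", {
  # 6-sample 1D fixture, equal priors
  d <- tibble::tibble(x1 = c(-2, -1, -1.5, 1, 1.5, 2),
                      label = factor(rep(c("neg", "pos"), each = 3),
                                     levels = c("neg", "pos")))
  fit <- fit_nb(d)
  newx <- tibble::tibble(x1 = c(-1.2, 0, 0.8))
  mu0 <- mean(d$x1[1:3]); v0 <- var(d$x1[1:3])
  mu1 <- mean(d$x1[4:6]); v1 <- var(d$x1[4:6])
  lik0 <- dnorm(newx$x1, mu0, sqrt(v0)) * 0.5
  lik1 <- dnorm(newx$x1, mu1, sqrt(v1)) * 0.5
  expect_equal(predict(fit, newx), lik1 / (lik0 + lik1), tolerance = 1e-12)

  # symmetric data: posterior at the midpoint is exactly 1/2
  sym <- tibble::tibble(x1 = c(-3, -2, -1, 1, 2, 3),
                        label = factor(rep(c("neg", "pos"), each = 3),
                                       levels = c("neg", "pos")))
  expect_equal(predict(fit_nb(sym), tibble::tibble(x1 = 0)), 0.5,
               tolerance = 1e-12)

  # zero-variance feature is floored, never NaN
  degen <- tibble::tibble(x1 = c(1, 1, 1, 2, 2, 2),
                          x2 = rnorm(6),
                          label = factor(rep(c("neg", "pos"), each = 3)))
  p <- predict(fit_nb(degen), degen)
  expect_true(all(is.finite(p)))

  expect_error(fit_nb(tibble::tibble(x1 = 1:4,
                                     label = factor(rep("a", 4)))),
               class = "ffldyn_input_error")
})

test_that("LOOCV is an explicit deterministic fold loop", {
  set.seed(21)
  d <- simulate_panel(20, delta = 1.5, n_features = 2, seed = 33)
  s1 <- loocv_scores(d)
  s2 <- loocv_scores(d)
  expect_identical(s1, s2)

  # oracle: naive re-fit loop computed from first principles
  x <- as.matrix(d[, 1:2]); y <- d$label
  oracle <- vapply(seq_len(nrow(d)), function(i) {
    xm <- x[-i, , drop = FALSE]; ym <- y[-i]
    ll <- c(neg = log(mean(ym == "neg")), pos = log(mean(ym == "pos")))
    for (cl in c("neg", "pos")) {
      for (j in 1:2) {
        mu <- mean(xm[ym == cl, j]); v <- var(xm[ym == cl, j])
        ll[cl] <- ll[cl] + dnorm(x[i, j], mu, sqrt(v), log = TRUE)
      }
    }
    1 / (1 + exp(ll["neg"] - ll["pos"]))
  }, numeric(1))
  expect_equal(s1, oracle, tolerance = 1e-10)

  # minimal panel: 4 folds of 3
  d4 <- tibble::tibble(x1 = c(0, 0.2, 5, 5.3),
                       label = factor(rep(c("neg", "pos"), each = 2)))
  expect_length(loocv_scores(d4), 4)
  expect_error(loocv_scores(d4[1:3, ]), class = "ffldyn_input_error")

  # duplicated dataset: LOOCV close to resubstitution
  dd <- dplyr::bind_rows(d, d)
  fit_full <- fit_nb(dd)
  expect_equal(loocv_scores(dd), predict(fit_full, dd), tolerance = 0.05)
})

test_that("AUC: rank formula equals trapezoidal integration and behaves at the extremes", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- factor(c("neg", "neg", "pos", "pos"))
  expect_equal(roc_auc(scores, labels)$auc, 1.0)
  expect_equal(roc_auc(-scores, labels)$auc, 0.0)

  set.seed(9)
  for (i in 1:10) {
    s <- round(rnorm(30), 1)  # rounding forces ties
    l <- factor(sample(c("neg", "pos"), 30, replace = TRUE,
                       prob = c(0.4, 0.6)))
    if (nlevels(droplevels(l)) < 2) next
    r <- roc_auc(s, l)
    trap <- sum(diff(r$curve$fpr) *
                  (utils::head(r$curve$tpr, -1) + r$curve$tpr[-1]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(2 * s), l)$auc, r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, factor(rep("pos", 4))),
               class = "ffldyn_input_error")
})

test_that("label permutation centres the AUC at one half", {
  d <- simulate_panel(50, delta = 2, seed = 5)
  scores <- loocv_scores(d)
  set.seed(6)
  aucs <- vapply(1:500, function(i) {
    roc_auc(scores, sample(d$label))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("panel evaluation reports the combination and single genes, train and test", {
  cfg <- sim_config(n_genes = 300, n_tfs = 20, n_controls = 10,
                    n_cases_per_stage = 12, biomarker_delta = 2.5, seed = 44)
  sim <- simulate_expression(cfg)
  genes <- sim$truth$biomarker_genes
  rep1 <- evaluate_panel(genes, sim$expr, sim$samples, task = "diagnosis",
                         stage = 1)
  expect_equal(nrow(rep1), 3)  # combination + 2 single genes
  expect_equal(rep1$panel[1], paste(genes, collapse = "+"))
  expect_true(all(rep1$train_auc > 0.7))

  # independent test set from a different seed
  cfg2 <- sim_config(n_genes = 300, n_tfs = 20, n_controls = 10,
                     n_cases_per_stage = 12, biomarker_delta = 2.5, seed = 45)
  sim2 <- simulate_expression(cfg2)
  # the test matrix must carry the same planted biomarkers: rename genes
  expr2 <- sim2$expr
  expr2[[1]] <- sim$expr[[1]]
  rep2 <- evaluate_panel(genes, sim$expr, sim$samples,
                         test_expr = expr2, test_samples = sim2$samples,
                         task = "diagnosis", stage = 1)
  expect_true(all(c("n_test", "test_auc") %in% names(rep2)))

  expect_error(evaluate_panel("NOT_A_GENE", sim$expr, sim$samples),
               "NOT_A_GENE", class = "ffldyn_input_error")
})

test_that("recurrence task uses the recurrence annotation", {
  set.seed(8)
  expr <- ffldyn:::expr_tibble(matrix(
    rnorm(5 * 20, 8), nrow = 5,
    dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:20))))
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    group = "case", stage = 1L,
    recurrence = c(rep("yes", 6), rep("no", 10), rep(NA, 4)))
  # plant a strong signal for g1
  x <- ffldyn:::expr_matrix(expr)
  x["g1", 1:6] <- x["g1", 1:6] + 4
  expr <- ffldyn:::expr_tibble(x)
  rep <- evaluate_panel("g1", expr, samples, task = "recurrence")
  expect_equal(rep$n_train, 16)  # NA follow-up excluded
  expect_gt(rep$train_auc, 0.9)
})
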