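panel_parts <- function(data, label_col = "label") {
  if (!label_col %in% names(data)) {
    abort(sprintf("panel data needs a `%s` column", label_col),
          class = "ffldyn_input_error")
  }
  y <- data[[label_col]]
  x <- data[setdiff(names(data), label_col)]
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort("panel features must all be numeric", class = "ffldyn_input_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("panel contains missing values", class = "ffldyn_input_error")
  }
  y <- factor(y)
  list(x = as.matrix(x), y = y)
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Two-class naive Bayes with Gaussian class-conditional densities per
#' feature. Class priors are the sample class frequencies; per-class,
#' per-feature variances are floored at `1e-9` times the pooled feature
#' variance so degenerate (zero-variance) features cannot produce division
#' by zero. Posterior scores are computed in log space.
#'
#' @param data Data frame of numeric feature columns plus a two-level label
#'   column.
#' @param label_col Name of the label column (default `"label"`); its
#'   second factor level is the positive class.
#' @return An `nb_model`. `predict()` returns the positive-class posterior
#'   (`type = "posterior"`, default) or hard labels (`type = "class"`);
#'   `tidy()` the per-class parameters; `glance()` the priors.
#' @export
#' @examples
#' d <- simulate_panel(20, delta = 2, seed = 1)
#' fit <- fit_nb(d)
#' head(predict(fit, d))
fit_nb <- function(data, label_col = "label") {
  parts <- panel_parts(data, label_col)
  x <- parts$x; y <- parts$y
  if (nlevels(y) != 2) {
    abort("naive Bayes needs exactly two classes in the training data",
          class = "ffldyn_input_error")
  }
  classes <- levels(y)
  priors <- as.vector(table(y)[classes]) / length(y)
  mu <- matrix(NA_real_, nrow = 2, ncol = ncol(x))
  v <- matrix(NA_real_, nrow = 2, ncol = ncol(x))
  for (k in 1:2) {
    xk <- x[y == classes[k], , drop = FALSE]
    mu[k, ] <- colMeans(xk)
    v[k, ] <- apply(xk, 2, var)
  }
  global_var <- apply(x, 2, var)
  # a one-sample class has an undefined variance: fall back to the pooled one
  gv <- matrix(global_var, nrow = 2, ncol = ncol(x), byrow = TRUE)
  v[is.na(v)] <- gv[is.na(v)]
  floor_ <- pmax(1e-9 * global_var, 1e-12)
  v <- pmax(v, matrix(floor_, nrow = 2, ncol = ncol(x), byrow = TRUE))
  dimnames(mu) <- dimnames(v) <- list(classes, colnames(x))
  structure(list(classes = classes, priors = setNames(priors, classes),
                 mu = mu, var = v, features = colnames(x),
                 label_col = label_col),
            class = "nb_model")
}

#' @export
predict.nb_model <- function(object, newdata,
                             type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  x <- newdata[, object$features, drop = FALSE]
  x <- as.matrix(x)
  loglik <- matrix(0, nrow = nrow(x), ncol = 2,
                   dimnames = list(NULL, object$classes))
  for (k in 1:2) {
    cl <- object$classes[k]
    s <- rep(log(object$priors[[cl]]), nrow(x))
    for (j in seq_along(object$features)) {
      s <- s + dnorm(x[, j], object$mu[cl, j], sqrt(object$var[cl, j]),
                     log = TRUE)
    }
    loglik[, k] <- s
  }
  # posterior of the positive (second) class, stabilised in log space
  m <- apply(loglik, 1, max)
  post <- exp(loglik[, 2] - m) /
    (exp(loglik[, 1] - m) + exp(loglik[, 2] - m))
  if (type == "posterior") unname(post)
  else factor(object$classes[1 + (post >= 0.5)], levels = object$classes)
}

#' @export
tidy.nb_model <- function(x, ...) {
  tidyr::expand_grid(class = x$classes, feature = x$features) |>
    dplyr::mutate(mean = purrr::map2_dbl(.data$class, .data$feature,
                                         ~ x$mu[.x, .y]),
                  variance = purrr::map2_dbl(.data$class, .data$feature,
                                             ~ x$var[.x, .y]),
                  prior = unname(x$priors[.data$class]))
}

#' @export
glance.nb_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 positive_class = x$classes[2],
                 prior_positive = unname(x$priors[2]))
}

#' Leave-one-out cross-validated posterior scores
#'
#' For each sample, fits the naive Bayes model on all other samples and
#' scores the held-out sample with the positive-class posterior. The
#' procedure is deterministic. A fold that loses an entire class (possible
#' only with a 2-sample class) is scored with the prior alone, with a
#' warning.
#'
#' @inheritParams fit_nb
#' @return Numeric vector of posterior scores, one per row of `data`.
#' @export
loocv_scores <- function(data, label_col = "label") {
  parts <- panel_parts(data, label_col)
  n <- nrow(data)
  if (n < 4) {
    abort("LOOCV needs at least 4 samples", class = "ffldyn_input_error")
  }
  y <- parts$y
  scores <- numeric(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (nlevels(droplevels(y[-i])) < 2) {
      warn(sprintf("fold %d lost an entire class; scored with the prior only", i))
      scores[i] <- mean(y[-i] == levels(y)[2])
      next
    }
    fit <- fit_nb(train, label_col)
    scores[i] <- predict(fit, data[i, , drop = FALSE])
  }
  scores
}

#' ROC curve and AUC
#'
#' Computes the AUC by the rank (Mann-Whitney) formulation with ties
#' counted one half, which equals the trapezoidal area under the ROC sweep.
#'
#' @param scores Numeric classifier scores (higher means more positive).
#' @param labels Two-level labels aligned with `scores`; the second factor
#'   level (or `1`) is the positive class.
#' @return A `roc_result`: list with `auc`, the threshold sweep `curve`
#'   (`threshold`, `tpr`, `fpr`), `n_pos`, `n_neg`. `glance()` returns the
#'   AUC; `tidy()` the sweep; `autoplot()` draws the curve.
#' @export
roc_auc <- function(scores, labels) {
  y <- factor(labels)
  if (nlevels(y) != 2) {
    abort("both classes must be present to compute a ROC curve",
          class = "ffldyn_input_error")
  }
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)

  ord <- order(scores, decreasing = TRUE)
  thr <- scores[ord]
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  keep <- c(thr[-length(thr)] != thr[-1], TRUE)  # last index per tied score
  curve <- tibble::tibble(
    threshold = c(Inf, thr[keep]),
    tpr = c(0, tp[keep] / n1),
    fpr = c(0, fp[keep] / n0)
  )
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.3f (%d pos / %d neg)>\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

build_panel <- function(genes, expr, samples, task, stage = NULL) {
  x <- expr_matrix(expr)
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0) {
    abort(paste0("gene(s) absent from the expression matrix: ",
                 paste(missing, collapse = ", ")),
          class = "ffldyn_input_error")
  }
  if (task == "diagnosis") {
    keep <- samples$group %in% c("case", "control")
    if (!is.null(stage)) {
      keep <- keep & (samples$group == "control" |
                        (!is.na(samples$stage) & samples$stage == stage))
    }
    ids <- samples$sample_id[keep]
    lab <- factor(samples$group[keep], levels = c("control", "case"))
  } else {
    keep <- !is.na(samples$recurrence)
    ids <- samples$sample_id[keep]
    lab <- factor(samples$recurrence[keep], levels = c("no", "yes"))
  }
  panel <- tibble::as_tibble(t(x[genes, ids, drop = FALSE]),
                             .name_repair = "minimal")
  names(panel) <- genes
  panel$label <- lab
  panel
}

#' Evaluate a gene panel as a diagnostic or prognostic signature
#'
#' Builds a feature panel from the expression of the given genes, scores it
#' with Gaussian naive Bayes under leave-one-out cross-validation on the
#' training set, and (when a test set is supplied) fits on the full
#' training set and scores the test samples. Single-gene panels are
#' evaluated alongside the combination.
#'
#' @param genes Character vector of panel genes (e.g. `c("STAT3", "ICAM1")`).
#' @param train_expr,train_samples Training expression tibble and sample
#'   annotations.
#' @param test_expr,test_samples Optional independent test set.
#' @param task `"diagnosis"` (case vs control) or `"recurrence"`
#'   (recurrent vs non-recurrent cases, using the `recurrence` annotation).
#' @param stage Optional stage restriction for the training cases.
#' @return Tibble with one row per panel (`combination` first, then each
#'   single gene): `panel`, `task`, `n_train`, `train_auc` and, when a test
#'   set is given, `n_test` and `test_auc`.
#' @export
evaluate_panel <- function(genes, train_expr, train_samples,
                           test_expr = NULL, test_samples = NULL,
                           task = c("diagnosis", "recurrence"),
                           stage = NULL) {
  task <- match.arg(task)
  panels <- c(list(genes), as.list(genes))
  names(panels) <- c(paste(genes, collapse = "+"), genes)
  if (length(genes) == 1) panels <- panels[1]
  purrr::imap_dfr(panels, function(gs, nm) {
    train <- build_panel(gs, train_expr, train_samples, task, stage)
    scores <- loocv_scores(train)
    row <- tibble::tibble(panel = nm, task = task,
                          n_train = nrow(train),
                          train_auc = roc_auc(scores, train$label)$auc)
    if (!is.null(test_expr)) {
      test <- build_panel(gs, test_expr, test_samples, task, stage = NULL)
      fit <- fit_nb(train)
      row$n_test <- nrow(test)
      row$test_auc <- roc_auc(predict(fit, test), test$label)$auc
    }
    row
  })
}
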