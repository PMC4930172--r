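#' Differential-expression configuration
#'
#' Thresholds and moderation settings for per-stage differential expression.
#' The defaults mirror the screening rule used throughout the package:
#' BH-adjusted p strictly below 0.001 together with a linear fold change
#' strictly above 1.2, in either direction.
#'
#' @param adj_p_threshold Adjusted-p cutoff (strict `<`).
#' @param fc_threshold Linear fold-change cutoff (strict `>`, `>= 1`).
#' @param moderation `"moderated"` (empirical-Bayes shrunken variance,
#'   default) or `"ordinary"` (pooled two-sample t).
#' @return A list of class `de_config`.
#' @export
de_config <- function(adj_p_threshold = 0.001, fc_threshold = 1.2,
                      moderation = c("moderated", "ordinary")) {
  check_scalar_number(adj_p_threshold, "adj_p_threshold", 0, 1,
                      strict_lower = TRUE)
  check_scalar_number(fc_threshold, "fc_threshold", 1)
  moderation <- match.arg(moderation)
  structure(list(adj_p_threshold = adj_p_threshold,
                 fc_threshold = fc_threshold,
                 moderation = moderation),
            class = "de_config")
}

# Newton solve of trigamma(y) = x, vectorised; used by the moment-matched
# prior-df estimate.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Moment-match s^2 ~ s0^2 * chi^2_d0-scaled prior on the log scale:
# e_g = log s_g^2 - digamma(df/2) + log(df/2) is an unbiased estimate of
# log sigma_g^2; its excess variance over trigamma(df/2) identifies d0.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    return(list(d0 = 0, s02 = 0))
  }
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e)
  rhs <- evar - trigamma(df / 2)
  if (is.na(rhs) || rhs <= 0) {
    # no excess dispersion beyond sampling noise: variances are exchangeable
    # and the prior collapses onto their plain average
    list(d0 = Inf, s02 = mean(s2[ok]))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Per-stage moderated t-test against the shared control group
#'
#' Compares the case samples of one stage with the single control group,
#' gene by gene. With `moderation = "moderated"` the residual variance of
#' each gene is shrunk toward a common prior,
#' `s_tilde^2 = (d0 s0^2 + df s^2) / (d0 + df)`, with the prior degrees of
#' freedom `d0` and prior variance `s0^2` estimated by moment-matching the
#' scaled-chi-square distribution of the gene-wise variances; the moderated
#' statistic `t = log2fc / (s_tilde sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `df + d0` degrees of freedom. With
#' `moderation = "ordinary"` (`d0 = 0`) the statistic is exactly the pooled
#' two-sample t.
#'
#' @param expr Gene-level expression tibble (first column gene ids).
#' @param samples Sample annotation tibble with `sample_id`, `group`
#'   (`case`/`control`) and `stage`.
#' @param stage Stage whose cases are tested.
#' @param cfg A [de_config()].
#' @return A `de_table` tibble: per gene `mean_case`, `mean_control`,
#'   `log2fc`, `fold_change` (`2^|log2fc|`), `s2`, `df`, `t`, `p_value`,
#'   `adj_p` (BH) and the `sde` flag. The fitted prior is attached as
#'   attributes `d0` and `s02`.
#' @export
moderated_t_test <- function(expr, samples, stage, cfg = de_config()) {
  x <- expr_matrix(expr)
  case_ids <- samples$sample_id[samples$group == "case" &
                                  !is.na(samples$stage) &
                                  samples$stage == stage]
  ctrl_ids <- samples$sample_id[samples$group == "control"]
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    abort(sprintf("stage %s needs at least 2 case and 2 control samples", stage),
          class = "ffldyn_input_error")
  }
  xc <- x[, case_ids, drop = FALSE]
  xk <- x[, ctrl_ids, drop = FALSE]
  n1 <- ncol(xc); n2 <- ncol(xk)
  mc <- rowMeans(xc); mk <- rowMeans(xk)
  df <- n1 + n2 - 2
  ss <- rowSums((xc - mc)^2) + rowSums((xk - mk)^2)
  s2 <- ss / df
  lfc <- mc - mk

  if (cfg$moderation == "moderated") {
    prior <- fit_variance_prior(s2, df)
  } else {
    prior <- list(d0 = 0, s02 = 0)
  }
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) rep(prior$s02, length(s2)) else {
    (d0 * prior$s02 + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- df + d0
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_stat)) else {
    2 * pt(-abs(t_stat), df = df_total)
  }
  p[se == 0 & lfc == 0] <- 1

  out <- tibble::tibble(
    gene = rownames(x),
    stage = stage,
    mean_case = unname(mc),
    mean_control = unname(mk),
    log2fc = unname(lfc),
    fold_change = unname(2^abs(lfc)),
    s2 = unname(s2),
    df = df,
    t = unname(t_stat),
    p_value = unname(p),
    adj_p = unname(bh_adjust(unname(p)))
  )
  out$sde <- out$adj_p < cfg$adj_p_threshold &
    out$fold_change > cfg$fc_threshold
  attr(out, "d0") <- d0
  attr(out, "s02") <- prior$s02
  class(out) <- c("de_table", class(out))
  out
}

#' Run differential expression for every stage
#'
#' @inheritParams moderated_t_test
#' @param stages Stages to test (default: all stages present among cases).
#' @return A combined `de_table` tibble with a `stage` column.
#' @export
diffexpr_stages <- function(expr, samples, cfg = de_config(), stages = NULL) {
  stages <- stages %||% sort(unique(samples$stage[!is.na(samples$stage)]))
  out <- purrr::map(stages, function(s) moderated_t_test(expr, samples, s, cfg))
  out <- dplyr::bind_rows(out)
  class(out) <- c("de_table", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns the step-up adjusted p-values
#' `q(i) = min_{k >= i} m p(k) / k` (over the ascending sort, capped at 1),
#' in the original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be numbers in [0, 1]", class = "ffldyn_input_error")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Call significantly differentially expressed genes
#'
#' @param det A `de_table` (one stage, or filter by stage first).
#' @param cfg A [de_config()]; both cutoffs are strict.
#' @return Sorted character vector of SDE gene ids.
#' @export
call_sde <- function(det, cfg = de_config()) {
  sort(det$gene[det$adj_p < cfg$adj_p_threshold &
                  det$fold_change > cfg$fc_threshold])
}

#' Summarise SDE sets across stages
#'
#' @param det Combined `de_table` with a `stage` column and `sde` flags.
#' @return A list with `per_stage` (tibble of stage and SDE count),
#'   `union_size`, `union` and `shared` (the genes SDE at every stage).
#' @export
sde_summary <- function(det) {
  stages <- sort(unique(det$stage))
  if (length(stages) < 2) {
    abort("sde_summary needs results for at least two stages",
          class = "ffldyn_input_error")
  }
  sets <- purrr::map(stages, function(s) det$gene[det$stage == s & det$sde])
  names(sets) <- as.character(stages)
  list(
    per_stage = tibble::tibble(stage = stages,
                               n_sde = unname(purrr::map_int(sets, length))),
    union = sort(Reduce(union, sets)),
    union_size = length(Reduce(union, sets)),
    shared = sort(Reduce(intersect, sets))
  )
}

#' Rank and take the top-k SDE genes
#'
#' Genes are ranked by their minimum adjusted p across stages, ties broken
#' by the larger maximum |log2 fold change|, then lexicographically by id.
#'
#' @param det Combined `de_table`.
#' @param k Number of genes to return.
#' @param genes Optional candidate set (e.g. the shared SDE genes); default
#'   all SDE genes of any stage.
#' @return Character vector of the first `k` ranked genes (truncated with a
#'   warning if fewer candidates exist).
#' @export
top_k_genes <- function(det, k, genes = NULL) {
  candidates <- genes %||% unique(det$gene[det$sde])
  ranked <- det |>
    dplyr::filter(.data$gene %in% candidates) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(min_adj_p = min(.data$adj_p),
                     max_abs_lfc = max(abs(.data$log2fc)),
                     .groups = "drop") |>
    dplyr::arrange(.data$min_adj_p, dplyr::desc(.data$max_abs_lfc),
                   .data$gene)
  if (k > nrow(ranked)) {
    warn(sprintf("requested k = %d but only %d candidates; truncating",
                 k, nrow(ranked)))
    k <- nrow(ranked)
  }
  ranked$gene[seq_len(k)]
}
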