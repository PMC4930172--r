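make_de_fixture <- function(n_genes = 20, n1 = 6, n2 = 8, seed = 5,
                            shift_first = 0, vary_sd = FALSE) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  sds <- if (vary_sd) runif(n_genes, 0.2, 1.5) else rep(0.6, n_genes)
  ctrl <- matrix(rnorm(n_genes * n2, 8, sds), n_genes,
                 dimnames = list(genes, sprintf("ctrl_%02d", 1:n2)))
  case <- matrix(rnorm(n_genes * n1, 8, sds), n_genes,
                 dimnames = list(genes, sprintf("case_s1_%02d", 1:n1)))
  case[1, ] <- case[1, ] + shift_first
  expr <- ffldyn:::expr_tibble(cbind(ctrl, case))
  samples <- tibble::tibble(
    sample_id = c(colnames(ctrl), colnames(case)),
    group = c(rep("control", n2), rep("case", n1)),
    stage = c(rep(NA_integer_, n2), rep(1L, n1)),
    recurrence = NA_character_)
  list(expr = expr, samples = samples)
}

test_that("ordinary mode reproduces the pooled two-sample t exactly", {
  fx <- make_de_fixture(shift_first = 1.5)
  det <- moderated_t_test(fx$expr, fx$samples, stage = 1,
                          cfg = de_config(moderation = "ordinary"))
  x <- ffldyn:::expr_matrix(fx$expr)
  for (g in det$gene) {
    tt <- t.test(x[g, fx$samples$group == "case"],
                 x[g, fx$samples$group == "control"], var.equal = TRUE)
    expect_equal(det$t[det$gene == g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(det$p_value[det$gene == g], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  fx <- make_de_fixture(n_genes = 200, seed = 8, shift_first = 2,
                        vary_sd = TRUE)
  det <- moderated_t_test(fx$expr, fx$samples, stage = 1)
  x <- ffldyn:::expr_matrix(fx$expr)
  design <- cbind(1, as.integer(fx$samples$group == "case"))
  fit <- limma::eBayes(limma::lmFit(x[, fx$samples$sample_id], design))
  expect_equal(unname(attr(det, "d0")), unname(fit$df.prior),
               tolerance = 1e-6)
  expect_equal(unname(attr(det, "s02")), unname(fit$s2.prior),
               tolerance = 1e-6)
  expect_equal(det$t, unname(fit$t[det$gene, 2]), tolerance = 1e-8)
  expect_equal(det$p_value, unname(fit$p.value[det$gene, 2]),
               tolerance = 1e-8)
})

test_that("degenerate genes give t = 0 and p = 1, not NaN", {
  fx <- make_de_fixture(n_genes = 5)
  x <- ffldyn:::expr_matrix(fx$expr)
  x[1, ] <- 3.25  # identical constant in both groups
  det <- moderated_t_test(ffldyn:::expr_tibble(x), fx$samples, 1,
                          de_config(moderation = "ordinary"))
  expect_equal(det$t[1], 0)
  expect_equal(det$p_value[1], 1)
  expect_equal(det$log2fc[1], 0)
})

test_that("in the infinite-prior limit all variances shrink to s0^2", {
  prior <- ffldyn:::fit_variance_prior(rep(1.3, 40), df = 10)
  expect_identical(prior$d0, Inf)
  d0 <- prior$d0; s02 <- prior$s02; df <- 10
  s2 <- runif(40, 0.5, 3)
  shrunk <- if (is.infinite(d0)) rep(s02, 40) else
    (d0 * s02 + df * s2) / (d0 + df)
  expect_true(all(shrunk == s02))
})

test_that("bh_adjust matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ffldyn_input_error")
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
})

test_that("SDE calling applies both thresholds strictly", {
  det <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    adj_p = c(0.0005, 0.0005, 0.001, 0.0002),
    fold_change = c(1.3, 1.1, 1.5, 1.2))
  out <- call_sde(det)
  expect_equal(out, "a")  # b fails fc, c fails p (boundary), d fails fc boundary
})

test_that("stage summary and top-k agree with direct set algebra and sorting", {
  det <- tibble::tibble(
    gene = rep(c("a", "b", "c", "d"), 3),
    stage = rep(1:3, each = 4),
    log2fc = c(2, 1, 0.5, 1, 2, 1, 0.5, 1, 2, 1, 0.5, 1),
    adj_p = c(1e-6, 1e-4, 0.5, 1e-5, 1e-5, 1e-4, 0.5, 0.9,
              1e-4, 1e-4, 0.5, 0.9),
    sde = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
            TRUE, TRUE, FALSE, FALSE))
  s <- sde_summary(det)
  expect_equal(s$per_stage$n_sde, c(3L, 2L, 2L))
  expect_equal(s$shared, c("a", "b"))
  expect_equal(s$union_size, 3)

  # identical sets at all stages: union equals intersection
  det2 <- dplyr::mutate(det, sde = rep(c(TRUE, TRUE, FALSE, FALSE), 3))
  s2 <- sde_summary(det2)
  expect_equal(s2$union, s2$shared)

  expect_equal(top_k_genes(det, 2), c("a", "d"))
  ranked_oracle <- det |>
    dplyr::group_by(gene) |>
    dplyr::summarise(mp = min(adj_p), ml = max(abs(log2fc))) |>
    dplyr::arrange(mp, dplyr::desc(ml), gene)
  expect_equal(top_k_genes(det, 3, genes = c("a", "b", "c", "d")),
               ranked_oracle$gene[1:3])
  expect_warning(top_k_genes(det, 10), "truncating")
})

test_that("null simulations keep the raw type-I rate near nominal", {
  cfg <- sim_config(n_genes = 2000, de_log2fc = 0, n_stages = 1, seed = 77)
  sim <- simulate_expression(cfg)
  det <- moderated_t_test(sim$expr, sim$samples, 1)
  frac <- mean(det$p_value < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), se3)
})

test_that("stronger planted effects never reduce recovery (monotone power)", {
  recalls <- vapply(c(0.3, 0.6, 1.2), function(lfc) {
    hits <- vapply(1:5, function(r) {
      cfg <- sim_config(n_genes = 500, de_log2fc = lfc, n_stages = 1,
                        frac_low_intensity = 0, seed = 100 + r)
      sim <- simulate_expression(cfg)
      det <- moderated_t_test(sim$expr, sim$samples, 1)
      planted <- sim$truth$de_genes_per_stage[[1]]
      length(intersect(call_sde(det), planted)) / length(planted)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(recalls) >= -0.02))
})
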