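#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults emulate the design of a three-stage myocardial-infarction cohort:
#' a shared control group of 14 stable-CAD patients and 28 cases sampled at
#' the acute, subacute and chronic phases, profiled on a log2 microarray
#' scale. Planted differential expression decays across stages so that the
#' acute phase carries the largest significant set, and a subset of planted
#' feed-forward loops (FFLs), enriched gene sets and a two-gene biomarker
#' signal give every downstream module a known ground truth to recover.
#'
#' @param n_genes Number of protein-coding genes in the universe.
#' @param n_mirnas Number of miRNA identifiers available to the catalog.
#' @param n_tfs Number of genes that are transcription factors (the first
#'   `n_tfs` gene ids double as the TF registry).
#' @param n_controls Control samples (no stage label).
#' @param n_cases_per_stage Case samples per stage.
#' @param n_stages Number of disease stages (default 3: acute, subacute,
#'   chronic).
#' @param frac_de_per_stage Fraction of genes planted as differentially
#'   expressed at stage 1; persistence thins the set at later stages.
#' @param de_log2fc Planted |log2 fold change| at stage 1.
#' @param de_decay Multiplicative decay of the planted effect per stage, so
#'   stage-s effect is `de_log2fc * de_decay^(s-1)`; gives the acute >
#'   subacute > chronic ordering of significant counts.
#' @param de_persistence Probability that a planted gene stays active at the
#'   next stage (once inactive it stays inactive).
#' @param noise_sd Per-gene Gaussian noise standard deviation on the log2
#'   scale.
#' @param frac_low_intensity Fraction of non-planted genes whose baseline
#'   mean is centred near 5 so the intensity-7 probe filter is exercised.
#' @param n_planted_ffls Number of planted miRNA-TF-gene feed-forward loops.
#' @param n_decoy_edges Number of decoy catalog edges added around the
#'   planted loops.
#' @param n_gene_sets Number of gene sets (subpathways) emitted.
#' @param set_size_range Length-2 integer vector, min/max genes per set.
#' @param planted_enriched_sets Number of sets built to be enriched for
#'   stage-1 DE genes.
#' @param planted_set_de_frac Fraction of each planted set drawn from the
#'   stage-1 DE genes (>= 0.5).
#' @param biomarker_delta Class-mean separation of the two biomarker genes,
#'   in units of `noise_sd`.
#' @param seed Integer seed; together with the configuration it fully
#'   determines every simulated output.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_controls = 6, n_cases_per_stage = 8)
#' cfg$n_stages
sim_config <- function(n_genes = 2000,
                       n_mirnas = 30,
                       n_tfs = 60,
                       n_controls = 14,
                       n_cases_per_stage = 28,
                       n_stages = 3,
                       frac_de_per_stage = 0.1,
                       de_log2fc = 1.0,
                       de_decay = 0.7,
                       de_persistence = 0.7,
                       noise_sd = 0.5,
                       frac_low_intensity = 0.05,
                       n_planted_ffls = 10,
                       n_decoy_edges = 200,
                       n_gene_sets = 50,
                       set_size_range = c(10L, 40L),
                       planted_enriched_sets = 5,
                       planted_set_de_frac = 0.75,
                       biomarker_delta = 2,
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", 10L),
    n_mirnas = check_count(n_mirnas, "n_mirnas"),
    n_tfs = check_count(n_tfs, "n_tfs"),
    n_controls = check_count(n_controls, "n_controls", 2L),
    n_cases_per_stage = check_count(n_cases_per_stage, "n_cases_per_stage", 2L),
    n_stages = check_count(n_stages, "n_stages"),
    frac_de_per_stage = frac_de_per_stage,
    de_log2fc = de_log2fc,
    de_decay = de_decay,
    de_persistence = de_persistence,
    noise_sd = noise_sd,
    frac_low_intensity = frac_low_intensity,
    n_planted_ffls = check_count(n_planted_ffls, "n_planted_ffls", 0L),
    n_decoy_edges = check_count(n_decoy_edges, "n_decoy_edges", 0L),
    n_gene_sets = check_count(n_gene_sets, "n_gene_sets", 0L),
    set_size_range = set_size_range,
    planted_enriched_sets = check_count(planted_enriched_sets,
                                        "planted_enriched_sets", 0L),
    planted_set_de_frac = planted_set_de_frac,
    biomarker_delta = biomarker_delta,
    seed = check_count(seed, "seed", 0L)
  )
  check_scalar_number(frac_de_per_stage, "frac_de_per_stage", 0, 1,
                      strict_lower = TRUE)
  if (frac_de_per_stage >= 1) {
    abort("invalid configuration: field `frac_de_per_stage` must be < 1",
          class = "ffldyn_config_error")
  }
  check_scalar_number(de_log2fc, "de_log2fc", 0)
  check_scalar_number(de_decay, "de_decay", 0, 1, strict_lower = TRUE)
  check_scalar_number(de_persistence, "de_persistence", 0, 1)
  check_scalar_number(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  check_scalar_number(frac_low_intensity, "frac_low_intensity", 0, 0.5)
  check_scalar_number(planted_set_de_frac, "planted_set_de_frac", 0.5, 1)
  check_scalar_number(biomarker_delta, "biomarker_delta", 0)
  if (!is.numeric(set_size_range) || length(set_size_range) != 2 ||
      any(set_size_range < 1) || set_size_range[1] > set_size_range[2]) {
    abort("invalid configuration: field `set_size_range` must be c(min, max) with 1 <= min <= max",
          class = "ffldyn_config_error")
  }
  cfg$set_size_range <- as.integer(set_size_range)
  if (cfg$n_tfs >= cfg$n_genes) {
    abort("invalid configuration: field `n_tfs` must be smaller than `n_genes`",
          class = "ffldyn_config_error")
  }
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(cfg) {
  c(sprintf("TF%04d", seq_len(cfg$n_tfs)),
    sprintf("G%05d", seq_len(cfg$n_genes - cfg$n_tfs)))
}

sim_mirna_ids <- function(cfg) {
  sprintf("hsa-mir-%04d", seq_len(cfg$n_mirnas))
}

#' Simulate a stage-resolved expression matrix with ground truth
#'
#' Draws a log2 expression matrix for `n_controls` control samples and
#' `n_cases_per_stage` case samples at each stage. Controls are gene-wise
#' `Normal(mu_g, noise_sd^2)`; at stage `s` planted genes are shifted by
#' `sign_g * de_log2fc * de_decay^(s-1)` while they remain active. Baseline
#' means are `Normal(10, 1.5^2)` except for a low-intensity fraction centred
#' near 5, so the intensity filter has something to remove. Two always-active
#' planted genes are designated biomarkers and carry a fixed shift of
#' `biomarker_delta * noise_sd` at every stage.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `expr`: tibble, `feature_id` plus one column per sample (log2 values);
#'   * `samples`: tibble with `sample_id`, `group` (`case`/`control`),
#'     `stage` (integer, `NA` for controls), `recurrence` (`NA`; no
#'     recurrence signal is planted in the matrix);
#'   * `truth`: ground-truth list (`de_genes_per_stage`, `de_signs`,
#'     `biomarker_genes`, `class_labels`, id registries, ...).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 100, n_controls = 4,
#'                                       n_cases_per_stage = 4, seed = 7))
#' dim(sim$expr)
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  genes <- sim_gene_ids(config)
  tfs <- genes[seq_len(config$n_tfs)]
  n <- config$n_genes

  # de_log2fc = 0 is the global null: nothing is planted, including the
  # biomarker shift, so every gene is identically distributed in both groups
  n_de <- if (config$de_log2fc == 0) 0L else
    max(0L, round(config$frac_de_per_stage * n))
  # Guarantee DE TFs so feed-forward loops can be planted on stage-1 SDE TFs.
  n_tf_de <- min(config$n_tfs,
                 max(ceiling(n_de * config$n_tfs / n),
                     min(config$n_tfs, config$n_planted_ffls)))
  n_tf_de <- min(n_tf_de, n_de)
  de_tf <- sample(tfs, n_tf_de)
  de_other <- sample(setdiff(genes, tfs), n_de - n_tf_de)
  planted <- c(de_tf, de_other)

  mu <- rnorm(n, mean = 10, sd = 1.5)
  names(mu) <- genes
  n_low <- round(config$frac_low_intensity * n)
  low_pool <- setdiff(genes, planted)
  low_genes <- if (n_low > 0) sample(low_pool, min(n_low, length(low_pool))) else character()
  mu[low_genes] <- rnorm(length(low_genes), mean = 5, sd = 0.3)

  signs <- sample(c(-1, 1), length(planted), replace = TRUE)
  names(signs) <- planted

  # Activity span: every planted gene active at stage 1; thereafter each
  # active gene persists with probability de_persistence.
  active <- matrix(FALSE, nrow = length(planted), ncol = config$n_stages,
                   dimnames = list(planted, NULL))
  if (length(planted) > 0) {
    active[, 1] <- TRUE
    if (config$n_stages > 1) {
      for (s in 2:config$n_stages) {
        keep <- rbinom(length(planted), 1, config$de_persistence) == 1
        active[, s] <- active[, s - 1] & keep
      }
    }
  }

  # Biomarkers: two non-TF planted genes, forced active at all stages with a
  # constant shift of biomarker_delta * noise_sd.
  biomarkers <- character()
  if (length(de_other) >= 2) {
    biomarkers <- sample(de_other, 2)
    active[biomarkers, ] <- TRUE
  }

  effect <- matrix(0, nrow = n, ncol = config$n_stages,
                   dimnames = list(genes, NULL))
  for (s in seq_len(config$n_stages)) {
    amp <- config$de_log2fc * config$de_decay^(s - 1)
    idx <- planted[active[, s]]
    effect[idx, s] <- signs[idx] * amp
    effect[biomarkers, s] <- signs[biomarkers] *
      config$biomarker_delta * config$noise_sd
  }

  ctrl_ids <- sprintf("ctrl_%02d", seq_len(config$n_controls))
  case_ids <- unlist(lapply(seq_len(config$n_stages), function(s) {
    sprintf("case_s%d_%02d", s, seq_len(config$n_cases_per_stage))
  }))
  x <- matrix(NA_real_, nrow = n, ncol = length(ctrl_ids) + length(case_ids),
              dimnames = list(genes, c(ctrl_ids, case_ids)))
  x[, ctrl_ids] <- mu + rnorm(n * length(ctrl_ids), sd = config$noise_sd)
  for (s in seq_len(config$n_stages)) {
    ids <- sprintf("case_s%d_%02d", s, seq_len(config$n_cases_per_stage))
    x[, ids] <- mu + effect[, s] +
      rnorm(n * length(ids), sd = config$noise_sd)
  }

  samples <- tibble::tibble(
    sample_id = colnames(x),
    group = c(rep("control", length(ctrl_ids)),
              rep("case", length(case_ids))),
    stage = c(rep(NA_integer_, length(ctrl_ids)),
              rep(seq_len(config$n_stages), each = config$n_cases_per_stage)),
    recurrence = NA_character_
  )

  truth <- list(
    genes = genes,
    tfs = tfs,
    mirnas = sim_mirna_ids(config),
    de_genes_per_stage = lapply(seq_len(config$n_stages), function(s) {
      sort(planted[active[, s]])
    }),
    de_signs = signs,
    effect_per_stage = effect[planted, , drop = FALSE],
    low_intensity_genes = sort(low_genes),
    biomarker_genes = biomarkers,
    class_labels = setNames(samples$group, samples$sample_id),
    planted_ffls = tibble::tibble(mirna = character(), tf = character(),
                                  gene = character()),
    enriched_sets = character()
  )

  list(expr = expr_tibble(x), samples = samples, truth = truth)
}

#' Simulate a typed regulatory interaction catalog with planted FFLs
#'
#' Plants `n_planted_ffls` feed-forward loops: for each triple
#' `(miRNA m, TF t, gene g)` the four edges `m->t`, `t->m`, `m->g`, `t->g`
#' are emitted, with `t` and `g` drawn from the stage-1 DE genes. Decoy edges
#' are then added by rejection sampling under the constraint that no decoy
#' completes an additional FFL whose TF and target are both DE at any stage,
#' so the enumerable FFL set over the DE genes is exactly the planted set.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @return A list with `catalog` (an `interaction_catalog` tibble:
#'   `source_id`, `target_id`, `edge_type`, `evidence`) and `truth` (the
#'   input ground truth with `planted_ffls` filled in).
#' @export
simulate_catalog <- function(config, truth) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed + 1L)
  mirnas <- truth$mirnas
  tfs <- truth$tfs
  genes <- truth$genes
  de1 <- truth$de_genes_per_stage[[1]]
  de_union <- sort(unique(unlist(truth$de_genes_per_stage)))
  de_tfs <- intersect(tfs, de1)
  de_targets <- setdiff(de1, tfs)

  n_ffl <- config$n_planted_ffls
  if (n_ffl > 0 &&
      (length(de_tfs) < 1 || length(de_targets) < n_ffl)) {
    abort("cannot plant FFLs: not enough stage-1 DE TFs or target genes; increase frac_de_per_stage or n_genes",
          class = "ffldyn_sim_error")
  }

  edges <- tibble::tibble(source_id = character(), target_id = character(),
                          edge_type = character(), evidence = character())
  planted <- tibble::tibble(mirna = character(), tf = character(),
                            gene = character())
  if (n_ffl > 0) {
    m_pick <- sample(mirnas, n_ffl, replace = n_ffl > length(mirnas))
    t_pick <- sample(de_tfs, n_ffl, replace = n_ffl > length(de_tfs))
    g_pick <- sample(de_targets, n_ffl)  # distinct targets => distinct triples
    planted <- tibble::tibble(mirna = m_pick, tf = t_pick, gene = g_pick)
    edges <- dplyr::bind_rows(
      tibble::tibble(source_id = m_pick, target_id = t_pick,
                     edge_type = "mirna_tf", evidence = "planted"),
      tibble::tibble(source_id = t_pick, target_id = m_pick,
                     edge_type = "tf_mirna", evidence = "planted"),
      tibble::tibble(source_id = m_pick, target_id = g_pick,
                     edge_type = "mirna_gene", evidence = "planted"),
      tibble::tibble(source_id = t_pick, target_id = g_pick,
                     edge_type = "tf_gene", evidence = "planted")
    ) |> dplyr::distinct(.data$source_id, .data$target_id, .data$edge_type,
                         .keep_all = TRUE)
  }

  # Mutable edge index for the rejection test.
  ekey <- function(s, t, ty) paste(s, t, ty, sep = "\r")
  have <- new.env(parent = emptyenv())
  for (k in ekey(edges$source_id, edges$target_id, edges$edge_type)) {
    assign(k, TRUE, envir = have)
  }
  has_edge <- function(s, t, ty) exists(ekey(s, t, ty), envir = have)
  planted_key <- paste(planted$mirna, planted$tf, planted$gene, sep = "\r")
  is_de <- setNames(rep(TRUE, length(de_union)), de_union)

  cur <- edges
  # target lists rebuilt lazily; small scale makes direct scans affordable
  mirna_targets <- function(m) {
    cur$target_id[cur$source_id == m &
                    cur$edge_type %in% c("mirna_gene", "mirna_tf")]
  }
  tf_targets <- function(t) {
    cur$target_id[cur$source_id == t & cur$edge_type == "tf_gene"]
  }
  mutual_tfs <- function(m) {
    outs <- cur$target_id[cur$source_id == m & cur$edge_type == "mirna_tf"]
    ins <- cur$source_id[cur$target_id == m & cur$edge_type == "tf_mirna"]
    intersect(outs, ins)
  }
  mutual_mirnas <- function(t) {
    outs <- cur$target_id[cur$source_id == t & cur$edge_type == "tf_mirna"]
    ins <- cur$source_id[cur$target_id == t & cur$edge_type == "mirna_tf"]
    intersect(outs, ins)
  }
  new_motifs <- function(m, t, g) {
    # motifs among (mutual pair m,t) sharing target g, restricted to DE t,g
    key <- paste(m, t, g, sep = "\r")
    isTRUE(is_de[t]) && isTRUE(is_de[g]) && !(key %in% planted_key)
  }
  completes_bad_motif <- function(s, t, ty) {
    if (ty == "mirna_gene") {
      for (tf in mutual_tfs(s)) {
        if (t %in% tf_targets(tf) && new_motifs(s, tf, t)) return(TRUE)
      }
    } else if (ty == "tf_gene") {
      for (m in mutual_mirnas(s)) {
        if (t %in% mirna_targets(m) && new_motifs(m, s, t)) return(TRUE)
      }
    } else if (ty == "mirna_tf") {
      if (has_edge(t, s, "tf_mirna")) {
        shared <- intersect(c(mirna_targets(s), t), tf_targets(t))
        for (g in shared) if (new_motifs(s, t, g)) return(TRUE)
      }
      # t also becomes a target of s: check existing mutual partners of s
      for (tf in mutual_tfs(s)) {
        if (t %in% tf_targets(tf) && new_motifs(s, tf, t)) return(TRUE)
      }
    } else if (ty == "tf_mirna") {
      if (has_edge(t, s, "mirna_tf")) {
        shared <- intersect(mirna_targets(t), tf_targets(s))
        for (g in shared) if (new_motifs(t, s, g)) return(TRUE)
      }
    }
    FALSE
  }

  n_decoy <- config$n_decoy_edges
  added <- 0L
  attempts <- 0L
  max_attempts <- 100L * max(1L, n_decoy)
  types <- c("mirna_gene", "mirna_tf", "tf_gene", "tf_mirna")
  while (added < n_decoy && attempts < max_attempts) {
    attempts <- attempts + 1L
    ty <- sample(types, 1)
    src <- switch(ty,
                  mirna_gene = sample(mirnas, 1),
                  mirna_tf = sample(mirnas, 1),
                  tf_gene = sample(tfs, 1),
                  tf_mirna = sample(tfs, 1))
    tgt <- switch(ty,
                  mirna_gene = sample(genes, 1),
                  mirna_tf = sample(tfs, 1),
                  tf_gene = sample(genes, 1),
                  tf_mirna = sample(mirnas, 1))
    if (src == tgt && ty != "tf_gene") next
    if (has_edge(src, tgt, ty)) next
    if (completes_bad_motif(src, tgt, ty)) next
    cur <- dplyr::bind_rows(cur, tibble::tibble(
      source_id = src, target_id = tgt, edge_type = ty, evidence = "decoy"))
    assign(ekey(src, tgt, ty), TRUE, envir = have)
    added <- added + 1L
  }
  if (added < n_decoy) {
    abort(sprintf("decoy constraint unsatisfiable: placed %d of %d decoys after %d attempts; reduce n_decoy_edges",
                  added, n_decoy, max_attempts),
          class = "ffldyn_sim_error")
  }

  truth$planted_ffls <- dplyr::arrange(planted, .data$mirna, .data$tf,
                                       .data$gene)
  catalog <- new_catalog(cur, tfs = tfs, mirnas = mirnas)
  list(catalog = catalog, truth = truth)
}

#' Simulate subpathway gene sets with planted enrichment
#'
#' Emits `n_gene_sets` gene sets over the simulated gene universe. The first
#' `planted_enriched_sets` sets draw `planted_set_de_frac` of their members
#' from the stage-1 DE genes (so a hypergeometric test on the stage-1 SDE
#' list finds them); the rest are uniform draws. Consecutive pairs of sets
#' share a parent pathway id, exercising the minimum-p subpathway collapse.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @return A `gene_set_collection` tibble (`set_id`, `parent_id`, `genes`
#'   list-column) with the gene universe in `attr(, "universe")`; the ids of
#'   planted sets are recorded in `attr(, "planted_sets")`.
#' @export
simulate_gene_sets <- function(config, truth) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed + 2L)
  genes <- truth$genes
  de1 <- truth$de_genes_per_stage[[1]]
  rng <- config$set_size_range
  if (rng[2] > length(genes)) {
    abort("invalid configuration: field `set_size_range` exceeds the gene universe",
          class = "ffldyn_config_error")
  }
  n_sets <- config$n_gene_sets
  n_planted <- min(config$planted_enriched_sets, n_sets)
  sizes <- sample(seq(rng[1], rng[2]), n_sets, replace = TRUE)
  ids <- sprintf("SP%03d", seq_len(n_sets))
  parents <- sprintf("P%03d", ceiling(seq_len(n_sets) / 2))
  non_de <- setdiff(genes, de1)
  members <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_planted && length(de1) > 0) {
      k_de <- min(length(de1), max(1L, round(config$planted_set_de_frac * sizes[i])))
      members[[i]] <- sort(c(sample(de1, k_de),
                             sample(non_de, sizes[i] - k_de)))
    } else {
      members[[i]] <- sort(sample(genes, sizes[i]))
    }
  }
  out <- tibble::tibble(set_id = ids, parent_id = parents, genes = members)
  attr(out, "universe") <- genes
  attr(out, "planted_sets") <- ids[seq_len(n_planted)]
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Simulate a small Gaussian feature panel with a planted class signal
#'
#' Convenience generator for classifier calibration: two classes of
#' `n_per_class` samples with each feature shifted by `delta * sd` between
#' classes. With one feature the population ROC AUC is
#' `pnorm(delta / sqrt(2))`.
#'
#' @param n_per_class Samples per class.
#' @param delta Standardized mean difference per feature.
#' @param n_features Number of features.
#' @param sd Within-class standard deviation.
#' @param seed Integer seed.
#' @return A tibble with feature columns `x1..xk` and a `label` column
#'   (factor, levels `neg` < `pos`).
#' @export
simulate_panel <- function(n_per_class = 100, delta = 1, n_features = 1,
                           sd = 1, seed = 1L) {
  check_count(n_per_class, "n_per_class", 2L)
  check_scalar_number(delta, "delta")
  check_count(n_features, "n_features")
  check_scalar_number(sd, "sd", 0, strict_lower = TRUE)
  set.seed(seed)
  n <- 2L * n_per_class
  x <- matrix(rnorm(n * n_features, sd = sd), nrow = n)
  x[seq_len(n_per_class) + n_per_class, ] <-
    x[seq_len(n_per_class) + n_per_class, ] + delta * sd
  colnames(x) <- paste0("x", seq_len(n_features))
  out <- tibble::as_tibble(x)
  out$label <- factor(rep(c("neg", "pos"), each = n_per_class),
                      levels = c("neg", "pos"))
  out
}

#' Write all simulated pipeline inputs to disk
#'
#' Serialises a simulation to the plain-text interchange formats the loaders
#' read back: expression TSV, sample-annotation TSV, catalog TSV, GMT gene
#' sets plus a subpathway-to-pathway map TSV, a TF list, and the ground
#' truth as JSON.
#'
#' @param sim Result of [simulate_expression()].
#' @param catalog An `interaction_catalog` (from [simulate_catalog()]).
#' @param sets A `gene_set_collection` (from [simulate_gene_sets()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_sim_inputs <- function(sim, catalog, sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    subpathway_map = file.path(dir, "subpathway_map.tsv"),
    tf_list = file.path(dir, "tf_list.txt"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(sim$expr, paths[["expression"]])
  readr::write_tsv(sim$samples, paths[["samples"]])
  readr::write_tsv(as.data.frame(catalog), paths[["catalog"]])
  write_gmt(sets, paths[["gene_sets"]])
  readr::write_tsv(
    tibble::tibble(subpathway_id = sets$set_id, parent_pathway_id = sets$parent_id),
    paths[["subpathway_map"]])
  writeLines(sim$truth$tfs, paths[["tf_list"]])
  truth <- sim$truth
  truth$effect_per_stage <- NULL
  jsonlite::write_json(truth, paths[["ground_truth"]], auto_unbox = FALSE,
                       digits = NA)
  invisible(paths)
}
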