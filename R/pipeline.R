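#' Configuration for a full translatable-components run
#'
#' Inputs may be in-memory objects (as produced by the simulation and IO
#' readers) or file paths: Matrix Market directories for the two species,
#' a TSV ortholog table, a GMT collection and delimited drug tables.
#'
#' @param species_a,species_b reference / target species counts: an
#'   [expression_matrix()] or an MTX directory path.
#' @param orthologs ortholog pair table (`gene_a`, `gene_b`) or TSV path.
#' @param gene_sets optional `GeneSetCollection` or GMT path.
#' @param drug_signatures,drug_metadata optional drug tables or paths.
#' @param qc a [qc_thresholds()].
#' @param n_hvg variable genes selected on the reference species (default
#'   3250, capped at the available gene count).
#' @param n_components components to retain (default 50, capped at the
#'   matrix rank).
#' @param method `"pca"`, `"spca"` or `"both"`.
#' @param keep_per_component sparse-PCA nonzero budget (see
#'   [spca_decompose()]).
#' @param direction stepwise direction for [step_aic_glm()].
#' @param nperm GSEA permutations.
#' @param alpha significance level used for component selection, GSEA
#'   reporting and drug-gene selection.
#' @param min_overlap minimum drug/loading gene overlap.
#' @param max_enrich_components at most this many selected components are
#'   carried into GSEA and the drug screen (smallest index first).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a `run_config` list.
#' @export
run_config <- function(species_a, species_b, orthologs,
                       gene_sets = NULL, drug_signatures = NULL,
                       drug_metadata = NULL, qc = qc_thresholds(),
                       n_hvg = 3250L, n_components = 50L,
                       method = c("pca", "spca", "both"),
                       keep_per_component = NULL,
                       direction = c("backward", "both"),
                       nperm = 1000L, alpha = 0.05, min_overlap = 5L,
                       max_enrich_components = 5L, seed = 1L) {
  structure(list(species_a = species_a, species_b = species_b,
                 orthologs = orthologs, gene_sets = gene_sets,
                 drug_signatures = drug_signatures,
                 drug_metadata = drug_metadata, qc = qc,
                 n_hvg = as.integer(n_hvg),
                 n_components = as.integer(n_components),
                 method = match.arg(method),
                 keep_per_component = keep_per_component,
                 direction = match.arg(direction),
                 nperm = as.integer(nperm), alpha = alpha,
                 min_overlap = as.integer(min_overlap),
                 max_enrich_components = as.integer(max_enrich_components),
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x else read_counts_mtx(x)
}
resolve_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)))
  })
}

#' Run the full cross-species translatable-components workflow
#'
#' QC filtering of both species, variable-gene selection on the reference
#' species, ortholog alignment, per-species normalization and scaling,
#' decomposition of the reference matrix (dense and/or sparse), projection
#' of the target species, cross-species variance explained, stepwise-AIC
#' logistic regression of the target phenotype on the projected scores,
#' preranked enrichment of the selected components' loadings, and the drug
#' signature screen.  Deterministic under a fixed seed: each stochastic
#' stage gets a seed derived from the global one.
#'
#' @param config a [run_config()].
#' @return a `tcr_run`: list with `report` (serializable bundle, see
#'   [write_report()]) and `results` (the fitted objects per method).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  em_a <- run_stage("load_a", resolve_matrix(config$species_a))
  em_b <- run_stage("load_b", resolve_matrix(config$species_b))
  orth_raw <- run_stage("orthologs",
                        resolve_table(config$orthologs, read_ortholog_table))
  gene_sets <- if (!is.null(config$gene_sets)) {
    run_stage("gene_sets", resolve_table(config$gene_sets,
                                         read_gene_sets_gmt))
  }
  drugs <- if (!is.null(config$drug_signatures)) {
    run_stage("drug_tables", {
      sig <- if (is.character(config$drug_signatures)) {
        read_drug_signatures(config$drug_signatures,
                             config$drug_metadata)$signatures
      } else {
        config$drug_signatures
      }
      meta <- if (is.character(config$drug_metadata)) {
        read_drug_signatures(config$drug_signatures,
                             config$drug_metadata)$metadata
      } else {
        config$drug_metadata
      }
      list(signatures = sig, metadata = meta)
    })
  }

  qc_a <- run_stage("qc_a", qc_filter_cells(em_a, config$qc))
  qc_b <- run_stage("qc_b", qc_filter_cells(em_b, config$qc))

  map <- run_stage("ortholog_map", build_one_to_one_map(orth_raw))

  n_hvg <- min(config$n_hvg, length(qc_a$filtered$gene_ids))
  hvgs <- run_stage("hvg", select_hvgs(qc_a$filtered, n_hvg))
  sparsity_a <- compute_sparsity(qc_a$filtered, hvgs)

  # restrict the map to reference HVGs, then align both count matrices
  map_hvg <- map[map$gene_a %in% hvgs, , drop = FALSE]
  aligned <- run_stage("align",
                       align_matrices(qc_a$filtered, qc_b$filtered, map_hvg))
  scaled_a <- run_stage("scale_a", normalize_scale(aligned$a))
  scaled_b <- run_stage("scale_b", normalize_scale(aligned$b))

  n_comp <- min(config$n_components, length(scaled_a$gene_ids) - 1L,
                length(scaled_a$cell_ids) - 1L)
  methods_run <- if (config$method == "both") c("pca", "spca") else
    config$method

  results <- list()
  for (m in methods_run) {
    dec <- run_stage(paste0("decompose_", m), {
      if (m == "pca") {
        pca_decompose(scaled_a, n_comp)
      } else {
        spca_decompose(scaled_a, n_comp,
                       keep_per_component = config$keep_per_component)
      }
    })
    proj <- run_stage(paste0("project_", m),
                      project_cells(scaled_b, dec, map = map_hvg))
    fit <- run_stage(paste0("glm_", m), suppressWarnings(
      step_aic_glm(proj, direction = config$direction)))

    sig_comps <- fit$coefficients$term
    sig_comps <- sig_comps[sig_comps != "(Intercept)" &
                             fit$coefficients$p_value < config$alpha]
    sig_comps <- head(sig_comps[order(component_index(sig_comps))],
                      config$max_enrich_components)

    gsea_tabs <- list()
    drug_tabs <- list()
    for (comp in sig_comps) {
      load_vec <- dec$Q[, comp]
      if (!is.null(gene_sets)) {
        ranked <- suppressMessages(
          rank_genes_from_loadings(load_vec, map_hvg))
        gsea_tabs[[comp]] <- run_stage(
          paste0("gsea_", m, "_", comp),
          fgsea_preranked(ranked, gene_sets, nperm = config$nperm,
                          seed = stage_seed(config$seed,
                                            paste0("gsea_", m, "_", comp))))
      }
      if (!is.null(drugs)) {
        lv_b <- setNames(load_vec,
                         map_hvg$gene_b[match(names(load_vec),
                                              map_hvg$gene_a)])
        lv_b <- lv_b[!is.na(names(lv_b))]
        drug_tabs[[comp]] <- run_stage(
          paste0("drugscreen_", m, "_", comp), suppressMessages(
            screen_drugs(drugs$signatures, lv_b, drugs$metadata,
                         alpha = config$alpha,
                         min_overlap = config$min_overlap)))
      }
    }

    # orientation aid: per-component case vs control mean projected score
    cond <- scaled_b$cell_meta$condition
    score_means <- tibble::tibble(
      component = colnames(proj$projected_scores),
      mean_case = colMeans(proj$projected_scores[cond == "case", ,
                                                 drop = FALSE]),
      mean_control = colMeans(proj$projected_scores[cond == "control", ,
                                                    drop = FALSE]),
      variance_explained_a = dec$explained_variance_fraction,
      variance_explained_b = proj$variance_explained_in_b)

    results[[m]] <- list(decomposition = dec, projection = proj,
                         fit = fit, component_summary = score_means,
                         gsea = gsea_tabs, drug_screen = drug_tabs,
                         significant_components = sig_comps)
  }

  report <- list(
    parameters = config[setdiff(names(config),
                                c("species_a", "species_b", "orthologs",
                                  "gene_sets", "drug_signatures",
                                  "drug_metadata"))],
    qc = list(species_a = glance(qc_a$report),
              species_b = glance(qc_b$report)),
    ortholog_pairs = nrow(map),
    n_hvg_used = n_hvg,
    sparsity_reference_hvg = sparsity_a,
    n_aligned_genes = length(scaled_a$gene_ids),
    methods = purrr::imap(results, function(res, m) {
      list(component_summary = res$component_summary,
           glm = glance(res$fit),
           glm_coefficients = tidy(res$fit),
           selected_components = res$fit$selected_components,
           significant_components = res$significant_components,
           aic_trace = res$fit$aic_trace,
           gsea = res$gsea,
           drug_screen = res$drug_screen)
    }))
  structure(list(report = report, results = results, config = config),
            class = "tcr_run")
}

#' @export
print.tcr_run <- function(x, ...) {
  cat("<tcr_run>\n")
  for (m in names(x$results)) {
    fit <- x$results[[m]]$fit
    cat(sprintf("  %s: %d selected components, AIC = %.4f, AUC = %.4f\n",
                m, length(fit$selected_components), fit$aic, fit$auc))
  }
  invisible(x)
}

#' Benchmark decomposition methods over a grid of variable-gene counts
#'
#' For every `n_hvg` in the grid and each method, reruns variable-gene
#' selection, alignment, scaling, decomposition, projection and stepwise
#' model selection, recording the reference-matrix sparsity at that gene
#' count and the final model's AIC and AUC.
#'
#' @param config a [run_config()] (drug/GSEA inputs are ignored here).
#' @param hvg_grid integer vector of at least two `n_hvg` values.
#' @return tibble with columns `n_hvg`, `method`, `sparsity`, `aic`, `auc`,
#'   `n_selected`.
#' @export
benchmark_sweep <- function(config, hvg_grid) {
  assert_that(length(hvg_grid) >= 2, "hvg_grid needs at least 2 values")
  methods_run <- if (config$method == "both") c("pca", "spca") else
    config$method
  em_a <- resolve_matrix(config$species_a)
  em_b <- resolve_matrix(config$species_b)
  qc_a <- qc_filter_cells(em_a, config$qc)
  qc_b <- qc_filter_cells(em_b, config$qc)
  map <- build_one_to_one_map(resolve_table(config$orthologs,
                                            read_ortholog_table))
  purrr::map(as.integer(hvg_grid), function(nh) {
    nh <- min(nh, length(qc_a$filtered$gene_ids))
    hvgs <- select_hvgs(qc_a$filtered, nh)
    sparsity <- compute_sparsity(qc_a$filtered, hvgs)
    map_hvg <- map[map$gene_a %in% hvgs, , drop = FALSE]
    aligned <- align_matrices(qc_a$filtered, qc_b$filtered, map_hvg)
    scaled_a <- normalize_scale(aligned$a)
    scaled_b <- normalize_scale(aligned$b)
    n_comp <- min(config$n_components, length(scaled_a$gene_ids) - 1L,
                  length(scaled_a$cell_ids) - 1L)
    purrr::map(methods_run, function(m) {
      dec <- if (m == "pca") {
        pca_decompose(scaled_a, n_comp)
      } else {
        spca_decompose(scaled_a, n_comp,
                       keep_per_component = config$keep_per_component)
      }
      proj <- project_cells(scaled_b, dec, map = map_hvg)
      fit <- suppressWarnings(step_aic_glm(proj,
                                           direction = config$direction))
      tibble::tibble(n_hvg = nh, method = m, sparsity = sparsity,
                     aic = fit$aic, auc = fit$auc,
                     n_selected = length(fit$selected_components))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
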