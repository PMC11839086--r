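# shared fixtures: everything is generated in code, nothing read from disk

# a small paired-species simulation; QC thresholds scaled to the panel size
small_sim <- function(seed = 7, n_genes = 400L, n_orthologs = 250L,
                      n_cells = 150L, ...) {
  simulate_paired_species(sim_config(
    n_genes_a = n_genes, n_genes_b = n_genes, n_orthologs = n_orthologs,
    n_cells_per_group = n_cells, seed = seed, ...))
}

small_qc <- function() {
  qc_thresholds(min_genes_per_cell = 40L, min_counts_per_cell = 80L)
}

# plain dense counts wrapped in the container, condition split half/half
toy_em <- function(counts, gene_ids = NULL, cell_ids = NULL,
                   condition = NULL, sample_id = NULL) {
  counts <- as.matrix(counts)
  gene_ids <- gene_ids %||% paste0("G", seq_len(nrow(counts)))
  cell_ids <- cell_ids %||% paste0("c", seq_len(ncol(counts)))
  n <- length(cell_ids)
  meta <- tibble::tibble(
    cell_id = cell_ids,
    sample_id = sample_id %||% rep("s1", n),
    condition = condition %||% rep(c("control", "case"), length.out = n))
  expression_matrix(counts, gene_ids, cell_ids, meta, layer_tag = "counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gene-set collection with the simulation's planted set plus random decoys
planted_collection <- function(sim, n_random = 5L, set_size = 30L,
                               seed = 11) {
  withr::with_seed(seed, {
    decoys <- lapply(seq_len(n_random), function(i) {
      sample(sim$orthologs$gene_b, set_size)
    })
    names(decoys) <- paste0("RANDOM_", seq_len(n_random))
    gene_set_collection(c(
      stats::setNames(list(sim$truth$planted_set),
                      sim$truth$planted_set_name),
      decoys))
  })
}

# scaled + aligned matrices and reference decomposition for a simulation
prepared_spaces <- function(sim, n_hvg = 200L, n_components = 8L) {
  qa <- qc_filter_cells(sim$species_a, small_qc())$filtered
  qb <- qc_filter_cells(sim$species_b, small_qc())$filtered
  map <- build_one_to_one_map(sim$orthologs)
  hvgs <- select_hvgs(qa, min(n_hvg, length(qa$gene_ids)))
  map_hvg <- map[map$gene_a %in% hvgs, , drop = FALSE]
  al <- align_matrices(qa, qb, map_hvg)
  sa <- normalize_scale(al$a)
  sb <- normalize_scale(al$b)
  dec <- pca_decompose(sa, n_components)
  list(scaled_a = sa, scaled_b = sb, dec = dec, map = map_hvg)
}
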