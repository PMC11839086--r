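test_that("a cell with fewer than 200 detected genes is removed", {
  # 250 genes; cell1 detects 150 (lib 600), cells 2-3 detect 200 (lib 600)
  counts <- matrix(0L, 250, 3)
  counts[1:150, 1] <- 4L
  counts[1:200, 2] <- 3L
  counts[1:200, 3] <- 3L
  em <- toy_em(counts)
  res <- qc_filter_cells(em, qc_thresholds())
  expect_identical(res$filtered$cell_ids, c("c2", "c3"))
  expect_equal(unname(res$report$removed_per_rule["min_genes"]), 1)
  expect_equal(unname(res$report$removed_per_rule["mad"]), 0)
})

test_that("MAD = 0 removes any cell deviating from the median library size", {
  libs <- c(1000, 1000, 1000, 1000, 1e6)
  counts <- matrix(libs, nrow = 1)
  em <- toy_em(counts)
  t <- qc_thresholds(min_genes_per_cell = 1, min_counts_per_cell = 1)
  res <- qc_filter_cells(em, t)
  expect_identical(res$filtered$cell_ids, paste0("c", 1:4))
  expect_equal(res$report$n_final, 4L)
})

test_that("an all-passing matrix is returned unchanged with zero removals", {
  counts <- matrix(5L, 300, 4)
  em <- toy_em(counts)
  res <- qc_filter_cells(em, qc_thresholds())
  expect_identical(as.matrix(res$filtered$values), as.matrix(em$values))
  expect_equal(sum(res$report$removed_per_rule), 0)
  expect_equal(res$report$n_final, res$report$n_initial)
})

test_that("high-mitochondrial cells fail the mito rule", {
  counts <- matrix(2L, 300, 3)
  counts[1, 3] <- 200L                       # mito gene dominates cell 3
  em <- toy_em(counts, gene_ids = c("MT-ND1", paste0("G", 2:300)))
  t <- qc_thresholds(mad_k = 1000)           # isolate the mito rule
  res <- qc_filter_cells(em, t)
  expect_false("c3" %in% res$filtered$cell_ids)
  expect_equal(unname(res$report$removed_per_rule["mito"]), 1)
})

test_that("qc_filter_cells is idempotent and errors on an empty result", {
  sim <- small_sim(seed = 2, n_genes = 300, n_orthologs = 150, n_cells = 80)
  first <- qc_filter_cells(sim$species_a, small_qc())
  second <- qc_filter_cells(first$filtered, small_qc())
  expect_identical(second$filtered$cell_ids, first$filtered$cell_ids)
  expect_equal(second$report$n_final, second$report$n_initial)

  em <- toy_em(matrix(1L, 5, 3))             # 5 genes can never reach 200
  expect_error(qc_filter_cells(em, qc_thresholds()), "empty after QC")
})

test_that("sample-scope MAD filtering removes whole outlier samples", {
  counts <- matrix(10L, 200, 8)
  counts[, 7:8] <- 500L
  em <- toy_em(counts,
               sample_id = rep(c("s1", "s2", "s3", "s4"), each = 2))
  t <- qc_thresholds(min_genes_per_cell = 1, min_counts_per_cell = 1,
                     mad_scope = "sample")
  res <- qc_filter_cells(em, t)
  expect_identical(res$filtered$cell_meta$sample_id,
                   rep(c("s1", "s2", "s3"), each = 2))
})

test_that("sparsity is the zero fraction of the restricted matrix", {
  expect_equal(compute_sparsity(toy_em(matrix(0L, 3, 3) + 0L)), 1.0)
  expect_equal(compute_sparsity(toy_em(matrix(1L, 3, 3))), 0.0)
  em <- toy_em(matrix(c(5, 0, 0, 0, 0, 7), 3, 2, byrow = TRUE))
  expect_equal(compute_sparsity(em), 4 / 6)
  expect_equal(compute_sparsity(em, gene_subset = "G1"), 1 / 2)
  expect_error(compute_sparsity(em, gene_subset = "nope"), "subset")
})

test_that("HVG ranking puts constant genes last and recovers planted variance", {
  set.seed(31)
  n_cells <- 400
  base <- matrix(rpois(60 * n_cells, 5), 60, n_cells)
  base[60, ] <- 5L                            # constant gene
  em <- toy_em(base)
  ranked_all <- select_hvgs(em, n_hvg = 60)
  expect_identical(ranked_all[60], "G60")
  expect_setequal(ranked_all, em$gene_ids)
  expect_error(select_hvgs(em, n_hvg = 0), "positive")

  # an overdispersed gene at a matched mean should reach the top ranks
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    mus <- exp(runif(80, log(1), log(20)))
    counts <- matrix(rnbinom(80 * 300, mu = rep(mus, 300), size = 20),
                     80, 300)
    counts[40, ] <- rnbinom(300, mu = mus[40], size = 0.5)
    "G40" %in% select_hvgs(toy_em(counts), n_hvg = 8)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("scaled output is centered, unit-variance and clipped", {
  sim <- small_sim(seed = 4, n_genes = 200, n_orthologs = 100, n_cells = 60)
  em <- qc_filter_cells(sim$species_a, small_qc())$filtered
  sc <- normalize_scale(em)
  x <- as.matrix(sc$values)
  expect_lt(max(abs(rowMeans(x))), 1e-10)
  sds <- apply(x, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-8 | sds == 0))
  expect_lte(max(abs(x)), 10)
  expect_identical(sc$layer_tag, "scaled")
})

test_that("identical counts at equal depth scale to an all-zero row", {
  counts <- matrix(3L, 10, 6)
  counts[2, ] <- c(1L, 2L, 3L, 4L, 5L, 6L)  # give cells equal total depth
  counts[3, ] <- c(6L, 5L, 4L, 3L, 2L, 1L)
  em <- toy_em(counts)
  sc <- normalize_scale(em)
  expect_equal(unname(as.matrix(sc$values)["G1", ]), rep(0, 6))
})

test_that("regressing a gene on itself as covariate zeroes its residual row", {
  set.seed(8)
  counts <- matrix(rpois(20 * 50, 5), 20, 50)
  em <- toy_em(counts)
  lib <- Matrix::colSums(em$values)
  confounder <- log1p(as.numeric(counts[1, ]) / as.numeric(lib) * 1e4)
  sc <- normalize_scale(em, covariates = cbind(confounder))
  expect_equal(unname(as.matrix(sc$values)["G1", ]), rep(0, 50),
               tolerance = 1e-8)
})

test_that("zero-library cells are rejected at the normalization stage", {
  counts <- matrix(c(5L, 0L), 1, 2)
  expect_error(normalize_scale(toy_em(counts)), "zero-library")
})
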