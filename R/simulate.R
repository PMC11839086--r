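#' Simulation configuration for paired-species synthetic data
#'
#' Defines the generative model used throughout the test-suite: two species'
#' negative-binomial count matrices share planted latent factors over
#' orthologous genes, one factor is differentially loaded between case and
#' control cells in both species, mitochondrial genes are spiked in, and
#' dropout is applied as post-sampling zero inflation.
#'
#' Counts are drawn as `NB(mean = exp(base + loadings %*% scores),
#' dispersion)` with variance `mu + mu^2/dispersion`, then zeroed
#' independently with probability `dropout_rate`.  Orthologous genes share
#' loading values on all factors; case cells have their planted-factor score
#' shifted by `condition_effect` in both species.
#'
#' @param n_genes_a,n_genes_b genes per species.
#' @param n_orthologs number of one-to-one orthologous (non-mitochondrial)
#'   genes shared by the two species; at most the smaller gene count.
#' @param n_cells_per_group cells per (species, condition) group.
#' @param n_factors number of latent factors.
#' @param planted_factor_index which factor separates the conditions.
#' @param condition_effect mean shift added to the planted factor's score in
#'   case cells (both species); 0 gives the null model.
#' @param factor_loading_sparsity fraction of zero loadings per factor.
#' @param loading_sd standard deviation of the nonzero loadings.
#' @param nb_dispersion negative-binomial dispersion (size); `Inf` gives
#'   Poisson counts.
#' @param dropout_rate probability an observed count is zeroed.
#' @param mito_gene_fraction fraction of genes given mitochondrial
#'   (`MT-`/`mt-`) symbols, in `[0, 0.2]`.
#' @param seed integer seed; the generator is bit-reproducible under a fixed
#'   seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes_a = 2000L, n_genes_b = 2000L,
                       n_orthologs = 1000L, n_cells_per_group = 1000L,
                       n_factors = 5L, planted_factor_index = 1L,
                       condition_effect = 1.5,
                       factor_loading_sparsity = 0.3, loading_sd = 0.5,
                       nb_dispersion = 2, dropout_rate = 0.3,
                       mito_gene_fraction = 0.05, seed = 1L) {
  cfg <- list(n_genes_a = as.integer(n_genes_a),
              n_genes_b = as.integer(n_genes_b),
              n_orthologs = as.integer(n_orthologs),
              n_cells_per_group = as.integer(n_cells_per_group),
              n_factors = as.integer(n_factors),
              planted_factor_index = as.integer(planted_factor_index),
              condition_effect = condition_effect,
              factor_loading_sparsity = factor_loading_sparsity,
              loading_sd = loading_sd,
              nb_dispersion = nb_dispersion,
              dropout_rate = dropout_rate,
              mito_gene_fraction = mito_gene_fraction,
              seed = as.integer(seed))
  n_mito_a <- ceiling(cfg$mito_gene_fraction * cfg$n_genes_a)
  n_mito_b <- ceiling(cfg$mito_gene_fraction * cfg$n_genes_b)
  assert_that(cfg$n_orthologs <= min(cfg$n_genes_a - n_mito_a,
                                     cfg$n_genes_b - n_mito_b),
              "n_orthologs exceeds the available non-mitochondrial genes")
  assert_that(cfg$planted_factor_index >= 1 &&
                cfg$planted_factor_index <= cfg$n_factors,
              "planted_factor_index must lie in 1..n_factors")
  assert_that(cfg$dropout_rate >= 0 && cfg$dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  assert_that(cfg$mito_gene_fraction >= 0 && cfg$mito_gene_fraction <= 0.2,
              "mito_gene_fraction must be in [0, 0.2]")
  assert_that(all(c(cfg$n_genes_a, cfg$n_genes_b, cfg$n_orthologs,
                    cfg$n_cells_per_group, cfg$n_factors) >= 1),
              "all counts must be >= 1")
  assert_that(cfg$nb_dispersion > 0, "nb_dispersion must be > 0")
  structure(cfg, class = "sim_config")
}

# gene naming: mouse-style title case for species A, human-style uppercase
# for species B, so ortholog mapping is exercised non-trivially
sim_gene_names <- function(n_genes, n_mito, n_orth, species) {
  stopifnot(n_mito + n_orth <= n_genes)
  n_priv <- n_genes - n_mito - n_orth
  orth_base <- sprintf("ORTH%04d", seq_len(n_orth))
  priv_base <- sprintf("PRIV%04d", seq_len(max(n_priv, 0L)))
  title_case <- function(x) paste0(substr(x, 1, 1),
                                   tolower(substr(x, 2, nchar(x))))
  if (species == "a") {
    c(sprintf("mt-Gene%03d", seq_len(n_mito)),
      title_case(orth_base), title_case(priv_base))
  } else {
    c(sprintf("MT-GENE%03d", seq_len(n_mito)), orth_base, priv_base)
  }
}

sim_one_species <- function(cfg, species, shared_loadings, scores) {
  n_genes <- if (species == "a") cfg$n_genes_a else cfg$n_genes_b
  n_mito <- ceiling(cfg$mito_gene_fraction * n_genes)
  genes <- sim_gene_names(n_genes, n_mito, cfg$n_orthologs, species)
  orth_rows <- seq.int(n_mito + 1L, n_mito + cfg$n_orthologs)

  L <- matrix(rnorm(n_genes * cfg$n_factors, sd = cfg$loading_sd),
              n_genes, cfg$n_factors)
  L[matrix(runif(length(L)) < cfg$factor_loading_sparsity,
           n_genes, cfg$n_factors)] <- 0
  L[orth_rows, ] <- shared_loadings
  rownames(L) <- genes

  base <- rnorm(n_genes, mean = log(0.8), sd = 1)
  base[seq_len(n_mito)] <- rnorm(n_mito, mean = log(3), sd = 0.5)

  eta <- base + L %*% t(scores)           # genes x cells log-mean
  mu <- exp(pmin(eta, log(1e4)))
  n <- length(mu)
  counts <- if (is.finite(cfg$nb_dispersion)) {
    rnbinom(n, mu = as.vector(mu), size = cfg$nb_dispersion)
  } else {
    stats::rpois(n, as.vector(mu))
  }
  if (cfg$dropout_rate > 0) {
    counts <- counts * rbinom(n, 1L, 1 - cfg$dropout_rate)
  }
  counts <- matrix(counts, nrow(mu), ncol(mu))

  n_cells <- nrow(scores)
  half <- n_cells / 2L
  meta <- tibble::tibble(
    cell_id = sprintf("%s_cell%05d", species, seq_len(n_cells)),
    sample_id = paste0(rep(c("control", "case"), each = half), "_",
                       species, rep(rep(1:2, length.out = half), 2L)),
    condition = rep(c("control", "case"), each = half))

  em <- expression_matrix(methods::as(counts, "CsparseMatrix"), genes,
                          meta$cell_id, meta, layer_tag = "counts")
  list(em = em, loadings = L, base = base, orth_rows = orth_rows)
}

#' Simulate a paired-species single-cell dataset with planted structure
#'
#' Generates count matrices for two species that share latent factors over
#' their orthologous genes (see [sim_config()] for the generative model), an
#' ortholog lookup table, and a ground-truth record sufficient to compute
#' every recovery metric downstream: true loadings and factor scores per
#' species, the planted factor index, and a planted gene set (the
#' largest-|loading| orthologs of the planted factor, in the species-B
#' namespace) for enrichment checks.
#'
#' Cells are split half control, half case, across two samples per
#' condition; case cells have the planted factor's score shifted by
#' `condition_effect` in both species.
#'
#' @param cfg a [sim_config()].
#' @return list with `species_a`, `species_b` (ExpressionMatrix),
#'   `orthologs` (tibble `gene_a`, `gene_b`), and `truth`.
#' @export
simulate_paired_species <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    shared <- matrix(rnorm(cfg$n_orthologs * cfg$n_factors,
                           sd = cfg$loading_sd),
                     cfg$n_orthologs, cfg$n_factors)
    shared[matrix(runif(length(shared)) < cfg$factor_loading_sparsity,
                  cfg$n_orthologs, cfg$n_factors)] <- 0

    n_cells <- 2L * cfg$n_cells_per_group
    make_scores <- function() {
      s <- matrix(rnorm(n_cells * cfg$n_factors), n_cells, cfg$n_factors)
      case <- seq.int(cfg$n_cells_per_group + 1L, n_cells)
      s[case, cfg$planted_factor_index] <-
        s[case, cfg$planted_factor_index] + cfg$condition_effect
      s
    }
    scores_a <- make_scores()
    scores_b <- make_scores()

    a <- sim_one_species(cfg, "a", shared, scores_a)
    b <- sim_one_species(cfg, "b", shared, scores_b)

    orthologs <- tibble::tibble(
      gene_a = a$em$gene_ids[a$orth_rows],
      gene_b = b$em$gene_ids[b$orth_rows])

    planted_load <- shared[, cfg$planted_factor_index]
    top <- order(abs(planted_load), decreasing = TRUE)[
      seq_len(min(50L, cfg$n_orthologs))]
    truth <- list(
      loadings_a = a$loadings, loadings_b = b$loadings,
      base_a = a$base, base_b = b$base,
      scores_a = scores_a, scores_b = scores_b,
      shared_loadings = shared,
      planted_factor_index = cfg$planted_factor_index,
      condition_effect = cfg$condition_effect,
      planted_set_name = "PLANTED_FACTOR_TOP",
      planted_set = orthologs$gene_b[top],
      config = cfg)
    list(species_a = a$em, species_b = b$em,
         orthologs = orthologs, truth = truth)
  })
}

#' Simulate a drug-signature table with planted correlated drugs
#'
#' Emulates a LINCS-style characteristic-direction coefficient matrix:
#' planted-positive drugs receive coefficients `a * loading + noise` with
#' `a > 0`, planted-negative with `a < 0`, and the remaining drugs pure
#' noise, all over the gene namespace of `loading_vector` (symbols
#' uppercased).  A matching metadata table (targets, approval, BBB flags) is
#' generated alongside.
#'
#' @param loading_vector named numeric vector indexed by gene symbols.
#' @param n_drugs total number of drugs.
#' @param n_planted_pos,n_planted_neg planted correlated / anti-correlated
#'   drug counts; their sum must not exceed `n_drugs`.
#' @param signal_strength |a| above; the loading is rescaled to unit sd
#'   before mixing.
#' @param noise_sd standard deviation of the additive noise (0 gives
#'   `|rho| = 1` for planted drugs).
#' @param seed integer seed.
#' @return list with `signatures` (tibble drug x gene), `metadata` (tibble)
#'   and `truth` (planted drug ids with signed direction).
#' @export
simulate_drug_signatures <- function(loading_vector, n_drugs = 100L,
                                     n_planted_pos = 5L, n_planted_neg = 5L,
                                     signal_strength = 1, noise_sd = 0.5,
                                     seed = 1L) {
  assert_that(n_planted_pos + n_planted_neg <= n_drugs,
              "n_planted_pos + n_planted_neg exceeds n_drugs")
  assert_that(!is.null(names(loading_vector)),
              "loading_vector must be named by gene symbols")
  genes <- norm_symbol(names(loading_vector))
  s <- sd(loading_vector)
  unit <- if (isTRUE(s > 0)) loading_vector / s else loading_vector
  withr::with_seed(seed, {
    ids <- sprintf("drug%04d", seq_len(n_drugs))
    planted_pos <- head(ids, n_planted_pos)
    planted_neg <- head(setdiff(ids, planted_pos), n_planted_neg)
    coefs <- matrix(rnorm(n_drugs * length(genes)), n_drugs, length(genes))
    add_signal <- function(rows, a) {
      for (r in rows) {
        coefs[r, ] <<- a * unit +
          if (noise_sd > 0) rnorm(length(genes), sd = noise_sd) else 0
      }
    }
    add_signal(match(planted_pos, ids), signal_strength)
    add_signal(match(planted_neg, ids), -signal_strength)
    sig <- tibble::as_tibble(as.data.frame(coefs))
    names(sig) <- genes
    sig <- dplyr::bind_cols(tibble::tibble(drug = ids), sig)
    metadata <- tibble::tibble(
      drug = ids,
      targets = sprintf("TGT%03d", sample.int(200L, n_drugs, replace = TRUE)),
      approved = runif(n_drugs) < 0.3,
      bbb = runif(n_drugs) < 0.3)
    list(signatures = sig, metadata = metadata,
         truth = tibble::tibble(
           drug = c(planted_pos, planted_neg),
           direction = rep(c(1L, -1L), c(n_planted_pos, n_planted_neg))))
  })
}
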