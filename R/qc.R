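#' Cell-level quality-control thresholds
#'
#' Defaults follow standard single-nucleus RNA-seq practice: cells are
#' removed when they have fewer than 200 detected genes, fewer than 500
#' total transcripts, more than 10% mitochondrial counts, or a library size
#' more than three (scaled) median absolute deviations from the median.
#'
#' @param min_genes_per_cell minimum detected genes per cell.
#' @param min_counts_per_cell minimum total counts per cell.
#' @param max_mito_pct maximum mitochondrial percentage (0-100 scale).
#' @param mad_k library-size outlier cutoff in scaled MADs (constant
#'   1.4826); `MAD = 0` is treated as "any deviation from the median fails".
#' @param mito_prefixes case-sensitive gene-symbol prefixes identifying
#'   mitochondrial genes for both species' conventions.
#' @param mad_scope `"cell"` applies the MAD rule to cell library sizes
#'   (stratified by `sample_id`); `"sample"` applies it to whole samples
#'   using each sample's median library size.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200L,
                          min_counts_per_cell = 500L,
                          max_mito_pct = 10,
                          mad_k = 3,
                          mito_prefixes = c("MT-", "mt-"),
                          mad_scope = c("cell", "sample")) {
  mad_scope <- match.arg(mad_scope)
  assert_that(min_genes_per_cell > 0 && min_counts_per_cell > 0 &&
                max_mito_pct > 0 && mad_k > 0,
              "all thresholds must be positive")
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_counts_per_cell = as.integer(min_counts_per_cell),
                 max_mito_pct = max_mito_pct, mad_k = mad_k,
                 mito_prefixes = mito_prefixes, mad_scope = mad_scope),
            class = "qc_thresholds")
}

mito_gene_mask <- function(gene_ids, prefixes) {
  Reduce(`|`, lapply(prefixes, function(p) startsWith(gene_ids, p)),
         logical(length(gene_ids)))
}

# |x - median| > k * 1.4826 * MAD, with MAD = 0 meaning any deviation fails
mad_outlier <- function(x, k) {
  med <- median(x)
  m <- mad(x, constant = 1.4826)
  if (m == 0) x != med else abs(x - med) > k * m
}

#' Filter cells by quality-control rules
#'
#' All rules are evaluated jointly on the current count matrix, then every
#' cell failing at least one rule is removed: detected genes below
#' `min_genes_per_cell`, total counts below `min_counts_per_cell`,
#' mitochondrial percentage above `max_mito_pct`, and library size beyond
#' `mad_k` scaled MADs from the median (per sample, or per whole sample when
#' `mad_scope = "sample"`).  Because removing outliers shifts the median and
#' MAD, the joint pass is repeated until no further cell fails, so the
#' filter is idempotent: applying it to its own output removes nothing.
#'
#' @param em an [expression_matrix()] with `layer_tag = "counts"`.
#' @param thresholds a [qc_thresholds()].
#' @param max_passes safety bound on the fixed-point iteration.
#' @return list with `filtered` (ExpressionMatrix) and `report`: a
#'   `qc_report` holding the per-cell rule outcomes (tibble, across all
#'   passes), cells removed per rule, pass count, and initial/final cell
#'   counts.
#' @export
qc_filter_cells <- function(em, thresholds = qc_thresholds(),
                            max_passes = 100L) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  assert_that(em$layer_tag == "counts", "QC requires layer_tag = 'counts'")
  t <- thresholds
  n_initial <- ncol(em$values)
  initial_ids <- em$cell_ids
  all_flags <- list()
  passes <- 0L
  repeat {
    passes <- passes + 1L
    one <- qc_pass(em, t)
    all_flags[[passes]] <- one$flags
    if (!any(one$fail_any) || passes >= max_passes) break
    em <- subset_cells(em, !one$fail_any)
  }
  flags <- dplyr::bind_rows(all_flags)
  # a cell assessed in several passes keeps its final (failing or clean) row
  flags <- flags[!duplicated(flags$cell_id, fromLast = TRUE), ]
  flags <- flags[order(match(flags$cell_id, initial_ids)), ]
  report <- structure(list(
    per_cell = flags,
    removed_per_rule = c(min_genes = sum(flags$fail_min_genes),
                         min_counts = sum(flags$fail_min_counts),
                         mito = sum(flags$fail_mito),
                         mad = sum(flags$fail_mad)),
    n_initial = n_initial,
    n_final = ncol(em$values),
    n_passes = passes,
    thresholds = t), class = "qc_report")
  list(filtered = em, report = report)
}

# one joint evaluation of all QC rules on the current matrix
qc_pass <- function(em, t) {
  v <- em$values
  lib_size <- as.numeric(Matrix::colSums(v))
  n_genes <- as.numeric(Matrix::colSums(v > 0))
  mito <- mito_gene_mask(em$gene_ids, t$mito_prefixes)
  mito_pct <- if (any(mito)) {
    100 * as.numeric(Matrix::colSums(v[mito, , drop = FALSE])) /
      pmax(lib_size, 1)
  } else {
    rep(0, ncol(v))
  }

  sample_id <- em$cell_meta$sample_id
  fail_mad <- logical(ncol(v))
  if (t$mad_scope == "cell") {
    for (s in unique(sample_id)) {
      idx <- sample_id == s
      fail_mad[idx] <- mad_outlier(lib_size[idx], t$mad_k)
    }
  } else {
    sample_med <- tapply(lib_size, sample_id, median)
    bad_samples <- names(sample_med)[mad_outlier(as.numeric(sample_med),
                                                 t$mad_k)]
    fail_mad <- sample_id %in% bad_samples
  }

  flags <- tibble::tibble(
    cell_id = em$cell_ids,
    fail_min_genes = n_genes < t$min_genes_per_cell,
    fail_min_counts = lib_size < t$min_counts_per_cell,
    fail_mito = mito_pct > t$max_mito_pct,
    fail_mad = fail_mad)
  fail_any <- flags$fail_min_genes | flags$fail_min_counts |
    flags$fail_mito | flags$fail_mad
  if (all(fail_any)) rlang::abort("empty after QC: every cell fails a rule")
  list(flags = flags, fail_any = fail_any)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d -> %d cells (%d removed)\n",
              x$n_initial, x$n_final, x$n_initial - x$n_final))
  print(x$removed_per_rule)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) x$per_cell

#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_initial = x$n_initial, n_final = x$n_final,
                 removed = x$n_initial - x$n_final,
                 removed_min_genes = unname(x$removed_per_rule["min_genes"]),
                 removed_min_counts = unname(x$removed_per_rule["min_counts"]),
                 removed_mito = unname(x$removed_per_rule["mito"]),
                 removed_mad = unname(x$removed_per_rule["mad"]))
}

#' Fraction of zero entries over a gene subset
#'
#' @param em an [expression_matrix()].
#' @param gene_subset genes to restrict to (default: all genes).
#' @return fraction of zero entries in the restricted genes x cells matrix,
#'   in `[0, 1]`.
#' @export
compute_sparsity <- function(em, gene_subset = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  if (!is.null(gene_subset)) {
    assert_that(all(gene_subset %in% em$gene_ids),
                "gene_subset must be a subset of gene_ids")
    v <- v[match(gene_subset, em$gene_ids), , drop = FALSE]
  }
  n_nonzero <- if (inherits(v, "sparseMatrix")) {
    sum(v@x != 0)
  } else {
    sum(v != 0)
  }
  1 - n_nonzero / (as.numeric(nrow(v)) * ncol(v))
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: a mean-variance trend is fitted on
#' log10(mean) vs log10(variance) by local polynomial regression (loess)
#' over genes with positive variance, and each gene's observed variance is
#' divided by its trend-expected variance.  Constant genes get standardized
#' variance 0 and rank last.  Ties are broken by lexicographic gene id.
#'
#' @param em an [expression_matrix()] with `layer_tag = "counts"`.
#' @param n_hvg number of genes to return (default 3250).
#' @param span loess span for the trend fit.
#' @return character vector of `n_hvg` gene ids, most variable first.
#' @export
select_hvgs <- function(em, n_hvg = 3250L, span = 0.3) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  assert_that(em$layer_tag == "counts", "HVG selection expects counts")
  assert_that(n_hvg > 0, "n_hvg must be positive")
  assert_that(n_hvg <= length(em$gene_ids), "n_hvg exceeds the gene count")
  v <- em$values
  mu <- as.numeric(Matrix::rowSums(v)) / ncol(v)
  ex2 <- as.numeric(Matrix::rowSums(v^2)) / ncol(v)
  vr <- (ex2 - mu^2) * ncol(v) / (ncol(v) - 1)
  vr <- pmax(vr, 0)

  ok <- mu > 0 & vr > 0
  std_var <- numeric(length(mu))
  if (sum(ok) >= 10) {
    fit <- loess(log10(vr[ok]) ~ log10(mu[ok]), span = span, degree = 2,
                 family = "symmetric",
                 control = stats::loess.control(surface = "direct"))
    expected <- 10^predict(fit, log10(mu[ok]))
    std_var[ok] <- vr[ok] / pmax(expected, .Machine$double.eps)
  } else {
    std_var[ok] <- vr[ok]           # too few genes for a trend
  }
  ord <- order(-std_var, em$gene_ids)
  em$gene_ids[ord][seq_len(n_hvg)]
}

#' Normalize, optionally regress covariates, and scale
#'
#' Per-cell depth normalization to 10,000 counts followed by `log1p`;
#' restriction to `hvg_list`; optional per-gene linear regression on the
#' supplied covariates keeping residuals; then per-gene centering to mean 0
#' and scaling to unit variance, with values clipped to `[-clip, clip]`.
#' Genes constant across cells yield an all-zero scaled row.
#'
#' @param em an [expression_matrix()] with `layer_tag = "counts"`.
#' @param hvg_list genes to keep, e.g. from [select_hvgs()] (default: all).
#' @param covariates optional numeric matrix/data frame (cells x covariates)
#'   regressed out of each gene before scaling.
#' @param scale_factor per-cell target depth (default 1e4).
#' @param clip symmetric clipping bound on the scaled values.
#' @return an [expression_matrix()] with `layer_tag = "scaled"`.
#' @export
normalize_scale <- function(em, hvg_list = NULL, covariates = NULL,
                            scale_factor = 1e4, clip = 10) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  assert_that(em$layer_tag == "counts", "normalize_scale expects counts")
  lib <- as.numeric(Matrix::colSums(em$values))
  if (any(lib == 0)) {
    rlang::abort("zero-library cell reached normalization; run QC first")
  }
  hvg_list <- hvg_list %||% em$gene_ids
  idx <- match(hvg_list, em$gene_ids)
  assert_that(!anyNA(idx), "hvg_list contains unknown genes")

  x <- as_dense(em$values[idx, , drop = FALSE])
  x <- log1p(sweep(x, 2, lib / scale_factor, "/"))

  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    assert_that(nrow(cov) == ncol(x),
                "covariates must have one row per cell")
    design <- cbind(1, cov)
    # residuals of gene ~ covariates, all genes at once via one QR
    qrd <- qr(design)
    x <- x - t(qr.fitted(qrd, t(x)))
  }

  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  # guard: rows that are constant up to numerical noise must not be blown
  # up to unit variance
  zero <- s < 1e-8 * pmax(abs(mu), 1)
  x <- (x - mu) / ifelse(zero, 1, s)
  x[zero, ] <- 0
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  expression_matrix(x, em$gene_ids[idx], em$cell_ids, em$cell_meta,
                    layer_tag = "scaled")
}
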