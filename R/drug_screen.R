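#' Filter perturbagens to those with established targets
#'
#' Drops drugs whose metadata `targets` field is empty or missing and
#' collapses duplicate drug names, keeping the first occurrence in file
#' order.
#'
#' @param signatures drug x gene coefficient tibble (first column `drug`),
#'   as read by [read_drug_signatures()].
#' @param metadata drug metadata tibble with a `targets` column.
#' @return the filtered signatures tibble.
#' @export
filter_perturbagens <- function(signatures, metadata) {
  assert_that("targets" %in% names(metadata),
              "metadata needs a targets column")
  meta <- metadata[!duplicated(metadata$drug), , drop = FALSE]
  targeted <- meta$drug[!is.na(meta$targets) & nzchar(trimws(meta$targets))]
  out <- signatures[signatures$drug %in% targeted, , drop = FALSE]
  out[!duplicated(out$drug), , drop = FALSE]
}

#' Z-score a drug's coefficients and select significant genes
#'
#' For one drug, coefficients are standardized across its genes
#' (`z = (c - mean(c)) / sd(c)`), two-sided normal p-values are attached
#' (`p = 2 (1 - Phi(|z|))`), and the genes with `p < alpha` become the
#' drug's differentially-expressed (signature) set.  Constant coefficient
#' vectors cannot be z-scored and return `NULL` with a message.
#'
#' @param coefficients named numeric vector (genes) of
#'   characteristic-direction coefficients for one drug.
#' @param alpha significance cutoff (default 0.05, i.e. `|z| > 1.96`).
#' @return tibble `gene`, `coefficient`, `z`, `p_value`, `selected`; or
#'   `NULL` when the drug must be skipped.
#' @export
zscore_and_select <- function(coefficients, alpha = 0.05) {
  x <- coefficients[is.finite(coefficients)]
  assert_that(length(x) >= 3, "need at least 3 finite coefficients")
  s <- sd(x)
  if (s == 0) {
    rlang::inform("constant coefficients: drug skipped")
    return(NULL)
  }
  z <- (x - mean(x)) / s
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(gene = names(x), coefficient = unname(x), z = unname(z),
                 p_value = unname(p), selected = unname(p < alpha))
}

#' Tie-aware Spearman correlation
#'
#' Average ranks on both vectors, Pearson correlation of the ranks, and a
#' p-value from the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y paired finite numeric vectors, length >= 3.
#' @return list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need at least 3 paired finite values")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(list(rho = NA_real_, p_value = NA_real_))
  rho <- cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Screen drug signatures against a component loading vector
#'
#' For each drug: z-score its characteristic-direction coefficients and
#' keep genes with `p < alpha` ([zscore_and_select()]); intersect those
#' with the loading vector's eligible genes (nonzero loadings for sparse
#' components, all genes for dense ones); compute the tie-aware Spearman
#' correlation between coefficients and loadings over the overlap; adjust
#' p-values by Benjamini-Hochberg across all tested drugs; and return rows
#' sorted ascending by rho, annotated with metadata.  Drugs with overlap
#' below `min_overlap` (or skipped at the z-scoring stage) are excluded
#' with a message.
#'
#' Sign semantics: the component's orientation defines which pole is
#' disease-like — interpret rho against the component's case vs control
#' score means (carried by the pipeline report).
#'
#' @param signatures drug x gene coefficient tibble (first column `drug`).
#' @param loading_vector named numeric vector in the same (target-species)
#'   gene namespace; map through [rank_genes_from_loadings()]'s namespace
#'   first if needed.  Symbols are matched exactly after uppercasing.
#' @param metadata optional drug metadata (`drug`, `targets`, `approved`,
#'   `bbb`).
#' @param alpha per-gene significance cutoff for signature genes.
#' @param min_overlap minimum overlapping genes to test a drug (default 5).
#' @param sparse_loadings restrict eligible genes to nonzero loadings
#'   (default: automatic — TRUE when any loading is exactly zero).
#' @return tibble: `drug`, `n_overlap`, `rho`, `p_value`, `q_value`,
#'   `rank`, plus metadata columns; sorted ascending by rho.
#' @export
screen_drugs <- function(signatures, loading_vector, metadata = NULL,
                         alpha = 0.05, min_overlap = 5L,
                         sparse_loadings = NULL) {
  assert_that(!is.null(names(loading_vector)),
              "loading_vector must be named by gene symbols")
  names(loading_vector) <- norm_symbol(names(loading_vector))
  min_overlap <- max(as.integer(min_overlap), 3L)   # Spearman needs n >= 3
  sparse_loadings <- sparse_loadings %||% any(loading_vector == 0)
  eligible <- if (sparse_loadings) {
    names(loading_vector)[loading_vector != 0]
  } else {
    names(loading_vector)
  }
  gene_cols <- setdiff(names(signatures), "drug")

  rows <- purrr::pmap(list(seq_len(nrow(signatures))), function(i) {
    coefs <- as.numeric(signatures[i, gene_cols])
    names(coefs) <- gene_cols
    zs <- suppressMessages(zscore_and_select(coefs, alpha = alpha))
    if (is.null(zs)) return(NULL)
    overlap <- intersect(zs$gene[zs$selected], eligible)
    if (length(overlap) < min_overlap) return(NULL)
    sc <- spearman_cor(coefs[overlap], loading_vector[overlap])
    tibble::tibble(drug = signatures$drug[i],
                   n_overlap = length(overlap),
                   rho = sc$rho, p_value = sc$p_value)
  }) |> purrr::compact() |> purrr::list_rbind()

  if (is.null(rows) || nrow(rows) == 0) {
    rlang::abort("no drug passes the overlap/z-scoring requirements")
  }
  n_skipped <- nrow(signatures) - nrow(rows)
  if (n_skipped > 0) {
    rlang::inform(sprintf("%d drug(s) excluded (overlap < %d or constant)",
                          n_skipped, min_overlap))
  }
  rows$q_value <- bh_adjust(rows$p_value)
  rows <- rows[order(rows$rho, rows$drug), ]   # deterministic under ties
  rows$rank <- seq_len(nrow(rows))
  if (!is.null(metadata)) {
    rows <- dplyr::left_join(rows, metadata, by = "drug")
  }
  rows
}
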