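#' Expression matrix container
#'
#' A light container for a genes x cells expression matrix together with the
#' per-cell metadata the downstream analyses need.  The matrix is stored
#' sparse (`Matrix::dgCMatrix`) whenever it arrives sparse; all package
#' functions accept either representation.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, genes in rows,
#'   cells in columns.  For `layer_tag = "counts"` entries must be
#'   non-negative integers.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column.
#' @param cell_meta data frame with one row per cell.  Must contain
#'   `sample_id` and `condition` (values `"case"`/`"control"`) columns; a
#'   minimal one is synthesised when omitted.
#' @param layer_tag one of `"counts"`, `"lognorm"`, `"scaled"`, describing
#'   what the values are.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `cell_meta` (tibble) and `layer_tag`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 2), nrow = 4)
#' em <- expression_matrix(m, paste0("G", 1:4), paste0("c", 1:3))
#' dim(em)
expression_matrix <- function(values, gene_ids, cell_ids,
                              cell_meta = NULL,
                              layer_tag = c("counts", "lognorm", "scaled")) {
  layer_tag <- match.arg(layer_tag)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  assert_that(nrow(values) == length(gene_ids),
              "number of rows must equal length(gene_ids)")
  assert_that(ncol(values) == length(cell_ids),
              "number of columns must equal length(cell_ids)")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  assert_that(!anyDuplicated(cell_ids), "cell_ids must be unique")
  if (layer_tag == "counts") {
    v <- if (inherits(values, "sparseMatrix")) values@x else as.numeric(values)
    assert_that(all(v >= 0) && all(is_wholenumber(v)),
                "layer_tag = 'counts' requires non-negative integral entries")
  }
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell_id = cell_ids,
                                sample_id = "sample1",
                                condition = "control")
  } else {
    cell_meta <- tibble::as_tibble(cell_meta)
    assert_that(nrow(cell_meta) == length(cell_ids),
                "cell_meta must have one row per cell")
    if (!"cell_id" %in% names(cell_meta)) cell_meta$cell_id <- cell_ids
    assert_that(all(c("sample_id", "condition") %in% names(cell_meta)),
                "cell_meta must contain sample_id and condition columns")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_meta = cell_meta, layer_tag = layer_tag),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$layer_tag))
  cat("conditions:",
      paste(names(table(x$cell_meta$condition)), table(x$cell_meta$condition),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# subset cells by logical/index vector, keeping metadata in step
subset_cells <- function(em, keep) {
  expression_matrix(em$values[, keep, drop = FALSE],
                    em$gene_ids, em$cell_ids[keep],
                    em$cell_meta[keep, , drop = FALSE],
                    layer_tag = em$layer_tag)
}

# subset/reorder genes by id vector
subset_genes <- function(em, genes) {
  idx <- match(genes, em$gene_ids)
  assert_that(!anyNA(idx), "unknown gene ids in subset")
  expression_matrix(em$values[idx, , drop = FALSE],
                    em$gene_ids[idx], em$cell_ids, em$cell_meta,
                    layer_tag = em$layer_tag)
}

as_dense <- function(values) as.matrix(values)
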