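#' Build a strict one-to-one ortholog map
#'
#' Many-to-many input pairs are resolved by strict dropping: any gene (on
#' either side) that appears in more than one pair has *all* of its pairs
#' removed, guaranteeing a one-to-one match.  With
#' `ambiguous = "best_confidence"` and a `confidence` column, the
#' highest-confidence pair per gene is kept instead (ties resolved by first
#' occurrence), iterating until one-to-one.
#'
#' @param raw_pairs data frame with columns `gene_a`, `gene_b` and
#'   optionally `confidence`.
#' @param ambiguous `"drop"` (default, strict) or `"best_confidence"`.
#' @return an `ortholog_map`: tibble of `(gene_a, gene_b)` pairs sorted by
#'   `gene_a`, each gene appearing exactly once.
#' @export
build_one_to_one_map <- function(raw_pairs,
                                 ambiguous = c("drop", "best_confidence")) {
  ambiguous <- match.arg(ambiguous)
  p <- tibble::as_tibble(raw_pairs)
  assert_that(all(c("gene_a", "gene_b") %in% names(p)),
              "raw_pairs needs gene_a and gene_b columns")
  p <- dplyr::distinct(p, .data$gene_a, .data$gene_b, .keep_all = TRUE)
  if (ambiguous == "drop") {
    dup_a <- p$gene_a[duplicated(p$gene_a)]
    dup_b <- p$gene_b[duplicated(p$gene_b)]
    p <- p[!(p$gene_a %in% dup_a) & !(p$gene_b %in% dup_b), , drop = FALSE]
  } else {
    assert_that("confidence" %in% names(p),
                "best_confidence mode needs a confidence column")
    repeat {
      before <- nrow(p)
      p <- p |>
        dplyr::group_by(.data$gene_a) |>
        dplyr::slice_max(.data$confidence, n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::group_by(.data$gene_b) |>
        dplyr::slice_max(.data$confidence, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      if (nrow(p) == before) break
    }
  }
  if (nrow(p) == 0) rlang::abort("no one-to-one ortholog pair survives")
  p <- dplyr::arrange(p[, c("gene_a", "gene_b")], .data$gene_a)
  structure(p, class = c("ortholog_map", class(p)))
}

#' Align two expression matrices on orthologous genes
#'
#' Restricts both matrices to the mapped gene pairs present in both, with
#' rows ordered identically by map order: row *i* of the first output and
#' row *i* of the second are orthologs.  Genes absent from either matrix
#' are dropped from both.  Idempotent, and invariant to the input row
#' order.
#'
#' @param em_a,em_b [expression_matrix()] objects for species A and B.
#' @param map an [build_one_to_one_map()] result (or any `gene_a`/`gene_b`
#'   one-to-one table).
#' @return list `a`, `b` of aligned ExpressionMatrix objects with equal row
#'   counts.
#' @export
align_matrices <- function(em_a, em_b, map) {
  keep <- map$gene_a %in% em_a$gene_ids & map$gene_b %in% em_b$gene_ids
  if (sum(keep) < 2) {
    rlang::abort("fewer than 2 mapped genes shared by both matrices")
  }
  m <- map[keep, , drop = FALSE]
  list(a = subset_genes(em_a, m$gene_a),
       b = subset_genes(em_b, m$gene_b))
}

#' Count orthologous genes shared by two DEG lists
#'
#' @param deg_list_a,deg_list_b character vectors of gene symbols for the
#'   two species.
#' @param map a one-to-one ortholog table (`gene_a`, `gene_b`).
#' @return list with `n` (count of map pairs whose both members appear in
#'   the respective lists) and `pairs` (the matching sub-table).
#' @export
deg_ortholog_overlap <- function(deg_list_a, deg_list_b, map) {
  hit <- map$gene_a %in% deg_list_a & map$gene_b %in% deg_list_b
  list(n = sum(hit), pairs = tibble::as_tibble(map[hit, c("gene_a", "gene_b")]))
}

#' Read an ortholog table
#'
#' TSV with header `gene_a<TAB>gene_b[<TAB>confidence]`.
#'
#' @param path file path.
#' @return tibble of raw pairs (pass to [build_one_to_one_map()]).
#' @export
read_ortholog_table <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(p)[1:2] <- c("gene_a", "gene_b")
  p
}
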