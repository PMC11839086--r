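#' Read a 10x-style Matrix Market count directory
#'
#' Reads `matrix.mtx(.gz)` together with `features.tsv(.gz)` (or
#' `genes.tsv(.gz)`) and `barcodes.tsv(.gz)` from a directory, oriented genes
#' in rows and cells in columns (the 10x convention; transposed inputs are
#' handled by `transpose = TRUE`, never guessed).  Duplicate gene identifiers
#' are disambiguated deterministically by suffixing `.1`, `.2`, ... in file
#' order.  Gzipped files are read transparently.
#'
#' @param directory_path directory containing the three files.
#' @param transpose set `TRUE` when the matrix file is cells x genes.
#' @return An [expression_matrix()] with `layer_tag = "counts"`.
#' @export
read_counts_mtx <- function(directory_path, transpose = FALSE) {
  find_one <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      p <- file.path(directory_path, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    rlang::abort(sprintf("no %s file found in %s",
                         paste(stems, collapse = "/"), directory_path))
  }
  mtx_path <- find_one("matrix.mtx")
  feat_path <- find_one(c("features.tsv", "genes.tsv"))
  bc_path <- find_one("barcodes.tsv")

  m <- Matrix::readMM(mtx_path)
  if (transpose) m <- Matrix::t(m)
  feats <- readr::read_tsv(feat_path, col_names = FALSE, col_types = readr::cols(),
                           progress = FALSE)
  bcs <- readr::read_tsv(bc_path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  if (nrow(bcs) == 0) {
    rlang::abort(sprintf("format error in %s: 0 cells", bc_path))
  }
  if (nrow(feats) != nrow(m)) {
    rlang::abort(sprintf(
      "format error in %s: %d features but matrix header declares %d rows",
      feat_path, nrow(feats), nrow(m)))
  }
  if (nrow(bcs) != ncol(m)) {
    rlang::abort(sprintf(
      "format error in %s: %d barcodes but matrix header declares %d columns",
      bc_path, nrow(bcs), ncol(m)))
  }
  gene_ids <- make.unique(as.character(feats[[1]]), sep = ".")
  expression_matrix(methods::as(m, "CsparseMatrix"),
                    gene_ids, as.character(bcs[[1]]),
                    layer_tag = "counts")
}

#' Write an expression matrix as a Matrix Market directory
#'
#' Inverse of [read_counts_mtx()]: writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` so that a read/write round trip is the identity on values,
#' identifiers and ordering.
#'
#' @param em an [expression_matrix()].
#' @param directory_path output directory (created if missing).
#' @return `directory_path`, invisibly.
#' @export
write_counts_mtx <- function(em, directory_path) {
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  m <- em$values
  if (!inherits(m, "sparseMatrix")) m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- NULL
  Matrix::writeMM(m, file.path(directory_path, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(id = em$gene_ids, name = em$gene_ids),
                   file.path(directory_path, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(bc = em$cell_ids),
                   file.path(directory_path, "barcodes.tsv"), col_names = FALSE)
  invisible(directory_path)
}

#' Read a GMT gene-set collection
#'
#' GMT dialect: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a set are deduplicated; sets whose (deduplicated)
#' size falls outside `[min_size, max_size]` are dropped.
#'
#' @param path GMT file (optionally gzipped).
#' @param min_size,max_size inclusive size bounds applied after
#'   deduplication.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors), `min_size`, `max_size`.
#' @export
read_gene_sets_gmt <- function(path, min_size = 1L, max_size = 500L) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      rlang::abort(sprintf("format error in %s line %d: fewer than 3 fields",
                           path, i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[fields[[1]]]] <- genes
  }
  gene_set_collection(sets, min_size = min_size, max_size = max_size)
}

#' Construct a gene-set collection from a named list
#'
#' @param sets named list of character vectors of gene symbols.
#' @inheritParams read_gene_sets_gmt
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, min_size = 1L, max_size = 500L) {
  sets <- lapply(sets, function(g) unique(g[nzchar(g)]))
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  assert_that(length(sets) > 0, "no gene set survives size filtering")
  structure(list(sets = sets, min_size = min_size, max_size = max_size),
            class = "GeneSetCollection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output file.
#' @export
write_gene_sets_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read drug signature and metadata tables
#'
#' The signature file is a delimited matrix with drugs as rows and genes as
#' columns, holding characteristic-direction coefficients (a per-gene
#' differential-expression direction for each perturbation).  The metadata
#' table carries drug id, targets, approval flag and blood-brain-barrier
#' flag.  Gene symbols are uppercased (and whitespace-stripped) for exact
#' matching downstream; drugs present in the signatures but absent from the
#' metadata are retained with empty metadata.
#'
#' @param signature_path delimited file (TSV or CSV by extension), first
#'   column drug ids, remaining columns one per gene.
#' @param metadata_path delimited file with columns `drug`, `targets`,
#'   `approved`, `bbb` (extra columns kept).  `NULL` for no metadata.
#' @return list with `signatures` (tibble, `drug` + one numeric column per
#'   gene) and `metadata` (tibble).
#' @export
read_drug_signatures <- function(signature_path, metadata_path = NULL) {
  reader <- function(p) {
    if (grepl("\\.csv(\\.gz)?$", p)) {
      readr::read_csv(p, col_types = readr::cols(), progress = FALSE)
    } else {
      readr::read_tsv(p, col_types = readr::cols(), progress = FALSE)
    }
  }
  sig <- reader(signature_path)
  names(sig)[1] <- "drug"
  dup <- sig$drug[duplicated(sig$drug)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicated drug row ids in %s: %s", signature_path,
                         paste(unique(dup), collapse = ", ")))
  }
  gene_cols <- names(sig)[-1]
  for (gc in gene_cols) {
    v <- sig[[gc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      rlang::abort(sprintf(
        "non-numeric coefficient in %s at row %s, column %s",
        signature_path, sig$drug[bad %||% 1], gc))
    }
  }
  names(sig) <- c("drug", norm_symbol(gene_cols))

  meta <- if (is.null(metadata_path)) {
    tibble::tibble(drug = character(), targets = character(),
                   approved = logical(), bbb = logical())
  } else {
    m <- reader(metadata_path)
    names(m)[1] <- "drug"
    tibble::as_tibble(m)
  }
  missing <- setdiff(sig$drug, meta$drug)
  if (length(missing) > 0) {
    pad <- tibble::tibble(drug = missing)
    for (col in setdiff(names(meta), "drug")) pad[[col]] <- NA
    meta <- dplyr::bind_rows(meta, pad)
  }
  if ("targets" %in% names(meta)) meta$targets <- as.character(meta$targets)
  list(signatures = sig, metadata = meta)
}
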