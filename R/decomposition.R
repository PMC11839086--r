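# Shared constructor for decomposition results.  Q: genes x components with
# unit-norm columns; scores: cells x components; explained variance as a
# fraction of the total sum of squares of the (centered) input.
new_decomposition <- function(Q, scores, explained, is_sparse,
                              keep_per_component = NULL, converged = NULL) {
  colnames(Q) <- colnames(scores) <- paste0("PC", seq_len(ncol(Q)))
  structure(list(Q = Q, scores = scores,
                 explained_variance_fraction = explained,
                 is_sparse = is_sparse,
                 keep_per_component = keep_per_component,
                 converged = converged),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %s, %d genes x %d components, %d cells\n",
              if (x$is_sparse) "sparse PCA" else "PCA",
              nrow(x$Q), ncol(x$Q), nrow(x$scores)))
  cat(sprintf("explained variance (first %d): %s\n",
              min(5L, ncol(x$Q)),
              paste(sprintf("%.3f", head(x$explained_variance_fraction, 5)),
                    collapse = " ")))
  invisible(x)
}

# flip each loading column so its largest-|entry| element is positive, so
# results are reproducible across linear-algebra backends
fix_signs <- function(Q, scores) {
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) {
      Q[, j] <- -Q[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(Q = Q, scores = scores)
}

# accept an ExpressionMatrix (genes x cells) or a plain cells x genes matrix
as_cells_by_genes <- function(x) {
  if (inherits(x, "ExpressionMatrix")) {
    list(X = Matrix::t(x$values) |> as_dense(), genes = x$gene_ids,
         cells = x$cell_ids)
  } else {
    list(X = as_dense(x),
         genes = colnames(x) %||% paste0("g", seq_len(ncol(x))),
         cells = rownames(x) %||% paste0("c", seq_len(nrow(x))))
  }
}

#' Principal component analysis of a scaled expression matrix
#'
#' Computes the top right singular vectors of the cells x genes matrix as
#' loadings `Q`, scores as `X %*% Q`, and per-component explained-variance
#' fractions as squared singular values over the total sum of squares.
#' Loadings are sign-fixed so each component's largest-|loading| gene is
#' positive.
#'
#' @param x an [expression_matrix()] with `layer_tag = "scaled"` (genes x
#'   cells) or a plain cells x genes matrix already centered per gene.
#' @param n_components number of components to retain (default 50).
#' @return a `decomposition` object.
#' @export
pca_decompose <- function(x, n_components = 50L) {
  d <- as_cells_by_genes(x)
  X <- d$X
  assert_that(n_components >= 1 && n_components <= min(dim(X)),
              "n_components must be in 1..min(cells, genes)")
  sv <- svd(X, nu = 0, nv = n_components)
  Q <- sv$v
  rownames(Q) <- d$genes
  scores <- X %*% Q
  rownames(scores) <- d$cells
  total_ss <- sum(X^2)
  explained <- sv$d[seq_len(n_components)]^2 / total_ss
  fx <- fix_signs(Q, scores)
  new_decomposition(fx$Q, fx$scores, explained, is_sparse = FALSE)
}

# soft-threshold keeping (at most) `keep` nonzero entries
soft_threshold_keep <- function(v, keep) {
  if (keep >= length(v)) return(v)
  a <- abs(v)
  lambda <- sort(a, decreasing = TRUE)[keep + 1L]
  sign(v) * pmax(a - lambda, 0)
}

#' Sparse principal component analysis by soft-threshold deflation
#'
#' Iterative rank-1 penalized matrix decomposition: for each component,
#' alternate `v <- soft_threshold(X'u, lambda)` — with `lambda` chosen so at
#' most `keep` loadings stay nonzero — renormalize `v`, and
#' `u <- Xv / ||Xv||`, until the loading change drops below `tol` or
#' `max_iter` iterations (non-convergence is a warning, the last iterate is
#' returned).  `u` is initialized from the residual's leading dense
#' singular vector, so the procedure is deterministic and, with
#' `keep = n_genes`, reproduces dense PCA.  After each component the
#' residual is deflated by its best rank-1 fit `d u v'`.
#'
#' Because sparse loadings are not orthogonal, explained variance uses the
#' QR-adjusted variance of `X %*% Q` rather than naive column variances.
#'
#' @inheritParams pca_decompose
#' @param keep_per_component integer, scalar or one per component: maximum
#'   nonzero loadings per component.  Default: 25% of genes (rounded up) —
#'   a package default, tunable per dataset.
#' @param tol,max_iter convergence control for the alternating updates.
#' @return a `decomposition` object with `is_sparse = TRUE`.
#' @export
spca_decompose <- function(x, n_components = 50L, keep_per_component = NULL,
                           tol = 1e-6, max_iter = 500L) {
  d <- as_cells_by_genes(x)
  X <- d$X
  n_genes <- ncol(X)
  assert_that(n_components >= 1 && n_components <= min(dim(X)),
              "n_components must be in 1..min(cells, genes)")
  keep <- keep_per_component %||% ceiling(0.25 * n_genes)
  keep <- as.integer(rep_len(keep, n_components))
  assert_that(all(keep >= 1 & keep <= n_genes),
              "keep_per_component entries must lie in [1, n_genes]")

  Q <- matrix(0, n_genes, n_components, dimnames = list(d$genes, NULL))
  converged <- logical(n_components)
  Xr <- X
  for (comp in seq_len(n_components)) {
    sv <- svd(Xr, nu = 1, nv = 0)
    u <- sv$u[, 1]
    v <- rep(0, n_genes)
    for (it in seq_len(max_iter)) {
      v_new <- soft_threshold_keep(drop(crossprod(Xr, u)), keep[comp])
      nv <- sqrt(sum(v_new^2))
      if (nv == 0) break                   # degenerate residual
      v_new <- v_new / nv
      delta <- sqrt(sum((v_new - v)^2))
      v <- v_new
      Xv <- Xr %*% v
      nu_ <- sqrt(sum(Xv^2))
      if (nu_ == 0) break
      u <- drop(Xv) / nu_
      if (delta < tol) { converged[comp] <- TRUE; break }
    }
    if (!converged[comp]) {
      rlang::warn(sprintf(
        "sparse PCA component %d did not converge in %d iterations",
        comp, max_iter))
    }
    dval <- drop(crossprod(u, Xr %*% v))
    Xr <- Xr - dval * tcrossprod(u, v)
    Q[, comp] <- v
  }

  scores <- X %*% Q
  rownames(scores) <- d$cells
  explained <- adjusted_variance_fractions(X, Q)
  fx <- fix_signs(Q, scores)
  new_decomposition(fx$Q, fx$scores, explained, is_sparse = TRUE,
                    keep_per_component = keep, converged = converged)
}

# QR-adjusted explained variance for (possibly) non-orthogonal loadings:
# the squared diagonal of R from qr(XQ) over the total sum of squares
adjusted_variance_fractions <- function(X, Q) {
  S <- X %*% Q
  R <- qr.R(qr(S))
  diag(R)^2 / sum(X^2)
}

#' @exportS3Method generics::tidy
tidy.decomposition <- function(x, matrix = c("loadings", "scores",
                                             "variance"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    loadings = tibble::as_tibble(x$Q, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "component",
                          values_to = "loading"),
    scores = tibble::as_tibble(x$scores, rownames = "cell") |>
      tidyr::pivot_longer(-"cell", names_to = "component",
                          values_to = "score"),
    variance = tibble::tibble(
      component = colnames(x$Q),
      explained_variance_fraction = x$explained_variance_fraction))
}

#' @exportS3Method generics::glance
glance.decomposition <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$Q), n_genes = nrow(x$Q),
                 n_cells = nrow(x$scores), is_sparse = x$is_sparse,
                 total_explained =
                   sum(x$explained_variance_fraction))
}
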