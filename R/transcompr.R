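# Row-by-row identity check between the target matrix's gene ids and the
# loading rows, optionally translated through a one-to-one ortholog map
# (gene_a = loading/reference namespace, gene_b = target namespace).
# Identifiers are compared, never just lengths.
check_gene_match <- function(genes_b, genes_q, map = NULL) {
  expected <- if (is.null(map)) {
    genes_q
  } else {
    map$gene_b[match(genes_q, map$gene_a)]
  }
  if (!identical(as.character(genes_b), as.character(expected))) {
    rlang::abort("gene ids of x_b do not match the loading matrix rows")
  }
  invisible(TRUE)
}

#' Project a second species' cells into a reference component space
#'
#' The heart of translatable components regression: the reference (species
#' A) loading matrix is applied to the aligned, scaled species-B matrix, so
#' `projected_scores = X_b %*% Q` with no rescaling of `Q`.  Gene
#' identifiers must match the loading rows exactly and in order (ids are
#' compared, not just lengths); align with [align_matrices()] first.
#' Species B is expected to be centered/scaled with its *own* gene means
#' and SDs.
#'
#' @param x_b an [expression_matrix()] with `layer_tag = "scaled"` (genes x
#'   cells) or a cells x genes matrix with gene column names.
#' @param dec a `decomposition` from [pca_decompose()] or
#'   [spca_decompose()].
#' @param map optional one-to-one ortholog table (`gene_a` in the loading
#'   namespace, `gene_b` in the target namespace) used to verify that row
#'   *i* of `x_b` is the ortholog of loading row *i*; omit when both
#'   matrices share a namespace.
#' @return a `projection` object: `projected_scores` (cells_b x
#'   components), `variance_explained_in_b` per component, plus the cell
#'   metadata of species B when available.
#' @export
project_cells <- function(x_b, dec, map = NULL) {
  stopifnot(inherits(dec, "decomposition"))
  d <- as_cells_by_genes(x_b)
  check_gene_match(d$genes, rownames(dec$Q), map)
  S <- d$X %*% dec$Q
  rownames(S) <- d$cells
  structure(list(
    projected_scores = S,
    variance_explained_in_b = cross_species_variance_explained(dec, x_b,
                                                               map = map),
    cell_meta = if (inherits(x_b, "ExpressionMatrix")) x_b$cell_meta else NULL,
    is_sparse = dec$is_sparse), class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection> %d cells x %d components\n",
              nrow(x$projected_scores), ncol(x$projected_scores)))
  invisible(x)
}

#' Cross-species variance explained
#'
#' Fraction of the projected second-species variance captured by each
#' reference component: `q_i' [X'X] q_i / sum(diag(Q' X'X Q))`, where `Q`
#' holds the reference loadings over genes and `X` is the second species'
#' scaled cells x genes matrix.  For sparse (non-orthogonal) loadings the
#' formula is applied verbatim by default; `adjusted = TRUE` substitutes
#' the QR-adjusted variance, which accounts for loading non-orthogonality.
#'
#' @inheritParams project_cells
#' @param adjusted use QR-adjusted variances (sparse loadings only).
#' @return numeric vector of per-component fractions (summing to 1 over the
#'   retained components in the verbatim form).
#' @export
cross_species_variance_explained <- function(dec, x_b, adjusted = FALSE,
                                             map = NULL) {
  stopifnot(inherits(dec, "decomposition"))
  d <- as_cells_by_genes(x_b)
  check_gene_match(d$genes, rownames(dec$Q), map)
  if (sum(d$X^2) == 0) rlang::abort("x_b is all zero: variance undefined")
  S <- d$X %*% dec$Q                     # column i is X q_i
  if (adjusted) {
    r2 <- diag(qr.R(qr(S)))^2
    return(r2 / sum(r2))
  }
  num <- colSums(S^2)                    # q_i' X'X q_i
  num / sum(num)
}

auc_mann_whitney <- function(prob, y) {
  r <- rank(prob)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

labels_to_binary <- function(labels) {
  y <- as.integer(as.character(labels) == "case")
  assert_that(all(labels %in% c("case", "control")),
              "labels must be 'case'/'control'")
  assert_that(length(unique(y)) == 2L, "both classes must be present")
  y
}

#' Logistic regression of phenotype on projected component scores
#'
#' Binomial logistic regression (fit by iteratively reweighted least
#' squares via [stats::glm()]) of case/control labels on a subset of
#' projected component scores, with Wald z/p per component, the model
#' log-likelihood, `AIC = 2k - 2 ln(L)` with `k` the number of estimated
#' parameters, and the AUC computed as the Mann-Whitney statistic of the
#' fitted probabilities.  Cells are treated as independent observations;
#' `cluster` (e.g. subject/sample ids) switches the Wald tests to
#' cluster-robust sandwich standard errors, guarding against per-cell
#' pseudoreplication.
#'
#' @param projection a `projection` from [project_cells()], or a cells x
#'   components score matrix.
#' @param labels per-cell `"case"`/`"control"` labels; defaults to the
#'   projection's cell metadata `condition` column.
#' @param component_subset component names (or indices) to include;
#'   default all.
#' @param cluster optional per-cell cluster ids for robust standard errors.
#' @return a `tcr_glm` object.
#' @export
fit_component_glm <- function(projection, labels = NULL,
                              component_subset = NULL, cluster = NULL) {
  S <- if (inherits(projection, "projection")) {
    projection$projected_scores
  } else {
    as.matrix(projection)
  }
  if (is.null(colnames(S))) colnames(S) <- paste0("PC", seq_len(ncol(S)))
  labels <- labels %||% (if (inherits(projection, "projection"))
    projection$cell_meta$condition else NULL)
  assert_that(!is.null(labels), "labels are required")
  y <- labels_to_binary(labels)
  comps <- component_subset %||% colnames(S)
  if (is.numeric(comps)) comps <- colnames(S)[comps]
  assert_that(all(comps %in% colnames(S)), "unknown components requested")

  dat <- data.frame(.y = y, S[, comps, drop = FALSE], check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) {
    rlang::warn("possible perfect separation: coefficients may be unstable")
  }

  V <- if (is.null(cluster)) vcov(fit) else
    sandwich::vcovCL(fit, cluster = cluster)
  est <- coef(fit)
  se <- sqrt(diag(V))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  ll <- as.numeric(logLik(fit))
  k <- length(est)
  structure(list(
    coefficients = tibble::tibble(
      term = names(est), estimate = unname(est), std_error = unname(se),
      z = unname(z), p_value = unname(p)),
    loglik = ll, k = k, aic = 2 * k - 2 * ll,
    auc = auc_mann_whitney(stats::fitted(fit), y),
    selected_components = comps,
    separation = separation,
    fit = fit, y = y, scores = S), class = "tcr_glm")
}

#' @export
print.tcr_glm <- function(x, ...) {
  cat(sprintf("<tcr_glm> %d components, AIC = %.4f, AUC = %.4f\n",
              length(x$selected_components), x$aic, x$auc))
  print(x$coefficients, n = 8)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tcr_glm <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.tcr_glm <- function(x, ...) {
  tibble::tibble(n_components = length(x$selected_components),
                 k = x$k, log_likelihood = x$loglik, aic = x$aic,
                 auc = x$auc, separation = x$separation)
}

# component index used for deterministic tie-breaking ("PC12" -> 12)
component_index <- function(comp) {
  idx <- suppressWarnings(as.integer(gsub("\\D", "", comp)))
  ifelse(is.na(idx), seq_along(comp), idx)
}

#' Stepwise AIC selection of predictive components
#'
#' Greedy stepwise search minimizing `AIC = 2k - 2 ln(L)`: starting from
#' the full model, each step evaluates all single-component deletions (and,
#' with `direction = "both"`, re-additions of removed components), applies
#' the move with the lowest AIC if strictly lower than the current model's,
#' and stops otherwise.  Ties are broken by the smallest component index,
#' deletions preferred over additions.  The resulting AIC trace is strictly
#' decreasing.
#'
#' @inheritParams fit_component_glm
#' @param direction `"backward"` (default) or `"both"`.
#' @return a `tcr_glm` for the final model, with `selected_components`,
#'   `aic_trace` and a `steps` tibble describing each move.
#' @export
step_aic_glm <- function(projection, labels = NULL,
                         direction = c("backward", "both"), cluster = NULL) {
  direction <- match.arg(direction)
  S <- if (inherits(projection, "projection")) {
    projection$projected_scores
  } else {
    as.matrix(projection)
  }
  if (is.null(colnames(S))) colnames(S) <- paste0("PC", seq_len(ncol(S)))
  labels <- labels %||% (if (inherits(projection, "projection"))
    projection$cell_meta$condition else NULL)

  all_comps <- colnames(S)
  current <- all_comps
  fit_sub <- function(comps) suppressWarnings(
    fit_component_glm(S, labels, component_subset = comps,
                      cluster = cluster))
  cur_fit <- fit_sub(current)
  trace <- cur_fit$aic
  steps <- list()

  repeat {
    cand <- tibble::tibble(move = character(), component = character(),
                           aic = numeric())
    if (length(current) > 1) {
      for (comp in current) {
        cand <- dplyr::bind_rows(cand, tibble::tibble(
          move = "drop", component = comp,
          aic = fit_sub(setdiff(current, comp))$aic))
      }
    }
    if (direction == "both") {
      for (comp in setdiff(all_comps, current)) {
        cand <- dplyr::bind_rows(cand, tibble::tibble(
          move = "add", component = comp,
          aic = fit_sub(union(current, comp))$aic))
      }
    }
    if (nrow(cand) == 0) break
    cand <- cand[order(cand$aic, match(cand$move, c("drop", "add")),
                       component_index(cand$component)), ]
    if (cand$aic[1] >= cur_fit$aic - 1e-12) break
    best <- cand[1, ]
    current <- if (best$move == "drop") {
      setdiff(current, best$component)
    } else {
      all_comps[all_comps %in% c(current, best$component)]
    }
    cur_fit <- fit_sub(current)
    trace <- c(trace, cur_fit$aic)
    steps[[length(steps) + 1L]] <- best
  }

  cur_fit$aic_trace <- trace
  cur_fit$steps <- if (length(steps)) dplyr::bind_rows(steps) else
    tibble::tibble(move = character(), component = character(),
                   aic = numeric())
  cur_fit
}
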