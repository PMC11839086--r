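#' Rank genes by component loadings in the target-species namespace
#'
#' Maps the reference-species gene symbols of a loading vector to the
#' second species through a one-to-one ortholog map, then orders genes by
#' descending loading value.  Ties (including the zero loadings of sparse
#' components, which are retained in the ranked background) are broken by
#' gene symbol, so the ranking is strictly ordered and deterministic.
#' Unmapped genes are dropped with a message reporting the count.
#'
#' @param loadings named numeric vector (names = reference-species gene
#'   ids), e.g. one column of a decomposition's `Q`.
#' @param map one-to-one ortholog table (`gene_a`, `gene_b`); `NULL` keeps
#'   the original namespace.
#' @return a `ranked_list` tibble with columns `gene` (target namespace)
#'   and `stat`, ordered by descending `stat`.
#' @export
rank_genes_from_loadings <- function(loadings, map = NULL) {
  assert_that(!is.null(names(loadings)), "loadings must be a named vector")
  genes <- names(loadings)
  if (!is.null(map)) {
    idx <- match(genes, map$gene_a)
    n_drop <- sum(is.na(idx))
    if (n_drop > 0) {
      rlang::inform(sprintf("%d gene(s) without ortholog mapping dropped",
                            n_drop))
    }
    keep <- !is.na(idx)
    genes <- map$gene_b[idx[keep]]
    loadings <- loadings[keep]
  }
  out <- tibble::tibble(gene = genes, stat = unname(loadings))
  out <- out[order(-out$stat, out$gene), ]
  structure(out, class = c("ranked_list", class(out)))
}

# ES of a gene set given hit positions in a ranked list: weighted
# Kolmogorov-Smirnov running sum, extremum-of-deviation convention.
# absp = |stat|^p over the whole ranked list.
es_from_positions <- function(absp, hit_idx) {
  n <- length(absp)
  m <- length(hit_idx)
  if (m == n) return(1)
  hit_idx <- sort(hit_idx)
  inc <- absp[hit_idx]
  tot <- sum(inc)
  cw <- if (tot > 0) cumsum(inc) / tot else seq_len(m) / m
  d <- 1 / (n - m)
  misses_before <- hit_idx - seq_len(m)
  after <- cw - misses_before * d
  before <- c(0, cw[-m]) - misses_before * d
  es_max <- max(0, after)
  es_min <- min(0, before)
  if (es_max >= abs(es_min)) es_max else es_min
}

#' Enrichment score of a gene set in a ranked list
#'
#' Weighted Kolmogorov-Smirnov statistic: walking down the ranked list,
#' hits increment the running sum by `|stat|^p / sum_set |stat|^p` and
#' misses decrement it by `1/(N - m)`; the enrichment score is the running
#' sum's maximal deviation from zero (signed).  `p = 0` gives the
#' unweighted statistic, invariant to monotone transforms of the ranking
#' statistic.
#'
#' @param ranked a `ranked_list` from [rank_genes_from_loadings()].
#' @param gene_set character vector of gene symbols.
#' @param p weighting exponent (default 1).
#' @return list with `es` and the full `running_sum` vector (length N).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  hits <- ranked$gene %in% gene_set
  m <- sum(hits)
  assert_that(m >= 1, "gene set has empty intersection with the ranked list")
  n <- length(hits)
  absp <- abs(ranked$stat)^p
  steps <- numeric(n)
  if (m == n) {
    tot <- sum(absp)
    steps <- if (tot > 0) absp / tot else rep(1 / n, n)
  } else {
    tot <- sum(absp[hits])
    steps[hits] <- if (tot > 0) absp[hits] / tot else 1 / m
    steps[!hits] <- -1 / (n - m)
  }
  rs <- cumsum(steps)
  i <- which.max(abs(rs))
  list(es = rs[i], running_sum = rs)
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' For every set in the collection with a non-empty intersection with the
#' ranked list, computes the enrichment score, a permutation p-value from
#' `nperm` random same-size gene subsets using the `(1 + #exceed)/(1 + n)`
#' estimator restricted to permutations on the same side, the normalized
#' score `NES = ES / mean(|ES_perm|, same sign)`, Benjamini-Hochberg
#' adjusted p-values over all tested sets, and the leading-edge genes (hits
#' at or before the running-sum extremum).  Deterministic under a fixed
#' seed.
#'
#' @inheritParams enrichment_score
#' @param collection a `GeneSetCollection`.
#' @param nperm number of permutations (default 1000; fewer than 100 draws
#'   a warning).
#' @param seed integer seed for the permutation null.
#' @return tibble with columns `set`, `size`, `es`, `nes`, `p_value`,
#'   `padj`, `leading_edge`.
#' @export
fgsea_preranked <- function(ranked, collection, nperm = 1000L, seed = 1L,
                            p = 1) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (nperm < 100) rlang::warn("nperm < 100: permutation p-values are coarse")
  n <- nrow(ranked)
  absp <- abs(ranked$stat)^p

  rows <- withr::with_seed(seed, {
    purrr::imap(collection$sets, function(genes, set_name) {
      hit_idx <- which(ranked$gene %in% genes)
      m <- length(hit_idx)
      if (m == 0) {
        rlang::inform(sprintf("set %s skipped: empty intersection", set_name))
        return(NULL)
      }
      es <- es_from_positions(absp, hit_idx)
      perm <- vapply(seq_len(nperm), function(i) {
        es_from_positions(absp, sample.int(n, m))
      }, numeric(1))
      same_side <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
      p_val <- (1 + sum(abs(same_side) >= abs(es))) / (1 + length(same_side))
      denom <- mean(abs(same_side))
      nes <- if (isTRUE(denom > 0)) es / denom else NA_real_
      # leading edge: hits up to the running-sum extremum
      rs <- enrichment_score(ranked, genes, p = p)$running_sum
      ext <- which.max(abs(rs))
      le <- if (es >= 0) {
        ranked$gene[intersect(hit_idx, seq_len(ext))]
      } else {
        ranked$gene[intersect(hit_idx, seq.int(ext, n))]
      }
      tibble::tibble(set = set_name, size = m, es = es, nes = nes,
                     p_value = p_val,
                     leading_edge = paste(le, collapse = ";"))
    }) |> purrr::compact() |> purrr::list_rbind()
  })
  if (is.null(rows) || nrow(rows) == 0) {
    rlang::abort("no gene set overlaps the ranked list")
  }
  rows$padj <- bh_adjust(rows$p_value)
  rows[, c("set", "size", "es", "nes", "p_value", "padj", "leading_edge")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (`q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, mapped back to input order), delegated to
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
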