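test_that("target filtering removes targetless and duplicate drugs", {
  sig <- tibble::tibble(drug = c("d1", "d2", "d3", "d4", "d4"),
                        G1 = 1:5, G2 = 6:10)
  meta <- tibble::tibble(drug = c("d1", "d2", "d3", "d4"),
                         targets = c("", NA, "EGFR", "TP53"))
  out <- filter_perturbagens(sig, meta)
  expect_equal(out$drug, c("d3", "d4"))
})

test_that("z-scoring selects |z| beyond the alpha normal quantile", {
  coefs <- stats::setNames(c(-2.5, -0.5, 0, 0.5, 2.5, 0.1, -0.1),
                           paste0("G", 1:7))
  zs <- zscore_and_select(coefs, alpha = 0.05)
  expect_equal(mean(zs$z), 0, tolerance = 1e-12)
  expect_equal(sd(zs$z), 1, tolerance = 1e-12)
  expect_identical(zs$selected, abs(zs$z) > qnorm(0.975))

  expect_message(out <- zscore_and_select(
    stats::setNames(rep(1, 5), paste0("G", 1:5))), "constant")
  expect_null(out)
  expect_error(zscore_and_select(c(a = 1, b = 2)), "at least 3")
})

test_that("null z-scoring selects about the nominal gene fraction", {
  set.seed(71)
  zs <- zscore_and_select(stats::setNames(rnorm(10000),
                                          sprintf("G%05d", 1:10000)))
  frac <- mean(zs$selected)
  moe <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_gt(frac, 0.05 - moe)
  expect_lt(frac, 0.05 + moe)
})

test_that("Spearman reproduces the worked example and handles monotone maps", {
  res <- spearman_cor(c(1, 2, 3), c(10, 20, 15))
  expect_equal(res$rho, 0.5, tolerance = 1e-12)

  x <- rnorm(20)
  expect_equal(spearman_cor(x, exp(x))$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_cor(x, -x^3)$rho, -1, tolerance = 1e-12)
})

test_that("Spearman matches the rank/Pearson reference including ties", {
  set.seed(72)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    # coarse rounding forces ties
    x <- round(rnorm(n), sample(0:1, 1))
    y <- round(rnorm(n), sample(0:1, 1))
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    ours <- spearman_cor(x, y)
    ref_rho <- stats::cor(x, y, method = "spearman")
    expect_equal(ours$rho, ref_rho, tolerance = 1e-12)
    if (abs(ref_rho) < 1) {
      ref_p <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
      expect_equal(ours$p_value, ref_p, tolerance = 1e-9)
    }
  }
})

test_that("noise-free planted drugs occupy the extreme ranks", {
  set.seed(73)
  lv <- stats::setNames(rnorm(150), sprintf("ORTH%04d", 1:150))
  dr <- simulate_drug_signatures(lv, n_drugs = 40, n_planted_pos = 3,
                                 n_planted_neg = 3, noise_sd = 0, seed = 2)
  res <- suppressMessages(
    screen_drugs(dr$signatures, lv, dr$metadata, min_overlap = 3))
  pos <- dr$truth$drug[dr$truth$direction == 1]
  neg <- dr$truth$drug[dr$truth$direction == -1]
  expect_equal(sort(utils::tail(res$drug, 3)), sort(pos))   # highest rho
  expect_equal(sort(utils::head(res$drug, 3)), sort(neg))   # lowest rho
  expect_equal(abs(res$rho[res$drug %in% dr$truth$drug]), rep(1, 6),
               tolerance = 1e-12)
  expect_true(all(res$q_value >= res$p_value))
  expect_true(!is.unsorted(res$rho))
})

test_that("screening composes the per-drug Spearman on the same overlap", {
  set.seed(74)
  lv <- stats::setNames(rnorm(100), sprintf("ORTH%04d", 1:100))
  dr <- simulate_drug_signatures(lv, n_drugs = 25, n_planted_pos = 2,
                                 n_planted_neg = 2, noise_sd = 0.4,
                                 seed = 6)
  res <- suppressMessages(screen_drugs(dr$signatures, lv, dr$metadata))
  gene_cols <- setdiff(names(dr$signatures), "drug")
  for (i in sample(nrow(res), 5)) {
    coefs <- as.numeric(dr$signatures[
      dr$signatures$drug == res$drug[i], gene_cols])
    names(coefs) <- gene_cols
    zs <- zscore_and_select(coefs)
    overlap <- intersect(zs$gene[zs$selected], names(lv))
    direct <- spearman_cor(coefs[overlap], lv[overlap])
    expect_equal(res$rho[i], direct$rho, tolerance = 1e-12)
    expect_equal(res$n_overlap[i], length(overlap))
  }
})

test_that("screen results ignore drug order and loading rescaling", {
  set.seed(75)
  lv <- stats::setNames(rnorm(120), sprintf("ORTH%04d", 1:120))
  dr <- simulate_drug_signatures(lv, n_drugs = 30, seed = 9)
  base <- suppressMessages(screen_drugs(dr$signatures, lv, dr$metadata))
  shuffled <- dr$signatures[sample(nrow(dr$signatures)), ]
  perm <- suppressMessages(screen_drugs(shuffled, lv, dr$metadata))
  expect_equal(dplyr::arrange(base, drug), dplyr::arrange(perm, drug))
  rescaled <- suppressMessages(screen_drugs(dr$signatures, 7.3 * lv,
                                            dr$metadata))
  expect_equal(base$rho, rescaled$rho, tolerance = 1e-12)

  expect_error(suppressMessages(
    screen_drugs(dr$signatures[1, ], lv, min_overlap = 1e6)), "no drug")
})

test_that("sparse loadings restrict the eligible overlap genes", {
  set.seed(76)
  lv <- stats::setNames(c(rep(0, 60), rnorm(60)), sprintf("ORTH%04d", 1:120))
  dr <- simulate_drug_signatures(lv, n_drugs = 20, seed = 3)
  res <- suppressMessages(screen_drugs(dr$signatures, lv, dr$metadata,
                                       min_overlap = 1))
  # every tested overlap fits inside the nonzero-loading gene pool
  expect_true(all(res$n_overlap <= 60))
})
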