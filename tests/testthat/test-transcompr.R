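# independent oracle: the printed variance-explained formula evaluated
# naively, component by component, with explicit X'X
naive_cross_var <- function(Q, X) {
  XtX <- t(X) %*% X
  num <- vapply(seq_len(ncol(Q)), function(i) {
    drop(t(Q[, i]) %*% XtX %*% Q[, i])
  }, numeric(1))
  den <- sum(diag(t(Q) %*% XtX %*% Q))
  num / den
}

test_that("identity loadings project cells onto themselves", {
  Q <- diag(2)
  rownames(Q) <- c("g1", "g2")
  dec <- transcompr:::new_decomposition(Q, matrix(0, 1, 2), c(0.5, 0.5),
                                        is_sparse = FALSE)
  X_b <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("g1", "g2")))
  proj <- project_cells(X_b, dec)
  expect_equal(unname(proj$projected_scores), unname(X_b))
})

test_that("self-projection returns the decomposition scores exactly", {
  sim <- small_sim(seed = 10, n_genes = 150, n_orthologs = 80, n_cells = 50)
  sc <- normalize_scale(qc_filter_cells(sim$species_a, small_qc())$filtered)
  dec <- pca_decompose(sc, 5)
  proj <- project_cells(sc, dec)
  expect_identical(proj$projected_scores, dec$scores)
})

test_that("projection equals an explicit matrix product", {
  set.seed(15)
  X_a <- matrix(rnorm(40 * 12), 40, 12,
                dimnames = list(NULL, sprintf("g%02d", 1:12)))
  X_a <- sweep(X_a, 2, colMeans(X_a))
  dec <- pca_decompose(X_a, 6)
  X_b <- matrix(rnorm(15 * 12), 15, 12,
                dimnames = list(NULL, sprintf("g%02d", 1:12)))
  proj <- project_cells(X_b, dec)
  expect_equal(unname(proj$projected_scores), unname(X_b %*% dec$Q),
               tolerance = 1e-12)
})

test_that("gene-id mismatches are rejected by identifier, not length", {
  set.seed(16)
  X_a <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(NULL, sprintf("g%d", 1:6)))
  dec <- pca_decompose(sweep(X_a, 2, colMeans(X_a)), 3)
  X_bad <- matrix(rnorm(12), 2, 6,
                  dimnames = list(NULL, sprintf("h%d", 1:6)))
  expect_error(project_cells(X_bad, dec), "gene ids")
  # ortholog map translating the namespaces makes the same call valid
  map <- tibble::tibble(gene_a = sprintf("g%d", 1:6),
                        gene_b = sprintf("h%d", 1:6))
  expect_s3_class(project_cells(X_bad, dec, map = map), "projection")
})

test_that("variance explained reproduces the hand example X'X = diag(4, 1)", {
  Q <- diag(2)
  rownames(Q) <- c("g1", "g2")
  dec <- transcompr:::new_decomposition(Q, matrix(0, 1, 2), c(0.5, 0.5),
                                        is_sparse = FALSE)
  X <- matrix(c(2, 0, 0, 1), 2, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(unname(cross_species_variance_explained(dec, X)),
               c(0.8, 0.2), tolerance = 1e-12)

  dec1 <- transcompr:::new_decomposition(Q[, 1, drop = FALSE],
                                         matrix(0, 1, 1), 0.5,
                                         is_sparse = FALSE)
  expect_equal(unname(cross_species_variance_explained(dec1, X)), 1)
})

test_that("self variance-explained is proportional to the PCA variances", {
  sim <- small_sim(seed = 19, n_genes = 150, n_orthologs = 80, n_cells = 60)
  sc <- normalize_scale(qc_filter_cells(sim$species_a, small_qc())$filtered)
  dec <- pca_decompose(sc, 6)
  frac <- cross_species_variance_explained(dec, sc)
  expect_equal(unname(frac),
               dec$explained_variance_fraction /
                 sum(dec$explained_variance_fraction),
               tolerance = 1e-10)
})

test_that("variance explained matches the naive formula on random problems", {
  set.seed(33)
  for (rep in 1:10) {
    X_a <- matrix(rnorm(30 * 20), 30, 20,
                  dimnames = list(NULL, sprintf("g%02d", 1:20)))
    X_a <- sweep(X_a, 2, colMeans(X_a))
    dec <- spca_decompose(X_a, 5, keep_per_component = 8)
    X_b <- matrix(rnorm(25 * 20), 25, 20,
                  dimnames = list(NULL, sprintf("g%02d", 1:20)))
    expect_equal(unname(cross_species_variance_explained(dec, X_b)),
                 naive_cross_var(dec$Q, X_b), tolerance = 1e-10)
  }
  expect_error(cross_species_variance_explained(
    pca_decompose(matrix(rnorm(20), 10, 2,
                         dimnames = list(NULL, c("g1", "g2"))), 2),
    matrix(0, 4, 2, dimnames = list(NULL, c("g1", "g2")))), "all zero")
})

test_that("GLM bookkeeping follows AIC = 2k - 2 ln L and flags separation", {
  set.seed(41)
  n <- 300
  S <- matrix(rnorm(n * 4), n, 4)
  y <- ifelse(runif(n) < stats::plogis(1.5 * S[, 2]), "case", "control")
  fit <- fit_component_glm(S, y)
  expect_equal(fit$k, 5L)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik, tolerance = 1e-8)
  expect_equal(fit$aic, stats::AIC(fit$fit), tolerance = 1e-8)
  expect_lt(fit$coefficients$p_value[fit$coefficients$term == "PC2"], 1e-4)

  # a perfectly separating score: AUC 1 and a separation warning
  S1 <- matrix(c(seq(-2, -0.1, length.out = 20),
                 seq(0.1, 2, length.out = 20)), ncol = 1)
  y1 <- rep(c("control", "case"), each = 20)
  expect_warning(fit1 <- fit_component_glm(S1, y1), "separation")
  expect_equal(fit1$auc, 1.0)
  expect_true(fit1$separation)
})

test_that("cluster-robust standard errors widen under pseudoreplication", {
  set.seed(55)
  n_subj <- 12; cells_per <- 40
  subj_effect <- rnorm(n_subj, sd = 2)
  subj <- rep(seq_len(n_subj), each = cells_per)
  s <- subj_effect[subj] + rnorm(n_subj * cells_per, sd = 0.3)
  y <- ifelse(rep(rbinom(n_subj, 1, 0.5), each = cells_per) == 1,
              "case", "control")
  naive <- suppressWarnings(fit_component_glm(cbind(PC1 = s), y))
  robust <- suppressWarnings(fit_component_glm(cbind(PC1 = s), y,
                                               cluster = subj))
  se_n <- naive$coefficients$std_error[2]
  se_r <- robust$coefficients$std_error[2]
  expect_gt(se_r, se_n)
})

test_that("stepwise AIC keeps the informative component and only improves", {
  hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 500
    S <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("PC", 1:6)))
    y <- ifelse(runif(n) < stats::plogis(1.2 * S[, 3]), "case", "control")
    fit <- suppressWarnings(step_aic_glm(S, y))
    expect_true(all(diff(fit$aic_trace) < 0))
    "PC3" %in% fit$selected_components
  }, logical(1))
  expect_equal(sum(hits), 5L)

  # all-noise scores: the final AIC never exceeds the full model's
  set.seed(77)
  S <- matrix(rnorm(400 * 5), 400, 5)
  y <- rep(c("case", "control"), 200)
  fit <- suppressWarnings(step_aic_glm(S, y))
  full <- suppressWarnings(fit_component_glm(S, y))
  expect_lte(fit$aic, full$aic)

  # a single already-optimal component takes zero steps
  set.seed(78)
  s1 <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "PC1"))
  y1 <- ifelse(runif(300) < stats::plogis(2 * s1[, 1]), "case", "control")
  fit1 <- suppressWarnings(step_aic_glm(s1, y1))
  expect_equal(nrow(fit1$steps), 0L)
  expect_length(fit1$aic_trace, 1L)
})

test_that("stepwise selection agrees with the reference stepAIC", {
  skip_if_not_installed("MASS")
  set.seed(91)
  n <- 400
  S <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("PC", 1:5)))
  y <- ifelse(runif(n) < stats::plogis(1.5 * S[, 2] - S[, 4]),
              "case", "control")
  ours <- suppressWarnings(step_aic_glm(S, y))
  dat <- data.frame(y = as.integer(y == "case"), S)
  ref <- suppressWarnings(MASS::stepAIC(
    glm(y ~ ., data = dat, family = binomial()), trace = 0))
  ref_terms <- attr(stats::terms(ref), "term.labels")
  expect_setequal(ours$selected_components, ref_terms)
  expect_equal(ours$aic, stats::AIC(ref), tolerance = 1e-6)
})
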