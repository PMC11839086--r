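---
title: "Translatable components regression: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translatable components regression: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcompr)
```

## The model

Translatable components regression asks a cross-species question in three
linear-algebra steps.  A reference species (typically a mouse disease
model) provides a scaled expression matrix $X_a$ (cells × genes) whose
decomposition yields a loading matrix $Q$ (genes × components).  A target
species (typically human) provides $X_b$, restricted to one-to-one
orthologs of the reference genes, scaled *within its own species*.  Then:

1. **Projection.** $S_b = X_b Q$ places every target cell in the
   reference component space.  No rescaling of $Q$ is applied, so the
   direction of each reference axis is preserved and only the magnitude
   adapts to the target data.
2. **Cross-species variance explained.** For component $i$,
   $$v_i = \frac{q_i^\top X_b^\top X_b\, q_i}{\sum_j \operatorname{diag}(Q^\top X_b^\top X_b Q)_j},$$
   the share of the projected target variance captured by that axis.  For
   dense (orthonormal) loadings the $v_i$ sum to one over the retained
   components.  For sparse loadings the columns of $Q$ are not orthogonal
   and this quotient double-counts shared directions; we apply it verbatim
   by default, because that is the quantity the method defines, and expose
   a QR-adjusted alternative (`adjusted = TRUE`) that orthogonalizes
   $X_b Q$ first.
3. **Component selection.** Case/control labels of the target cells are
   regressed on $S_b$ by binomial logistic regression.  Backward stepwise
   search minimises $\mathrm{AIC} = 2k - 2\ln L$ ($k$ = number of
   estimated parameters, intercept included); at each step all
   single-component deletions (and re-additions, if `direction = "both"`)
   are scored and the strictly best move is taken, ties broken by the
   smallest component index, deletions before additions.  The AIC trace is
   therefore strictly decreasing.  Wald z-tests give per-component
   p-values; the AUC is the Mann–Whitney statistic of the fitted
   probabilities.

Cells are treated as independent observations, which is how this class of
analyses is usually run and what the per-cell p-values mean.  With
hundreds of cells per subject this pseudoreplicates: effective sample
sizes are subjects, not cells, and p-values deflate accordingly.
`fit_component_glm(..., cluster = sample_id)` switches the Wald tests to
cluster-robust sandwich errors; it is off by default to match standard
practice but recommended whenever subjects are few.

## Decomposition: dense and sparse

`pca_decompose()` takes the top right singular vectors of the cell-centred
matrix; explained variance fractions are squared singular values over the
total sum of squares.  Signs are fixed so each component's
largest-|loading| gene is positive — decompositions are otherwise only
defined up to sign, and this convention makes results reproducible across
linear-algebra backends.

`spca_decompose()` implements penalized rank-1 decomposition with
deflation: alternate $v \leftarrow \mathrm{soft}(X^\top u, \lambda)$, with
$\lambda$ set to the $(\text{keep}+1)$-th largest coefficient so at most
`keep` loadings stay nonzero, renormalize, $u \leftarrow Xv/\lVert Xv\rVert$,
until the loading change is below $10^{-6}$ or 500 iterations
(non-convergence warns and returns the last iterate).  $u$ starts at the
residual's leading singular vector, so the algorithm is deterministic and
the `keep = n_genes` limit reproduces dense PCA exactly — the property the
test-suite leans on.  After each component the residual is deflated by its
best rank-1 fit $d\,uv^\top$.  The per-component sparsity budget defaults
to 25% of the genes; that is a package default, not an estimate of
anything, and should be tuned per dataset (there is no universally right
sparsity level, and model fit metrics such as AIC/AUC after projection —
see `benchmark_sweep()` — are the honest way to compare settings).

## Upstream processing

**QC.** Cells are removed when they fail any of: detected genes < 200,
total counts < 500, mitochondrial percentage > 10 (symbol prefixes
`MT-`/`mt-`, covering both species' conventions), or library size more
than 3 scaled MADs (constant 1.4826) from the median.  The MAD rule is
computed within each sample by default, so a deep-sequenced batch cannot
eject another batch's cells; `mad_scope = "sample"` instead drops whole
samples whose median library size is an outlier among samples, for designs
where one subject's library failed globally.  `MAD = 0` is read as "any
deviation from the median fails".  Because removing outliers shifts the
median and MAD, the joint pass is iterated to a fixed point — this makes
the filter idempotent (re-filtering filtered data removes nothing), at the
cost of being marginally more aggressive than a single pass.  Thresholds
are sized for genome-wide panels; small simulated panels need
proportionally smaller `min_genes_per_cell`/`min_counts_per_cell`.

**Variable genes.** Genes are ranked by observed variance over
trend-expected variance, the trend being a loess fit of log10 variance on
log10 mean across genes (span 0.3, degree 2, robust family).  Constant
genes rank last; ties break lexicographically so the ranking is total and
deterministic.

**Normalization.** Counts are depth-normalized to 10,000 per cell,
log1p-transformed, optionally residualized per gene against user-supplied
covariates (e.g. cell-cycle scores) via a single QR, then centred and
scaled to unit variance per gene and clipped at ±10.  This is a
deliberately simple, transparent stand-in for variance-stabilizing count
models: the downstream mathematics needs exactly a centred/scaled genes ×
cells matrix, and every choice here is inspectable.  Rows constant up to
numerical noise (sd below 1e-8 relative) become zero rows rather than
amplified noise.

**Orthologs.** One-to-one mapping is enforced by strict dropping: a gene
appearing in more than one candidate pair loses all its pairs.  This
discards real signal in gene families but guarantees that projection
never mixes paralogs; a `best_confidence` mode keeps the
highest-confidence pair instead when a confidence column exists.
Alignment requires at least two shared mapped genes — below that a
"projection" is a scalar product and nothing downstream is meaningful.

## Enrichment and drug screening

Component loadings are mapped to the target namespace and ranked by
signed value, ties broken by symbol; zero loadings of sparse components
stay in the ranked background so dense and sparse results share the same
null.  The enrichment score is the classic weighted Kolmogorov–Smirnov
running sum (hits add $|s|^p/\sum_{set}|s|^p$, misses subtract $1/(N-m)$,
score = maximal deviation from zero; $p=1$ by default, $p=0$ gives the
rank-only statistic).  The null is gene-permutation: `nperm` random
same-size subsets, $p = (1 + \#\{\text{same-side} \ge |ES|\})/(1 + n_{side})$,
NES = ES over the mean same-side |ES|, BH across sets.  The adaptive
multilevel p-value refinement used by modern enrichment tools is out of
scope; below $p \approx 1/nperm$ resolution stops, which matters only
when very small adjusted p-values are themselves the object of interest.

Drug signatures arrive as per-drug characteristic-direction coefficient
vectors.  Each drug is z-scored *across its own genes* (the coefficients
are a direction, so the drug's internal distribution is the natural
reference; z-scoring per gene across drugs is a different question —
which drugs move this gene most — and is not what the screen asks),
genes at two-sided normal p < 0.05 form the drug's signature, and the
tie-aware Spearman correlation with the component loadings is computed
over the overlap of that signature with the loading's eligible genes
(nonzero loadings for sparse components).  BH runs across all drugs
tested for one component.  A minimum overlap (default 5, floor 3 — the
correlation needs three points) guards degenerate correlations.  Sign
semantics are deliberately surfaced rather than hidden: a component's
orientation is arbitrary, so the report carries each component's
case/control mean projected scores, and the sign of a drug's rho is
interpreted against that orientation.

## The synthetic generator

`simulate_paired_species()` draws counts as
$\mathrm{NB}(\mu = \exp(b_g + \ell_g^\top s_c),\ \theta)$ with variance
$\mu + \mu^2/\theta$, followed by independent Bernoulli dropout
(zero-inflation applied after sampling).  Both species share loading
values on their orthologous genes across all latent factors; one planted
factor's per-cell score is shifted by `condition_effect` in case cells of
both species — the cross-species translatable axis the pipeline should
find.  Mitochondrial spike-ins get `mt-`/`MT-` prefixes; mouse-style
title-case vs human-style uppercase symbols force the ortholog mapping to
do real work.  Defaults — 2,000 genes and 2,000 cells per species, 1,000
orthologs, 5 factors, effect 1.5, loading sd 0.5 with 30% zeros,
dispersion 2, 30% dropout, 5% mitochondrial genes — are the package's
study conditions: counts in the typical snRNA-seq range, factor structure
strong enough to be found but far from noise-free.

What the generator does *not* emulate: batch effects, ambient RNA,
doublets, gene-length/GC bias, cell-type mixtures, or many-to-many
homology.  Passing tests therefore demonstrate that the mathematics and
the plumbing are right under the stated generative model, not that any
given biological dataset satisfies that model.  One interaction worth
knowing: because library size is $\sum_g \exp(\ell_g^\top s_c)$-driven,
the planted factor shifts case cells' depths, and the MAD filter at
default settings removes a substantial fraction of simulated cells.  That
is faithful behaviour of the filter on heavy-tailed depth distributions —
and the reason the recovery benchmarks below run on the unfiltered
matrices, keeping their stated sample size while QC is exercised by its
own tests.

`simulate_drug_signatures()` plants positive/negative drugs as
$a\cdot\hat\ell + \varepsilon$ around a chosen loading vector (rescaled
to unit sd) among pure-noise drugs, with planted recall at $q<0.05$
approaching 1 as the noise vanishes.

## Numerical and benchmark choices

- Convergence: sparse-PCA loading change $<10^{-6}$ (500 iterations max);
  GLM deviance change $<10^{-8}$ (100 IRLS iterations).
- Degenerate inputs: empty-after-QC, zero-library cells, all-zero target
  matrices, empty gene-set intersections and constant drug signatures all
  raise or skip explicitly rather than propagating NaNs.
- Determinism: no stage uses unseeded randomness; the pipeline derives
  per-stage seeds from the global seed and stage name, so adding a stage
  never perturbs earlier stages, and identical configurations produce
  byte-identical JSON reports.
- Benchmark sizes: the planted-factor recovery benchmark uses the
  generator defaults (2,000 cells/species, 1,000 orthologs) with 500
  variable genes and 10 components over 20 seeds; GLM calibration uses
  1,000 permuted-label fits at 200 cells; enrichment calibration 200
  independent draws at 300 genes; the drug-screen false-discovery check
  1,000 pure-noise drugs over 20 seeded runs.  These sizes give the
  Monte-Carlo error bands the assertions state while keeping a full run
  of the suite comfortable on a laptop.  The acceptance script's drug
  screen uses a 1,000-gene variable panel (≈500 aligned orthologs) so
  per-drug overlaps land in the 20–30-gene range typical of
  landmark-style signature screens, and planted noise 0.1; at a few
  hundred eligible genes per drug the Spearman screen has little power —
  a real limitation of overlap-based screening on small namespaces, not
  an implementation artifact.

## Known limitations

- The variance-explained quotient for sparse components double-counts
  correlated loadings unless the QR-adjusted form is requested.
- In-sample AUC of the selected model is optimistic (selection and
  evaluation share the data); between-method comparisons
  (`benchmark_sweep()`) are on equal footing, but absolute AUCs should be
  read as descriptive.
- Stepwise AIC is greedy; with strongly correlated components the
  selected set is one good model among several, not a unique answer.
- Per-cell GLM p-values ignore subject structure unless `cluster` is
  supplied (see above).
- The permutation null permutes genes, not phenotypes, matching the
  preranked formulation; inter-gene correlation within sets is therefore
  not accounted for.
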