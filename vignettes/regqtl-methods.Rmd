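---
title: "Methods: interaction-QTL screening for miRNA-mRNA regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction-QTL screening for miRNA-mRNA regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An ordinary eQTL shifts a gene's mean expression by genotype. A
*regulatory* QTL (regQTL), the object of this package, changes the
coupling between a regulator and its target: the slope of gene
expression on miRNA expression differs by genotype, as would happen if
an allele creates, strengthens, weakens, or abrogates a miRNA binding
site. For each candidate (miRNA, gene, SNP) trio we fit, by ordinary
least squares,

$$Y = \beta_0 + \beta_1 PC1 + \beta_2 PC2 + \beta_3 X_{miR}
  + \beta_4 \mathbf{1}(\text{het}) + \beta_5 \mathbf{1}(\text{hom})
  + \beta_6 \mathbf{1}(\text{het}) X_{miR}
  + \beta_7 \mathbf{1}(\text{hom}) X_{miR} + \varepsilon$$

with $Y$ the gene's log2 expression, $X_{miR}$ the miRNA's log2
expression, genotype coded as a categorical factor with the
homozygous-major class as reference, and $PC1$, $PC2$ the two leading
genotype principal components. Genotype enters categorically rather
than as a dosage so that dominant, recessive and additive allelic
effects on the coupling are all representable; $\beta_4,\beta_5$ absorb
eQTL-like mean shifts so that $\beta_6,\beta_7$ isolate the change in
slope. Per-genotype miRNA slopes are $\beta_3$, $\beta_3+\beta_6$ and
$\beta_3+\beta_7$; `fit_trio()` reports them with standard errors
derived from the coefficient covariance (including the $2\,\mathrm{cov}$
cross term).

The null hypothesis $\beta_6=\beta_7=0$ is tested by comparing the full
model to the model without the interaction columns:
$F = \frac{(RSS_{red}-RSS_{full})/q}{RSS_{full}/(n-k)}$ with $q$ the
number of interaction columns (2 with three genotype classes, 1 with
two) and $k$ the full design's column count. Because the interaction is
the highest-order term, this partial F is identical to the Type III
(Yates weighted-squares-of-means) F for the interaction; the test suite
verifies the equality against `anova()` on nested `lm` fits. P-values
use the exact F reference distribution. Across all fitted trios of a
screen, q-values are computed with the Benjamini–Hochberg step-up
$q_{(i)} = \min_{j\ge i} p_{(j)} m / j$, chosen because trios sharing a
miRNA or gene are positively dependent and BH controls the FDR under
such dependency. $m$ counts only trios with `status == "ok"`; skipped
trios (degenerate or rank-deficient) carry no p and do not dilute the
adjustment.

## Per-trio pipeline and its order of operations

1. Drop samples with missing genotype calls (never imputed at fit
   time), then samples with no appreciable miRNA expression — defined
   as raw reads-per-million exactly 0, the only unambiguous zero; on
   the log2 scale with offset $c$ these sit at the point mass
   $\log_2 c$ and carry no information about the miRNA–gene coupling.
2. Skip the trio (`skipped_degenerate`) if fewer than two genotype
   classes remain or any observed class retains fewer than
   `min_class_n = 5` samples. The cohort-level 5% genotype-frequency
   filter does not survive per-trio masking, and a 1–2 sample class can
   single-handedly manufacture an interaction; the floor is
   configurable and 0 disables it. Two-class trios are tested
   ($q = 1$) rather than skipped: the model generalizes naturally and
   the cohort filters admit two-class SNPs.
3. Fit full and reduced models; rank deficiency is detected from the QR
   factorization and reported (`skipped_rank_deficient`), never
   silently pseudo-inverted.
4. Compute Cook's distances
   $D_i = r_i^2 h_{ii} / (k s^2 (1-h_{ii})^2)$ on the **full** model
   (the model whose inference is reported); if any $D_i > 1$, remove
   those samples and refit both models **exactly once**. A single pass
   keeps sample loss bounded and makes the procedure idempotent: when
   no point exceeds the threshold the refit path is a strict no-op,
   byte-identical to the single-pass fit.

### What Cook's D can and cannot remove

For a pure response outlier the internally studentized residual is
bounded, so $D_i \le h_{ii}(n-k)/(k(1-h_{ii}))$ — approximately 1 at
average leverage $h \approx k/n$ *regardless of how large the shift
is*. A 100-$\sigma$ contaminated sample at below-average leverage is
therefore not removable by the $D>1$ rule, while the same shift at high
leverage (extreme miRNA expression) is removed essentially always;
Monte-Carlo checks in the test suite put the unconditional detection
rate of random-position 50-$\sigma$ shifts near 16–25%, not near 1.
Cook's distance is an *influence* cutoff, not an outlyingness cutoff,
and the screen inherits that semantics. Tests and the acceptance report
therefore inject outliers at the maximum-leverage sample, where removal
is deterministic, and additionally verify that contaminated samples
dominate the $D$ distribution and that $D>1$ flags are specific.

## Preprocessing defaults

| parameter | default | meaning |
|---|---|---|
| `gene_median_min` | 1e-9 | genes with raw median below this (before TPM) are removed; unit depends on the upstream quantifier, hence configurable |
| `mirna_detect_level` / `frac` | 1 / 0.5 | miRNAs with raw expression ≤ 1 RPM in strictly more than half the samples are removed |
| `mrna_offset`, `mirna_offset` | 1.0 | log2 offsets; 1 maps raw 0 to log 0 and is the common convention |
| `maf_min` | 0.01 | SNPs below 1% minor allele frequency are removed |
| `class_freq_min` | 0.05 | every *observed* genotype class must reach 5% of non-missing calls |
| `cooks_threshold` | 1.0 | conventional high-influence cutoff |
| `pair p`, `FDR` | 0.01, 0.1 | strict inequalities for pair selection and significance |

The genotype-frequency rule is applied to observed classes only: an
absent class has frequency 0, so counting unobserved classes would
remove every two-class SNP, which cannot be the intent of a filter
whose purpose is to keep per-class sample counts stable. Missing calls
are excluded from both MAF and class-frequency denominators. Dosage
always counts the cohort-minor allele: inputs whose stated ALT/minor
allele is in fact major are re-polarized on load (d → 2 − d, labels
swapped), which makes MAF and the reference-genotype choice
deterministic. Multi-allelic records are excluded (the model is defined
for three classes), and all coordinates are 1-based as in VCF.

## Population-structure covariates

Genotypes are normalized EIGENSTRAT-style before PCA: missing calls are
mean-imputed per SNP (PCA only — fits never impute), each SNP column is
centered at $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$ (the
binomial SD of dosage), and monomorphic columns are dropped; plain
centering is available via `method = "center"`. Scores come from the
SVD of the normalized matrix, with component signs fixed
deterministically (largest-magnitude score positive) so results are
reproducible and order-invariant. Exactly two PCs enter the regression,
matching the model; `n_components` is configurable for sensitivity
analyses.

Why additive PCs help an interaction test: when ancestry shifts both
gene expression and miRNA expression and the SNP's allele frequency
diverges between subpopulations, genotype classes differ in ancestry
composition, so the *apparent* within-class miRNA slope
$\beta_3 + a\,\mathrm{cov}(S, X_{miR} \mid g)/\mathrm{var}(X_{miR}
\mid g)$ varies by class — a spurious interaction. Absorbing the
ancestry mean shift $a S$ with PC1 removes the bias. The acceptance
suite constructs exactly this scenario (expression shift 2σ, miRNA mean
shift 2, MAF 0.1 vs 0.4) and verifies ~4-fold type-I inflation without
PCs and nominal calibration with estimated PCs.

## The synthetic-data generator

`simulate_genotypes()` draws each sample's subpopulation from
`subpop_props` and each dosage as Binomial(2, f) with f the
subpopulation allele frequency — i.e. Hardy–Weinberg classes, with
substructure expressed purely through allele-frequency divergence.
`simulate_trio_expression()` draws $X_{miR} \sim N(5, 1)$ on the log2
scale (raw-zero dropout is a separate Bernoulli point mass with
probability 0.02, since a Normal cannot produce it) and builds $Y$ from
the model equation with $\varepsilon \sim N(0, 1)$ and intercept 8 —
log2-RPM-like magnitudes at which the raw matrices ($2^v - 1$) are
non-negative with overwhelming probability. Defaults state a mid-range
cohort (n = 500 of the 300–700 the method targets), MAF 0.3, and a
moderately repressive miRNA slope $\beta_3 = -0.5$. The true
subpopulation indicator (centered) is what multiplies $\beta_1$ during
generation; the screen must *recover* a proxy via genotype PCA, closing
the loop between generator and pipeline. Effect grids use
$\beta_6/\sigma \in \{0, 0.5, 1.0\}$ with "strong" defined as an
interaction slope of one residual SD per miRNA-expression SD
($\beta_7 = \beta_6$).

What the generator does **not** emulate: LD blocks (SNPs are marginally
independent, so the clustered-hit structure of real screens is absent),
read-count noise (expression is Gaussian on the log scale),
heteroskedasticity, batch effects, and shared-miRNA correlation beyond
block-wise reuse of the miRNA vector. A green end-to-end test therefore
establishes correctness of the statistics and plumbing under the
model's own assumptions — not robustness to their violation.

## Numerical choices

- OLS goes through the QR factorization; rank is taken from the QR and
  deficiency is a reported status, not an approximation.
- RSS equal to zero to working precision (relative to the fitted sum of
  squares, threshold 1e-22) makes the F undefined
  (`skipped_degenerate`) and Cook's distances 0 — an exact fit has no
  influence to measure.
- $F$ is clamped at 0 against floating-point $RSS_{red} < RSS_{full}$.
- Exact leverage points ($h_{ii} = 1$) report $D = \infty$.
- Reference genotype ties (no homozygous-major class, equal counts)
  break toward the lower dosage.
- Results TSVs serialize floats at 17 significant digits so a
  write–read round trip is bit-for-bit.
- The screen is deterministic end to end; all simulation randomness
  flows from scenario seeds (trio-level draws consume the caller's RNG
  stream so bundle trios are independent, while bundle-level generation
  is byte-reproducible from its seed).

## Known limitations

- One SNP per fit; joint modeling of multiple variants is out of scope.
- No permutation or robust-regression alternative to the F-test; gross
  low-leverage outliers survive the Cook's rule (above) and inflate
  $\sigma^2$ instead.
- The SNP→gene assignment is consumed, not computed; window choices
  (gene body vs. flanks) belong to the upstream annotation.
- Between-sample normalization beyond TPM (quantile normalization,
  batch correction) is deliberately absent.
- BH controls the FDR under positive dependency; under adversarial
  dependence the guarantee is weaker.
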