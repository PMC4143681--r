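---
title: "GLS-SKAT: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GLS-SKAT: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gene-region rare-variant tests (SKAT, burden, SKAT-O) assume exchangeable
individuals. Family studies violate that: relatives share polygenic
background, so naive region tests are miscalibrated. The approach
implemented here removes family structure by generalized least squares
(GLS): estimate pairwise relatedness from the dense genotype data itself,
build a whitening transform from that matrix, apply it jointly to the
phenotype and the genotype matrix, and then run standard
population-sample region tests on the decorrelated data. Because the
relatedness matrix is estimated from genotypes rather than declared
pedigrees, the same transform also absorbs cryptic relatedness and
population stratification; no ancestry covariates or principal components
are used anywhere.

## Model and procedure

For a quantitative trait $y$ on $n$ genotyped individuals:

1. **Covariate residualization.** An OLS model
   $y = \beta_0 + \beta_1\,\mathrm{sex} + \beta_2\,\mathrm{age} +
   \beta_3\,\mathrm{age}^2 + \beta_4\,\mathrm{med} +
   \beta_5\,\mathrm{smoke} + \varepsilon$
   is fitted on a mutually unrelated subset (a curated list when
   available, otherwise a greedy independent set on the relatedness graph
   at kinship > 0.10) and projected to *all* individuals:
   $r_i = y_i - \hat y_i$. Fitting on unrelateds keeps the covariate
   coefficients free of family confounding; projecting (rather than
   re-fitting) preserves the family structure in the residuals for the
   next step to remove.
2. **Kinship.** The Balding–Nichols (BN) genetic relationship matrix
   $K_{ij} = M^{-1}\sum_m (g_{im}-2\hat p_m)(g_{jm}-2\hat p_m) /
   (2\hat p_m(1-\hat p_m))$
   over all variants with folded MAF $\ge$ 0.01 (an IBS sharing matrix is
   available as an alternative). One member of each identical twin pair
   is removed first — twins make the matrix singular. Because the
   estimator centers at sample frequencies, $K\mathbf{1}=0$ structurally;
   the nonsingularity certificate therefore deflates the all-ones
   direction before checking the spectrum, and the decorrelator handles
   that direction through its ridge policy plus the transformed-intercept
   projection below.
3. **GLS transform.** A covariance model $\Sigma$ is factorized and
   inverted: Cholesky $\Sigma = LL'$, $T = L^{-1}$, or eigen
   $\Sigma = U D U'$, $T = D^{-1/2}U'$. Both whiten $\Sigma$ exactly and
   give identical test p-values (they differ by an orthogonal rotation, to
   which the statistics are invariant); the package tests this
   equivalence. Then $\tilde y = Tr$, $\tilde G = TG$ (all region
   variants, rare and common alike), $\tilde\imath = T\mathbf{1}$.
4. **Region tests.** For each gene, a region spans the transcript $\pm$20
   kb. With score residuals $\tilde r$ of $\tilde y$ on
   $\tilde\imath$, variance estimate $\hat\sigma^2$, and
   Madsen–Browning weights $w_j = 1/\sqrt{p_j(1-p_j)}$ from
   pre-transformation MAFs,
   $Q_\rho = (1-\rho)\sum_j (w_j \tilde g_j'\tilde r)^2 +
   \rho\,(\sum_j w_j \tilde g_j'\tilde r)^2$.
   $\rho=0$ is SKAT, $\rho=1$ the burden test, and SKAT-O minimizes the
   p-value over the grid $\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25,
   0.5, 1\}$ with the analytic min-p correction (integration over the
   shared burden component). Tail probabilities of the
   $\sum_k \lambda_k \chi^2_1$ null come from characteristic-function
   inversion (below).

## The covariance model: why the default is heritability-weighted

The transform needs the covariance of the residual trait. Two models are
offered:

* `mode = "kinship"`: $\Sigma \propto K$ (rescaled to unit mean
  diagonal). This is the classical EMMAX/GRAMMAR-style projection.
* `mode = "heritability"` (default): $\Sigma = h^2 K + (1-h^2) I$, with
  $h^2$ estimated by REML from the residuals. This is the mixture that a
  polygenic model actually implies, and it is also numerically safer: the
  inverse square root of a *noisy* $\hat K$ amplifies the directions
  where $\hat K$ underestimates variance, and because both $\tilde y$ and
  $\tilde G$ are whitened with the same wrong directions the errors
  compound into anticonservative region tests. The identity component
  bounds the smallest eigenvalue of $\Sigma$ by $1-h^2$ and so damps
  exactly those directions. With kinship panels that are enormous
  relative to $n$ the two modes converge, which is why the raw-kinship
  projection behaves well on dense real data; at simulation scale the
  mixture is the calibrated choice. The package's acceptance suite
  measures the pooled type-I error of the default pipeline end to end; it
  is nominal at the 0.01 and 0.001 levels, with a small excess (of order
  0.003) remaining at the 0.05 level that traces to the unrelated-subset
  covariate projection: the fitted coefficients carry sampling noise from
  a few hundred unrelateds into every residual as structure the transform
  does not model.

REML uses the single-random-effect spectral profile: with
$K = U\,\mathrm{diag}(\xi)\,U'$, the restricted likelihood is a
one-dimensional function of $\delta = \sigma^2_e/\sigma^2_g$, scanned on
a 101-point log grid over $[10^{-5}, 10^5]$ and refined by Brent search;
$\hat h^2 = 1/(1+\hat\delta)$. A flat spectrum (kinship numerically
proportional to the identity) is unidentifiable and reported as
$\hat h^2 = 0$ with a warning.

## Quadratic-form tails

`quadform_pvalue()` computes $P(\sum_k \lambda_k \chi^2_1 > q)$ by
numerical inversion of the characteristic function (midpoint rule on the
standard one-sided integral). The discretization step is set from a
Chernoff bound on the mixture tail so the aliasing error is below the
accuracy target (1e-6 absolute by default), and summation stops when
either the integrand envelope or an Abel-summation bound on the
oscillating tail is negligible. A single weight is a scaled
$\chi^2_1$ and handled in closed form. Failures and the far tail (below
ten times the accuracy target, where inversion returns noise) fall back
to the four-moment (Liu-type, kurtosis-matched) chi-square approximation
and are flagged in the result. The SKAT-O min-p integral substitutes
$x = t^2$ to remove the $\chi^2_1$ density singularity and uses fixed
Gauss–Legendre panels on $t \in [0, 8.5]$; tests check the panel
quadrature against adaptive integration on integrands of the same form
and bracket every SKAT-O p-value between the grid minimum and its
Bonferroni multiple.

## The simulator

`simulate_study_base()` + `simulate_replicate()` emulate a
workshop-style simulated family study so that every stage is testable without any data download:

* **Pedigrees**: 85 identical 3-generation families of 10 (two founders,
  four offspring, four grandchildren), 850 individuals. Each grandchild
  has one listed parent; the other is an unlisted married-in individual
  whose transmitted allele is drawn from the founder MAF — this keeps
  exactly two listed founders per family while remaining Mendelian.
* **Genotypes**: gene dropping, variants independent (no LD). 1,000 null
  gene regions of 20–40 variants; founder MAFs 80% rare
  (U(0.0005, 0.01)) and 20% common (U(0.01, 0.5)), so both the kinship
  MAF filter and the rare-variant weighting are exercised. A background
  panel of 15,000 common variants (U(0.05, 0.5)) placed between regions
  stands in for the genome-wide panel practitioners use for kinship
  estimation; kinship quality is governed by the ratio $n/M$ and a
  regions-only panel would be far too small.
* **Phenotype**: $y = 110 + 4\,\mathrm{sex} + 0.5\,\mathrm{age} +
  0.005\,\mathrm{age}^2 - 8\,\mathrm{med} + 3\,\mathrm{smoke} + g + e$
  with $g \sim N(0,\, h^2\sigma^2\, 2\Phi)$ ($\Phi$ the pedigree kinship,
  $h^2 = 0.3$), $e \sim N(0, (1-h^2)\sigma^2)$, $\sigma^2 = 225$ —
  adjusted-SBP-like numbers in mmHg; only the ratios matter to the
  method, and all are configurable. Age is U(20, 80), medication
  Bern(0.3), smoking Bern(0.25).
* **Causal gene** (power studies): 10 variants with founder MAF $\le$
  0.05 in the last gene, effect $\beta_j = 3\,|\log_{10}\mathrm{MAF}_j|$
  with 80% positive signs. The true generating model of the original
  workshop data is not public, so power magnitudes are design-dependent;
  the harness therefore checks direction (power $\gg$ type-I error,
  monotone in $\alpha$) rather than specific values.
* **Study structure**: genotypes, kinship and regions are fixed across
  the 100 phenotype replicates of a study — the structure of
  workshop-simulated data — which also lets `gls_skat_study()` cache the
  kinship spectrum and rotated genotypes; a test pins this fast path to
  the plain per-replicate pipeline.

What the simulator does *not* emulate: linkage disequilibrium,
genotyping error, missingness, ascertainment, X chromosome, and realistic
site-frequency spectra beyond the two-block mixture. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to those real-data features.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `kinship_maf_min` | 0.01 | folded-MAF filter for kinship estimation only; region tests never filter |
| `unrelated_threshold` | 0.10 | kinship cut for the greedy unrelated subset (separates 3rd-degree relatives from GRM noise) |
| `twin_concordance` | 0.99 | genotype concordance above which a pair is treated as identical twins; detection scans at most 1,000 variants (twin duplicates are exact, so a subsample suffices) |
| `flank` | 20,000 bp | region extension beyond the transcript span, both sides, clipped at position 1 |
| `weights` | `"mb"` | Madsen–Browning $1/\sqrt{p(1-p)}$; `"beta"` gives Beta(1, 25) density weights |
| `rho_grid` | 8 points | SKAT-O mixing grid |
| `mode` / `h2` | `"heritability"` / REML | covariance model of the transform (see above) |
| ridge | 1e-8 → 1e-4 | escalating diagonal added when the Cholesky pivot vanishes; recorded in the fit |

## Numerical and degenerate-input policy

* Monomorphic variants: dropped (with a count) before kinship; dropped
  per region before testing (their weight is undefined); an all-empty
  region is retained in the output, flagged, with NA p-values.
* Single-variant regions: SKAT, burden and SKAT-O coincide; reported as
  such without the min-p integral.
* Coordinates are 1-based inclusive throughout; `chr` prefixes are
  stripped on both sides of variant-region matching. Strand is ignored —
  with symmetric flanks, up/downstream orientation does not matter.
* Multiallelic VCF records are rejected (counted), not split; missing
  genotypes are an error — the simulator emits complete data and the
  pipeline assumes it.
* Ties in the greedy unrelated selection break by input order, making
  selection deterministic.
* All simulation entry points take an explicit integer seed; a study's
  replicate $r$ uses `seed + r`.

## Problem sizes

The shipped acceptance study uses 100 phenotype replicates × 1,000 null
gene regions (~30,000 region variants plus the 15,000-variant background
panel, n = 850), i.e. 100,000 pooled region tests per study; the power
study uses 150 null genes plus the causal gene at the same sample size.
Unit and property tests run on 10–60 family subsets of the same
generator.

## Known limitations

* No LD means the kinship panel is effectively larger per variant than a
  real LD-structured panel of the same size; real studies should use as
  dense a panel as available and prefer the heritability-weighted mode.
* Covariate coefficients come from a few hundred unrelateds, so their
  sampling error propagates into the residuals of everyone; with very
  small unrelated subsets this adds structured noise the transform does
  not model.
* The score-test variance $\hat\sigma^2$ is estimated globally; no
  small-sample moment corrections are applied (n ≈ 850 is comfortably
  large; below ~100 individuals consider permutation checks).
* Binary traits and within-test covariates are out of scope: covariates
  are handled once, upstream, by residualization.
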