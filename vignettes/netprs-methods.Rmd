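---
title: "Network-annotated polygenic risk scores: model, tuning, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-annotated polygenic risk scores: model, tuning, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`netprs` builds polygenic risk scores (PRS) for a quantitative target trait
from GWAS summary statistics and a population-matched reference panel for
linkage disequilibrium (LD). Its distinguishing feature is an
annotation-weighted L1 penalty: SNP-specific penalty weights are derived
from the topology of a signed genotype–phenotype bipartite network (GPN)
spanning traits genetically correlated with the target, so that candidate
pleiotropic variants — SNPs strongly connected to many relevant traits — are
shrunk less aggressively than unsupported ones.

The pipeline has five stages, each usable on its own:

1. **Input handling** (`read_sumstats()`, `harmonize()`, `compute_ld()`):
   read and allele-align per-trait summary statistics against a PLINK
   bed/bim/fam panel; estimate blockwise LD and LD scores.
2. **Relevant-trait selection** (`cross_trait_ldsc()`,
   `select_relevant_traits()`): cross-trait LD score regression with a
   Bonferroni rule on the genetic-covariance p-value.
3. **Network annotation** (`build_gpn()`, `degree_centrality()`,
   `betweenness_centrality()`, `normalize_annotation()`).
4. **Model fitting and tuning** (`fit_netprs()`, `tune_grid()`,
   `score_prs()`).
5. **Summary-statistic-only evaluation** (`subsample_sumstats()`,
   `approx_r2()`, `evaluate_repeated()`), for the common situation where no
   individual-level validation cohort exists.

A multi-trait phenotype simulator (`sim_config()`, `simulate_traits()`,
`marginal_gwas()`) generates every input the pipeline needs, so the whole
method is testable end to end without external data.

# The model

## Penalized regression on summary statistics

With the trait and every genotype standardized to mean 0 and variance 1,
the effect sizes minimize

$$f(\beta) \;=\; \tfrac{1}{2}\,\beta^\top R\,\beta \;-\;
\tilde\beta^\top \beta \;+\; \sum_{m=1}^M \tau_m\,|\beta_m|,
\qquad
\tau_m = \lambda_0 + \frac{\lambda_1}{s_m},$$

which is the summary-statistic form of penalized least squares:
$\tilde\beta_m = z_m/\sqrt{n_m}$ is the standardized marginal effect
recoverable from any summary table, and $R$ is the SNP correlation
(LD) matrix estimated from the reference panel. $\lambda_0$ is a baseline
penalty on all SNPs; $\lambda_1/s_m$ adds shrinkage inversely proportional
to the normalized network annotation $s_m \in (0, 1]$, so well-connected
(pleiotropic) SNPs are penalized close to the baseline only. We use the
reciprocal form because the penalty's subgradient is the natural reading of
the model — a larger annotation must mean a *smaller* penalty — but
`penalty_form = "times"` preserves the alternative
$\tau_m = \lambda_0 + \lambda_1 s_m$ for sensitivity analyses.

Minimization is by cyclic coordinate descent with soft-thresholding:

$$\hat\beta_m \leftarrow
S\Big(\tilde\beta_m - \sum_{l \ne m} \hat\rho_{lm}\hat\beta_l,\ \tau_m\Big),
\qquad S(w, \tau) = \operatorname{sign}(w)\,(|w| - \tau)_+ .$$

Coordinates are visited in genomic order; the LD sum runs within the SNP's
block only (cross-block LD is exactly zero by construction). Each sweep
records the objective; with positive-semidefinite blocks every coordinate
step is an exact univariate minimization, so the trace is non-increasing —
the test suite asserts this on every fit it makes, and checks the solution
against an independent proximal-gradient solver.

## Network annotations

For each relevant trait $k$ and SNP $m$ the edge weight is the signed
1-df chi-square quantile
$T_{mk} = \operatorname{sign}(\hat\beta_{mk})\,
F^{-1}_{\chi^2_1}(1 - p_{mk})$, which recovers $z_{mk}^2$ with the sign of
the effect. Two centralities summarize a SNP's position in this bipartite
network:

* **degree** $d_m = \sum_k |T_{mk}|$ — aggregate association strength. The
  absolute value is deliberate: a signed sum would let opposing effect
  directions cancel, which contradicts the interpretation of high-degree
  SNPs as pleiotropic (a signed mode is available behind
  `signed = TRUE` for sensitivity work);
* **approximate betweenness** $b_m = \sum_{k<s}
  \sigma_{ks}(m)/\max(\sigma_{ks}, 1)$ on the binarized graph
  (edge iff $p_{mk} < \alpha$, default $\alpha = 0.05$): every shortest
  path between two traits in a bipartite graph has length 2, so
  $\sigma_{ks}$ counts the SNPs adjacent to both traits and each connected
  pair distributes one unit of mass over its connectors. Unweighted
  length-2 paths are the literal bipartite reading; weighted shortest paths
  would need an edge-length convention the association strengths do not
  supply.

Raw centralities are normalized by their maximum and floored at
$\varepsilon$ (default 0.01), since the reciprocal penalty is undefined at
$s_m = 0$. When every raw score is zero the annotation carries no
information and all weights are set to 1, reducing the model to a uniform
lasso — the same happens when no candidate trait passes selection.

## Relevant-trait selection

Cross-trait LD score regression regresses $z_{1j} z_{2j}$ on
$\sqrt{N_1 N_2}\,\ell_j / M$ with a free intercept. The slope estimates the
genetic covariance $\rho_g$; the intercept absorbs phenotypic correlation
among overlapping samples, which is why no overlap bookkeeping is needed.
We use unweighted least squares by default (the moment condition itself;
an optional $1/\ell_j$ weighting flag exists), a delete-one block jackknife
over 200 contiguous SNP blocks for standard errors, and a normal
approximation for p-values; the intercept is always free. Candidates pass
at $p < \alpha/K$. These are deliberate, transparent simplifications of
the full LDSC machinery (no iterated regression weights, no partitioned
heritability).

# Tuning and evaluation without individual-level data

The statistic $X^\top y = \sqrt{n}\,z$ per SNP can be partitioned into
pseudo training/validation/test sets by drawing the training part from its
conditional distribution under random subsampling of individuals:

$$X_{tr}^\top y_{tr} \,\big|\, X^\top y \;\sim\;
\mathcal N\!\Big(\tfrac{n}{N}\,X^\top y,\ \tfrac{n(N-n)}{N}\,\Sigma\Big),$$

with $\Sigma$ the per-observation covariance of $x_j y$, approximated
blockwise by the reference-panel LD matrix with unit diagonal on the
standardized scale. The test part is drawn the same way from the
remainder and the validation part is the residual, so the three parts sum
to the full statistic exactly. The mean scaling $n/N$ is forced by
$\mathbb E[X_{tr}^\top y_{tr}]$ under random subsampling and the variance
$n(N-n)/N$ is the finite-population (hypergeometric-style) one; a literal
$(N-n)/N$ scaling of both moments is selectable via `scaling = "literal"`
for comparison, and a diagonal-only $\Sigma$ fast mode via
`sigma_mode = "diagonal"`. The sampler's moments are verified against
Monte-Carlo expectations in the test suite.

Prediction accuracy on a partition is approximated by

$$R^2 \;\approx\; \frac{\big[\tfrac{1}{n_{ev}}\sum_m w_m\,
(X^{(ev)\top}_m y^{(ev)})\big]^2}
{\big[N \max_m \widehat{SE}_m^2\,\hat\sigma_m^2\big]\,
\big[\sum_m w_m^2 \hat\sigma_m^2\big]},$$

where $\hat\sigma_m^2$ is a MAF-based estimate of $\mathbb E[X_m^2]$
($2f(1-f)$ on the allelic scale, 1 on the standardized scale) and the
denominator's first factor proxies the phenotypic variance. Two properties
of this estimator matter in practice: it is scale-invariant in $w$, and it
omits the LD cross-terms from the PRS-variance proxy, so its *level* can
exceed 1 for strongly correlated weights even though its *ranking* of
candidate models tracks individual-level validation — which is all tuning
needs, and what the concordance tests assert.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window` | 250 SNPs | LD block extent (per chromosome); also the clumping radius |
| `shrinkage` | 0.1 | off-diagonal LD shrinkage; guarantees strictly PD blocks and a convex objective |
| `edge_alpha` | 0.05 | p-value threshold of the binarized GPN topology |
| `floor` | 0.01 | lower floor of the normalized annotation $s_m$ |
| `lambda0` grid | fractions 0.8–0.05 of $\max_m|\tilde\beta_m|$ | baseline penalty path (warm-started, decreasing) |
| `lambda1` grid | $\{0, 0.5, 1, 2\} \times \min(s)\,\lambda_0^{ref}$ | annotation penalty expressed through the extra shrinkage on the weakest-annotated SNP; 0 (plain lasso) always included |
| `tol` | 1e-4 | max absolute coordinate change per sweep (standardized scale) |
| `alpha` | 0.05 | family-wise level of the Bonferroni trait-selection rule |

Tuning maximizes validation $R^2$ over the $(\lambda_0, \lambda_1)$ grid;
ties break toward the sparser model (larger $\lambda_0$, then larger
$\lambda_1$). Per-SNP sample sizes may differ; the solver uses per-SNP $n$
in $\tilde\beta$ and the median $n$ wherever a scalar is required.

# The simulator and what it does (not) emulate

Phenotypes follow the matrix-normal model $Y = XB + E$: the
$\lceil pM \rceil$ causal rows of $B$ are i.i.d. multivariate normal with
cross-trait covariance $\Sigma_g / (pM)$,
$\Sigma_g[k,s] = \rho_g^{ks}\sqrt{h_k^2 h_s^2}$, and noise rows have
covariance $\Sigma_e$ (diagonal $1 - h_k^2$, off-diagonal $\rho_e$,
default 0.1). Genetic correlations are accepted as *correlations* and
converted to covariances internally — less error-prone than covariance
input. Heritability is defined on the standardized-genotype scale so the
realized $\mathrm{Var}(XB)/\mathrm{Var}(Y)$ is $h_k^2$ without rescaling.
Sample overlap is `none`, `partial` (the first $N_s$ rows of every trait's
cohort share one genotype draw; correlated noise applies to those rows
only — correlated noise between disjoint individuals would not be
meaningful), or `complete`.

Genotypes are Gaussian-copula Hardy–Weinberg draws: two latent haplotype
layers of blockwise AR(1) normals thresholded at the allele-frequency
quantile. `ld_rho` may be a range, in which case each block draws its own
AR(1) strength — heterogeneous LD is essential for LD score regression,
whose slope is unidentified when LD scores are (near-)constant, and the
LDSC recovery studies therefore use `ld_rho = c(0.1, 0.9)`. The MAFs and
per-block LD strengths define the simulated population and can be fixed
across draws (`maf`, `block_rho` arguments) to generate matched reference
panels and replicate cohorts.

What the generator does **not** emulate: coalescent genealogies, allele
frequency spectra, long-range LD, population structure or relatedness, and
binary traits on the liability scale. Passing tests therefore demonstrate
the statistical machinery under a clean polygenic architecture, not
robustness to those real-data complications.

# Study sizes used by the test suite

The package's own validation studies run at sizes chosen to keep a full
check-out under half an hour on a single core while leaving each estimate
well inside its statistical resolution:

* concordance of individual-level vs summary-statistic evaluation: the
  $2\times2\times2$ factorial over $K \in \{5, 10\}$,
  $h^2 \in \{0.2, 0.6\}$, $\rho_g \in \{0.1, 0.6\}$ with $N = 2000$,
  $M = 1000$, causal proportion 0.01, partial overlap
  ($N_s = 800$, i.e. 40% of the cohort), 5 replicate cohorts per setting;
* LD score regression recovery: trait pairs at $N = 5000$, $M = 2000$,
  infinitesimal architecture ($p = 1$, matching LDSC's polygenic
  assumption), 50 replicates each for the correlated and null cases. This
  study uses short (10-SNP) LD blocks with heterogeneous strengths and the
  $1/\ell$ regression weighting: the genetic-correlation ratio is a
  nonlinear function of three regression slopes, and its block-jackknife
  normal interval is only calibrated when the genome contains enough
  independent LD blocks ($\approx 200$ here) for the slopes to be in
  their normal regime — with long blocks (few independent loci) the
  jackknife demonstrably understates the ratio's spread;
* solver and centrality oracles: dozens to hundreds of random small
  instances against brute-force or generic-solver references.

At these sizes the cross-trait LDSC standard error is a large fraction of
$\rho_g$ whenever $M$ is only 1000, so the desk-scale end-to-end studies
pass all simulated candidate traits to the GPN (`trait_selection = "all"`)
rather than filtering through an underpowered Bonferroni test; the
selection rule itself is validated at the $M = 2000$, $N = 5000$ scale
where it has meaningful power.

# Numerical choices and degenerate inputs

* LD blocks: a sample correlation matrix is PSD by construction and
  shrinkage makes it strictly PD; eigenvalue clipping at zero is a
  round-off backstop only. The unit diagonal is restored after clipping.
* Missing dosages are mean-imputed before standardization (standard PRS
  practice); monomorphic SNPs are dropped at panel construction, and a
  constant (zero-variance) dosage column reaching LD estimation is an
  error rather than a silent NaN.
* P-values are clamped to $[10^{-300}, 1]$ before quantile inversion;
  entries at the clamp boundary use $z^2 = (\beta/SE)^2$ directly.
* $p = 1$ maps to edge weight 0; an all-zero annotation normalizes to
  $s \equiv 1$ (uniform lasso) rather than erroring.
* Convergence is the max absolute coordinate change (`tol`, default 1e-4);
  non-finite updates abort with a pointer to the offending SNP and a
  suggestion to increase LD shrinkage.
* The coordinate order follows genomic position; with strictly PD blocks
  the optimum is unique so order-dependence does not affect the solution.
* The genetic-correlation ratio $\hat\rho_g/\sqrt{\hat h_1^2 \hat h_2^2}$
  floors the heritability slopes at 0.01 inside the jackknife so
  leave-one-block replicates cannot blow the ratio up when a slope crosses
  zero.
* All simulator draws are seedable and bit-reproducible for a fixed seed;
  replicate cohorts share population parameters (MAFs, per-block LD) but
  not sampling noise.

# Known limitations

* Cross-block LD is zero by construction; very long-range LD (e.g. within
  extended haplotypes) is not represented, and the within-block sum is an
  approximation to the full-genome sum of the exact model.
* The summary-statistic $R^2$ approximation omits LD terms in the
  PRS-variance proxy; its level is only comparable across models, not an
  unbiased estimate of predictive accuracy.
* No binary-trait (liability-scale) modeling, no covariate adjustment, no
  multi-ancestry LD, and no VCF ingestion.
* The LDSC component is a transparent subset of the full tool: no
  regression-weight iteration, no partitioned heritability, no constrained
  intercept.
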