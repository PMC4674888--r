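---
title: "Differential PPI network inference: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential PPI network inference: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppin)
```

## The model

dppin infers, per sample condition, a protein association network constrained
to a candidate protein–protein interaction (PPI) graph. For target protein
$i$ with candidate interactors $j \in N(i)$ (its $M_i$ graph neighbors), the
linear association model is

$$x_i(n) = \sum_{j \in N(i)} \alpha_{ij}\, x_j(n) + \omega_i(n),$$

where $x_i(n)$ is the expression of protein $i$ in sample $n$,
$\alpha_{ij}$ is the association (combination) strength, and $\omega_i$ is
Gaussian noise. Under Gaussian noise the maximum-likelihood estimate of the
$\alpha_{ij}$ is ordinary least squares, so each row of the coefficient
matrix is an independent no-intercept regression of the target on its
interactors.

Each condition $k$ (three post-stroke time points in the motivating study)
and the control yield coefficient matrices $A_{S_k}$ and $A_N$. Their
elementwise difference $D^k = A_{S_k} - A_N$ (absent edges count as zero) is
the differential network, and each protein is scored by its rewiring
statistic

$$\mathrm{SRV}_i^k = \sum_j |d^k_{ij}|,$$

large values flagging proteins whose association pattern changed most
between condition and control. Proteins passing a significance screen on the
SRV are ranked into a biomarker table carrying raw group mean intensities
and $\log_2$ fold changes.

## Estimation pipeline and its tunables

1. **Pool selection** (`anova_screen`): a classical one-way fixed-effects
   ANOVA per gene across all sample groups, on `log2(x + 1)` intensities
   (variance stabilization; fold changes are always computed from raw
   means). Default `alpha_screen = 0.05` with Benjamini–Hochberg
   correction; both are configuration keys, and a raw-p variant and a
   per-time-point screen (`groups =`) are selectable, because the source
   study states the ANOVA but neither its threshold nor its scope.
2. **Per-target fit** (`fit_target`): expression is standardized per gene
   *within* the condition, and the no-intercept OLS/ML fit runs on that
   scale. The model has no intercept and standardization makes that exact;
   it also makes the marginal-correlation ordering below scale-free.
3. **Model-order selection** (`aic_select`): candidates enter in decreasing
   $|$marginal correlation with the target$|$ (deterministic lexicographic
   tie-break) and the order $m$ minimizing
   $\mathrm{AIC}(m) = n\ln(\mathrm{RSS}_m/n) + 2m$ along this greedy path is
   kept, $m = 0$ always admissible. A greedy path rather than exhaustive
   subset search is used because with ~23 samples per group hub proteins can
   have more candidate interactors than samples; `max_order` defaults to
   $n - 3$ so the subsequent t-test keeps at least one residual degree of
   freedom.
4. **Edge pruning** (`prune_by_ttest`): edges with two-sided
   $p > \alpha_{\mathrm{edge}}$ (default 0.05) on $t = \hat\alpha/\mathrm{SE}$,
   $df = n - m$, are removed and the model is refit once on the survivors.
   Refit-once is the default; iterated prune/refit until all survivors are
   significant is available (`iterate_prune = TRUE`). After a single refit a
   surviving edge's p-value can drift slightly above the threshold; it is
   reported as-is.
5. **Scale of the assembled matrices**: fitted coefficients are mapped back
   to the raw expression scale
   ($\hat\alpha_{ij}^{\mathrm{raw}} = \hat\alpha_{ij}^{\mathrm{std}}\, s_i / s_j$
   with the condition's own gene standard deviations). This is deliberate:
   each condition standardizes with *its own* variances, so differencing
   standardized coefficients would confound genuine rewiring with
   per-condition variance changes; on the raw scale the difference matrix
   compares like with like, which is also the scale on which the association
   model is written. $t$ statistics and p-values are scale-invariant, so
   pruning is unaffected.
6. **SRV significance** (`srv_pvalues`): the source study screens proteins
   by an SRV p-value without describing how it was obtained. The package
   uses a two-group label permutation: condition and control samples are
   pooled, labels reshuffled $B$ times preserving group sizes, both networks
   refit, and $p_i = (1 + \#\{b: \mathrm{SRV}_i^{(b)} \ge \mathrm{SRV}_i\})/(B+1)$.
   Defaults: $B = 200$, screen threshold $0.01$ inclusive. $B$ must resolve
   the threshold ($1/(B+1) \le$ threshold) or the call errors. The control
   network is fitted once and shared across the time-point comparisons;
   per-time-point refitting is possible by calling the stages directly.
7. **SRV sign convention**: the row sum is taken over $|d_{ij}|$. A literal
   signed sum could cancel opposite rewiring on the same row, and the
   published per-protein scores are all positive; the signed variant remains
   available (`srv(diff, abs = FALSE)`).

## The synthetic-data generator

`generate_truth` draws an undirected support graph (pair probability
`edge_density`), assigns each directed coefficient a value uniform on
$\pm[0.2, 0.6]$, and rescales the control matrix to spectral radius at most
0.8 so the simultaneous system is well-defined. `simulate_expression` draws
$w \sim N(0, \sigma^2 I)$ per sample and solves $x = (I - A)^{-1} w$
exactly, then shifts by `base_mean` to positive intensities (clamping, which
the defaults never trigger, is logged). The sample covariance therefore
converges to $(I-A)^{-1}\sigma^2(I-A)^{-\top}$, which several tests exploit
as a closed-form oracle.

Rewiring: each condition perturbs `n_perturbed` nodes sampled among
*connected* nodes (an isolated node cannot change the matrix), shifting
every coefficient incident to them by exactly `effect_size` with random
sign, redrawing signs if the perturbed matrix approaches instability.
Decoy candidate edges (`make_candidate_edges`) are sampled from non-edges
and carry a `source` annotation that only scoring harnesses read.

Because the linear system differs across conditions only in covariance, a
generator emulating *only* that structure would be emptied by the
mean-based ANOVA pool selection. Each condition therefore also receives
per-gene differential mean offsets (magnitude uniform 2–4 $\sigma$, random
sign, `de_shift`): the simulated genes emulate the differential pool the
screen retains in the real study. Group size defaults to 23 per group,
matching the study design. Calibration and power harnesses that target the
permutation machinery set `de_shift = c(0, 0)` so the no-rewiring null is
exactly exchangeable.

What the generator does **not** emulate: probe-level microarray artifacts,
background correction, batch effects, heavy-tailed or heteroskedastic
noise, and mean–variance coupling. Passing tests therefore demonstrate the
estimation machinery under the model's own assumptions, not robustness to
real microarray pathologies.

## What the per-row regression estimates

A point that matters for interpreting benchmarks: when data are generated
by the simultaneous system $x = (I-A)^{-1} w$, the noise $\omega_i$ is
correlated with the regressors (every gene feeds back into every other
through the graph), so per-row OLS converges to the *best linear predictor*
of $x_i$ given its interactors — not to the structural row of $A$. The two
coincide only as the feedback (spectral radius) becomes negligible. With
coefficients drawn on $\pm[0.2, 0.6]$ the population-level correlation
between best-linear-predictor rows and structural rows is typically around
0.8. The package's consistency tests therefore check convergence to the
closed-form best linear predictor (computable exactly from
$(I-A)^{-1}(I-A)^{-\top}$), while benchmark reports also state the
correlation with the structural coefficients for transparency. For the same
reason, a rewiring whose coefficient shifts nearly cancel in the covariance
is invisible to *any* covariance-based method; a minority of random-sign
perturbation draws are of this kind, which bounds attainable detection
power below 1 regardless of sample size.

## Numerical choices

- RSS values along the AIC path are floored at $10^{-12}\cdot\mathrm{TSS}$
  before the logarithm: numerically-zero residuals at different orders then
  tie and the $2m$ penalty resolves the tie toward the smaller model
  (otherwise float noise at $10^{-28}$ vs $10^{-30}$ would dominate).
- Collinear design columns are dropped deterministically in selection-path
  order (decreasing $|$correlation$|$, lexicographic ties), with a message.
- Zero-variance (degenerate) genes within a condition are excluded as
  predictors and keep an all-zero coefficient row as targets.
- An edge fitted with zero residual variance gets $t = \pm\infty$, $p = 0$
  (retained); a zero coefficient with zero SE gets $t = 0$, $p = 1$
  (pruned).
- Permutation p-values use the add-one estimator, so $p \ge 1/(B+1) > 0$.
- All stochastic stages (generator, permutations) take explicit seeds and
  restore the caller's RNG state.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run on deliberately small
instances chosen to exercise every stage while keeping a full run in the
minutes range: pools of 8–40 genes, 23–500 samples per group, $B = 200$
permutations, 50–200 Monte-Carlo repetitions per calibration claim. The
pipeline itself has no such limits; cost grows roughly as
$B \times M \times$ (per-target OLS at the selected order).

## Known limitations

- Rows are estimated independently; no symmetry or joint likelihood across
  rows, and no sparse-penalized alternative.
- The permutation null refits both networks per draw; with thousands of
  pool genes this is the dominant cost.
- SRV p-values are raw (the study screens on raw p); no multiplicity
  correction over proteins is applied.
- The best-linear-predictor/structural-coefficient gap described above is
  inherent to fitting simultaneous-system data with per-row regressions —
  as in the source method — and should be kept in mind when interpreting
  coefficient magnitudes as physical interaction strengths.
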