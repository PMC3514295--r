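---
title: "Clade models of codon evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade models of codon evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clademodels)
```

# The problem

After a gene duplication, selective constraint can change in complex ways:
a subset of codon sites may evolve under different dN/dS ratios (ω) in
different parts of the gene tree — between paralog clades, between lakes
or lineages within a clade, or between duplicates and single-copy
orthologs. Branch-site tests ask a narrow question (is ω > 1 on a
prespecified branch at some sites?); clade models ask a broader one: does
a class of sites evolve under *divergent* constraint between prespecified
tree partitions, whether or not either side exceeds 1?

`clademodels` implements the full ladder of codon site-class mixture
models used in this kind of analysis — M0, M1a, M2a_rel, M3, branch
models, branch-site model A with its null, and clade models C and D with
two *or more* tree partitions (the multi-clade extension) — together with
maximum-likelihood fitting, nested likelihood ratio tests (LRTs), AIC
weighting, empirical-Bayes identification of divergently evolving codons,
per-branch dN/dS for synonymous-saturation checks, an exact codon
simulator with known site-class labels, and a simulation-based calibration
study of the multi-clade LRT's null distribution.

# The codon model

All models share a Goldman–Yang style 61-state codon rate matrix over the
universal genetic code (stops excluded). For codons $i \ne j$:

$$q_{ij} = \begin{cases}
0 & \text{more than one nucleotide differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases}$$

with $\pi$ the codon equilibrium frequencies (equal 1/61, F3x4 computed
from position-specific nucleotide frequencies pooled over sequences, or
custom), $\kappa$ the transition/transversion rate ratio, and $\omega$
the dN/dS ratio. The matrix is reversible, so transition probabilities
$P(t) = e^{Qt}$ are computed exactly by symmetric eigendecomposition.

A *site-class model* is a finite mixture over classes $k$ with
proportions $p_k$, each class carrying one ω per tree *partition* (a
prespecified set of branches). In clade model C the first class is
purifying ($0 < \omega_0 < 1$, all branches), the second neutral
($\omega_1 = 1$), and the third *divergent*: a separately estimated
$\omega$ for every partition. Clade model D frees all classes; M2a_rel is
the partition-free null (one tree-wide ω in the third class); M1a drops
the third class entirely. Branch-site model A has four classes with
derived proportions $p_0, p_1, p_0p_2/(1-p_2), p_1p_2/(1-p_2)$ and a
foreground-only $\omega_2 \ge 1$; its null fixes $\omega_2 = 1$.

## Branch-length units and rate scaling

Branch lengths are expected substitutions per codon *averaged over site
classes*. One global divisor normalizes all class/partition matrices so
the mixture-averaged mean rate equals 1, with each partition weighted by
its share of total tree length — so a branch's length is measured under
the ω set that actually applies to it. Because that share depends on the
branch lengths themselves, the scale factor is recomputed at every
likelihood evaluation (and enters the analytic gradient through the chain
rule). The simulator uses the identical convention, which keeps simulated
total tree length and estimated branch lengths commensurable. We do not
attempt bit-parity with other implementations' internal scaling; the
convention is self-consistent and tested as such (fits of the generating
model to large self-simulations recover the generating branch lengths and
total tree length).

## Likelihood and its gradient

The mixture log-likelihood is
$\ln L = \sum_{\text{sites}} \ln \sum_k p_k L(\text{site} \mid k)$, with
per-class site likelihoods from Felsenstein pruning over distinct site
patterns (gaps and ambiguous codons contribute all-ones partials, i.e.
missing data, rather than column deletion — this preserves the codon
accounting of the input alignment; readers can mask instead). Per-pattern
log-scaling guards against underflow.

Fitting maximizes over transformed parameters: log branch lengths
(floored at $10^{-8}$), log κ, log or logit ω depending on each
parameter's constraint tag, and stick-breaking logits for proportions,
under L-BFGS-B. The gradient with respect to *all* branch lengths is
computed analytically in one inside/outside sweep (the derivative of
$e^{Qs}$ along an edge is $Qe^{Qs}$, and scale factors cancel in the
per-edge ratio), including the term from the global scale factor's
dependence on branch lengths; the few selection parameters use central
finite differences. Eigensystems are cached between evaluations. Each
model is fitted from several starting points with ω and κ perturbed
(defaults: ω starts 0.1 / 1.0 / 2.0, κ starts 2 / 4, seeded jitter on
branch lengths), and non-converged restarts are reported, never silently
dropped. Convergence uses the optimizer's function-change tolerance
(`factr = 1e7`, i.e. ~1e-9 relative) with up to 2000 iterations.

## Tests between models

LRTs compare nested pairs by $2\Delta\ln L$ against $\chi^2_d$ with $d$
the number of extra free parameters; for the boundary branch-site null a
50:50 mixture of 0 and $\chi^2_1$ is available. Free parameters are
counted as branch lengths + κ + free selection parameters; F3x4
frequencies are not counted, which reproduces the conventional df gaps of
1 / 2 / 3 / 4 across the ladder. Nesting is verified by introspection (a
null must be reachable from its alternative by equality constraints;
partition schemes must coarsen). Because LRTs only compare nested pairs,
AIC with Akaike weights conveys relative fit across the whole ladder. No
multiple-testing correction is applied across the ladder's tests — P
values are reported raw, and users should treat them accordingly.

Site-level inference is plug-in empirical Bayes: at the MLEs, the
posterior that a site belongs to class $k$ is
$p_k L(\text{site}|k) / \sum_j p_j L(\text{site}|j)$, with sites flagged
when the divergent-class posterior exceeds a threshold (default 0.75).
This is the NEB form; a full hierarchical-prior BEB integration is out of
scope, and the recovery behaviour we test (most flagged sites are truly
divergent in simulations) is achieved by the plug-in form. At realistic
parameter settings the two approaches differ mainly in small samples.

Per-branch dN and dS derive from an M0 fit by splitting each branch's
substitution rate into synonymous and nonsynonymous flow
($\sum \pi_i q_{ij}$ over the respective single-step pairs) and dividing
by the corresponding proportions of mutational opportunity (the same
quantities at ω = 1). By construction dN/dS equals the fitted ω on every
branch; the point of the table is the saturation check that per-branch dS
stays well below 1.

# The simulator

`simulate_alignment()` draws each site's class from the mixture
proportions, the root codon from π, and evolves states tip-ward by
sampling from the same branch- and class-specific transition matrices the
likelihood uses (partition-specific ω inside the divergent class). Site
classes are drawn stochastically per site rather than in fixed-count
blocks, matching the mixture assumption of the models under test. True
class labels are returned alongside the alignment, so classification
accuracy can be scored. Determinism is per-seed, and replicate $r$ of a
batch uses `base_seed + r`, making any subset reproducible in isolation.

What the simulator emulates: codon substitution under the exact generating
mixture on a fixed tree. What it does not: indels, recombination or gene
conversion, among-site rate variation beyond the ω classes, selection on
codon usage, or alignment error. Tests passing on these simulations
therefore validate the estimator and test calibration under the model's
own assumptions, not robustness to real-data pathologies.

# The calibration study

The multi-clade LRT compares clade model C with three tree partitions
against a nested two-partition version; its null distribution should be
$\chi^2_1$ (one non-boundary equality constraint). The study conditions
are fixed by design: 100-replicate batches of 10 taxa × 500 codons
generated under two-partition CmC with $p = (0.5, 0.2, 0.3)$,
$\omega = (0, 1, 0.15 \mid 0.65)$, κ = 2, total tree length 3
substitutions per codon, equal codon frequencies; analysis fixes κ and π
at their generating values, estimating branch lengths and selection
parameters freely. Rejection counts are judged by an exact one-sided
binomial test against the nominal 5% and the empirical CDF by a one-sided
Kolmogorov–Smirnov statistic in the direction of the empirical
distribution falling below $\chi^2_1$ (the anticonservative direction),
using the classical tail approximation $p = e^{-2nD^2}$; the opposite
direction is also computed and reported.

The source study's tree is published only as a figure, so the bundled
tree is a symmetric 10-taxon topology with 17 equal-length branches
rescaled to total length 3. The "dashed" generating partition is the
clade of tips t5–t8 including its stem (7 edges); the three-partition
analysis scheme splits it into "dashed" ({t5, t6} plus their stem, 3
edges) and "dotted" (the remaining 4 edges). In the misspecification
analysis the terminal branch of tip t10 — truly background, ω = 0.15 — is
moved into the dashed partition, making its length-weighted divergent ω
$(3 \times 0.65 + 0.15)/4 \approx 0.52$ against the clean partition's
0.65; the study then tests dashed-vs-dotted divergence. These choices
reproduce the published ω-displacement arithmetic exactly. The *power* of
the misspecification test, however, depends on the branch-length
information content of the partitions, which cannot be recovered from a
figure: with equal branch lengths this design yields rejection rates near
the nominal level rather than the ~23% the original tree produced. We
report this as a known limitation rather than adjusting the tree toward
the published rate.

Default replicate counts in the test-suite versions of these experiments
are scaled (20–25 replicates for calibration, 12–15 for misspecification,
20 seeds for parameter recovery at 500 codons) so the whole suite runs in
tens of minutes on one core; `run_null_calibration()` and
`run_misspecification_study()` take `n_reps = 100` for full-scale runs.
The alternative model in each replicate is warm-started from the null
model's maximum; one quasi-Newton run from there reproduces multi-restart
results on this problem class (verified by re-running replicates with four
restarts at a tighter tolerance), and the null fit itself uses two
restarts.

# Numerical choices and degenerate inputs

* Transition-matrix entries are clamped at 0 against eigendecomposition
  roundoff; rows re-sum to 1 within 1e-10.
* Pattern compression is exact (identical columns share one pruning
  computation) and is tested against uncompressed evaluation.
* All-missing columns contribute likelihood 1; alignments of identical
  sequences drive branch lengths to the 1e-8 floor.
* Stop codons in input data are an error by default (`"mask"` treats them
  as missing); non-ACGT characters are skipped in F3x4 counting, never
  imputed.
* Proportions at simplex corners are kept strictly interior by the logit
  parameterization; ω constraint tags (`bounded01`, `positive`, `ge1`,
  `fixed`) are enforced at evaluation time.
* A clade's stem branch belongs to its partition by default
  (`include_stem = TRUE`), matching the convention that a duplication's
  daughter lineages carry their clade's regime from the duplication node.
* LRT statistics are clamped at 0 (a tiny negative value triggers a
  convergence warning instead of a spurious test result).
* In `M3`/`CmD`, class labels are not identifiable a priori; starting
  values spread the class ωs and restarts guard against label-swap
  optima.

# Known limitations

* The empirical-Bayes site table is plug-in (NEB), not fully Bayesian
  (BEB); posterior probabilities near the flagging threshold should be
  read with MLE uncertainty in mind.
* The scale-factor convention, while self-consistent, is not guaranteed
  to match other software's branch-length units parameter-for-parameter;
  ω, κ, proportions and all tests are unit-free and comparable.
* The misspecification study's rejection rate is tree-dependent (above);
  its ω-displacement predictions are not.
* Codon frequencies are treated as known (F3x4 plug-in or fixed), not as
  free parameters, mirroring standard practice; they are excluded from
  the free-parameter counts used in LRT df and AIC.
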