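---
title: "Detecting and testing ancient whole-genome duplications with wgdcompass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing ancient whole-genome duplications with wgdcompass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wgdcompass` turns two classical lines of evidence for ancient polyploidy —
peaks in Ks-age distributions and gene tree – species tree reconciliation —
into one statistically guarded workflow. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
bundled simulator does and does not emulate, and the numerical and design
choices a user or maintainer should know about.

## 1. The Ks engine

**Estimator.** Pairwise synonymous distance is computed with the NG86
counting estimator: per codon, each of the three positions contributes the
fraction of its three possible single-nucleotide changes that are synonymous
(changes to stop codons count as nonsynonymous); observed differences at
codons differing at several positions are averaged over all mutational
pathways, dropping pathways that pass through a stop codon (if every pathway
is blocked, all are used). The synonymous and nonsynonymous proportions are
corrected for multiple hits with the one-parameter Jukes–Cantor formula
`d = -(3/4) ln(1 - (4/3) p)`; a proportion at or beyond 3/4 lies outside the
correction's domain and flags the pair as saturated. A counting estimator
was chosen over a maximum-likelihood codon model deliberately: it is
dependency-free, exactly checkable against a brute-force pathway-enumeration
oracle (the test suite verifies agreement to 1e-12), and for the distances
that matter here (Ks below the ceiling) the two approaches differ far less
than the biological noise. Unequal-length pairs are aligned codon-wise
first (Needleman–Wunsch on amino acids, affine gaps, match 2 / mismatch -1 /
open -5 / extend -1); gapped codons are excluded from all counts.

**Node weighting.** Within a family of n genes all `choose(n,2)` pairs are
redundant descriptions of n-1 duplication events. Pairs are clustered by
average linkage on Ks and each inferred duplication node distributes total
weight 1 equally over the pairs it joins, so a family contributes weight
n-1 regardless of size. These weights follow every pair into the mixture
models as fractional observation counts, and the effective sample size
`sum(w)` is used in the BIC penalty so that penalty and weighted likelihood
stay on the same scale.

**Ceiling.** Pairs with Ks above a ceiling (default 5) or saturated are
dropped; the ceiling is configurable per analysis.

## 2. Peak calling

**Log-scale Gaussian mixtures.** Ks values are log-transformed and fitted
with weighted-EM Gaussian mixtures for k = 1..8 components; BIC selects k.
Each k runs six restarts — five k-means initializations plus one
quantile-spread start, with restart seeds derived from one user seed — and
EM stops at a relative log-likelihood change below 1e-8 or 500 iterations;
monotonicity of the log-likelihood is recorded at every iteration and
asserted in the tests. Components that collapse (responsibility mass below
1e-8 of the effective n) are pruned with a warning and the fit restarted at
the smaller k. Peak locations are reported as back-transformed component
medians `exp(m)` — the median is invariant under the log transform, the
mean is not.

**Exponential–lognormal variant.** For the focal-species analysis the
background of small-scale duplications is L-shaped on the Ks scale, so a
mixture of one exponential (anchored at Ks = 0) plus 1–5 lognormal
components is fitted by the same weighted EM with BIC selection.

**SiZer.** The mixture models overfit readily, so every candidate peak must
also pass a kernel significance check. For a grid of 20 log-spaced
bandwidths between 0.05 and 1.0 (ln-Ks units) and 101 locations, the
Gaussian-kernel density-derivative estimate and its pointwise normal
confidence interval (level 0.05, weighted effective sample size) label each
cell significantly increasing, significantly decreasing, not significant,
or sparse (local effective count below 5). A candidate peak is validated
when at some bandwidth h the nearest significant cells on its two sides
form an increasing-to-decreasing zero crossing that is local to the
candidate: crossing width at most 4h and crossing midpoint within h/2.
The centring requirement is the package's own formalization of "the peak is
verified by SiZer"; without it, a genuine mode anywhere in the distribution
would validate mixture components sitting on its shoulders, which is
exactly the overfitting artefact the check exists to catch. The intervals
are pointwise, so isolated false cells at the nominal rate are expected and
harmless — only structured crossings produce verdicts.

## 3. Substitution-rate correction

Comparing a paralog peak with ortholog divergence peaks is meaningful only
on a common rate scale. Two complementary schemes are implemented.

**Halved peaks on a Ks phylogram.** Branch lengths in Ks units are fitted
to the fixed species topology by non-negative least squares on the
tree-additivity equations, using the pairwise ortholog peak matrix
(KDE modes, Sheather–Jones bandwidth, bootstrap uncertainty) as distances.
On an additive matrix the recovery is exact; the residual norm is reported
and a warning raised when it exceeds 10% of the data norm. Pairwise
distances identify the two root-adjacent branch lengths only through their
sum, so a tiny balance row splits that sum evenly — placements onto those
two branches should be read accordingly. Each species' peak is then halved
(assuming duplicates evolve at similar rates after the event) and walked
from the tip rootward into the branch whose cumulative Ks interval contains
it. A value exactly on a node boundary is assigned rootward — under the
workflow's own logic, a peak exactly at a speciation is evidence for the
shared, older branch. Values past the root are flagged as root-stem
overflow and cannot be tested.

**Trio correction.** For focal species F, comparison species S and outgroup
O, the focal branch contribution is `b_F = (d_FS + d_FO - d_SO) / 2` and
the divergence re-expressed on the focal scale is `2 b_F`; the correction
is exact on additive inputs for arbitrary rate multipliers and is the
identity under a clock. Negative estimates (strong rate contrast plus
noise) are clamped to zero with a warning. For every divergence on the
focal root path, trios are enumerated nearest-outgroup-first (minimizing
saturation), ties broken alphabetically, truncated at 14, and averaged into
a consensus with a standard deviation. The deepest divergence of the tree
has no outgroup and is skipped — with the tree rooted at the study clade's
limit, events on the root stem are untestable by construction, matching
the hypothesis-placement rule above.

**Ranking.** A peak is placed between the two adjacent consensus
divergences; a peak within one consensus sd of a divergence is reported as
"at the speciation event". The package treats the two schemes as
independent lines of evidence: their branch assignments are unioned into
the hypothesis list, never averaged, and adjacent-branch conflicts are kept
as separate competing hypotheses for reconciliation to resolve.

## 4. The DL+WGD reconciliation model

**Model.** Gene families evolve along the species tree by a linear
birth–death process with per-branch duplication rate λ_b and loss rate μ_b;
a WGD mark on a branch retains each surviving lineage as two copies with
probability q; the number of ancestral lineages at the root is geometric
with parameter η on {1, 2, ...} (a family must have existed at the root);
each extant gene is observed with probability `1 - p_miss` of its species
(the missing-gene fractions of transcriptome assemblies). Gene-tree
uncertainty enters through each family's conditional clade distribution
(CCD): marginal clade frequencies and conditional split frequencies
tabulated from a topology sample after burn-in.

**Likelihood.** For a single lineage at a point of the species tree, let
W[γ] be the probability that it yields exactly the observed genes of clade
γ. Along a branch W obeys the ordinary differential equation

    dW[γ]/ds = (2 λ ε(s) − (λ + μ)) W[γ] + λ Σ_splits p(γ1,γ2|γ) W[γ1] W[γ2]

whose linear part is the single-surviving-lineage propagator G'(ε0, s) of
the birth–death generating function, with the extinction probability ε(s)
available in closed form. Speciation nodes combine the two child branches
over CCD splits (plus the one-side-extinct terms); a WGD mark applies
ε' = (1-q) ε + q ε² and the matching retention terms for W. At the root the
geometric prior is integrated analytically, amalgamating up to two observed
root subtrees, and the likelihood is conditioned on at least one observed
gene in each root-child clade — consistent with the family filter that
demands a common ancestor at the root. The per-branch ODE is integrated
with classical RK4, 10 steps per branch by default and extra steps for
stiff (high-rate) proposals; halving the step changes test log-likelihoods
by far less than 1e-4, and the whole dynamic program agrees with an
independent history-integral oracle (nested adaptive quadrature over
duplication times) to better than 1e-6 on all 3- and 4-taxon topologies
with up to two WGDs. The core is compiled (Rcpp) and reuses a parsed model
object across MCMC iterations.

Two consequences of the truncation at two root subtrees deserve mention.
Families whose observed genes descend from three or more distinct root
lineages cannot be represented by any binary gene tree with valid clades
and receive likelihood zero; such families are dropped with a warning
before sampling (simulated data can flag them exactly via
`n_root_subtrees()`). And the root split of a sampled gene tree is
reinterpreted as possibly separating two root lineages, which is what makes
root-origin paralog pairs testable at all.

**Priors and models.** Critical branch-specific model: log rates
x_b = log λ_b = log μ_b are Gaussian around a mean m with standard
deviation σ ~ Exponential(mean 0.1); the improper flat prior on the mean
branch rate is implemented as a flat prior on m over [-10, 3] to keep the
posterior proper. Relaxed model: per-branch (log λ_b, log μ_b) are
bivariate normal with per-coordinate mean prior Normal(0,1), correlation
Uniform(-1,1) and σ ~ Exponential(mean 1). η ~ Beta(3,1) (or held fixed,
e.g. at 0.75 for anchor-family runs); each retention rate q ~ Uniform(0,1).
The covariance structure across branches is taken as independent given the
hyperparameters — the natural reading of a branch-exchangeable prior.

**Sampler.** Adaptive Metropolis-within-Gibbs: per-branch single-site
random-walk updates (scales adapted to 44% acceptance), one global
translation move of the whole log-rate field together with its mean, and
one funnel move that rescales the residuals jointly with σ (the centred
hierarchical parameterization otherwise mixes σ very slowly when the data
are clock-like), each twice per sweep; logit random walks for η and each q;
conjugate or slice-sampling updates for the hyperparameters, which do not
touch the likelihood. Chains are bit-reproducible given a seed. Default
11000 iterations thinned by 10 with the first 10% discarded; the shorter
chains used in the test suite are sized so that every parameter's effective
sample size (Geyer initial-positive-sequence estimator) clears 200, the
usual adequacy bar.

**Hypothesis testing.** Each WGD hypothesis is judged by the Savage–Dickey
density ratio `K = p(q = 0 | data) / p(q = 0)` with prior density 1 at the
boundary; the posterior density at 0 is a reflection-corrected kernel
estimate (Sheather–Jones bandwidth) whose sensitivity to halving/doubling
the bandwidth is reported alongside. Verdicts: K < 0.1 strong evidence
against the no-WGD null, K < 10^(-1/2) substantial, K < 1 barely worth
mention, K ≥ 1 null supported. A posterior with no mass near zero is
floored at K = 1e-12 rather than reported as exactly zero.

**Per-pair placement.** For individual (anchor) pairs, stochastic
backtracking of a sliced version of the dynamic program yields, per
posterior draw, the event at which the pair diverged — a duplication on a
specific branch, a WGD retention, a speciation, or the root split — giving
a posterior distribution over branches that sums to 1.

## 5. The simulator

`sim_model()`/`simulate_family()` run the DL+WGD model forward with
Gillespie event-by-event sampling (event times are exact, which Ks emission
needs), label every surviving internal node speciation / duplication / wgd,
and record deleted (missing) genes. Ks values are rate-weighted path
lengths on the species tree — per-branch multipliers ρ_b generate the
lineage-rate heterogeneity that motivates the correction stage — times a
median-unbiased lognormal noise (σ = 0.1 by default). `emit_codon_pair()`
generates sequence pairs whose expected NG86 Ks equals the requested value
by construction (four-fold degenerate third positions under Jukes–Cantor;
amino-acid-changing moves confined to an alphabet that cannot create stop
codons). `perturb_tree_sample()` emulates posterior topology samples by
Poisson-many random NNI moves per tree.

What the simulator does *not* emulate: alignment error, codon-usage and
rate variation across sites and through time (corrected rates are treated
as constants — placements of very ancient events inherit that
approximation), hybridization and incomplete lineage sorting, and assembly
artefacts beyond uniform missingness. Passing tests therefore demonstrate
that each stage recovers what its own model family generates at realistic
sizes, not that real transcriptome data sets satisfy these assumptions.

One generator-specific artefact matters in practice: because every family
is conditioned to exist at the root, pairs coalescing at the root form an
artificially sharp Ks pile at exactly twice the root depth, where real data
smear family origins across deeper time. Analyses of simulated paranomes
should therefore set the Ks ceiling below twice the root-path Ks depth
(`ks_ceiling` in `run_pipeline()`), the same way real analyses cut the
saturation tail.

## 6. Study conditions used by the packaged tests

The reference scenario is a six-taxon tree of depth 1.3 time units with one
WGD planted halfway up the {A,B,C} stem, λ = μ = 0.2 events per gene per
time unit, η = 0.75, 20% missing genes, and 200 reconciled families —
small enough for a laptop, large enough that the Bayes-factor calibration
properties (few false strong verdicts under the null, high power at
q = 0.4, near-nominal credible-interval coverage) are expected to hold.
The rate-bias study uses three two-species clades plus an outgroup, a WGD
shared by two clades, and one clade at ρ = 0.3: raw comparison misplaces
the slow clade's peak tipward of the truth, while both correction schemes
recover the shared stem. Mixture and SiZer properties use n = 2000 pairs
per distribution. The problem sizes are stated here as the package's
reference conditions; all of them are plain arguments.

## 7. Known limitations

* Rates are constant along each branch and corrections treat them as
  constants through time.
* The root amalgamation truncates at two observed root subtrees; deeper
  forest-like families are excluded rather than modelled.
* Hypotheses on the root stem (and, for the phylogram, the split of the
  root-adjacent branch pair) are structurally untestable without extra
  outgroups.
* SiZer inference is pointwise, not simultaneous; its verdicts are gated by
  the crossing-locality rule rather than by family-wise error control.
* The likelihood engine supports at most 30 species and families of at
  most ~50 genes (bitmask clade representation; the family-size filter
  defaults to 50).
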