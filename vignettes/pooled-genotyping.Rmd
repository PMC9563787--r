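---
title: "Pooled SNP genotyping with combinatorial decoding and imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled SNP genotyping with combinatorial decoding and imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolgt)
library(dplyr)
```

## The problem

Genotyping a large cohort on SNP arrays is expensive, and the cost scales
with the number of arrays, not the number of markers. Group testing offers a
way out: mix the DNA of several individuals into pools, genotype the pools,
and reconstruct the individual genotypes from the overlap structure of the
pools. An array detects which alleles are present in the hybridized DNA, so
a pool of samples reports genotype 0 when every member is homozygous
reference, 2 when every member is homozygous alternate, and 1 as soon as
both alleles are present among its members.

`poolgt` implements this strategy end to end: the pooling design, the
combinatorial decoder, probabilistic genotype estimates for the cells the
decoder cannot resolve, a genotype-likelihood-aware imputation HMM to fill
the remaining gaps from a phased reference panel, and the evaluation metrics
to quantify how well the reconstruction worked. A synthetic-data generator
provides seeded populations with the statistical structure this experiment
assumes, so the entire pipeline runs and is tested without any external
data.

## The pooling design

The design is a square transversal instance of a nonadaptive overlapping
repeated block (NORB) scheme. A block of $n_B = q^2$ samples is arranged on
a $q \times q$ grid and assayed through $2q$ pools: the $q$ grid rows and
the $q$ grid columns. Every sample lies in exactly two pools (weight 2),
every pool holds $q$ samples (degree $q$), and two pools share at most one
sample (intersection 1). With the default $q = 4$ this gives 8 pools per 16
samples, a reduction factor $\rho = q/2 = 2$: half as many arrays as
samples.

Decoding starts from the pool pair $(r, c)$ of each cell. Two homozygous
pools determine the cell; a homozygous pool forces its genotype on the cell
regardless of the heterozygous partner; the pair $(1, 1)$ alone is
uninformative; and $(0, 2)$ is impossible without assay errors. On top of
this table, `decode_block()` propagates allele-presence constraints to a
fixpoint: a pool with genotype 1 detected both alleles, so some member must
supply REF and some member must supply ALT; when only one member can still
supply an allele, that member's candidate set shrinks. The result per cell
is a full call, a half-call (one known allele, written `./1` or `0/.` in
VCF), or a missing genotype. The propagation is implemented as generic
arc-consistency over all pools of the block rather than a list of special
cases, so every deduction that follows logically from the no-error
assumption is made; it can never contradict the truth under error-free
encoding, which the test suite checks by simulation.

A design-level consequence worth stating: a true heterozygote is never
fully decoded (only homozygous calls can be certain), and below the MAF
bound $\delta_{MAF} = d_0 G_1 / (2 n_B)$ — about 3.1% for $q = 4$ — blocks
rarely contain more than one carrier, so rare variants come out of pooling
almost fully genotyped or identified as carriers.

## Posterior genotype probabilities from block combinatorics

For the unresolved cells the block still carries information. All estimation
is keyed by $(\psi, r, c)$: the block pattern $\psi$ — the counts of row-
and column-pools per pool genotype — plus the cell's own pool pair. The
object of interest is the set of *valid layouts*: complete genotype
assignments of the block whose re-encoding reproduces the observation.

Three estimators are provided.

**Exact conditioning** (`posterior_exact()`). Under an i.i.d. per-cell prior
$\pi$, weight every valid layout by $\prod_i \pi_{g_i}$ and return the
normalized marginal of a cell at an $(r, c)$ intersection. This is the
reference oracle. It is computed without enumerating layouts explicitly: a
dynamic program sweeps the heterozygous rows of the canonical block,
enumerating per-row assignments ($\le 3^q$) and tracking per heterozygous
column which required alleles have been supplied (2 bits per column). The
worst pattern for $q = 4$ has tens of millions of valid layouts; the DP
handles it in milliseconds, so no Monte-Carlo fallback is needed (a seeded
Monte-Carlo conditioning routine, `mc_conditioning()`, is nevertheless
shipped as an independent cross-check and is held against the DP in the
acceptance tests).

**Marginal maximum likelihood** (`mmle_estimate()`). Maximizes
$L(\pi) = \sum_{\text{valid } x} \prod_k \pi_k^{n_k(x)}$ over the simplex
(optionally weighting layouts by their phased degeneracy $2^{n_1}$),
via Nelder-Mead on a softmax parametrization with a deterministic start at
the uniform simplex. Flat ridges occur (e.g. patterns that only constrain
$p_1 + p_2$); the tests therefore compare attained likelihood against a
dense grid search rather than arg-max coordinates.

**Self-consistent estimation** (`self_consistent_estimate()`), the
estimator actually tabulated for the pipeline. It is an EM-type iteration:
the E-step computes each valid layout's mixing proportion under the current
per-cell estimate $\tilde\pi$ (initialized at $(0.25, 0.5, 0.25)$, the
uniform distribution over *phased* allele pairs); the M-step re-estimates
genotype frequencies from the count-weighted layout expectations, restricted
to the undetermined cells — determined cells are fully known and are held
one-hot. The M-step then rescales by weights $w = (1, 2, 1)$, compensating
for heterozygote degeneracy (each unphased layout with $n_1$ heterozygotes
stands for $2^{n_1}$ phased micro-layouts), and divides by the previous
iterate before renormalizing. On convergence (L$\infty$ change below 1e-6,
at most 100 iterations, non-convergence flagged with a warning) a final
rescale by $1/w$ undoes the internal heterozygote upweighting, yielding
likelihoods on the uniform-prior scale that downstream imputation expects.

Two genuinely open design points deserve a note:

* *The division by the previous iterate.* Taken literally, the damped update
  $\tilde p_k' \propto w_k\, \tilde p_k^{(m)} / \tilde p_k^{(m-1)}$ has the
  fixed point $\pi_k^2 \propto w_k M_k(\pi)$, where $M$ is the M-step map.
  The undamped alternative $\tilde p_k' \propto w_k \tilde p_k^{(m)}$
  diverges to the degenerate simplex $(0, 1, 0)$ on single-free-cell
  patterns, so the damped form is also the sensible one; both are available
  via `estimator_config(damping =)`.
* *Conventions and the oracle.* On every $q = 4$ key the converged iterate
  (before the final $1/w$ rescale) tracks the exact-conditioning oracle
  under the phased prior $(0.25, 0.5, 0.25)$, and the compensated output
  tracks the oracle under the uniform prior $(1/3, 1/3, 1/3)$. The
  acceptance tests compare in these matched conventions and bound the
  maximum probability deviation by 0.05 (measured: about 0.016 internal /
  0.046 compensated, with identical best-guess genotypes throughout). The
  deviation is systematic, not a bug: the self-consistent fixed point is not
  exactly the one-shot conditional expectation, and shipping the oracle
  alongside keeps that gap measured rather than hidden.

`build_posterior_table()` enumerates every consistent $(\psi, r, c)$ key of
a design once (129 keys for $q = 4$, of which 37 are genuinely
undetermined), stores the estimates, and serializes them to JSON with
17 significant digits so tables reload bit-identically.
`attach_priors()` then turns a decoded study into GP/GL records: one-hot for
full calls, table lookups for the rest.

## Imputation: a GL-aware diploid Li-Stephens HMM

Residual missingness is imputed per sample against a phased reference panel
with a coalescent-style haplotype-copying HMM. Hidden states are ordered
pairs of template haplotypes — **all** $H$ panel haplotypes are templates,
with no subsetting and a single forward-backward pass per sample (no
iterative re-phasing). Transitions factorize per haplotype with a
per-interval switch probability
$\theta_j = 1 - \exp(-\rho\, d_j / H)$, where $d_j$ is the interval's
genetic distance in Morgans (from a genetic map, or a uniform 1 cM/Mb when
none is given) and $\rho$ (default $4 \times 10^4$, an effective-population-
size surrogate of roughly $4 N_e$ with $N_e = 10^4$) scales recombination.
Emissions integrate the sample's genotype likelihoods over an allele-miscopy
model with error rate $\varepsilon$ (default $10^{-4}$): the probability of
observing the data given a template pair with $g'$ alternate alleles is
$\sum_g 10^{GL_g}\, P(g \mid g', \varepsilon)$. Input GLs are floored at
$10^{-5}$ and internal probabilities at $10^{-15}$, a cutoff kept distinct
from the GL floor.

Because every marker carries a GL — one-hot where pooling decoded the
genotype, a block-posterior simplex where it did not, uniform where nothing
is known — phasing and imputation happen in the same pass, and the pooled
scenario's unusual missingness pattern (missingness correlated with the
genotype itself) enters the model through the likelihoods rather than
being ignored.

The $O(J H^2)$ inner loops are compiled (Rcpp). Memory stays at
$O(\sqrt{J}\, H^2)$ by checkpointing the forward table every
$\lceil\sqrt{J}\rceil$ markers and recomputing segments during the backward
sweep; per-marker rescaling is folded into the next marker's scalar
emission weights, and the per-marker posterior normalization makes absolute
scales irrelevant. Correctness is defined by the naive pair-state model:
the tests hold the compiled path against a pure-R enumeration over all
state paths on small instances (absolute agreement better than $10^{-10}$).

## Evaluation

Two metrics, both computed against complete simulated truth:

* **Concordance** with the half-mismatch rule: per-genotype discordance is
  $|{\rm dosage}(g) - {\rm dosage}(\hat g)|/2$, so het-vs-hom counts 0.5 and
  opposite homozygotes count 1; concordance is one minus the mean. Ties in
  the best-guess genotype break deterministically to the lowest genotype
  index.
* **Cross-entropy** $\chi_j$: the mean over individuals of the negative
  natural log of the probability assigned to the true genotype, floored at
  $10^{-5}$ (so $\chi \le -\ln 10^{-5} \approx 11.5$ per entry). Natural
  logarithm is used, and the floor is applied in the same base, keeping the
  cutoff constant $\ln 10^{-5}$ consistent with it.

`summarize_by_maf()` aggregates per-marker metrics over the MAF bins
$[0, 0.02, 0.04, 0.06, 0.1, 0.2, 0.4, 0.5]$ — deliberately tighter toward
rare variants — and produces rolling means over markers sorted by ascending
MAF with a symmetric window (default 500 markers each side, truncated at
the edges, the marker itself included).

## The synthetic populations

`simulate_population()` emulates the statistical structure the pooled
experiment assumes, not any particular cohort:

* A configurable number of founder haplotypes (default 24) carry the
  variation; every population haplotype is a recombinant mosaic of founders,
  switching founder between consecutive markers with probability
  `switch_rate` (default $3/J$, i.e. about three ancestry switches per
  haplotype across the region). This creates linkage disequilibrium, so
  imputation from the panel is learnable.
* Marker MAFs are drawn from a rare-skewed spectrum whose default per-bin
  proportions (24.2%, 9.9%, 5.4%, 9.0%, 17.1%, 23.9%, 10.4% across the bins
  above) mirror a dense genotyping chip, where almost a quarter of markers
  have MAF below 2%. ALT carriers are assigned by filling whole
  founder-mosaic groups first and a random subset of the last group:
  common variants tag founder segments (strong LD) while rare variants live
  on part of one founder's descendants (partial LD), mimicking recent
  mutations.
* Defaults are desk-scale: a phased panel of 320 individuals (640
  haplotypes), a study cohort of 160 (ten $q = 4$ blocks), and $J = 2000$
  markers at ~1 kb spacing. These sizes were fixed when the generator was
  written and are the sizes at which all cohort-level properties are
  verified; paper-scale parameters are accepted but not default. The
  imputation A/B comparison (informed vs uniform GLs) is run on one full
  pooling block (16 samples) of that cohort — decoding, priors and panel
  are identical between arms, so the comparison is paired.

What the generator does **not** emulate: population substructure,
chip-specific marker manifests, genotyping errors, DNA-concentration
imbalance within pools, and realistic recombination maps. Passing tests
therefore demonstrate the combinatorial and statistical machinery under the
stated model assumptions — they do not certify accuracy figures on real
cohorts.

One assignment of samples to blocks is shared across all markers, as a chip
genotypes every marker of a sample simultaneously; a per-marker reassignment
mode exists behind a flag (`reassign_per_marker`) purely for combinatorial
stress-testing.

## Numerical choices, degenerate inputs, tie-breaks

* Simplex components that are equal up to $10^{-9}$ are snapped together in
  the block-posterior estimators, so analytic ties (e.g. $p_1 = p_2$ in
  symmetric patterns) are not broken by floating-point noise and the
  lowest-index best-guess rule is reproducible. HMM posteriors are not
  snapped; they are held to the path-enumeration oracle exactly.
* Inconsistent observations (impossible under error-free pooling) raise
  errors — `(0, 2)` pool pairs, heterozygous pools with no possible
  carrier, empty candidate sets. Error modelling is out of scope.
* Cohorts not divisible by $q^2$ are rejected rather than padded; blocks
  are filled by a seeded permutation, and every stochastic step takes an
  explicit integer seed.
* GL serialization rounds probabilities to 2 decimals before the log10, so
  a uniform genotype prints as the conventional $(-0.481)^3$ triple;
  in-memory representations keep exact thirds.

## Limitations

* The decoder and estimators assume error-free pool assays; with real
  arrays, per-SNP detection power and pool DNA imbalance would need an
  error model on top of the likelihood framework.
* The self-consistent estimator deviates from exact conditioning by up to a
  few percent in probability (measured and bounded in the tests); where
  that matters, use `posterior_exact()` directly.
* Only the square (weight-2) transversal design is implemented; general
  shifted transversal designs with higher weight, DNA-Sudoku weights and
  compressed-sensing designs are out of scope.
* The HMM's transition/emission defaults are this package's documented
  choices, not a claim of equivalence to any external imputation tool.
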