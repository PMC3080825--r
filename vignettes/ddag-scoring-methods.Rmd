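---
title: "Scoring DDAG models of SNP epistasis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring DDAG models of SNP epistasis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiddag)
```

## The model

We model the dependence of a binary disease status $D$ on a panel of $n$
biallelic SNPs $S_1,\dots,S_n$, each with three genotype states (minor-allele
dosage 0/1/2, treated categorically).  A **direct DAG (DDAG)** is a Bayesian
network in which the only edges point from SNP nodes into $D$; it is fully
identified by $D$'s parent set.  This deliberately does *not* model
SNP–SNP dependence (linkage disequilibrium): the target of inference is
which SNPs jointly predict disease, and restricting to DDAGs shrinks the
model space from super-exponential (all DAGs) to $2^n$, making exhaustive
search over all parent sets of size $1\dots k_{\max}$ feasible
(`count_parent_sets()`, `enumerate_parent_sets()`).

The sufficient statistics of a DDAG with parent set $\mathbf{P}$, $|\mathbf
P| = k$, are the $2 \times 3^k$ counts $s_{jk}$ of disease state by joint
parent genotype (`family_counts()`).  Joint parent states are indexed in a
fixed mixed-radix order (parents ascending by column position, lowest
column most significant), so every score is bit-reproducible.

## Scoring criteria

**Bayesian scores.**  With independent Dirichlet priors (pseudo-counts
$a_{jk}$) on the disease node's conditional distributions, the marginal
likelihood of the disease family is

$$\sum_j \Big[\log\Gamma(a_{j\cdot}) - \log\Gamma(a_{j\cdot}+s_{j\cdot}) +
\sum_k \big(\log\Gamma(a_{jk}+s_{jk}) - \log\Gamma(a_{jk})\big)\Big],$$

computed entirely in natural-log space because the underlying product of
predictive probabilities underflows at realistic $m$.  The **K2** scheme
sets every $a_{jk}=1$; the **BDeu** scheme spreads a prior equivalent
sample size $\alpha$ uniformly, $a_{jk} = \alpha/(r q)$.  $\alpha$ is the
scientifically meaningful tuning parameter: it acts as an inverse
structure penalty, so small $\alpha$ favours small parent sets and large
$\alpha$ tolerates extra parents.  The test suite verifies the
implementation against a *prequential* oracle (the sequential product of
Dirichlet-multinomial predictive probabilities, order-invariant) and
verifies that BDeu — but not K2 — assigns equal scores to the two
Markov-equivalent orientations of a two-node network.

**MDL scores** are data-encoding bits plus structure-penalty bits, lower
better.  The encoding term is $m$ times the empirical conditional entropy
of $D$ given its parents.  Penalty variants (per node, with $d_D = 3^k$
free parameters for the disease node and $d_S = 2$ per parent SNP):

| variant  | per-node penalty (bits) | disease term at size $k$ |
|----------|--------------------------|---------------------------|
| `suzuki` | $(d/2)\log_2 m$          | $(3^k/2)\log_2 m$         |
| `aic`    | $d$                      | $3^k$                     |
| `epi`    | precision-adapted        | $(3^k/2)\log_2 (m/3^k)$   |
| `none`   | 0                        | 0                         |

The `epi` penalty stores each disease parameter to the precision of its
*expected cell count* $m/3^k$ rather than $m$; each parent SNP contributes
$\log_2 m$ bits (two free parameters at half a $\log_2 m$ each).  When
$m < 3^k$ its disease term is negative; the function warns and returns the
value, since the comparison semantics remain well defined.

**Version semantics.**  Version 1 treats all $n$ SNPs as part of every
model, so SNP-node contributions are identical across models and only the
disease-node penalty varies.  Version 2 treats only the $k$ parent SNPs as
model nodes and adds their penalty terms.  A deliberate design decision
applies the same logic to *data* terms: SNP-node data contributions
(root-family marginal likelihoods, marginal encoding lengths) are omitted
from every criterion, in both versions.  Because SNP nodes never have
parents in a DDAG, these terms are properties of the data alone; including
them only for the $k$ parent SNPs would add $\approx m H(S)$ bits per
parent — a data-scale term that swamps every structure penalty and forces
the single-SNP model to win any search regardless of signal.  Version 2
therefore differs from version 1 *only through the penalty*, which is what
makes criteria with different conventions comparable on one ranking and is
consistent with how these scores are used in the epistasis-screening
literature.  `score_bayesian(include_parent_roots = TRUE)` restores the
parent root-family terms for the one situation where they belong: treating
the score as a joint marginal likelihood of the model's own variables
(there the test suite checks that marginal likelihoods sum to one over the
space of datasets, and that BDeu's likelihood equivalence holds).

**MML** is implemented as the K2 score converted to $\log_2$ space minus a
$(d/2)\log_2 m$ parameter penalty over the model's nodes (v1: disease node
only; v2: plus $k \log_2 m$).  This "K2 plus a parameter penalty" form is a
reconstruction — as is the AIC penalty above (one bit per free parameter)
and the exact `epi` formula — because the canonical printed forms were not
available to us; each reconstruction is pinned down by closed-form unit
tests so any future correction is a one-line change with a visible diff.

**Search.**  `exhaustive_search()` scores every enumerated model; ties are
broken by smaller $k$, then lexicographic parent set (the tie-break is our
choice; it only matters on degenerate data).  `score_all_ddags()` counts
each model's contingency table once and evaluates all requested criteria on
the shared counts with vectorised per-size arithmetic — adding the whole
$\alpha$ grid costs far less than re-searching.  `two_stage_screen()`
implements the anchored screen for large panels: stage 1 scores all
$\{anchor, S_i\}$ pairs, stage 2 exhausts $1..k_{\max}$-parent models over
the anchor plus the partners of the `top_m` best pairs.  The same criterion
is used in both stages by default (our choice; the stage-1 criterion is
exposed implicitly through the single `criterion` argument).

## The synthetic-data generator

`simulate_epistasis()` emulates the classic two-locus pure-epistasis
benchmark design: two functional SNPs whose 3×3 penetrance table
$f_{ab} = P(D\,|\,a,b)$ carries all the signal, *exactly* zero marginal
single-locus effects, Hardy–Weinberg genotype frequencies, unlinked noise
SNPs, and exact 1:1 case-control counts via retrospective sampling from the
exact conditional genotype distributions $P(a,b\,|\,\text{case}) \propto
p_a p_b f_{ab}$ (no rejection step).  Defaults follow the benchmark's
stated conditions: 18 noise SNPs (a 20-SNP panel), noise MAF equal to the
functional MAF, sample sizes 200–1600, and the `velez_grid()` design of
seven broad-sense heritabilities $\{0.01, 0.025, 0.05, 0.10, 0.20, 0.30,
0.40\}$ crossed with MAFs $\{0.2, 0.4\}$, five models per cell (70 models).

Broad-sense heritability for a dichotomous penetrance model is the
variance-ratio definition $h^2 = \sum_{ab} p_a p_b (f_{ab}-K)^2 / K(1-K)$
with $K$ the prevalence.  `build_pure_epistasis_model()` constructs tables
by seeded random search: a random 3×3 table is projected (exactly, via the
SVD null space of the six weighted-marginal constraints) onto the
zero-marginal-effect subspace, the deviation from a candidate prevalence
$K_0$ is rescaled analytically to hit the target $h^2$, and candidate
$K_0$ values on a 0.05 grid are scanned until the table stays inside
$[0,1]$.  The result is deterministic given the seed, matches the target
$h^2$ to $10^{-6}$ and has marginal-penetrance deviations below $10^{-9}$.
For $h^2 = 0$ the constant-0.5 table is returned.  Infeasible targets
(e.g. $h^2$ near 1 at low MAF, where the rare-genotype cells cannot carry
enough variance) raise an error reporting the largest heritability the
search attained.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium between markers,
population structure, genotyping error and missingness, covariates,
quantitative phenotypes, and more-than-two-locus generating models.  The
original benchmark's exact 70 penetrance tables are also not reproduced
(they are not redistributable from here); the grid reproduces their
*design parameters*, so experiment results reproduce the published
comparisons in shape and direction, not in exact counts.

## The evaluation harness and the MDR baseline

A criterion *correctly learns* a data set's generating model when the
exact true parent set ranks first; *recall* is the fraction of true SNPs
in the top model.  `accuracy_experiment()` tallies both per (criterion,
sample size) and compares the best criterion to the others with McNemar's
test on the discordant counts (continuity correction on by default — our
choice, both offered).  Recall is measured against the top-ranked model
only.  `marker_hit_report()` reproduces the top-25 marker-hit table
format used when validating against a known risk gene.

The MDR baseline labels each multilocus cell high-risk when its
case:control ratio reaches the overall ratio (cells at the threshold are
high; empty cells low; case-only cells high — explicit substitutes for
conventions the original software does not document), and evaluates
combinations by stratified 10-fold cross-validated balanced accuracy,
with cross-validation consistency as tie-break.  Fold assignment is keyed
to a canonical row ordering so rankings are invariant to row permutation.

## Numerical and scale choices

All Bayesian scores are computed and compared in natural logs, MDL/MML in
bits.  Degenerate families with $q > m$ are allowed: empty parent states
contribute nothing to either the marginal likelihood or the encoding
length.  Model-space counts are IEEE doubles — exact below $2^{53}$ and
carrying ~15 significant digits beyond, ample for any panel size of
interest.  The test suite and `scripts/acceptance.R` run the full
experiment pipeline at desk scale: 100 simulated data sets of $n = 1600$
(five h² = 0.4, MAF = 0.4 models × 20 replicates) for the directional
accuracy/recall comparison, and 50 data sets of $n = 400$ at $h^2 = 0.05$
for the $\alpha$-sensitivity trend — sizes chosen so a complete run
finishes in minutes on one core while keeping the Monte-Carlo error well
below the effect sizes being checked.  All randomness flows through
explicit seeds (`withr::with_seed()`), leaving the caller's RNG state
untouched.

## Known limitations

Exhaustive search is exponential in $k_{\max}$: the 4,254,726-model
two-stage screen is supported by the streaming design but takes hours in
plain R; genome-scale stage-1 scans (hundreds of thousands of pairs) are
out of scope.  Missing genotypes are rejected rather than imputed.
Structure priors other than uniform, general DAGs with SNP–SNP edges, and
constraint-based learning are intentionally not implemented.
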