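# epiddag

Epistasis — interaction between genetic loci whose joint effect on a
phenotype is not predictable from their individual effects — is easy to miss
with single-marker association tests, especially when the interacting SNPs
have no marginal effect at all.  `epiddag` detects such interactions in
case-control genotype data by scoring **direct DAG (DDAG)** Bayesian-network
models: networks in which the only edges run from candidate SNP nodes into a
binary disease node, so a model is identified by the disease node's parent
set.  The DDAG space over *n* SNPs has only 2^*n* members (versus ~4.2 × 10^18
general DAGs for just ten variables), which makes exhaustive search over all
1–4-SNP parent sets practical for panels of tens to low hundreds of loci.

The package is aimed at statistical geneticists who want to compare — or
simply use — the classical Bayesian-network scoring criteria for this task,
together with the simulation design those criteria are usually benchmarked
on, and an MDR baseline.

## Scoring criteria

For a DDAG with parent set of size *k*, the disease family has *r* = 2 child
states and *q* = 3^*k* joint parent states with sufficient statistics
*s<sub>jk</sub>*.  All criteria are functions of this family (SNP-node data
terms are identical across models and cancel):

* **Bayesian (K2, BDeu)** — the Dirichlet-multinomial log marginal
  likelihood

  > Σ<sub>j</sub> [ log Γ(a<sub>j·</sub>) − log Γ(a<sub>j·</sub> + s<sub>j·</sub>) +
  >   Σ<sub>k</sub> { log Γ(a<sub>jk</sub> + s<sub>jk</sub>) − log Γ(a<sub>jk</sub>) } ]

  with hyperparameters a<sub>jk</sub> = 1 (**K2**) or a<sub>jk</sub> = α/(r q)
  (**BDeu**, where α is the prior equivalent sample size).  Larger α means a
  smaller implicit structure penalty, hence larger selected models.
* **MDL** — data-encoding bits (m × empirical conditional entropy of disease
  given parents) plus a structure penalty: (d/2) log₂ m per node
  (*Suzuki*), d bits per node (*AIC*), or the epistasis-tailored bit-length
  penalty (3^k/2) log₂(m/3^k) + k log₂ m in which each disease parameter is
  stored to the precision of its expected cell count (*Epi*).  Version 1
  penalises the disease node only; version 2 adds the k parent SNPs.
  `mdl-none` is the pure encoding length.  Lower is better.
* **MML** — the K2 score in log₂ space minus a (d/2) log₂ m parameter
  penalty.  Higher is better.

Criteria are addressed by string ids: `"k2"`, `"bdeu:alpha=15"`,
`"mdl-epi-v2"`, `"mml-v1"`, ….

## What else is in the box

* `simulate_epistasis()` / `build_pure_epistasis_model()` / `velez_grid()` —
  a two-locus *pure* epistasis simulator (exactly zero marginal single-SNP
  effects) with controlled broad-sense heritability (0.01–0.40 grid), MAF
  (0.2/0.4), 18 unlinked noise SNPs and exact 1:1 case-control sampling.
* `exhaustive_search()`, `score_all_ddags()`, `two_stage_screen()` — full
  enumeration of 1..k-SNP models, shared-count multi-criterion scoring, and
  an anchored two-stage screen for large panels.
* `accuracy_experiment()`, `recall()`, `mcnemar_test()`,
  `marker_hit_report()` — the evaluation harness (top-model accuracy,
  recall of the generating SNPs, paired McNemar comparisons, top-25
  marker-hit tables).
* `mdr_search()` — a minimal multifactor dimensionality reduction baseline
  (high/low-risk cell labelling, 10-fold CV, balanced testing accuracy).
* MDR-format I/O (`read_genotype_table()` / `write_genotype_table()`), tidy
  `tidy()`/`glance()` summaries and `autoplot()` methods throughout, and a
  thin CLI at `inst/cli/epiddag` (`search`, `screen`, `simulate`, `mdr`).

## Worked example

```r
library(epiddag)

mod <- build_pure_epistasis_model(h2_target = 0.2, maf = 0.4, seed = 11)
mod
#> <two_locus_model> maf1 = 0.4, maf2 = 0.4, K = 0.4, h2 = 0.2
#>       locus2
#> locus1      0      1      2
#>      0 0.7351 0.1752 0.3206
#>      1 0.1302 0.5397 0.5881
#>      2 0.4556 0.4868 0.0145

d <- simulate_epistasis(mod, n = 800, n_noise = 18, seed = 23)
functional_snps(d)
#> [1] 5 9

ranking <- exhaustive_search(d, "bdeu:alpha=15", kmin = 1, kmax = 4)
head(tidy(ranking), 5)
#>    rank parent_set     k score criterion     orientation
#> 1     1 S5,S9          2 -488. bdeu:alpha=15 higher
#> 2     2 S5,S7,S9       3 -508. bdeu:alpha=15 higher
#> 3     3 S5,S9,S12      3 -508. bdeu:alpha=15 higher
#> 4     4 S5,S9,S10      3 -514. bdeu:alpha=15 higher
#> 5     5 S2,S5,S9       3 -516. bdeu:alpha=15 higher
```

The penetrance table gives P(disease | joint genotype); every row/column
mixture equals the prevalence 0.4, so neither SNP is marginally associated
with disease, yet heritability is 0.2.  The simulated data set hides the
functional pair at columns S5/S9 among 18 noise SNPs.  The BDeu(α = 15)
search scores all 6195 candidate models and ranks the true pair first
(scores are log marginal likelihoods: higher, i.e. less negative, is
better); the runners-up are its 3-SNP supersets.  The MDR baseline agrees
here:

```r
head(tidy(mdr_search(d, 1, 2, folds = 10, seed = 1)), 3)
#>    rank parent_set     k score criterion orientation
#> 1     1 S5,S9          2 0.691 mdr       higher
#> 2     2 S16,S20        2 0.561 mdr       higher
#> 3     3 S5,S7          2 0.555 mdr       higher
```

where `score` is cross-validated balanced testing accuracy.

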