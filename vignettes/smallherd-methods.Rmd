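---
title: "Genetic evaluation of very small, weakly connected dairy herds: models and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation of very small, weakly connected dairy herds: models and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Smallholder dairy production systems — typical of much of East Africa —
record milk yield in herds of one to a handful of cows, with little
artificial insemination and therefore weak genetic links between herds.
Classical pedigree-based genetic evaluation struggles in these conditions
for three compounding reasons: herds are tiny, so an animal's herd
environment is estimated from almost no contemporaries; connectedness is
weak, so genetic and herd effects are confounded; and milk-yield
heritability is low, so each record carries little signal.  `smallherd`
simulates exactly this data structure and asks two questions of it: how
much does genomic information (GBLUP) buy over pedigree information
(PBLUP), and should the herd enter the evaluation model as a fixed or a
random effect when herds are this small?

The package simulates the whole causal chain — neutral founder genomes,
a polygenic milk-yield trait, eleven generations of breeding, herd
structure — and then evaluates the resulting training populations with
the standard animal model, so estimated breeding values can be compared
with the true ones they estimate.

## The evaluation model

All evaluations solve the single-trait animal model

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{u} + \mathbf{e},$$

with $\mathbf{u} \sim N(0, \mathbf{A}\sigma^2_a)$ under PBLUP or
$\mathbf{u} \sim N(0, \mathbf{G}\sigma^2_a)$ under GBLUP, and
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$.  Every model carries an
overall intercept.  The herd effect enters in one of three ways:

* **none** — omitted entirely;
* **fixed** — herd dummies join $\mathbf{X}$, first level dropped
  (reference coding; any full-rank constraint gives identical
  $\hat{\mathbf{u}}$);
* **random** — a herd incidence $\mathbf{W}$ with
  $\mathbf{h} \sim N(0, \mathbf{I}\sigma^2_h)$.

$\mathbf{A}$ is the numerator relationship matrix from the tabular method
with inbreeding, and its sparse inverse is assembled directly from the
pedigree by Henderson's rules with inbreeding coefficients from the
Meuwissen–Luo algorithm.  $\mathbf{G}$ is VanRaden's method 1,
$\mathbf{G} = \mathbf{M}\mathbf{M}'/2\sum_j p_j(1-p_j)$, with dosages
centred by twice the allele frequency *observed in the genotyped cows* —
base-population frequencies are not available to a real evaluation.
Variance components are treated as known and set to the simulated values;
estimating them is out of scope.

Accuracy is the Pearson correlation between estimated and true breeding
values over the phenotyped cows.

### Two solution routes

Pedigree models are solved through Henderson's mixed-model equations with
the sparse $\mathbf{A}^{-1}$ (`build_mme()` + `solve_mme()`, direct sparse
factorization).  Genomic models are solved through the algebraically
identical covariance form (`solve_blup_gls()`):
$\mathbf{V} = \sigma^2_a\mathbf{Z}\mathbf{G}\mathbf{Z}' +
\sigma^2_h\mathbf{W}\mathbf{W}' + \sigma^2_e\mathbf{I}$, GLS for
$\hat{\mathbf{b}}$, then
$\hat{\mathbf{u}} = \sigma^2_a\mathbf{G}\mathbf{Z}'\mathbf{V}^{-1}
(\mathbf{y}-\mathbf{X}\hat{\mathbf{b}})$.  The reason is numerical: after
eleven generations of selection from a bottlenecked founder population,
$\mathbf{G}$ among the training cows is routinely close to singular, and
an explicit $\mathbf{G}^{-1}$ amplifies that ill-conditioning into the
equations, whereas $\mathbf{V}$ is kept well away from singularity by
$\sigma^2_e\mathbf{I}$.  The two routes agree to machine precision on
well-conditioned systems (this is tested), and `chol()` of $\mathbf{G}$
falls back to a `1e-8` diagonal ridge (with a message) in the one place an
inverse is still offered.  Solutions are invariant to record order;
relative residuals above `1e-8` trigger a warning.

## What the generator simulates

The pipeline follows the study design it reproduces:

1. **Founder genomes** (`simulate_founder_haplotypes()`): 2,000 diploid
   founders, 10 chromosomes of 1 Morgan, effective population size
   1,035 (reflecting the high diversity of African cattle), at least
   6,000 segregating sites per chromosome.
2. **Loci** (`select_loci()`): 5,000 SNP + 1,000 QTL per chromosome,
   drawn uniformly among segregating sites with no MAF filter, SNP and
   QTL disjoint.
3. **Trait** (`sample_qtl_effects()`): QTL effects from $N(0,1)$, scaled
   once so founder TBV variance is exactly $\sigma^2_a = 0.2$; with
   $h^2 = 0.1$ and a herd variance ratio of 0.4 this fixes
   $\sigma^2_h = 0.8$ and $\sigma^2_e = 1.0$.
4. **Burn-in** (`run_burn_in()`): 5 discrete generations, 225 sires and
   1,000 dams truncation-selected on phenotype, 2,000 offspring per
   generation.
5. **Evaluation phase** (`run_evaluation_phase()`): 6 generations, 1,000
   sires selected on phenotype, dams at random, equal sex ratio; only
   final-generation records are used for evaluation and the pedigree
   spans the last 5 generations (earlier parents coded unknown).
6. **Herds** (`sample_herd_sizes()`, `assign_cows_to_herds()`): the
   8,000 training cows are assigned at random to herds whose sizes come
   from the two-step procedure below; one $N(0, \sigma^2_h)$ effect per
   herd.

### The founder coalescent

Founder haplotypes come from a discrete-locus **sequentially Markov
coalescent (SMC′)** implemented in C++: genealogies are tracked along a
grid of loci; between adjacent loci at distance $d$ Morgans,
recombination hits the current tree as a genuine point process at rate
$2N_e d$ per unit branch length (the inter-event distance is redrawn from
the current tree length after every move, which is what keeps the tree
process stationary), and each event is a subtree-prune-regraft in which
back-coalescence onto the original branch is allowed.  The SMC′ move has
the Kingman coalescent as its exact stationary distribution, so the
marginal genealogy at every locus is exactly coalescent — the test suite
verifies Watterson's $E[S] = \theta\sum_{i<n} 1/i$ by simulation.
Mutations are dropped per locus as Poisson in the branch length
(infinite-sites style), so every emitted site is segregating; the scaled
mutation rate defaults to 1.2 times the target site count and short draws
are retried a bounded number of times before erroring.

A constant $N_e$ is used: only the final-generation value is specified by
the design, and a constant trajectory is the simplest model consistent
with it (a piecewise trajectory could be added behind the same
interface).  Chromosome length defaults to 1 Morgan, the standard
per-chromosome convention in breeding simulations.  SNP and QTL sets are
kept disjoint so markers never carry direct causal effects.

### The herd-size procedure

Step 1 draws `round(n_slots / lambda)` sizes from Poisson($\lambda$) — so
the *expected* total is exactly the 8,000 slots — and discards zero-size
draws, since a herd must hold at least one cow; this is what makes the
realized distribution zero-truncated.  Step 2 repairs the stochastic
gap between the realized total and 8,000 by unit increments, or unit
decrements never below size one, on uniformly chosen herds.  Because the
correction neither creates nor destroys herds, the realized mean herd
size is `8000 / #herds`, concentrated on $\lambda/(1-e^{-\lambda})$:
1.58, 2.31, 4.07, 8.00 and 16.00 for $\lambda \in \{1, 2, 4, 8, 16\}$.
The exact mechanics of the correction only perturb the size distribution,
not its mean, which is the quantity the design pins down.

### Deliberate simplifications

* Phenotypes are simulated for **all** animals in the selection
  generations (males included) with an individual herd-of-one
  environmental effect, because herd structure is only defined for the
  final training population; final-generation animals receive their
  record when the training set is built, so the record reflects the herd
  they are placed in.
* The evaluation-phase litter design (16,000 offspring: 16 per sire, 2
  per dam) is the smallest symmetric design guaranteeing 8,000 cows; the
  source design leaves it unstated.
* Generations are discrete and non-overlapping; no culling, repeated
  lactations, missing records, genotyping errors, dominance or
  genotype-by-environment interaction.  QTL effects are never rescaled
  after the founders, so genetic variance drifts under selection, as it
  would in the generator being emulated.
* The herd variance ratio is interpreted against **total** phenotypic
  variance (so $h^2 + r_h + r_e = 1$), matching the empirical literature
  the value is taken from and keeping $h^2 = 0.1$ internally consistent.

What passing tests at desk scale do **not** show: real milk records have
missing values, repeated lactations, and herd effects correlated with
management and genetics in ways random assignment rules out.  The
simulation isolates the connectedness/herd-size mechanism; it does not
certify field performance.

## Replication and summaries

`run_replicate()` simulates one population and evaluates **all** scenario
cells (herd-size $\lambda$ $\times$ method $\times$ herd model) on it, so
model contrasts are paired within replicate; `run_study()` repeats this
over independent seeds (10 in the full design).  Summaries report the
mean, the standard error $\mathrm{sd}/\sqrt{n}$, and a 95% percentile
interval (2.5%–97.5% quantiles across replicates; the percentile form is
a package choice — the source design reports "mean and 95% interval"
without defining the interval).

```{r, eval = FALSE}
library(smallherd)
res <- run_study(study_config(), n_replicates = 10, seed = 1)
summarize_accuracy(res) |> plot_accuracy()
```

## Problem sizes used by the test suite

The shipped tests run two profiles, chosen so the whole suite completes
in minutes while still exercising every stage end to end:

* a **micro** profile (80–250 founders, 1–2 chromosomes, tens of loci)
  for structural and determinism checks;
* the **reduced study** profile — 2 chromosomes, 500 founders, 1,000 SNP
  + 200 QTL per chromosome, 800 training cows, 2 replicates — for the
  paired directional comparisons (genomic vs pedigree information,
  random vs fixed herd).

Absolute accuracies scale with training size, marker density and the
number of independent chromosome segments, so reduced-profile accuracies
sit below the full-scale values; the *orderings* (GBLUP above PBLUP;
herd-random at least herd-fixed in tiny herds; fixed and random
converging by herd size 8) are scale-stable and are what the reduced
profile asserts.  The full design (`study_config()` defaults: 2,000
founders, 50k SNP, 8,000 cows, 10 replicates) is the one whose published
accuracies are targeted; it takes hours of single-core compute, and
`scripts/full_study.R` runs it.

## Known limitations

* The SMC′ is a Markov approximation of the full ancestral recombination
  graph: marginal trees are exact, long-range linkage correlations are
  approximate.  At $N_e = 1035$ with thousands of loci per Morgan,
  adjacent-locus correlation is weak and the approximation is far inside
  the Monte-Carlo noise of the downstream comparisons.
* Dense GBLUP systems are solved by $O(n^3)$ factorizations; 8,000 cows
  is comfortable, hundreds of thousands are not — APY-type
  approximations are out of scope.
* Variance components are inputs; there is no REML/Gibbs machinery.
* Single-step (combined pedigree-genomic) evaluation, VanRaden method 2,
  and metafounders are not implemented.
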