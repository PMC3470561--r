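---
title: "Bound-guided search for strict epistatic interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bound-guided search for strict epistatic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibound)
```

## The model

A *SNP pattern* is a Bayesian network in which k SNP variables, each with
three states (minor-allele counts 0/1/2), are the parents of a binary
disease variable D. Writing q = 3^k for the number of joint parent
instantiations and N_jk for the number of individuals with joint genotype j
and disease value k, the BDeu local score of the disease node is the log
marginal likelihood of the case/control column given the pattern's joint
genotypes, under Dirichlet priors with hyperparameters α/(2q) per cell
(a prior uniform distribution over each variable with total prior weight
α, the *prior equivalent sample size*):

$$\ln \mathrm{score} = \sum_j \Big[\ln\Gamma(\tfrac{\alpha}{q}) -
\ln\Gamma(\tfrac{\alpha}{q} + N_{j+})\Big] + \sum_{j,k}
\Big[\ln\Gamma(\tfrac{\alpha}{2q} + N_{jk}) -
\ln\Gamma(\tfrac{\alpha}{2q})\Big].$$

Only the disease node's local score is computed: under the uniform prior
the SNP nodes' own local scores are identical for all same-size patterns
and cancel from every comparison. All scores are natural logs, computed
with `lgamma` throughout; a direct gamma-ratio-product oracle in the test
suite confirms the log-space evaluation to 1e-10 on small counts.

## The expansion bound

For a pattern P with counts N_jk, the package computes an upper limit on
the score of any pattern P ∪ A with |A| = m added SNPs. Adding m 3-state
SNPs refines the parent space to q′ = q·3^m sub-instantiations, and the
score of the refined pattern is maximal when every sub-instantiation is
*pure* — all its individuals share one disease value. Assigning each
nonzero cell N_jk wholesale to its own pure sub-instantiation gives

$$\ln \mathrm{bound}(P, m) = \sum_{j,k:\,N_{jk}>0}
\Big[\ln\Gamma(\tfrac{\alpha}{q'}) - \ln\Gamma(\tfrac{\alpha}{q'} + N_{jk})
+ \ln\Gamma(\tfrac{\alpha}{2q'} + N_{jk}) -
\ln\Gamma(\tfrac{\alpha}{2q'})\Big].$$

Two elementary superadditivity facts make this a true bound: splitting a
pure cell across sub-instantiations only lowers its contribution (the
per-cell term is superadditive in the count), and any mixed
sub-instantiation is dominated by the pure cells it could be separated
into. The test suite nevertheless re-verifies dominance by exhaustive
enumeration over randomized small datasets, because the bound is the
package's load-bearing object. The bound is *loose* by construction — pure
sub-instantiations are wildly optimistic — so it cannot prune a search
with guarantees; its value is as a sort key.

## The search

To search for a k-SNP pattern, all single SNPs are ranked — either by
their 1-SNP score or by their 1-SNP expansion bound with m = k−1 (the
number of SNPs still to be added) — and k-subsets of the ranked list are
enumerated so that every subset of the top j ranks precedes any subset
reaching beyond rank j: (1,2), (1,3), (2,3), (1,4), (2,4), (3,4), (1,5), …
The 1-based position of the subset with ranks r_1 < … < r_k has the closed
form

$$\mathrm{position} = 1 + \sum_{i=1}^{k} \binom{r_i - 1}{i},$$

which `find_pattern_analytic()` uses to locate a target without scoring
intermediate patterns — necessary at 1000 SNPs and k ≥ 3, where the
enumerated prefix can run to millions of patterns. `find_pattern()`
enumerates explicitly and supports two stopping rules: `set_identity`
(stop on the target SNP set; the default for experiments, as it is free of
floating-point comparisons) and `score_equality` (stop on the first
pattern matching the target's score within 1e-9, the rule the search
would use when only a score is known; collisions with non-target patterns
are possible in principle but not observed). Ties in sort keys are broken
by ascending column index so every run is reproducible.

Why does bound-sorting find strict interactions when score-sorting cannot?
Under strict epistasis the interacting SNPs' marginal genotype
distributions are *exactly* those of null SNPs — their 1-SNP counts carry
no signal in distribution. The bound, however, is strongly shaped by how
concentrated a SNP's six genotype-by-disease counts are: rarer genotype
classes give more concentrated counts and a higher (less negative) bound.
Sorting by the bound therefore ranks low-MAF SNPs — including low-MAF
interacting SNPs — near the top. When the interaction's MAF is low
relative to the bulk of the panel, its SNPs sit in the first few ranks and
the rank-driven enumeration reaches them almost immediately; as the
interaction MAF approaches the middle of the noise-MAF distribution the
advantage dissolves, and past it the bound sorts the true SNPs *late*
(mean fractions slightly above the 0.5 chance level at MAF 0.4). The
experiments reproduce exactly this profile, including its failure mode.

## The simulator

`generate_penetrance_model()` builds k-SNP penetrance tables f(g) over all
3^k joint genotypes that are *strict*: under Hardy–Weinberg genotype
weights at the model's MAF, the mean penetrance conditional on any proper
subset of the loci equals the prevalence K for every genotype assignment
of that subset. Heritability is the penetrance variance on the HWE-
weighted table, normalized by the Bernoulli variance of the trait:
h² = Σ_g P(g)(f_g − K)² / (K(1−K)).

Generation samples a random *architecture* — a near-binary random table,
the kind of all-or-nothing penetrance pattern that maximizes attainable
variance — and alternates projections between the [0,1] box and the
affine subspace of strict tables (the pure k-way interaction subspace,
under the HWE-weighted inner product, where the per-coordinate centering
operators commute). The converged deviation is then scaled around K to hit
the target h² exactly; scaling down stays inside the box, so the final
clip is a no-op and strictness is never traded away. Models are validated
on construction and re-validated in tests by an independent brute-force
enumerator over all proper subsets.

Two consequences of strictness shaped the design:

* **Prevalence is a soft target.** Strictness caps the achievable
  penetrance variance — deviations at common genotype cells are pinned
  near zero by the marginal constraints, so almost all variance must live
  on rare cells, whose weight shrinks with MAF. The cap depends on K, and
  at MAF 0.05 no strict 2-SNP table with K = 0.25 reaches h² = 0.05 at
  all. The generator therefore scans a prevalence grid and keeps the
  feasible K closest to `prevalence_target` (default 0.25), recording the
  achieved value in the model. This mirrors how penetrance-table
  generators behave when prevalence is left unspecified.
* **Some grid cells are infeasible outright.** Numerical maximization
  (300 random architectures × a K grid) puts the ceiling at h² ≈ 0.052
  for 3 loci at MAF 0.1 and h² ≈ 0.0012 for 4 loci at MAF 0.05, so the
  study grid's high-heritability entries 0.1 and 0.002 at those positions
  cannot be realized by any strict HWE-weighted table. The generator
  fails loudly, naming the (MAF, h²) pair, and the grid runner records
  such cells as skipped rather than silently lowering h². The across-k
  high-heritability comparison is therefore made at MAF 0.2, where all
  three pattern sizes are feasible.

Datasets are drawn retrospectively: joint genotypes of the interacting
SNPs come from the exact conditionals P(g|case) = f_g P(g)/K and
P(g|control) = (1−f_g)P(g)/(1−K); each noise SNP is independent of
phenotype under HWE at a MAF drawn uniformly from [0.05, 0.5] (a generic
common-variant panel; configurable, and consequential — see limitations).
The interacting SNPs are placed at seeded-random columns, recorded in the
dataset's `truth` field. Goodness-of-fit of the sampled joint genotypes
against the closed forms is tested by chi-square at n = 10^5 with sparse
cells pooled, under fixed seeds.

## Parameters that matter

* `alpha` (default 4): the BDeu prior equivalent sample size; it sets the
  implicit complexity penalty. Every experiment records it in its config.
* `m` in `sort_snps()`: the expansion size of the bound used as sort key;
  experiments use m = k−1, the number of SNPs missing from a 1-SNP
  pattern.
* `prevalence_target` (default 0.25) and `noise_maf_range` (default
  [0.05, 0.5]): simulator settings discussed above.
* `max_tries` (default 500): architectures attempted before a (MAF, h²)
  pair is declared infeasible. The grid cell (k=3, MAF 0.1, h² 0.05) sits
  at ~97% of its feasibility cap and legitimately consumes tens of tries;
  500 makes a false infeasibility verdict vanishingly unlikely while
  keeping true verdicts quick.

## Problem sizes

The packaged experiment defaults run each grid cell at 20 replicates (the
original design used 100; `replicates = 100` restores it), with 1000 cases
and 1000 controls per dataset and 100 or 1000 SNPs. The acceptance script
uses 100 replicates for the cheap 100-SNP cells and 25 for the 1000-SNP
cells, with positions computed analytically. Test-suite property checks
use ≤ 8 SNPs and ≤ 50 individuals, where exhaustive enumeration over all
pattern expansions is feasible.

## What the simulations do and do not show

The generator emulates idealized strict epistasis: HWE within each locus,
linkage equilibrium between all loci, a single shared MAF per interaction,
no missing genotypes, no covariates, and noise SNPs truly independent of
phenotype. Passing tests show the bound-sorted search recovers planted
interactions under these conditions, and that the advantage is driven by
the bound's sensitivity to genotype-frequency concentration. They do not
show robustness to linkage disequilibrium, population structure,
genotyping error, or a real panel's MAF spectrum — in particular, the mean
fraction checked depends directly on where the interaction's MAF falls
within the panel's MAF distribution, so absolute fractions from these
simulations transfer to other panels only qualitatively. Real-data
workflows should read their panel through `read_dataset()` and treat the
simulated fractions as a mechanism demonstration, not a power estimate.

## Numerical choices

Scores and bounds are computed in log space only; counts are integers and
`lgamma` arguments stay positive, so all values are finite. Empty datasets
give score and bound 0 (the empty product). The strictness tolerance is
1e-6 in absolute conditional-mean deviation; achieved heritability is
exact to floating point by construction and asserted within 1% relative.
Alternating projections stop when the deviation table moves less than
1e-10 in sup norm, or after 300 iterations. Sort ties break by ascending
column index; rank ties cannot occur in `pattern_position`, which rejects
non-increasing rank tuples.
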