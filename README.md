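# epibound

Bound-guided Bayesian search for strict epistatic interactions in
case-control genotype data.

## The problem

Epistasis — loci interacting to affect a phenotype — is *strict* when no
proper subset of the interacting loci shows any marginal effect. Strict
interactions are the worst case for genome-wide association analysis: no
single-locus (or any lower-order) statistic carries signal, so in principle
only an exhaustive scan over all k-SNP subsets can find them, and
\(\binom{n}{k}\) explodes for realistic n.

`epibound` implements a way around this. A **SNP pattern** is a small
Bayesian network in which k SNP nodes (genotypes coded 0/1/2) are parents of
a binary disease node D. Patterns are compared by the BDeu local score of
the disease node, in natural logs:

```
ln score(P) = Σ_j [ lnΓ(α/q) − lnΓ(α/q + N_j+) ]
            + Σ_j Σ_k [ lnΓ(α/(2q) + N_jk) − lnΓ(α/(2q)) ]
```

with q = 3^|P| joint parent instantiations, N_jk the number of individuals
with joint genotype j and disease value k, and α the prior equivalent sample
size (default 4). The package's central object is an **expansion bound**: an
upper limit on the score of *any* pattern obtainable by adding m SNPs to a
given pattern, obtained by placing each nonzero count cell into its own pure
sub-instantiation of the refined parent space q′ = q·3^m:

```
ln bound(P, m) = Σ_{j,k: N_jk>0} [ lnΓ(α/q′) − lnΓ(α/q′ + N_jk)
                                 + lnΓ(α/(2q′) + N_jk) − lnΓ(α/(2q′)) ]
```

The bound is far too loose to prune a search with guarantees, but it is an
excellent *ordering* heuristic: sorting SNPs by their 1-SNP expansion bound
(m = k−1) and enumerating k-subsets of the ranked list in the order
(1,2), (1,3), (2,3), (1,4), … locates injected strict interactions after
checking a tiny fraction of the search space — even though the interacting
SNPs' 1-SNP *scores* are indistinguishable from noise.

The package also ships a GAMETES-style simulator of strict epistatic
penetrance models (shared MAF, Hardy–Weinberg genotype weights, exact
heritability control, prevalence as a soft target) and an experiment driver
that reruns the full simulation grid at configurable scale.

## Worked example

```r
library(epibound)

# a strict 2-SNP interaction: MAF 0.05, heritability 0.05
model <- generate_penetrance_model(k = 2, maf = 0.05, h2 = 0.05, seed = 9)
model
#> strict epistatic penetrance model: k = 2, MAF = 0.05,
#>   prevalence K = 0.175, heritability h2 = 0.05 (target 0.05, 5 architectures tried)

# 1000 cases + 1000 controls, the pair hidden among 98 noise SNPs
ds <- sample_dataset(model, sim_config(2, 0.05, 0.05, n_snps = 100, seed = 5))
ds
#> genotype_dataset: 2000 individuals (1000 cases / 1000 controls), 100 SNPs
#>   injected interacting SNPs at columns: 37, 64

# sort SNPs by the expansion bound on adding one SNP, then search
ord <- sort_snps(ds, "bound", m = 1)
find_pattern(ds, k = 2, ord, target = ds$truth)
#> search_result (enumerate): target {37, 64} found at position 1 of 4,950 (fraction 0.000202)
```

The injected pair is the very first of the 4,950 two-SNP patterns the
sorted enumeration visits — its two SNPs have the highest expansion bounds
in the dataset, although their single-SNP scores are unremarkable. Averaged
over replicates (`run_cell()`), bound-sorted search at MAF 0.05 checks well
under 1% of the search space, against ~50% for an unsorted scan; the
fraction rises toward (and past) chance level as the MAF approaches 0.4,
and falls as the number of interacting SNPs grows.

A command-line wrapper for the same operations is installed at
`inst/cli/epibound.R` (subcommands `score`, `simulate`, `search`,
`experiment`).

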