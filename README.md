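# ibdscreen

Detection of cryptic relatedness in nominally unrelated study samples.

Standard inference in genetic association studies assumes that subjects are
independent draws from the population.  Undocumented close relationships —
duplicated samples, parent–offspring pairs, siblings — violate that
assumption and inflate test statistics.  `ibdscreen` screens a homogeneous
sample of SNP-genotyped subjects for such pairs.  It is aimed in particular
at **candidate-gene panels**, where markers cluster within genes and are in
strong linkage disequilibrium (LD), so that thinning to an independent
marker subset would discard most of the relationship information.

## Method

For a pair of individuals, let `Z ∈ {0, 1, 2}` be the number of alleles
shared identical-by-descent (IBD) at a locus and `I ∈ {0, 1, 2}` the number
shared identical-by-state (IBS).  The relatedness of the pair is summarised
by the IBD coefficients `k_z = P(Z = z)`.  At each SNP,

```
P_m(I = i) = Σ_z  P_m(I = i | Z = z) · P(Z = z),
```

and summing these identities over SNPs and solving sequentially gives the
method-of-moments estimators

```
k̂0 = N̂(I=0) / N̂(I=0|Z=0)
k̂1 = [N̂(I=1) − k̂0 · N̂(I=1|Z=0)] / N̂(I=1|Z=1)
k̂2 = [N̂(I=2) − k̂0 · N̂(I=2|Z=0) − k̂1 · N̂(I=2|Z=1)] / N̂(I=2|Z=2)
```

where `N̂(I=i)` counts SNPs at which the pair shows IBS state `i`, and
`N̂(I=i|Z=z)` accumulates per-SNP conditional IBS probabilities.  Those
conditional probabilities are estimated from a reference pool (e.g. the
controls of a case–control study) by **exactly unbiased count-form
estimators** — proportions of ordered without-replacement draws from the
pool's `T` observed alleles, e.g.

```
P̂(I=0 | Z=0) = 2·X(X−1)·Y(Y−1) / [T(T−1)(T−2)(T−3)]
```

for allele counts `X + Y = T`, which removes the finite-sample bias of the
plug-in value `2p²q²`.

Because the sampling distribution of `(k̂0, k̂1)` under LD is analytically
intractable, reference clusters are built **empirically**: pairs of known
relationship (duplicate/MZ, parent–offspring, full sibs, half sibs, first
cousins, or any user pedigree) are simulated by gene drop — founder
haplotypes drawn from a per-chromosome Markov haplotype-frequency model
fitted to the reference pool, transmitted with Poisson (Haldane)
recombination on the genetic map, with study missingness patterns copied
onto the simulated genotypes.  Each cluster is summarised by a bivariate
normal prediction ellipse; study pairs falling **inside a relationship's
95% ellipse and outside the Bonferroni-adjusted unrelated ellipse** are
flagged automatically.

## Worked example

```r
library(ibdscreen)

# synthetic candidate-gene study: 200 subjects, 1250 SNPs in ~210 gene-like
# LD clusters on 22 autosomes, with 2 parent-offspring + 3 full-sib pairs
# planted among the cases
fx <- generate_fixture(seed = 42)
fx$data
#> genotype_table: 200 subjects x 1250 SNPs on 22 chromosome(s); 104 reference subjects; 0.98% missing

res <- run_ibdcheck(fx$data, sim = sim_control(simulate = TRUE), seed = 1)
res
#> ibd_result: 19900 study pairs; 5 simulated relationship cluster(s); 5 flagged pair(s)
#> flagged pairs:
#>   subject1 subject2     relationship      mode        k0        k1
#> 1   sub191   sub192        full.sibs automatic 0.4125714 0.3340292
#> 2   sub193   sub194        full.sibs automatic 0.1891221 0.4497728
#> 3   sub195   sub196        full.sibs automatic 0.3161700 0.4625247
#> 4   sub197   sub198 parent.offspring automatic 0.0000000 1.0421269
#> 5   sub199   sub200 parent.offspring automatic 0.0000000 1.0054011
```

All five planted pairs — and no others — are flagged.  `k0 = 0` with
`k1 ≈ 1` is the parent–offspring signature (one allele is always shared
IBD, so opposite homozygotes are impossible); full siblings sit around
`(k0, k1) = (0.25, 0.5)`.  Estimates are deliberately not clamped to
`[0, 1]`, so values slightly outside (e.g. `k1 = 1.04`) reflect estimation
noise.  Any pair can be interrogated against all reference ellipses:

```r
query_pair(res$study, res$ellipses, "sub191", "sub192")
#>   subject1 subject2        k0        k1    L status in_unrelated in_dup.mz
#> 1   sub191   sub192 0.4125714 0.3340292 1235     ok        FALSE     FALSE
#>   in_parent.offspring in_full.sibs in_half.sibs in_unrelated_adjusted
#>                 FALSE         TRUE        FALSE                 FALSE
```

`render_report(res, "out/")` writes the estimate/flag tables and the
overview plot plus one windowed plot per simulated relationship.  A thin
command-line wrapper is installed at `inst/cli/ibdscreen.R`
(`ibdscreen run --ped ... --map ... --simulate`, `ibdscreen
simulate-fixture`, `ibdscreen query-pair`).

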