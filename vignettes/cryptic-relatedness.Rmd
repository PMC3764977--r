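---
title: "Screening for cryptic relatedness with ibdscreen"
author: "ibdscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for cryptic relatedness with ibdscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdscreen)
```

## The problem

Association studies assume nominally unrelated subjects really are
unrelated.  Duplicated samples, parent–offspring pairs or siblings hiding in
a sample ("cryptic relatedness") induce correlation between observations and
inflate association statistics.  `ibdscreen` estimates, for every pair of
subjects, the identity-by-descent (IBD) coefficients
$(k_0, k_1, k_2) = (P(Z{=}0), P(Z{=}1), P(Z{=}2))$ — the proportions of the
genome at which the pair shares 0, 1 or 2 alleles IBD — and compares each
pair against empirical reference clusters of simulated pairs of known
relationship.

The package is designed for the regime where this is hardest: a **modest
number of SNPs in strong linkage disequilibrium (LD)**, as in candidate-gene
panels.  There, (i) estimation error in $(\hat k_0,\hat k_1)$ cannot be
ignored, so theoretical reference distributions for the *true* coefficients
are inadequate; and (ii) thinning to independent SNPs would leave too few
markers to be informative.  Both issues are addressed by simulating
reference pairs under a haplotype model that preserves the LD of the data.

## The moment estimator

At each SNP $m$, identity-by-state ($I$) and identity-by-descent ($Z$) are
linked by
$$P_m(I=i) \;=\; \sum_{z\le i} P_m(I=i \mid Z=z)\, P(Z=z),$$
where the conditional probabilities are population quantities shared by all
pairs, and $P(Z=z)$ belongs to the pair.  Summing over the $L$ SNPs
non-missing in both members and solving the three equations sequentially
gives
$$\hat k_0 = \frac{\hat N(I{=}0)}{\hat N(I{=}0\mid Z{=}0)},\qquad
  \hat k_1 = \frac{\hat N(I{=}1)-\hat k_0\hat N(I{=}1\mid Z{=}0)}
                  {\hat N(I{=}1\mid Z{=}1)},\qquad
  \hat k_2 = \frac{\hat N(I{=}2)-\hat k_0\hat N(I{=}2\mid Z{=}0)-\hat k_1\hat N(I{=}2\mid Z{=}1)}
                  {\hat N(I{=}2\mid Z{=}2)}.$$
$\hat N(I{=}i)$ is the observed count of SNPs in IBS state $i$;
$\hat N(I{=}i\mid Z{=}z)$ accumulates the estimated conditional
probabilities over the same SNPs.  The three estimates sum to one by
construction; they are **not clamped** to $[0,1]$, because excursions
outside the simplex carry information about estimation noise and are
handled naturally by the graphical reference clusters.  The method assumes
a homogeneous, random-mating, non-inbred study population; population
structure will masquerade as relatedness.

### Exactly unbiased conditional IBS probabilities

With reference-pool allele counts $X + Y = T$ (counting both alleles of
every non-missing genotype), the conditional probabilities are estimated as
exact proportions of ordered without-replacement draws from the $T$-allele
pool — four distinct draws for $Z=0$, three (one shared) for $Z=1$, e.g.
$$\hat P(I{=}0 \mid Z{=}0) = \frac{2X(X-1)Y(Y-1)}{T(T-1)(T-2)(T-3)}.$$
These count-form estimators are *exactly* unbiased for the
infinite-population values (here $2p^2q^2$) when $X$ is binomial — the test
suite verifies this by weighted enumeration — whereas the plug-in forms
using $\hat p = X/T$ are biased at any finite $T$.  We implement the count
form rather than the algebraically equivalent "plug-in × correction factor"
form because the latter degenerates to $0/0$ at $X=0$ or $Y=0$; an
equivalence test links the two.  SNPs with $T < 4$ admit no four-allele
draw and are excluded from *all* sums (observed and conditional alike), so
numerator and denominator always range over the same SNP set.

The tables are computed once from the **reference pool** — the subjects
flagged `is_reference`, e.g. the controls of a case–control study, which
can be regarded as a population random sample — and reused for every pair,
including pairs involving non-reference subjects.

## Reference clusters by LD-aware gene drop

The joint distribution of $(\hat k_0,\hat k_1)$ under LD is analytically
intractable, so reference clusters are built empirically.  For each
requested relationship a minimal pedigree is simulated (default 200 pairs):
founders receive haplotypes from a fitted haplotype model, meioses transmit
recombinant haplotypes, and the resulting target-pair genotypes are pushed
through *exactly the same estimation path* as study pairs.

**Haplotype model.**  Per chromosome, a first-order inhomogeneous Markov
chain over alleles: an initial allele frequency and one $2\times2$
transition matrix per adjacent SNP pair.  It is fitted to the reference
pool by the classic two-locus haplotype-frequency EM applied to each
adjacent pair (only double heterozygotes have ambiguous phase), started
from linkage equilibrium — so fitting is deterministic — and iterated to a
parameter tolerance of $10^{-6}$ (at most 500 iterations).  A Markov chain
captures adjacent-marker LD only; it is a deliberately simple, samplable
stand-in for richer graphical haplotype models, sufficient because its only
role is founder-haplotype generation, and its kind (`markov_ld` vs
`independence`) is recorded in every model file so outputs cannot be
misattributed.  Fitted models are saved as one plain-text TSV per
chromosome (17 significant digits, bit-exact round-trip) and can be reused
by later runs, skipping the fitting stage.  The `independence` variant sets
every transition row to the marginal frequency and reproduces the naive
independent-SNP analysis.

**Gene drop.**  Crossovers are a homogeneous Poisson process on the genetic
map (Haldane model, no interference) — the standard minimal recombination
model; the starting parental haplotype of each meiosis is equiprobable, and
chromosomes segregate independently.  If genetic positions are absent they
are inferred at a constant 1 cM/Mb (the genome-wide human average;
overridable, and users of non-human organisms should supply their own map).
Duplicate/MZ pairs are one simulated genome copied.  To mimic the study's
missing-data process, each simulated *individual* independently adopts the
missingness mask of one uniformly drawn study subject.  (Whether masks
should be drawn per individual or per pair is a free choice; per individual
was chosen as the more conservative — it widens the reference clusters
slightly.)  Founder-haplotype labels can be tracked (`return_ibd = TRUE`),
giving the realised IBD state at every SNP; tests use this to confirm e.g.
the $(0.25, 0.5, 0.25)$ genome-wide proportions of full siblings.

## Prediction ellipses and flagging

Each simulated cluster of $(\hat k_0, \hat k_1)$ points is summarised by
its sample mean and covariance; a point belongs to the region when its
squared Mahalanobis distance is at most the $\chi^2_2$ quantile at the
coverage level (default 0.95), the standard bivariate-normal prediction
region.  Because the vast majority of study pairs are unrelated, the
unrelated ellipse alone is widened by a Bonferroni-type adjustment of its
coverage to $1-(1-\alpha)/n_p$ for $n_p$ study pairs.  A study pair is
flagged **automatically** when it falls inside a relationship's (nominal)
ellipse *and* outside the adjusted unrelated ellipse.  Pairs compatible
with both — typically in the overlap of the half-sib and unrelated
regions — are deliberately not auto-flagged; `query_pair()` reports all
ellipse memberships for any named pair, a deterministic, scriptable
replacement for interactive point-clicking, with no plotting-window
restriction.

Numerical notes:

* **Degenerate clusters.**  A duplicate/MZ cluster with complete data is a
  single point, and parent–offspring clusters are degenerate in $k_0$
  (opposite homozygotes are impossible when one allele is always shared
  IBD, so $\hat k_0$ is exactly 0 for every simulated pair).  Near-singular
  covariances get a $10^{-10}$ ridge on the diagonal; membership then
  reduces to the non-degenerate direction(s).  A side effect is that the
  *bivariate* coverage calibration only applies to genuinely 2-D clusters
  (unrelated, full sibs, half sibs, cousins): a cluster degenerate in one
  direction is covered at the 1-D rate implied by the 2-df threshold
  (≈0.986), and a point cluster at rate 1.
* **Coverage band.**  Estimated IBD coefficients are slightly
  heavier-tailed than bivariate normal, so fresh simulated pairs fall
  inside their own nominal-95% ellipse at a rate verified to lie in
  [0.90, 0.98] rather than exactly 0.95.
* **Ellipse boundary** membership is closed ($\le$), and ties in the exact
  HWE test are guarded with a $1+10^{-12}$ relative tolerance.

## Quality control

Subjects are filtered first (call rate $\ge$ 0.9 over SNPs), then SNPs:
call rate $\ge$ 0.9 over subjects, minor allele frequency $\ge$ 0.01 and
exact two-sided Hardy–Weinberg $p \ge 10^{-3}$, the latter two computed on
the reference pool to avoid case-enrichment artifacts.  These are
conventional GWAS-QC values, exposed as explicit configuration
(`filter_control()`); `filter = FALSE` bypasses QC entirely for data
already filtered in an earlier run.  The subjects-then-SNPs order makes the
SNP statistics reflect the retained subjects; filtering is monotone in its
thresholds and idempotent.

## The synthetic-data generator

`generate_fixture()` emulates a candidate-gene case–control panel: SNPs in
gene-like clusters (default 6 SNPs per gene, genes 10 Mb apart on 22
autosomes, 1250 SNPs, 200 subjects of which the first 52% form the
reference pool), with within-gene adjacent-haplotype correlation
`ld_strength` (default 0.6; 0.9 is used as the "strong LD" stress case) and
independence between genes.  Gene-level allele frequencies are uniform on
(0.1, 0.9) with small within-gene jitter, so within-gene LD near the
requested strength is always feasible.  Planted related pairs are generated
by gene drop from the same truth model and replace subjects in the
non-reference block, so the reference pool remains a population random
sample; a truth table records them.  Missingness is independent Bernoulli
(default 1%).

What the generator does *not* emulate: population structure or admixture,
genotyping error, sex chromosomes, allele-frequency spectra skewed toward
rare variants, and LD that extends beyond adjacent markers within a gene.
Passing tests on these fixtures therefore demonstrate correctness of the
estimation and simulation machinery and the LD-vs-independence contrast,
not robustness to structure or genotyping artifacts in real data.

## Problem sizes used by the tests

The test suite and acceptance script size their simulations as follows, as
a balance between Monte-Carlo resolution and a test run a developer will
actually wait for: parameter recovery uses 500 independent SNPs
(MAF $\sim U(0.05, 0.5)$), a 200-subject reference pool and 200 pairs per
relationship (mean $(\hat k_0,\hat k_1)$ within $\pm 0.03$ of theory);
ellipse calibration uses a 120-subject, 600-SNP LD fixture with 200
fitting and 400 fresh pairs; the end-to-end LD contrast runs five
200-subject, 1250-SNP strong-LD fixtures with two planted parent–offspring
and three full-sib pairs, analysed once with the fitted Markov model and
once under independence.  On those runs every planted pair is auto-flagged
under the LD model, while the independence analysis produces dozens of
false half-sib flags per fixture and the LD analysis essentially none —
the quantitative form of "ignoring LD makes reference clusters too tight".

## Known limitations

* First cousins are rarely distinguishable from unrelated pairs with
  candidate-gene data; `cousins` is therefore not in the default
  relationship set (nor is `user`).
* The moment estimators assume a homogeneous, non-inbred base population;
  the reference-cluster machinery nevertheless supports inbred *pedigrees*
  (e.g. an offspring of first cousins) for simulation.
* Detection of a planted pair is itself a coverage event: a true
  relationship falls inside its own 95% ellipse about 95% of the time, so
  single borderline pairs can be missed; `query_pair()` exists for exactly
  these cases.
* Only adjacent-marker LD is modelled; long-range LD (e.g. inversions)
  will widen study-pair clusters relative to simulated ones.
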