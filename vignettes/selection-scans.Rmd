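---
title: "Detecting selective sweeps in multi-population SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps in multi-population SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Livestock breeds under artificial selection accumulate localized excesses of
genetic differentiation around the selected loci. Given SNP-array genotypes
for a set of related populations (for instance a panel of sheep breeds split
into dairy and non-dairy trait groups), `sweepscan` asks: which genomic
regions are more differentiated than neutral drift can explain, and do the
regions found by different statistics — or by different studies — coincide
more often than chance would allow?

The package implements the full analysis chain: PLINK-text input and SNP
quality control, population-structure summaries, a Bayesian
F~ST~-outlier scan, the FLK and hapFLK haplotype-differentiation tests,
sweep-region calling, and a circular permutation test for interval-set
overlap. A tree-structured drift simulator generates data with known truth
for calibration and power checks.

## Quality control

`apply_qc()` filters SNPs in three ordered steps, each applied to the
survivors of the previous one:

1. unmapped SNPs and SNPs outside autosomes 1–26 are removed;
2. SNPs with a genotyping call rate strictly below 0.90 or a minor allele
   frequency strictly below 0.05 are removed (a MAF exactly at the threshold
   is kept — the thresholds follow the wording "lower than 90%" and a
   MAF threshold *of* 0.05 literally);
3. SNPs with a Hardy–Weinberg exact-test P-value at or below 0.001 are
   removed, the test being computed on all individuals pooled, which matches
   a default PLINK invocation; HWE departures at array SNPs are most often
   genotyping artefacts, which is why the filter is pooled rather than
   per-breed.

The HWE test is the exact conditional test on the heterozygote count
(`hwe_exact_test()`), summing the probabilities of all outcomes at most as
probable as the observed one — the PLINK convention — and is checked in the
test suite against a closed-form enumeration oracle for every genotype
configuration with up to 20 individuals.

## The drift model and the synthetic-data generator

All three scans share one null model: populations descend from a common
ancestor by pure drift. `simulate_frequencies()` draws each SNP's ancestral
frequency $p_0$ uniformly (default range $[0.05, 0.95]$) and propagates it
along a population tree; across a branch with drift coefficient $c$ the
descendant frequency is Beta-distributed with mean $p$ and variance
$c\,p(1-p)$ (the Balding–Nichols parameterization, shapes $p(1-c)/c$ and
$(1-p)(1-c)/c$). Genotypes are Binomial(2, $p_{pop}$) — Hardy–Weinberg
within populations — with independent missingness.

Selection is injected as a deterministic post-drift shift: at a selected
locus the frequency in each target population moves toward fixation by
$\delta (1-p)$, truncated to $[10^{-6}, 1-10^{-6}]$. This gives a
controllable single-locus effect size without a forward simulation.

Two properties of this design matter for interpreting results:

* **Reynolds distances halve the drift path.** With the ratio-of-sums
  Reynolds estimator used here (chosen because it admits exact small-case
  oracles), two populations that each drifted $c$ from the ancestor are
  separated by $D = -\ln(1 - (c_1+c_2)/2)$, i.e. half the summed branch
  drift, because the denominator term $p_i + p_j - 2 p_i p_j$ has
  expectation $2 p_0 (1-p_0)(1 - F_{ij})$. A neighbor-joining tree built
  from these distances therefore carries branch lengths of about $c/2$, and
  the pipeline doubles the branch lengths before converting the tree to the
  FLK kinship matrix so that $\mathrm{Var}(p_i) = F_{ii}\,p_0(1-p_0)$ holds
  in drift-variance units.
* **No linkage disequilibrium.** Genotypes are independent across SNPs given
  the frequencies. Multi-SNP sweeps are emulated by shifting a block of
  consecutive SNPs, which creates local frequency structure but not true
  haplotypes. Passing the calibration and power tests therefore shows that
  the statistics behave correctly under drift and detect frequency-block
  signals; it does not exercise recombination gradients, ascertainment bias
  of array SNPs, or bottleneck-induced LD, all of which real data contain.

The default star tree uses $c = 0.05$ per branch, a typical differentiation
level for related regional breeds; 26 chromosomes default to lengths
decreasing linearly from 275 Mb to 45 Mb, the scale of the sheep autosomal
karyotype. One seed drives each generator call in a fixed order
(frequencies first, then map and genotypes).

## The Bayesian F~ST~-outlier scan

`run_rjmcmc()` implements the logistic decomposition of locus-by-group
F~ST~: $\mathrm{logit}(F_{ST,ij}) = \alpha_i + \beta_j$, with $\alpha_i$ a
locus effect shared across groups and $\beta_j$ a group effect shared
across loci. Group allele counts are beta-binomial given the ancestral
frequency $p_i$ and concentration $1/F_{ST,ij} - 1$ (the Dirichlet
allele-frequency model in the biallelic case). Directional selection pushes
$\alpha_i > 0$; balancing or purifying selection pushes $\alpha_i < 0$.

Priors are $\alpha_i \sim N(0,1)$, $\beta_j \sim N(-1,1)$ and
$p_i \sim U(0,1)$ — the published defaults of the reference implementation
of this model. A reversible-jump move toggles each locus's $\alpha$ in and
out of the model with prior inclusion probability $1/(1+\text{prior
odds})$, using the $\alpha$ prior as the trans-dimensional proposal so that
the acceptance ratio reduces to the likelihood ratio times the prior odds.
Random-walk updates (ancestral frequencies on the logit scale with the
Jacobian included) are tuned by pilot runs into the acceptance band
$[0.25, 0.45]$ with multiplicative width steps of 1.25. The default run
plan is 20 pilot runs of 5,000 iterations, 50,000 burn-in iterations and
5,000 samples at a thinning of 10, with prior odds 10.

Per locus the scan reports the posterior inclusion probability $P$, the
posterior odds $P/(1-P)$ with $P$ clamped at $1 - 1/n_{samples}$, the
model-averaged posterior mean $\alpha$, and a q-value: loci are ranked by
decreasing $P$ and the q-value is the running mean of $1-P$ — the estimated
false discovery rate if the list were cut at that locus — with ties sharing
the worse value.

Power at a given effect size is governed by the pooled group allele counts
and by where the ancestral frequency sits: a shift $\delta(1-p)$ at $p$
near 1 is small, and with only ~50 alleles per group the Bayes factor for
inclusion rarely overcomes prior odds of 10 even for $\delta = 0.6$. The
packaged power checks therefore pool several populations per trait group
(16 populations of 25 diploids, eight per group — about the sample size of
a two-group 50K study) and plant signals at intermediate ancestral
frequencies, where a $\delta = 0.6$ shift is a 4–6 standard-deviation
displacement of the group contrast.

## FLK and hapFLK

`flk_statistic()` contrasts a SNP's population frequency vector $p$ with
its drift expectation: $\hat p_0 = (1'F^{-1}p)/(1'F^{-1}1)$,
$V = \hat p_0 (1 - \hat p_0) F$, $T_{FLK} = (p-\hat p_0 1)' V^{-1}
(p - \hat p_0 1)$, which is $\chi^2_{n-1}$ under neutrality in the
small-drift Gaussian limit. The kinship $F$ is the shared-branch-length
matrix of the rooted population tree (`kinship_from_tree()`); the suite
verifies the $\chi^2$ calibration on 20,000 neutral SNPs at drift 0.02,
where the Beta drift distribution is close to its Gaussian limit. SNPs
with $\hat p_0$ outside $(0,1)$ or with no differentiation return
statistic 0 and P = 1; populations with an absent frequency are dropped
with the degrees of freedom adjusted.

`hapflk_scan()` extends the contrast to local haplotype structure. A
fastPHASE-style hidden Markov model (`fit_cluster_model()`) assigns each
haplotype to one of $K$ clusters: across each inter-SNP interval a
haplotype either stays in its cluster or jumps to one drawn from local
cluster weights, and the unphased dosage is the sum of two Bernoulli draws
with cluster allele frequencies $\theta$. The forward–backward recursions
run over the $K^2$ ordered cluster pairs with factorized transitions;
chromosomes restart the chain. EM alternates exact E-steps with
closed-form M-steps (cluster frequencies, jump probabilities per interval,
local weights) until the log-likelihood gain drops below $10^{-4}$ or 100
iterations; the log-likelihood is asserted non-decreasing at every step and
a decrease beyond numerical tolerance aborts the run. Because cluster
labels are only locally identified, independent fits can swap labels along
the genome; all downstream use is label-free.

The hapFLK statistic averages, over independently seeded EM fits, an
FLK-type quadratic form on the per-population mean posterior cluster
memberships. Two whitening choices define the form. Population space uses
$(F + \mathrm{diag}(1/n_j))^{-1}$: the $1/n_j$ term accounts for averaging
memberships over $n_j$ individuals. Cluster space uses the pseudo-inverse
of the pooled within-population covariance of individual membership
vectors, which spans the $K-1$ free cluster dimensions. The within-
population covariance is preferred over the naive multinomial covariance
$\mathrm{diag}(q_0) - q_0 q_0'$ because posterior memberships are shrunk
toward their prior by an amount that varies strongly from SNP to SNP with
local cluster separability; the within-population covariance carries the
same shrinkage, so the null scale of the statistic stays comparable across
SNPs. With the naive form the neutral statistic is a scale mixture and no
global transformation can make its P-values uniform.

Defaults follow the published analysis design: $K = 20$ clusters and 30 EM
fits. The test suite runs reduced problems (K = 2–4, 2–3 fits, a few
hundred SNPs, 15 EM iterations) chosen so the whole calibration suite
completes in minutes on one CPU; the statistic's construction is identical
at full scale.

### Empirical null P-values

The exact null distribution of hapFLK is unknown, so raw P-values come from
a robust fit of the bulk of the genome-wide statistic
(`empirical_pvalues()`): the statistic is aligned by its median and
median-absolute-deviation scale to a $\chi^2_{df}$ candidate (aligned by
*its* median and MAD, so a minority of true signals cannot distort the
fit), and $df$ is chosen on a logarithmic grid in $[0.5, 400]$ to minimize
the Kolmogorov–Smirnov distance between the mapped statistic and the
candidate. An earlier variant that fixed $df$ by matching the standardized
upper quartile proved unstable — the statistic's MAD-standardized upper
quartile can fall outside the range attainable by the $\chi^2$ family,
pushing $df$ to a boundary and making the P-values grossly conservative —
which is why the distribution-wide fit is used instead. Each scan attaches
a uniformity diagnostic (decile histogram counts and the KS statistic
against Uniform(0,1)); on neutral simulations the KS distance is about
0.05, and the acceptance suite requires it below 0.08 with no decile
outside $[3\%, 20\%]$. Multiple-testing correction is Benjamini–Hochberg
(`fdr_qvalues()`, via `stats::p.adjust`).

## Sweep regions and the overlap permutation test

`call_regions()` collapses runs of SNPs with $P < \alpha$ into regions,
bridging up to `max_gap_snps` (default 2) non-significant SNPs; region
bounds are the flanking significant SNPs. Point outliers from the
F~ST~-outlier scan become ±1 Mb windows (`snp_windows()`); the 1 Mb
half-width is the value at which the packaged outlier table reproduces
exactly its nine printed co-localizations with earlier scans. For
overlap counting the windows are deliberately left unmerged — one window
per outlier SNP — so that the observed overlap count equals the number of
co-localized outliers; merging (the default elsewhere) would fuse the two
windows on chromosome 2 and undercount by one.

`circular_permutation_test()` assesses whether the overlap between two
interval sets exceeds chance. The chromosome-ordered SNP map is treated as
a circle; both sets become SNP-index ranges (intervals containing no SNP
are dropped with a warning); each of the 10,000 default replicates draws a
single uniform shift $d$ and rotates every query interval by $d$ SNPs with
wrap-around (intervals crossing the seam split into two ranges). Overlap
is counted in index space — the shift operates in SNP units, so counting
must live in the same space. The bootstrapped P-value is the proportion of
replicates whose count *strictly exceeds* the observed one (the literal
reading of the procedure); a $(b+1)/(N+1)$ estimator is available via
`plus_one = TRUE` for users who prefer a never-zero estimate. Note that the
strict convention is exact only when overlap counts are well spread: on
tiny maps where most shifts tie at the same count, excluding ties makes the
P-value anti-conservative, whereas the tie-inclusive rank P is always a
valid conservative test (the suite checks both properties). At the scale of
a 50K-array map the tie mass at the observed count is negligible.

## Orchestration

`run_pipeline()` sequences simulation (optional), QC, structure
(frequencies, Reynolds distances, NJ tree, kinship, identity-by-state MDS
via classical scaling), the F~ST~-outlier scan on a configured
population-to-group map, FLK and hapFLK, region calling, and the overlap
permutation test between the two scans' sweep sets. One divergent
population can be excluded from the selection scans while remaining in the
structure summaries, mirroring the usual treatment of a genetically distant
breed. Every stochastic stage derives its seed from the global seed at a
fixed offset; rerunning a configuration reproduces every output
bit-for-bit, and written outputs carry the seed and a configuration digest
in their header.

## Numerical choices

* Frequency clamps at $10^{-6}$; F~ST~ clamps at $10^{-8}$ in the
  beta-binomial likelihood; cluster allele frequencies kept in
  $[10^{-6}, 1-10^{-6}]$.
* Reynolds $\theta \ge 1$ (complete fixation) maps to a documented cap of
  50; jointly monomorphic SNPs contribute to neither sum.
* NJ negative branch estimates are floored at 0 after construction;
  rooting is by midpoint unless an outgroup is configured (no outgroup is
  assumed by default because none is dictated by the study design).
* Classical MDS drops non-positive eigenvalues with a warning.
* EM initialization adds seed-controlled uniform jitter to marginal
  frequencies and weights; jump probabilities start at 0.05 within
  chromosomes and are fixed at 1 at chromosome starts.
* The EM monotonicity guard tolerates $10^{-6}(1+|\ell|)$ of rounding.
* Degenerate inputs error early with the offending SNP, interval, stage or
  population named.

## Known limitations

* The simulator has no recombination or LD; hapFLK's advantage over FLK is
  demonstrated on frequency-block signals, not true haplotype sweeps.
* FLK's $\chi^2$ null is exact only in the small-drift Gaussian limit; at
  drift 0.05 and above the tails deviate visibly from $\chi^2$.
* The kinship estimated from Reynolds distances relies on the doubling
  convention described above; with very asymmetric trees the factor is
  approximate to first order in the drift coefficients.
* The F~ST~-outlier sampler explores a spike-and-slab posterior with
  moderate per-locus evidence; at fewer than ~100 alleles per group,
  posterior inclusion probabilities for moderate shifts stay well below 1
  regardless of chain length.
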