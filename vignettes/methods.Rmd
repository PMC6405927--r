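---
title: "Models and methods behind popadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popadapt)
```

popadapt separates *adaptive* from *neutral* population divergence in a
clonal-genotype expression study, and cross-references the expression-level
verdict with sequence-level neutrality statistics. This vignette is the
package's own account of the models, the defaults, and the choices made
where the design was genuinely open.

## The study design and the synthetic generator

The target design is `P` populations x `G` clonal genotypes x `R`
biological replicates, default 4 x 6 x 3 = 72 RNA-seq libraries, with
neutral marker loci (microsatellite-like, multi-allelic) genotyped in a
larger per-population sample (default 40 diploids), per-transcript phased
haplotypes, CDS sequences, and orthology-cluster assignments.

`sim_config()` fixes the generator's conditions once:

* `theta_true = (0.1, 0.2, 0.3, 0.4)` — per-population drift coefficients
  spanning weak to strong drift, so estimator bias and rank recovery are
  both visible.
* `sigma_a2 = 0.04`, `sigma_g2 = 0.04` (log2 scale) — modest population and
  genotype effects (SD 0.2 log2 units), the order observed in bulk RNA-seq
  between close populations; neither dominates the NB noise.
* `nb_dispersion = 0.2` — a typical bulk RNA-seq dispersion; count variance
  `mu + 0.2 mu^2`.
* `frac_de = 0`, `frac_selected_expression = 0` — **the generator is null by
  default**; effects are planted explicitly per experiment (`de_log2fc = 2`
  for population-exclusive upregulation; the selection shift defaults to
  five drift-null standard deviations, `5 * sqrt(2 * max(theta) * sigma_a2)`).
* coalescent: `n = 12` haplotypes per population (2 per clonal genotype),
  `theta_w = 5` per transcript — roughly 15 segregating sites per locus,
  enough for a defined Tajima's D in most transcripts without saturating
  the 1 kb coordinate space.

Marker loci follow the F model exactly: ancestral frequencies
`pi_l ~ Dirichlet(1)`, population frequencies
`p_pl ~ Dirichlet(pi_l (1 - theta_p)/theta_p)`, multinomial counts. Neutral
expression effects are `a ~ MVN(0, 2 diag(theta) sigma_a2)` — the generator
*is* the drift null the H test assumes. Off-diagonal coancestry is zero in
the generator (independent drift from a shared ancestor); the H test
nevertheless accepts arbitrary PSD coancestry matrices so externally
estimated admixture structure can be supplied.

What the generator does **not** emulate: library-size artefacts beyond
scalar size factors, count outliers, GC/length biases, isoform-level
expression, recombination within transcripts (deliberate: the loci are
transcript-scale), indels, genotyping error, and linkage between
transcripts. Passing tests therefore demonstrate correctness of the
statistics under their stated models, not robustness to those artefacts.

One global seed drives everything; subsystem streams are derived by a
labelled string hash (`derive_seed()`), so stages are independently
reproducible and the end-to-end manifest hashes are bit-stable.

## Differential expression and the DET sign rule

Normalization uses median-of-ratios size factors computed on transcripts
with no zero count (as the exp-median-log form, matching the canonical
implementation). Dispersions come from a pooled method of moments,
`phi = max(1e-8, (s2 - m)/m^2)` with `s2` the within-population variance of
normalized counts — deliberately plain: the DET rule downstream consumes
only the fold-change sign and the BH-adjusted p-value, so shrinkage
machinery and outlier replacement (Cook's distance) are out of scope here.
Wald contrasts use `log2FC` of group means with a 0.5 pseudocount and a
standard error from the NB Fisher information, `(1/mu_g + phi)/n_g` per
group. BH runs within each pair across transcripts; a tie at
`p_adj = 0.05` counts as significant.

A transcript is a DET of population X iff all `P - 1` contrasts involving X
are significant with X upregulated. No minimum |log2FC| is imposed beyond
the sign — the rule is exclusive by construction, so the four lists are
disjoint and, with `nonDET`, partition the transcriptome.

Variance partitioning uses the two-level nested ANOVA on
`log2(normalized + 1)`: population tested against the genotype-within-
population mean square (df `P-1`, `G_tot - P`), genotype against the
residual (df `G_tot - P`, `N - G_tot`), BH per factor, categories at 0.05.

## Coancestry estimation

The F-model likelihood is marginalised over the population frequencies,
giving a Dirichlet-multinomial in `(theta, pi)`. The sampler is
componentwise MH: a logit random walk on each `theta_p` (uniform prior on
(0.001, 0.999), proposal SD 0.3) and a Dirichlet proposal centred on the
current `pi_l` (concentration 50, +0.05 floor) per locus, both vectorised
so one iteration costs two likelihood sweeps. Desk-scale defaults are
20,000 iterations, burn-in 2,000, thinning 100 (one tenth of a heavyweight
run; all three are arguments). Draw count is `(n_iter - burn_in)/thin`,
burn-in counted in raw iterations. Acceptance below 1% triggers a warning.
The posterior-mean drift coefficients carry a small upward bias at small
locus numbers (the ancestral frequencies are uncertain); the recovery
tests bound it at desk scale.

## The H statistic

Per transcript the model is `y_pg = mu + a_p + e_pg` on `log2(mean + 1)`
genotype means, `e ~ N(0, sigma^2)`, with the drift null
`a ~ MVN(0, 2 sigma^2 theta)`. Two decisions matter here:

1. **The drift-null scale is the within-population genetic variance.** With
   clonal genotypes, the spread of genotype means within a population
   estimates the (broad-sense) genetic variance, and neutral quantitative-
   genetics theory scales the expected between-population divergence as
   `2 theta` times exactly that variance. Leaving the between-population
   scale as a free parameter identified only by the `P = 4` population
   effects makes the Mahalanobis norm ancillary — every transcript then
   scores the same regardless of its divergence, and no calibration is
   possible. Tying the scale to the within-population variance (estimated
   with `P(G-1)` degrees of freedom) restores both calibration and power.

2. **H is computed from the exact pivot.** Conditional on a coancestry draw
   `theta^(s)`, the centred population means have covariance
   `sigma^2 C (2 theta + I/G) C'` under the null (`C` the centring
   projector), independent of the within-population sum of squares. The
   Mahalanobis norm over the variance estimator is therefore exactly
   `F(P-1, P(G-1))`-distributed, and the exceedance probability against a
   null replicate integrates analytically to the F cdf:
   `H = mean_s pf(F^(s), P-1, P(G-1))`. This is the same quantity as the
   posterior-predictive "observed exceeds replicate" probability, with the
   replicate distribution evaluated in closed form — zero Monte-Carlo noise
   from the replicate, exact uniformity under the null given `theta`, and
   monotone power in the planted shift. A Gibbs/MH sampler (conjugate
   updates for `mu` and `a` in the eigenbasis of `theta`; log random walk
   with a half-Cauchy prior, scaled to the sample SD, for `sigma`) still
   runs to report posterior summaries of the effects and variances.

`H >= 0.95` (inclusive) flags a transcript as more diverged than drift
explains. Genotype means are log2(x+1)-transformed before testing; the
pseudo-count keeps zero-expression genotypes finite. Transcripts with zero
variance across all values are flagged undefined rather than scored.

## Sequence-level statistics

* **Variant filtering**: fail if `QD < 2.0`, `FS > 30.0` (strict), or the
  SNP lies in any 35-bp window holding >= 3 SNPs (3 is the upstream
  caller's default cluster size; only the window width is usually quoted).
  Missing annotations fail with their own reason. Flags are idempotent and
  order-independent.
* **LD pruning**: transcripts are short, so pruning is an exhaustive greedy
  scan in position order within each transcript, dropping a SNP whose
  dosage `r^2` with any retained SNP exceeds 0.2. Zero-variance SNPs are
  retained (undefined correlation treated as 0).
* **Tajima's D**: classical constants from the closed forms; p-values from
  the beta approximation of the null density rescaled to D's theoretical
  support (two-sided at 0.05) — the usual choice when a p-value is quoted
  with no method. `S = 0` leaves D and p undefined.
* **Inbreeding**: `F = (O_hom - E_hom)/(L - E_hom)` with the small-sample
  `2n/(2n-1)` correction on expected heterozygosity, the convention of the
  standard VCF tooling.
* **FST**: Weir–Cockerham variance components in the haploid form
  (phased allele copies), with the `nc` correction for unequal sample
  sizes. Identical populations sit at the estimator's known small negative
  value `-1/(nc - 1)`, not exactly zero.

### The outlier envelope

The scan simulates single-mutation biallelic SNPs under a symmetric island
model (the package's own structured coalescent; one mutation placed
proportionally to branch length), tunes the scaled migration rate by
bisection until the mean simulated FST matches the observed mean (pilot
runs of 400, tolerance 0.015, warning beyond 0.05), then bins the
simulated loci into 12 equal-occupancy heterozygosity bins and flags
observed SNPs whose empirical tail probability within their bin is at most
`(1 - CI)/2`. The desk default is 20,000 simulated loci (configurable;
heavyweight runs use more). Two numerical caveats are deliberate:

* The empirical tail probability uses the standard `(+1)` correction, so
  ties make the test conservative: with 48 sampled haplotypes the FST null
  has sizeable atoms, and the realised flag rate under neutral data sits at
  roughly a third to a half of the nominal `1 - CI`. It never exceeds it.
* The per-SNP empirical p-value cannot be smaller than `1/(n_bin + 1)`;
  after BH across thousands of SNPs a *single* true outlier can therefore
  never stay significant at desk-scale simulation counts. The
  `class_envelope` column is the scan's classification; the `class` column
  additionally applies BH demotion and is the FDR-controlled call for
  set-level statements. Transcript-level labels (`NC`, `noOL`, `Bal`,
  `Div`, `BalDiv`) aggregate per-SNP classes.

The simulator is infinite-sites rather than the infinite-allele model of
the classical implementation; for biallelic SNP envelopes conditioned on
heterozygosity the difference is immaterial at these sample sizes.

## Divergence screen

Only clusters holding DETs from at least two populations are screened
(`no-cluster` and `1Pop` DETs are excluded). Pairs are aligned at the
protein level (global Needleman–Wunsch, BLOSUM62, gap open 10 / extend 1)
and the gaps back-propagated as codon triplets; frame 1 is always assumed
(ORF prediction is out of scope). Pairs that are not codon-multiples or
contain internal stops are skipped with a reason and classed `undefined` —
in this screen that is signal, not failure: frameshifted chimeric
assemblies are exactly the sequences that stop translating. K2P distances
use the closed forms; the gamma variant defaults to shape `alpha = 1`
(rate heterogeneity is usually cited without a shape; 1 is the common
default and the `alpha -> Inf` limit recovers the uncorrected distance).
Saturated pairs (`1 - 2P - Q <= 0`) are reported `undefined` rather than
capped. The cutoff `d = 2` separates inparalogs/isoforms from putative
misassemblies.

The generator's chimeras splice the second half of an unrelated CDS out of
frame onto a cluster partner's first half (length kept a codon multiple);
with ~100 out-of-frame codons the probability of escaping an internal stop
is under 1%, so planted chimeras are recovered as `undefined`/saturated,
while inparalogs (point mutations at rate 0.05, transition-biased,
stop-avoiding) stay far below the cutoff.

## Flow classification

Step 2 splits at `H >= 0.95` (the inclusive rule wins over the overlapping
caption convention). Step 4 requires significance (`p <= 0.05`) for a
signed Tajima call by default — exposed as `require_significance` since
the sign-only convention also circulates; populations with undefined D
count as nonsignificant, and only transcripts undefined in *all*
populations fall into the `Mixed-undefined` catch-all. `PosNeg` requires
every population significant with mixed signs. DETs missing a step label
fall back (`H_lt`, `NC`, `Mixed-undefined`) with a warning so the flow
always partitions the DET set.

## Problem sizes and limitations

The package's default problem sizes (1,000-transcript recovery studies,
20,000-locus envelopes, 20,000-iteration marker chains, 600-iteration
per-transcript chains) are chosen as the smallest sizes at which the
calibration properties are statistically decisive; all are arguments and
scale up linearly. Known limitations: the H test assumes a balanced design
and pools replicate noise into the genetic variance (at `R = 3` replicates
this inflates the drift-null scale slightly, making the test mildly
conservative on count data); the NB contrasts ignore genotype as a random
effect (the DET rule's three-way intersection compensates in practice);
the outlier scan's conservatism under heavy ties is documented above; and
the coalescent has no recombination, so within-transcript haplotype
structure is exchangeable.
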