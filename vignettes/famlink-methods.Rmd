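---
title: "Methods: linkage mapping in very large sibships with famlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage mapping in very large sibships with famlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famlink implements a family-based linkage analysis of a quantitative trait
(height is the motivating case) in cohorts of *very large* nuclear families
— 10 to 20 siblings per family — drawn from a founder population.  The
design exploits two frequency-amplification effects: a variant carried
heterozygously by one parent reaches ~25% frequency among that family's
children regardless of its population frequency, and in a founder population
(small effective size, strong drift) variants that are rare in cosmopolitan
reference panels can be common.  This vignette describes the models and
algorithms, the tunable parameters, what the synthetic cohort generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## 1. The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated against its ground truth.

* **Genome.** 1–22 autosomes with hg19-proportional physical lengths,
  rescaled by a single factor (`scaled_genome(total_bp, total_morgans)`).
  Recombination is uniform (default 1 cM/Mb) and crossovers are placed by a
  Haldane (no-interference) process: a Poisson count per chromosome with
  mean equal to the genetic length in Morgans, positions uniform.  The
  Haldane choice is the standard minimal model; crossover interference
  would slightly reduce the variance of segment lengths but not the means
  that the analyses below depend on.
* **Founder pool.** Parents draw two haplotypes (without replacement) from a
  finite pool of `n_haplotypes` phased haplotypes — the small-pool analogue
  of a founder population's effective size; unrelated parents therefore
  share background haplotypes, as in the real cohort.  Most SNP frequencies
  follow a uniform(0.05, 0.5) spectrum; `n_elevated` SNPs are
  "founder-elevated": frequency < 1% in the cosmopolitan reference but
  >= 5% in the pool, realized as exact allele counts so the contrast holds
  by construction.  `founder_frequency_contrast()` reproduces the
  rare-here/common-there comparison with a binomial subsampling control at
  the reference's sample size.
* **Phenotype.** Latent standardized height
  `z = sum_j beta_j x~_j + g + c + e` with `x~` the pool-frequency
  standardized dosage, a few large-effect causal variants (`beta` in SD per
  allele), a polygenic background bringing total narrow-sense heritability
  to `h2_total` (default 0.86, the pedigree estimate after quadratic age
  correction), an optional shared-sibship fraction (default 0; the
  random-QTL null downstream exists precisely to absorb such confounding),
  and residual noise.  Measured height is
  `sex mean + sex SD * z + HeightLoss(age, sex)` (male 172.7 ± 5.7 cm,
  female 161.6 ± 5.5 cm), with 4 technical repeats of SD 0.1 cm rounded to
  0.1 cm — the instrument precision of the design.
* **Array noise.** Calls are flagged low-quality at 7.8%, no-called at
  1.3%, and miscalled at 1/2247 (high-quality) or at a low-quality rate
  back-computed so the overall error is 1/110 — the measured error
  structure of a dense biobank array.
* **Not emulated:** linkage disequilibrium beyond what the finite pool
  induces, mutation, genotype intensity/clustering, X/Y/mito chromosomes,
  and population stratification.  Passing tests therefore demonstrate the
  statistical machinery under Mendelian transmission with realistic noise,
  not robustness to LD structure or cryptic relatedness beyond the pool
  effect.

One caveat worth knowing: with a single draw of polygenic effects and few
families, the *realized* between-family genetic variance fluctuates
strongly (long shared haplotype blocks make the effective number of
independent polygenic dimensions small).  Sibling phenotype correlations
approach the theoretical `0.5 h2` only when averaged over effect draws or
on many families/long genomes; the tests are constructed accordingly.

## 2. Phenotype correction

Adults begin to lose height around age 30 with a linearly increasing rate,
so integrating the published loss-rate fits gives a piecewise-quadratic
loss: 0 up to the onset and `-0.00208 (age-30)^2` cm for men,
`-0.003205 (age-30)^2` for women.  The derivation yields onsets 29.8/29.6;
because ages are recorded in full years the working model rounds the onset
to 30 — the rounded form is authoritative.  `correct_heights()` averages
the repeats (mean by default; median available), adds the lost height
back, and z-scores within sex before pooling.  The z-score uses the sample
SD (n-1); the population-SD convention is a documented option.  A linear
age correction, re-fit from the data at hand (`height ~ sex + age`) rather
than hard-coding someone else's coefficients, is available for the
comparison analysis: on data simulated with quadratic shrinkage the
quadratic correction yields at least the heritability of the linear one
(paired test over seeds).

## 3. IBD reconstruction without parental genotypes

The core of the package.  For every sibling pair, each informative SNP
(not identically homozygous in all siblings of the family; low-quality and
missing calls excluded per pair) is classified: opposite homozygotes imply
0 alleles shared, het-vs-hom implies at most 1, identical calls are
consistent with 2.

**Pairwise calling** is anchored on qualifying runs: at least 3 evidence
sites of one class spanning at most 2 Mb (class 0) or 1 Mb (classes 1/2) —
the run requirement suppresses isolated genotyping errors.  Two
interpretive choices were open and are resolved as follows:

* *Run chaining vs short 2-segments.*  A naive bp-gap chain of 1-evidence
  sites silently bridges short 2-shared segments (which contain no
  contradicting sites at all).  A chain therefore also breaks at
  `pure_break = 10` consecutive contradiction-free identical-call sites,
  which then qualify the gap as a 2-shared region.  Under 1 allele shared
  roughly half the informative sites are het-vs-hom, so a pure stretch of
  length k has probability ~0.5^k: k = 10 keeps the per-site false-break
  rate below 1e-3 while making 2-segments of >= 10 sites detectable.
* *Boundary placement.*  An anchored region is extended past its outermost
  evidence site by the mean within-anchor evidence spacing — the
  posterior-mean position of the true boundary given that evidence of the
  class stopped appearing (class-0 evidence occurs at only ~10% of sites
  inside a 0-region, so the last opposite-homozygote sits well short of
  the true boundary).  Residual slack between anchored regions is split at
  the midpoint.  This keeps the genome-wide sharing fractions unbiased;
  with the naive last-marker midpoint convention the 0-fraction is
  systematically shrunk by several percent.

**Family reconciliation** pools the boundaries of all C(S,2) pairwise
tracks (clustered within ~6 median marker spacings), takes per-pair
majority states per segment, and fits, at every segment, two sibling
bipartitions — one per parent — whose implied shared-allele counts
override as few pairwise states as possible (`fit_bipartitions()`: greedy
construction, single-sibling local search, and an exhaustive scan over all
2^(S-1) maternal bipartitions with pruning when a residual cost remains
and S <= 12; beyond that the greedy+local path stands alone).  Moving
along the chromosome, configurations are propagated by temporal
continuity — prefer the previous labels, then single label changes (one
change = one recombination) — in *both* directions, and the forward and
backward paths are stitched by dynamic programming that trades overridden
pair states (weight 2) against label-change events (weight 1).  The
bidirectional pass matters because segments where the two parental
bipartitions coincide are locally unidentifiable and a one-way greedy walk
can lock in the wrong branch.

Finally a **site-likelihood polish** re-scores suspicious segments (those
with contradicted evidence or multi-label boundaries) directly against the
per-site evidence classes under a simple emission table
(P(class | state); opposite homozygotes essentially impossible under
states 1/2, small error masses elsewhere), charging `lambda = 4` log-units
per extra label change as a recombination prior.  This repairs segments
whose pairwise majority states were smeared — e.g. a short 0-segment seen
by a single pair.  Every retained breakpoint is then re-localized by
maximizing the two-sided evidence likelihood of the affected pairs over
the flanking window, which concentrates all pairs' information on the
crossover interval; localization is ~1 marker spacing in noiseless data.

Calibration on synthetic data: single-pair calls recover the truth over
~98% of the genome at cohort-like marker density (boundary jitter
dominates); the reconciled family chain recovers the true inheritance
vectors — up to the per-chromosome label and parent relabelings that are
genuinely unidentifiable without parental genotypes — over >= 99.9% of the
genome in noiseless 12-sibling families, and the pairwise sharing
fractions land on the 25/50/25 expectation within fractions of a point.
The manual curation step of large mismatch blocks in the original workflow
is replaced by the automated polish/refinement passes above.

## 4. Haplotype phasing

At every SNP the siblings fall into at most four grandparental groups,
each carrying a known pair of parental haplotypes; the group consensus
dosages define the linear system `dosage(group) = x_a + x_b` over the four
binary alleles, solved exactly by enumeration of the 16 assignments.
This subsumes the rule hierarchy (homozygous groups fix both haplotypes;
propagation through groups sharing one haplotype) and flags contradictions
(left unresolved and counted).  Parents, when genotyped, are matched to a
haplotype pair by genotype compatibility on already-solved sites (accepted
below 1% mismatch per chromosome — the tolerance is a package choice) and
then contribute their own equations.  Within-family phase resolves ~95% of
haplotype sites on cohort-like synthetic data.  Remaining sites are filled
from a panel of the other families' phased haplotypes: the longest
haplotype matching on both flanks donates its allele (flank length =
consecutive matching solved sites, summed over both sides); contradicting
equal-length matches fall to a majority vote; with no usable information
the call defaults to the B allele — an array-convention constant kept
explicit and counted so its impact can be bounded.

QC compares observed calls with the calls inferred back from haplotypes
and inheritance vectors: the overall mismatch rate matches the raw array
error (~1/110) while the high-quality-only rate drops several-fold —
errors concentrate in low-quality calls, and the inferred genotypes are
*more* accurate than the observed ones (multi-sibling error correction),
which is why downstream variance analyses use them.  Blocks of clustered
mismatches adjacent to recombination breakpoints (mismatches appear only
where the two parental haplotypes differ, so blocks tolerate gaps of up to
10 matching sites) flag misplaced breakpoints.

## 5. The linkage scan

At every grid position (5 kb at full scale; a parameter) and for each
parent, siblings split by inherited haplotype and the contrast R² with
corrected height is computed — for the real heights and for `n_perm`
within-family permutations of the heights with the genetics held fixed.
One permutation per family per replicate is applied identically across the
genome, so replicates are coherent genome scans.  The local P of a score
is the fraction of permuted replicates reaching an equal or larger R² at
that position (raw counts; a local P of zero is representable); each
permuted replicate is scored against the *other* replicates.  This
leave-self-out detail matters: counting a replicate against itself floors
permuted local P at 1/n_perm while the real scan can reach 0, which breaks
real/permuted exchangeability and inflated null QTL counts about
three-fold in calibration runs.  The per-family local P is the minimum
over the two parents (capturing dominance-like signals); a parent
uninformative at a position contributes local P 1.

Families are combined by averaging local P values; the genome-wide
empirical P of a score is its rank in the pooled (replicate x position)
permutation distribution — this denominator makes P values near 2e-5
attainable with 1000 replicates, consistent with the reported significance
levels; the per-replicate expected-count reading of the same distribution
is available as a diagnostic.  LOD = one-sided chi-square(1) quantile of
2P over 2 ln 10, anchoring LOD 3.6 at P ~ 2e-5 (LOD 0 at P >= 0.5); for
LOD conversion only, genome-wide P is floored at half the smallest
resolvable rank.  QTLs are local maxima above threshold merged within
33 Mb (the empirical LOD decorrelation distance, recomputed by
`estimate_qtl_separation()` as the distance at which the mean absolute LOD
difference first reaches its median level), with 1-LOD-drop intervals
truncated at ±33 Mb.  The FDR sweep compares observed QTL counts against
the identical procedure on every permutation replicate: P = fraction of
permutations with an equal or larger count, FDR = expected/observed
(capped at 1), estimated true = observed − expected.

## 6. Variance components

GRMs follow the standard standardized-dosage formula with sample allele
frequencies; monomorphic SNPs are dropped and missing dosages
mean-imputed.  `reml_fit()` implements multi-component EM-REML
(non-negativity by projection to a tiny floor, tolerance 1e-6 on the
restricted log-likelihood, at most 2000 iterations; the log-likelihood is
non-decreasing along the EM path and asserted so in tests), with Fisher
information SEs and delta-method SEs for variance *fractions*
(total = all components + residual, the usual convention).  An
average-information update after a 5-iteration EM warm-up (`method="ai"`)
gives the same optimum in ~10 iterations and is used where many fits are
needed; duplicated (non-identifiable) relatedness matrices are dropped
with a warning.

The cross-validation design splits families 2/3 train : 1/3 test (19:10 at
the cohort's geometry), with participant balance within ±2 enforced by
rejection sampling.  QTLs are mapped on training families only (a
train/test overlap is a hard error), the k = 100 nearest SNPs per peak
form the QTL GRM on the held-out families, and a joint model with the
whole-genome GRM (and optionally a known-variants GRM) is fit; the same
fit is repeated with random QTL-like segments matched in number, SNP count
and minimal spacing (drawn per split; the minimal spacing defaults to the
real QTLs' minimal pairwise distance).  The reported quantity is
median(real) − median(random) per threshold, with a bootstrap-over-splits
SE of the median difference (the original SE-of-the-median estimator is
unstated, so the bootstrap is documented as the package's choice).  The
subtraction centres the estimate on zero for null cohorts and makes the
estimate conservative when random segments overlap real QTLs.

Per-chromosome partitioning lets one GRM per autosome compete jointly and
correlates the fractions with chromosome length and with each chromosome's
top LOD, with a leave-top-chromosome-out recomputation;
`infinitesimal_simulation()` draws phenotypes with i.i.d. normal effects
on every SNP at fixed total heritability and re-runs the partition,
providing the null distribution against which a disproportionate single
chromosome is judged.

## 7. Analytic power

`linkage_power()` evaluates the noncentral-F power of the contrast test:
`lambda = f n (MAF − MAF²) β² / (1 − 0.5 (h² − 2 (MAF − MAF²) β²))`,
df1 = 2f, df2 = fn − 3, with the critical value taken from the central F
quantile at the chosen significance level (pointwise, from a LOD threshold
via the one-sided chi-square conversion, or supplied directly — both
interpretations are exposed).  The published code snippet for this
calculation applies the F tail directly to the significance level rather
than to the F critical value; the package implements the mathematically
stated formula (quantile first), which satisfies power = alpha exactly at
β = 0 and matches numerical quadrature of the noncentral-F density to
1e-6.  The ambiguous bracket in the noncentrality denominator is read as
`1 − 0.5 (h² − 2 (MAF − MAF²) β²)`, the only parse consistent with the
surrounding derivation.

## 8. Problem sizes, determinism, limitations

The analysis scripts and tests run desk-scale geometries — typically 4–22
chromosomes totalling 20–350 Mb with the genetic length kept realistic
(up to 35 Morgans), 1,500–20,000 SNPs, 4–29 families, 60–400 permutations
— chosen so each stage completes in seconds to a few minutes on one core;
the full-cohort geometry (630k SNPs, 1000 permutations) runs through the
same code paths.  Every stochastic entry point requires an explicit seed
and named substreams derive per-stage seeds from a single root
(`run_pipeline()`), so reruns are bit-identical; the pipeline manifest
records md5 hashes of every output.

Known limitations: pairwise IBD boundaries retain ~1 marker-spacing
jitter, and segments where both parental bipartitions coincide are
intrinsically ambiguous until flanking evidence resolves them (the
bidirectional stitch handles most, not all, of these); reference-panel
phasing scans flanks in plain R and is the slowest step at scale; the
min-over-parents local P makes per-family P values conservative rather
than uniform (only the genome-wide calibration is relied on); and the
cross-validated variance above the null is conservative by construction
(random segments can overlap real QTLs), increasingly so at permissive
thresholds.
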