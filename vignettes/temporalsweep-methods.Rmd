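---
title: "Detecting temporal selective sweeps with temporalsweep: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting temporal selective sweeps with temporalsweep: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temporalsweep)
```

# The problem

A beneficial allele sweeping through a population drags linked variation
with it: diversity collapses around the selected site, differentiation
against an unaffected population rises, and haplotypes stay unusually long.
When the same wild population has been sampled at several time points
spanning the sweep's fixation — as in temporally resequenced field cohorts
— these signatures can be tracked through time and candidate loci can be
cross-validated between statistics, between time points, and against
differential-expression evidence.

`temporalsweep` implements that full analysis path: post-calling variant
filters, a joint windowed F\_ST / diversity-ratio outlier scan, exhaustive
leave-one-out resampling of the scan, phased-haplotype statistics (EHH,
iHS, XP-EHH), per-SNP Fisher exact association with LD summaries, and
gene-set overlap / functional-term enrichment. A forward Wright--Fisher
simulator with a planted hard sweep generates fully known test data, so
every claim the package makes about its own behaviour is backed by a test
against ground truth or an independent brute-force oracle.

# The scan

For two sample groups — a focal population against an unselected control
population, or a later time point against an earlier one — the genome is
tiled with 10 kb windows advancing by 2.5 kb. Per window the package
computes:

* **Nucleotide diversity** $\pi$ per group: per site the unordered
  pairwise-difference probability $c_0 c_1 / \binom{n}{2}$ over the $n$
  non-missing allele copies, summed over sites and divided by the full
  window length in bp. Monomorphic and absent positions therefore count as
  zero diversity, the convention of windowed-diversity tools; a per-SNP
  average would instead confound diversity with SNP density.
* **F\_ST** by the Weir--Cockerham (1984) variance components $a, b, c$,
  combined as the ratio of sums $\sum a / \sum(a+b+c)$ over the window.
  Slightly negative estimates are kept: clamping at zero would distort the
  empirical distribution that the outlier quantiles are computed from.
* **The diversity log-ratio** $\log_2(\pi_{control}/\pi_{focal})$. The log
  base is cosmetic — outlier calling is quantile-based, and the joint
  outlier set is invariant to any monotone transform of either statistic
  (this invariance is tested). A window whose focal diversity is exactly
  zero while the control retains variation is the strongest possible sweep
  signal and ranks above every finite value; windows with no variation in
  either group are unusable.

Windows in the top 5% of **both** statistics become candidate windows;
overlapping or book-ended candidates merge into candidate regions, and any
gene model with at least 1 bp of (half-open) overlap with a region becomes
a candidate gene. Quantiles are empirical order statistics over usable
windows, genome-wide, with inclusive thresholds so ties are kept — a
deterministic, tie-safe rule (a per-chromosome mode exists behind a flag).
Windows need at least `min_snps = 3` informative SNPs to be usable;
trailing chromosome-end windows are computed but excluded from quantile
estimation because their shorter span biases per-bp diversity.

For temporal comparisons the earlier time point takes the control
(numerator) role, so ongoing diversity loss at the later time point raises
the ratio.

An exclusion interface removes user-specified intervals (for instance a
known region of extreme long-range linkage, such as an X-linked wing-morph
locus) from the scan, the resampling and the enrichment universe before
any quantile is computed; association and LD scans intentionally ignore
the exclusion, since they are run genome-wide.

# Resampling validation

Field samples of ten individuals per year are small enough that a single
unusual individual can create or destroy outlier windows. The validation
treats this directly: for a comparison of two groups of ten, all ten
leave-one-out subsamples of each group are enumerated and the full scan is
re-run on every ordered pair — $10 \times 10 = 100$ iterations, exactly
the "ten scenarios per group" design. Every annotated gene receives a
support statistic: the percentage of iterations in which it was a
candidate. The enumeration is exhaustive, so the procedure is fully
deterministic; a random-pairing mode is unnecessary at these group sizes.

The retention threshold is the smallest support value inside the top 1% of
the genome-wide support distribution, zeros included — computing the
threshold over candidates only would be circular. Candidates at or above
the threshold are retained. With all-zero support the threshold
degenerates to zero and nothing is excluded (with a warning).

# Haplotype statistics

From phased haplotypes, EHH at distance $x$ from a core SNP is the
probability that two random haplotypes carrying the core allele are
identical over the inclusive interval from the core to $x$; it starts at 1
and is non-increasing. iHH integrates EHH over physical distance by
trapezoids until EHH falls below 0.05 (the terminal trapezoid is
included), with truncation flagged at chromosome ends, at inter-SNP gaps
above 200 kb, and beyond 1 Mb — the customary defaults of the standard
tool chain, all configurable.

* **iHS**: $\ln(\mathrm{iHH}_{ancestral}/\mathrm{iHH}_{derived})$ per core
  SNP with minor-allele frequency ≥ 0.05, standardised to z-scores within
  20 equal-width derived-allele-frequency bins (sparse bins merge with
  their nearest neighbour). With no outgroup the reference allele is taken
  as ancestral; swapping the polarity negates every raw score, which is
  tested. Truncated cores are dropped before normalisation by default. On
  the simulator's deliberately short chromosomes this removes cores inside
  a deep sweep (their EHH never decays before the chromosome end); on
  real chromosomes tens of Mb long the effect is confined to the ends.
* **XP-EHH**: $\ln(\mathrm{iHH}_{focal}/\mathrm{iHH}_{control})$ with iHH
  computed over all haplotypes of each population, standardised
  genome-wide. Positive scores mean longer haplotypes in the focal
  population, and only the positive tail is used for window flagging, so
  selection in the control population cannot validate a focal candidate.

For validation the genome is re-tiled with non-overlapping 10 kb windows;
a window is flagged if it holds at least one core SNP with |iHS z-score|
or XP-EHH z-score above the genome-wide 95th percentile, and a candidate
gene is validated if it overlaps at least one flagged window.

# Association, LD and enrichment

Case/control association is a per-SNP two-sided Fisher exact test on
allele-copy counts (the standard "sum of tables no more probable than the
observed" rule), with Bonferroni and Benjamini--Hochberg adjustments.
Pairwise $r^2$ comes from phased haplotype frequencies, or from the
two-locus EM algorithm when phase is hidden (tolerance $10^{-8}$, 1000
iterations; non-convergent pairs are excluded). Monomorphic pairs are
excluded rather than scored 0, which would drag decay curves down. LD
decay is the mean $r^2$ per distance bin; the comparison of decay between
two regions — a distance-matched two-sample rank test per bin with
Fisher's combination across bins — is this package's own construction, as
no standard test exists for that contrast.

Gene-set overlap uses Fisher's exact test on the 2×2 classification of a
gene universe; the universe — genes eligible for both the selection scan
and the expression contrast — is the single most consequential analysis
choice and is therefore a required argument rather than a hidden default.
Functional-term enrichment is the upper-tail hypergeometric test per term
with BH-FDR across terms, with the richness factor $(k/n)/(K/N)$ reported,
and a robustness mode that re-tests after filtering the gene set at
progressively stricter resampling-support cutoffs (top 1%, 0.5%, 0.3%).
One-sided (enrichment) p-values are reported as primary with two-sided
alongside; hypergeometric enrichment is conventionally one-tailed, and
both are emitted where conventions differ.

# The synthetic cohort generator

The generator is a forward Wright--Fisher simulation of diploids with an
additive selected site (fitnesses $1, 1+s, 1+2s$), written so that the
sampled data mirror the structure of a temporal field-resequencing study:

* Two chromosomes of 1 Mb with 2000 polymorphic sites each, a diploid
  population of $N = 1000$, and a neutral control population of the same
  size that split 200 generations before the present.
* Standing variation is initialised by drawing each site's allele count
  from the neutral site frequency spectrum ($P(k) \propto 1/k$) at linkage
  equilibrium, followed by a 200-generation neutral burn-in that builds
  realistic local linkage disequilibrium. A multi-$N_e$-generation forward
  burn-in would recreate the same two features the analysis actually
  consumes — an equilibrium-like frequency spectrum and short-range LD —
  at vastly higher cost, so the spectrum is imposed directly and only the
  LD is simulated.
* Recombination is a Poisson number of crossovers per gamete with uniform
  breakpoints. The default rate ($10^{-7}$ per bp) is deliberately high
  per bp so that the 1 Mb toy chromosome carries the map length of a much
  longer real chromosome; haplotype-length statistics then behave
  realistically at desk scale.
* The sweep is hard: a single copy arises at generation 160 (of 200) and
  is re-run from the same pre-sweep state if lost before the first sample
  — conditioning on establishment, the standard treatment of a hard sweep
  observed after the fact. With $s = 0.5$ this timing puts the allele at
  intermediate frequency (typically 0.1–0.55) at the first sample
  (generation 176) and at effective fixation (≥ 0.99) by the later samples
  (generations 196 and 200), emulating a cohort sampled in 2012, 2017 and
  2018 at roughly four generations per year with the sweep completing
  inside the sampled interval.
* Ten diploids are drawn without replacement at each focal time point and
  seven from the control population. Per-call depths are Poisson(30) with
  binomially split allele depths (error 0.005), and per-site caller-style
  QC annotations are drawn from passing distributions with a 2% planted
  failure rate, so the hard filters have something to remove. An optional
  hemizygous-X mode halves male depths and duplicates male haplotypes on
  a designated chromosome.
* Genes are tiled end-to-end (10 kb default) and two DEG lists are drawn
  with a configurable odds ratio between DEG membership and overlap with
  the recorded sweep window (±50 kb around the selected site).

The truth record keeps the realised allele-frequency trajectory, the
fixation generation, the sweep window and the planted DEG genes, enabling
parameter-recovery and calibration tests.

What the generator does **not** emulate: sequencing reads and mapping
artefacts (depths are Poisson, not produced by an aligner), population
structure beyond a clean two-population split, gene flow, ongoing
mutation, variable recombination maps, and background selection. Passing
tests therefore demonstrate correctness of the statistics and the
machinery under an idealised demography, not robustness to every
real-data pathology — which is precisely what a simulator-backed test bed
is for.

# Numerical choices and degenerate inputs

* Quantile thresholds are inclusive order statistics (`type = 1`), so the
  degenerate all-ties case selects everything rather than nothing, and
  `+Inf` ratio values are handled exactly.
* A scan needs at least $20/q$ usable windows for the $q$ upper quantile
  to be estimable; smaller problems are refused with advice rather than
  silently producing unstable outlier sets.
* Sites missing a QC annotation pass that filter criterion, matching
  caller behaviour of emitting rank-sum fields only when computable.
* Per-sample mean depth is computed from the VCF's DP field when not
  supplied.
* The hemizygosity correction requires a ≥ 3× allele-depth supermajority;
  otherwise the call becomes unknown. Calls lacking AD are set missing
  and counted.
* Internal coordinates are 0-based half-open everywhere (VCF's 1-based
  positions are converted at the boundary; GFF on read), making window
  arithmetic, merging and overlap checks uniform.
* In the resampling, iterations whose subsample leaves too few usable
  windows are skipped and counted; more than 10% skipped aborts the
  comparison.

# Problem sizes used by the test-suite and acceptance script

Oracle-equivalence checks run on matrices of at most 16 haplotypes by 40
sites and tables with margins up to 60, where exhaustive enumeration is
exact and immediate. End-to-end properties (sweep recovery, resampling
support, calibration) run at the generator's default scale — two 1 Mb
chromosomes, 2000 sites each, $N = 1000$ — with 30–50 replicates, and unit
tests use a reduced cohort ($N = 120$, shorter history) chosen to preserve
every qualitative regime of the default while keeping each simulated
cohort under a second. These sizes are the package's own testing design:
they are the smallest problems at which each property is statistically
identifiable.

# Known limitations

* The iHS/XP-EHH machinery refuses unphased heterozygous input rather than
  phasing it; statistical phasing is a separate concern best left to
  dedicated tools, and the simulator provides truth-phased data.
* Fisher-exact calibration is conservative at small set sizes (discrete
  p-values), so null rejection rates sit slightly below the nominal level;
  this is a property of the exact test, not of the implementation.
* The Wright--Fisher kernel models a single panmictic deme per population
  with non-overlapping generations; overlapping generations in real
  field populations blur the generations-per-year conversion.
* EM-based $r^2$ returns the maximum-likelihood estimate, which differs
  from realised-phase $r^2$ by a phase-assignment noise term that shrinks
  with sample size; the two agree closely for $n \gtrsim 400$ diploids at
  intermediate LD.
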