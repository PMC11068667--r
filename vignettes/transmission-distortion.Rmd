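---
title: "Detecting transmission distortion at chromosome fusions from pooled F2 sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transmission distortion at chromosome fusions from pooled F2 sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyodrive)
```

## The problem

The wood white butterfly *Leptidea sinapis* shows the largest intraspecific
chromosome number variation of any diploid eukaryote: Catalan (CAT)
populations carry 2n = 106–108 mostly small, unfused chromosomes, Swedish
(SWE) populations 2n = 57–58 largely fused ones. Hybrids between the races
are viable and fertile, and an F1 female is heterokaryotypic for dozens of
fusion/fission differences: at each rearranged "chromosome unit" one fused
SWE chromosome pairs with two unfused CAT homologs in a trivalent.
Lepidopteran chromosomes are holocentric and female meiosis is achiasmatic
(no crossing over), so each unit segregates intact to the egg or to a polar
body. If one side of the trivalent — say the unfused pair, with more
holokinetic activity — is captured by the egg pole more often than half the
time, its frequency in the offspring rises above the Mendelian expectation:
female meiotic drive.

`karyodrive` implements the analysis that detects such transmission ratio
distortion from pooled whole-genome resequencing of F2 offspring, together
with a forward simulator that generates every input synthetically, so the
whole pipeline is testable without access to the original sequencing data.

## The model

Each chromosome unit links one SWE chromosome to one or two CAT
chromosomes and carries a rearrangement class assigned by parsimony over
the fusion states of SWE, CAT and the outgroups *L. reali* and
*L. juvernica*:

* `FUSION_SWE` — derived fusion in the Swedish lineage (outgroups unfused);
* `FISSION_CAT` — derived fission in the Catalan lineage (outgroups fused);
* `UNKNOWN_POLARIZATION` — the polymorphism segregates in all three
  species, or the outgroups disagree, so parsimony cannot polarize it;
* `HOMOLOGOUS` — no rearrangement between the populations;
* `SEX_Z` — Z chromosome units (three in this karyotype), and
  `EXCLUDED_COMPLEX` for stacked rearrangements, both excluded from the
  scan.

Drive is a single probability $d$ per class: the chance that the unfused
(CAT-state) side of a heterokaryotypic trivalent segregates to the egg
pole, acting once per unit per meiosis (the two unfused homologs
co-segregate). Under a backcross (F1 female × SWE male) every paternal
allele is SWE, so the expected SWE allele frequency at a rearranged unit is

$$\mathbb{E}[p_\mathrm{SWE}] \;=\; \tfrac{1}{2}\bigl(1 + (1 - d)\bigr) \;=\; 1 - d/2,$$

which is $0.75$ at the Mendelian $d = 0.5$; any deviation isolates the
female meiosis. In an intercross (F1 × F1) both meioses contribute and the
expectation is $((1-d_f) + (1-d_m))/2$, i.e. $0.5$ under Mendelian
segregation.

## From reads to the class-level test

1. **Allele frequencies** (`estimate_marker_af`, `marker_af_table`). Reads
   are mapped against two modified references with all fixed differences
   set to the SWE or to the CAT allele; the per-marker frequency is the
   mean of the two orientations, which cancels symmetric reference bias to
   first order. Reads carrying neither marker allele are excluded — fixed
   differences are biallelic by construction. Pools are combined by a
   weighted mean with weights equal to the number of individuals per pool
   (equal weighting is available as an option).
2. **Polymorphism filter.** A marker is retained when a likelihood-ratio
   test rejects monomorphism at $p < 10^{-6}$. The statistic is
   $2[\ell(\hat q) - \ell(q_0)]$ for a binomial likelihood of SWE reads,
   with the null at the nearer of $q_0 \in \{\epsilon, 1-\epsilon\}$ and
   $p$ from the halved $\chi^2_1$ tail (boundary null). The error floor
   $\epsilon = 0.01$ keeps the null proper: a strictly monomorphic null
   has zero likelihood as soon as a single minor read appears, which would
   retain every marker with any noise. Both the threshold and the floor
   are configurable.
3. **Unit aggregation** (`aggregate_unit_af`). Retained marker frequencies
   are averaged per CAT chromosome, and per unit as the mean of its
   chromosome means — a 1:2 unit contributes one value, treating the
   unfused pair as the single entity that segregates.
4. **Counts and test** (`counts_from_af`, `exact_binomial_test`,
   `run_distortion_scan`). Per unit, the SWE count is
   $k_u = \mathrm{round}(\bar p_u \, n)$ with $n$ the number of F2
   individuals; class totals are $k = \sum_u k_u$ out of
   $n_\mathrm{trials} = (\#\text{units}) \times n$ "pairs" — one
   segregation event per bivalent/trivalent per meiosis, not per allele
   copy. Each class is tested against its design expectation with a
   two-sided exact binomial test (minimum-likelihood convention, relative
   tolerance $1 + 10^{-7}$) and an exact Clopper–Pearson 95% interval.
   Raw p-values are reported per class; a Bonferroni column is emitted for
   information only.

### Why this test is conservative

Counting pairs while deriving $k$ from allele frequencies deliberately
understates the evidence. In the backcross the unit frequency is
$(n + m_S)/2n$ with $m_S \sim \mathrm{Bin}(n, 1-d)$ maternal SWE
transmissions, so $k_u \approx (n + m_S)/2$ has variance $n/16$ — a third
of the $3n/16$ the binomial null assumes (half, $n/8$ vs $n/4$, in the
intercross). The exact test is therefore markedly conservative: in the
package's own calibration (2000 simulated Mendelian backcross experiments
at the study design, run by the acceptance suite) the family-wise
false-positive rate of the four class tests is below 1%, far under the
nominal 5%. This is a property of the published counting procedure, which
assumes the drive mechanism affects both unfused chromosomes equally;
significant results are correspondingly trustworthy, at a cost in power.

### Reconstructing the published tests

`recover_counts_from_summary()` inverts a printed (observed frequency,
95% CI) pair back to the integer counts $(k, n)$ whose frequency and exact
Clopper–Pearson bounds round to the printed values, and
`reproduce_published_table()` re-runs the exact test on the reconstruction,
preferring candidates whose $n$ is a multiple of the published offspring
count (67 backcross, 599 intercross, so $n$ = units × individuals). Seven
of the eight published class rows reproduce their printed p-value exactly
at 3 decimals; the backcross Homologous row does not (the reconstruction
gives $p \approx 0.31$ against a printed 0.725) and is reported as
`inconsistent` rather than forced to match — most plausibly a transcription
artifact in the printed row, which we flag instead of guessing.

```{r}
reproduce_published_table()
```

## The synthetic-data generator

`make_karyotype_and_markers()` + `simulate_backcross()` /
`simulate_intercross()` + `simulate_pool_reads()` emulate the study
design end to end. Defaults are fixed at the study conditions:

| parameter | default | rationale |
|---|---|---|
| units per class | 6 Fusion SWE / 5 Fission CAT / 4 Unknown / 5 Homologous | class sizes recovered from the published confidence intervals ($n$ = units × individuals: 402, 335, 268, 335 backcross pairs) |
| Z units | 3 | the *L. sinapis* karyotype has three Z chromosomes |
| markers per CAT chromosome | 730 | ≈ 27,700 fixed differences over the 38 autosomal CAT chromosomes, the study's genome-wide marker count |
| offspring | 67 backcross (pools 32/35), 599 intercross (pools 298/73/72/76/80) | published cohort and pool sizes |
| drive $d$ | 0.5 every class | Mendelian null; the study's observed deviations (0.049–0.098 from expectation) correspond to $d \approx 0.6$ |
| mean depth | 50 reads/marker/pool, Poisson | one short-read lane spread over pools; per-marker Poisson is the standard pool-seq depth model |
| error rate | 0.002 | post-quality-filter short-read error; errors hit a uniform random alternative base |
| reference bias | 0.02 per orientation | residual mapping asymmetry after strict filtering; the dual-reference design exists precisely because this is nonzero |

Mechanics worth knowing:

* Female meiosis is achiasmatic: maternal unit origins are single
  Bernoulli draws, no within-unit recombination ever.
* Male meiosis optionally carries one obligate crossover per unit at a
  uniform breakpoint (`recomb = TRUE`). With the Mendelian default
  $d_m = 0.5$ this changes genotype mosaics but no marker-frequency
  expectation; with $d_m \neq 0.5$, crossovers mix the two paternal
  haplotypes and pull per-marker paternal expectations towards 0.5 — drive
  is modeled at segregation, recombination after it.
* Inverted meiosis is not modeled mechanistically; $d$ subsumes any
  segregation asymmetry, since only transmission outcomes are observed.
* Sexes: females are ZW with the degenerate W invisible to markers; the F1
  mother carries SWE-origin Z chromosomes (her father was the SWE parent),
  so backcross offspring are monomorphic SWE on Z, and mixed-sex pools
  show the diagnostic ≈ 0.75× Z coverage.
* The same simulated reads are "mapped" in both orientations;
  non-reference reads are thinned with probability `ref_bias` per
  orientation (binomial thinning), reproducing the bias the orientation
  averaging is meant to cancel.
* `inject_aneuploidy()` adds a third copy of one unit to a fraction of
  individuals (dosage/3 allele weighting, 1.5× depth weight);
  `viability_filter()` applies genotype-dependent survival for
  drive-vs-viability sensitivity experiments. Both are off by default.
* Equimolar pooling is assumed exact (no pool-composition noise), per the
  stated extraction protocol; depth is the only sequencing noise source
  besides error and bias.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linkage disequilibrium within units beyond
the single-crossover model, locally varying depth and mappability,
PCR/duplication artifacts, contamination, segregating variation within the
parental lines (markers are perfect fixed differences), or family
structure within pools. Conclusions about those failure modes need real
reads.

## Numerical choices

* **Rounding ties** in count conversion are half-away-from-zero, applied
  per unit before summation (`rounding = "half_even"` available for
  sensitivity checks; at the study's scale both give identical counts).
  Whether rounding precedes or follows class aggregation is immaterial at
  3-decimal precision for these inputs; per-unit is the default.
* **Two-sidedness** follows the minimum-likelihood convention with
  relative tolerance $1+10^{-7}$, matching the reference implementation in
  `stats::binom.test` (verified against it exhaustively for $n \le 40$ in
  the test suite).
* **Degenerate inputs**: markers with zero informative reads get `NA`
  frequency and are never retained; units with no retained markers are
  dropped with a warning; classes with zero units are omitted with a
  warning; a zero within-class variance coverage ANOVA returns `F = NA`
  with a diagnostic instead of dividing by zero.
* **Seeds**: every simulator function takes an explicit seed and restores
  the caller's RNG state; an end-to-end run derives stage seeds by small
  offsets from the config seed, so identical configs give byte-identical
  output tables.

## Aneuploidy scan

Systematic aneuploidy would mimic transmission distortion; it would also
raise coverage. `coverage_by_chromosome()` averages marker depth per
chromosome (summed over pools, averaged over orientations) and
`coverage_anova()` runs a one-way fixed-effects ANOVA across the four
autosomal classes plus Z with Tukey HSD post-hoc contrasts. Chromosomes,
not markers, are the unit of replication — markers within a chromosome
share its copy number, and treating them as replicates would
pseudo-replicate the test. The expected signature in clean data is exactly
one significant family of contrasts: Z versus autosomes (≈ 0.75×, from ZW
females), with all autosome–autosome contrasts null.

## Design decisions that were genuinely open

* Outgroup disagreement (one fused, one unfused) maps to
  `UNKNOWN_POLARIZATION`: parsimony cannot polarize it, and the
  conservative assignment keeps the derived classes clean.
* Z units are excluded from the scan in **both** designs — they are
  monomorphic SWE in the backcross, and the class-level analysis is
  defined over the four autosomal classes only.
* Intercross individuals are pooled across all five life-stage pools into
  a single test: the combined expectation is 0.5 and conditioning on
  survival is avoided; per-pool scans remain available by subsetting.
* Pool combination weights by individual count by default (each individual
  contributes equimolar DNA); equal weighting is a config option.
* The post-hoc method is fixed to Tukey HSD; the replication unit and
  post-hoc procedure are configurable decisions, recorded in run logs.

## Problem sizes used by the test suite

Simulation-heavy checks run at reduced marker counts (10–40 per
chromosome instead of 730) and depths of 30–120, sizes at which read noise
contributes only a few percent of the meiotic sampling variance, so the
calibration and power properties they measure are those of the design, not
of sequencing noise. The type-I calibration uses 2000 simulated
experiments; drive recovery 200 replicates of 500-offspring backcrosses at
depth 100; the published-table reconstruction is exact arithmetic and runs
in seconds.

## Known limitations

* Drive strength is a free parameter: the published deviations imply
  $d \approx 0.55$–$0.6$ at derived fusions but the data do not identify
  the mechanism; the package estimates $\hat d = 2(1-\bar p)$ in the
  backcross without modeling kinetochore biology.
* The pair-counting test is conservative (see above); a likelihood model
  at the meiotic-event level would be better calibrated but is not what
  the published analysis does, and this package reproduces that analysis.
* The polymorphism filter's published threshold ("likelihood ratio score
  $< 10^{-6}$") is interpreted as a p-value threshold on the LR test; the
  upstream caller's exact semantics are not restated here, so both the
  threshold and the error floor are exposed as options.
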