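---
title: "Models and methods behind dmiscreen"
author: "dmiscreen authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmiscreen)
```

# Scope

`dmiscreen` implements the computational core of a species-wide screen for
condition-specific genetic incompatibility in *Saccharomyces cerevisiae*
crosses: scoring offspring viability across crosses and conditions,
recognising Mendelian two-locus Dobzhansky–Müller (DM) segregation in tetrad
data, mapping the loci involved from bulk-segregant pooled sequencing,
annotating the molecular lesions (premature stop codons and tRNA nonsense
suppressors), and quantifying the fitness consequences of carrying a
suppressor. Because the original wet-lab material (strains, dissected
tetrads, sequencing pools) is not reproducible computationally, the package
ships a first-class synthetic cross simulator that generates every input the
analysis consumes, under known ground truth. All wet-lab-only steps (read
alignment, SNP calling internals, genome assembly, plate image processing)
are out of scope; the package consumes or synthesises their tabular outputs.

# The tetrad model

A yeast tetrad holds the four haploid products of one meiosis; every marker
segregates 2:2. Consider a recessive two-locus DM pair: a spore dies (on a
restrictive condition) iff it inherits parent 2's allele at locus A
(a loss-of-function lesion) *and* parent 1's allele at locus B (absence of
the rescuing suppressor). For unlinked loci, each locus independently assigns
its 2:2 pattern: one of the 6 two-subsets of the four spores, uniformly. The
number of dead spores is the overlap of two independent random 2-subsets of
4, which is 0, 1 or 2 with probabilities 1/6, 2/3 and 1/6 — tetrads with 4,
3 and 2 viable spores in a 1:4:1 ratio, and a mean spore loss of exactly
one-fourth:

```{r tetrad-dist}
two_locus <- incompatibility_model(
  "two_locus_unlinked",
  lethal_loci = data.frame(chrom = c("chr05", "chr10"), pos = c(75500L, 75500L),
                           lethal_parent = c("P2", "P1")),
  conditions = "glycerol")
expected_tetrad_distribution(two_locus)
expected_spore_inviability(two_locus)
```

Generalisations follow the same logic. For `k` unlinked lethal loci the
distribution is computed by exhaustive enumeration of all `6^k` joint
partitions (dead spores are the intersection of the `k` lethal-allele
subsets); mean spore loss is `2^-k`. For two linked loci the package uses
the no-interference four-chromatid model: crossovers in the interval are
Poisson with mean `lambda`, a crossover exchanges the distal segments of one
randomly chosen chromatid from each homolog, and the closed-form
parental-ditype / tetratype / non-parental-ditype (PD/TT/NPD) probabilities

* PD  = 1/6 + e^(−λ)/2 + e^(−3λ/2)/3
* NPD = 1/6 − e^(−λ)/2 + e^(−3λ/2)/3
* TT  = 2/3 · (1 − e^(−3λ/2))

are mapped to viable-spore classes (a recombinant lethal combination kills
one spore in TT and two in NPD tetrads). The Haldane relation
`r = (1 − e^(−λ))/2` links λ to the recombination fraction, so `r → 0.5`
recovers the unlinked 1:4:1 limit. Penetrance below 1 thins each
lethal-genotype spore by an independent Bernoulli draw. These distributions
are exact; the test suite checks them against brute-force enumeration up to
`k = 4` and against simulation by chi-square at 10^5 tetrads.

## Segregation classification

`classify_segregation()` fits observed tetrad viable-count tables by
multinomial likelihood under each candidate model and selects by BIC.
Parameter counts: `none`, `two_locus_unlinked` and `k_locus` are
parameter-free; `two_locus_linked` profiles its recombination fraction over
a grid (`r` in 0, 0.025, …, 0.5; 1 parameter); `complex` is the saturated
multinomial over the five classes (4 parameters), playing the role of the
screen's "complex epistasis" catch-all. The decision rule behind the
published complex-epistasis labels is not stated anywhere we could adopt it
from, so the BIC rule is this package's explicit, documented stand-in; ties
break toward the simpler model and then lexicographic kind name, making the
call invariant to candidate order. Goodness of fit of the selected model is
an exact multinomial test: full enumeration of outcome probabilities for up
to 30 tetrads, Monte Carlo (fixed internal seed, 10^5 draws) up to 200, and
the chi-square approximation beyond. Large simulation studies can skip the
goodness-of-fit computation (`compute_fit_pvalue = FALSE`).

# The synthetic cross simulator

`simulate_tetrads()` performs meiosis marker-by-marker. Each chromosome's
four chromatids (two per parent) are dealt to the four spores uniformly at
random, giving independent assortment across chromosomes; within a
chromosome, inter-marker intervals receive Poisson(2d) crossovers (d = map
length in Morgans) applied to random non-sister chromatid pairs. A single
marker per chromosome therefore reduces exactly to the uniform 2:2 partition
assumed by the analytic model, and unlinked loci reproduce PD:NPD:TT =
1:1:4. Physical distance maps to genetic distance at 0.35 cM/kb, the
*S. cerevisiae* genome average. Centromere position and crossover
interference are deliberately not modelled: the screen's quantities of
interest (viable-count classes, pooled allele frequencies) are insensitive
to first/second-division segregation patterns.

The default simulated genome is scaled: 16 chromosomes of 150 kb with one
marker per kb (2400 markers). This preserves the marker density the mapping
rules operate on and realistic within-chromosome linkage, while keeping an
80-segregant pool simulation around a second; chromosome-scale length only
dilates the recombination landscape without changing any tested quantity.
The worked two-locus geometry places the driver locus on chromosome 5 and
the rescuer on chromosome 10, mirroring the two-chromosome arrangement of
the motivating case.

Pools (`simulate_spore_pool()`) pick one random spore per tetrad — tetrads
are independent — and keep spores matching the viability filter until the
target pool size is reached; an impossible filter (e.g. inviable spores
under a lethality-free model) raises an explicit no-progress error after a
bounded number of tetrads. Pooled sequencing (`simulate_bsa_counts()`) draws
Poisson depth per marker around the nominal coverage (default 50×), each
read sampled from a uniformly random pool member and flipped to the other
parent's allele with the per-read error probability (default 0.002) — the
simplest model consistent with uniform coverage and a small symmetric
sequencing error. No read-level FASTQ structure is simulated.

`simulate_screen()` emulates the screen design: 27 crosses × 20 conditions,
20 full tetrads per instance, an instance-level mix of incompatibility
kinds, and a configurable number of instances with a non-viable parent
(default 10% of instances) to exercise the exclusion filter. The default
mix (75.7% none, 17.6% three-locus, 6.7% two-locus) was chosen once so that
the planted severity composition echoes the proportions reported in the
motivating screen; `sampling = "expected"` replaces multinomial sampling of
tetrad classes by rounded expectations for noise-free round-trip tests.
Because per-tetrad classes are drawn from the analytic distribution rather
than full genotype simulation, screen tables are cheap at any size.

What the generator does *not* emulate about real data: sporulation and
dissection failures, aneuploidy and gene conversion, coverage biases along
the genome, mapping artefacts near repeats, and condition-specific partial
penetrance structure. Passing tests therefore demonstrate correctness of
the analysis rules under their stated model, not robustness to every
artefact of real screens.

# Viability screen scoring

Offspring viability of an instance is the number of spores viable on the
test condition divided by the number viable on permissive rich medium
(never the number dissected). Instances where either parent fails to grow
on the condition are excluded before interpretation. Severity uses loss
`= 1 − viability`: at least 20% loss is `severe` (the boundary is closed —
"at least 20%" — and guarded against floating-point rounding by a 1e-9
tolerance), loss from the epistasis threshold up to the severe cut is
`potential_epistasis`, else `none`. The epistasis threshold defaults to 1%
loss; the smallest reported losses in the motivating screen were 1%, and
whether that is a threshold or simply the smallest observation is ambiguous,
so it is a configurable parameter, not hard-coded. No statistical test is
applied by default (the screen's flagging rule is a ratio, not a test); an
optional exact binomial test of viability against 1 is available
(`binomial_test = TRUE`).

# Bulk-segregant mapping rules

The pool of inviable segregants is fixed for the non-reference allele at the
driver locus, depleting the reference-parent allele frequency (AF) nearby,
while the rescuer locus region is fixed *for* the reference parent — in real
reference-aligned data those positions yield no SNP calls at all, leaving a
marker desert. Three rules operationalise this:

* `detect_low_af_regions()`: maximal runs of at least `min_run = 5`
  consecutive depth-passing markers with AF below `af_threshold = 0.1`.
  The 0.1 cut is the published rule; the run length implements the
  "inconsecutive SNPs are sequencing noise" rule with an explicit constant
  (at 50× and 0.2% error, a lone marker dipping below 0.1 by chance is
  orders of magnitude more likely than five in a row). An optional
  `max_violations` tolerance merges runs split by a single noisy marker.
* `detect_marker_deserts()`: per-chromosome inter-marker gaps (including
  chromosome-end gaps) longer than `gap_factor = 10` times the chromosome's
  median spacing. `drop_uncalled_markers()` reproduces caller behaviour on
  simulated counts (markers without ≥ 2 alternate reads and ≥ 5% alternate
  fraction are dropped) so that reference-fixed regions become deserts.
* `candidate_features()`: 1-based inclusive interval overlap of annotated
  features with mapped regions (via `GenomicRanges`).

Depth below `min_depth = 10` flags a marker out of region detection; the
original analysis states no depth cut-off, and 10 at a nominal 50× excludes
only unstable AF estimates. All coordinates are 1-based inclusive in tables
and logs; BED export converts to 0-based half-open. No statistical
smoothing (G', loess) is layered on top of the run rule — the published
procedure is a run rule, and smoothing alternatives are extensions, not
implemented surface.

# Annotation

`call_nonsense()` applies each single-nucleotide variant independently to
its codon (1-based from the A of ATG) and reports a premature stop when a
non-stop codon becomes TAA, TAG or TGA before the terminal codon; the
reported coordinate is the first base of the affected codon, so a stop
gained in codon 39 sits at +115 whichever codon base mutated. Stop-to-stop
changes and lesions of the terminal stop are not nonsense gains. Multi-variant
codon compounding is not applied by default — counts are of SNP-induced
stops. Genomic-coordinate mode extracts ORFs from chromosome sequence,
reverse-complementing minus-strand genes and complementing variant alleles,
and is checked to be strand-consistent.

Anticodons are handled as DNA 5'→3'; the codon a tRNA reads is the reverse
complement of its anticodon (the tyrosine anticodon written GUA in RNA is
GTA in DNA and reads TAC). `detect_trna_suppressor()` reports a suppressor
exactly when the mutated anticodon reads a stop while the original did not;
the test suite checks all 576 single-base anticodon changes against an
independent enumeration. An empty genome-wide scan is a meaningful result —
suppressors are vanishingly rare in natural isolates.

# Growth and fitness

`fit_growth_rate()` offers two estimators of the maximum specific growth
rate:

* `method = "window"` (default): the maximum ordinary-least-squares slope of
  log OD over sliding windows of `window = 8` points, after flooring OD at
  `1e-4` (blank-subtracted readings can be ≤ 0) and a light centred
  rolling-mean smoothing of log OD (width 5; exactly slope-preserving on a
  pure exponential). This is the classic "exponential curve fit" and is
  exact on noiseless exponentials.
* `method = "logistic"`: a Levenberg–Marquardt fit of a logistic-with-lag
  trajectory on the OD scale. The window estimator is noise-limited at high
  read frequency: with 10-minute reads, 0.005 OD read noise and a 0.05
  inoculum OD, the maximum over many short noisy windows is upward-biased
  (about +13% at the default window), and enlarging the window trades that
  bias for saturation bias, so no window reliably recovers a planted rate
  within 5% per curve. The parametric fit recovers planted rates to a few
  tenths of a percent under the same conditions and is the recommended path
  for per-curve precision; the window method remains appropriate for
  sparser sampling and replicate-averaged comparisons (window 16 for
  10-minute data is calibrated at the 6-replicate-mean level).

Percent growth variation is `100 · (mean(sup) − mean(ctrl))/mean(ctrl)` with
a two-sided two-sample t-test; it is antisymmetric under arm swap in the
multiplicative sense. Colony fitness uses normalized growth ratios — colony
size on a condition over the matched colony's size on the reference medium,
cancelling pinning effects — aggregated as means of per-replicate ratios
(not ratios of means, matching per-colony normalization); the ≥ 10% display
flag is a magnitude filter, not a test, with a closed boundary. Variance
comparisons return both the two-sided F-test and the Brown–Forsythe/Levene
test (absolute deviations from group medians); two constant arms yield p = 1
by convention. Raw p-values are reported (as in the motivating figures); an
optional Benjamini–Hochberg adjustment can be applied downstream with
`p.adjust`. The plate-growth analysis operates on a single user-chosen time
point per colony file.

# Numerical choices and degenerate inputs

* Random numbers: every generator takes one integer seed; the pipeline
  derives stage-local seeds by fixed offsets, and identical seeds give
  bitwise-identical outputs. Seeded code restores the caller's RNG state.
* Linked-model class probabilities are clamped at 0 and renormalised to
  guard ~1e-17 cancellation error near r = 0.
* Exact multinomial enumeration is limited to 30 tetrads (≈ 4.6 × 10^4
  compositions over five classes); beyond that Monte Carlo, then chi-square.
* Zero permissive-viable spores make viability undefined (error);
  zero-reference colonies yield flagged missing ratios; flat OD curves
  return rate 0 with a warning rather than an error.
* `k_locus` enumeration refuses k with 6^k beyond 2 × 10^6 (k ≤ 8).

# Problem sizes used in the checks

The shipped tests and the acceptance script use: 10^5 tetrads (4 × 10^5
spores) for simulation/analytic agreement; pools of 80 inviable segregants
on the 16 × 150 kb genome at 50× and 0.2% error, with 50 seeded repetitions
for mapping-localization and null false-positive rates; 1000 simulated
40-tetrad screens for classifier recovery; 2000 null simulations at n = 288
per arm for variance-test calibration; and 145-point growth curves
(10-minute reads over 24 h). These sizes were chosen to estimate each
quantity well inside its acceptance tolerance.

# Interface design

The package is an R analysis toolkit: its public functions, the
`run_pipeline()` orchestrator (simulate → screen → classify → map →
annotate → growth, with provenance headers recording version, seed and
thresholds in every artifact) and this vignette are the intended interface,
so no separate shell wrapper is shipped. Table formats are plain TSV/CSV
with `#` provenance comments; pooled counts also load from a minimal VCF
with per-sample `AD` depths (via `vcfR`), and regions export as BED.

# Known limitations

* No centromere linkage, crossover interference, gene conversion or
  aneuploidy in meiosis simulation; no spore-autonomous vs ascus-level
  lethality distinction.
* The BIC-based "complex" call is a stand-in for an unstated published
  decision rule; borderline tables near 20 tetrads can be assigned
  differently by other reasonable rules.
* BSA mapping assumes dense, evenly spread markers; very sparse marker sets
  weaken both the run rule and the desert rule (the desert detector skips
  chromosomes with fewer than 10 markers).
* Growth-rate fitting assumes a single exponential phase; diauxic shifts
  produce a rate for the fastest phase only.
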