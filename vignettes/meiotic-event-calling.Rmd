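---
title: "Calling and classifying meiotic recombination events from tetrad and octad sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying meiotic recombination events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiorec)
```

## The measurement

Meiotic recombination in a hybrid yeast cross (e.g. S288c x SK1, ~0.57%
divergence, ~65,000 diagnostic markers) can be read out at near-base
resolution by sequencing all products of single meioses. In a **tetrad**,
the four spores are sequenced; in an **octad**, each spore is allowed one
mitotic division and the mother and daughter cells are sequenced
separately, so that the 8 genomes correspond to the 8 DNA strands present
at the end of recombination. Octads resolve **heteroduplex DNA (hDNA)** —
duplex with one strand from each parent — which persists only when
mismatch repair is disabled (*msh2* deletion) and segregates at the first
post-meiotic division.

The package implements the post-alignment portion of this analysis:

1. threshold-based genotype calling from per-marker allele counts;
2. assembly of 8-strand genotype matrices (octads, duplicated tetrads, or
   "mocktads" reconstructed from MMR-deficient tetrad colonies);
3. segmentation into segregation patterns and grouping into recombination
   events with crossover (CO) and noncrossover (NCO) counts;
4. classification into multi-DSB, trans-DSB and strand-transfer
   subcategories;
5. the spatial statistics: non-exchange chromosome null model, inter-CO
   distance (ICD) gamma modelling, event mid-lengths, homeostasis trends,
   telomere/centromere distance curves;
6. a synthetic-meiosis generator that produces all inputs with known
   ground truth.

Genotypes are binary: 1 for the parent-A (reference-like) allele, 0 for
parent B. An 8-strand column then has a **segregation pattern**, the ratio
of parent-A to parent-B calls: `4:4` is Mendelian; `5:3`/`3:5` mark
half-conversion (one strand of one chromatid carries the other parent's
allele, i.e. retained hDNA); `6:2`/`2:6` full conversion; `7:1` and `8:0`
require conversion of both sister chromatids and are evidence for two
DSBs *in trans*. A star marks aberrant arrangements in which at least one
mother/daughter strand pair is discordant — `6:2*` (two half-conversions
in trans), `4:4*` (symmetric hDNA on both recombining chromatids).

## Genotype calling

`call_genotypes()` applies the rules with inclusive (`>=`) thresholds
(`caller_config()`):

| rule | default |
|---|---|
| minimum depth for any call | 5 |
| SNP called parent B (variant) | variant fraction >= 0.70 |
| SNP called parent A (reference) | reference fraction >= 0.90 |
| SNP heteroduplex | (ref+var)/depth >= 0.90 **and** min/max >= 0.70 |
| indel called parent B | variant fraction >= 0.30 |
| indel called parent A | reference fraction >= 0.95 and < 2 variant reads |
| indel heteroduplex | never |
| recurrent heteroduplex | marker removed if heteroduplex in > 2 samples |

The asymmetric indel thresholds reflect alignment bias towards the
reference allele. "Within 70% of each other" is read as a min/max ratio;
the alternative reading (|ref − var|/depth <= 0.30) is available via
`caller_config(het_rule = "diff")` but is not the default.

Because indels cannot be called heteroduplex, hDNA spanning only indel
markers is invisible in tetrad (mocktad) data; octads do not suffer this,
since each strand is sequenced directly. This is why the octad/mocktad
equivalence tests run on SNP-only marker maps.

## Mocktads and strand phasing

When spore viability is too low to separate mother/daughter cells, an
MMR-deficient tetrad colony is sequenced whole: hDNA positions show mixed
(~50:50) reads and are called heteroduplex. `build_mocktad()` duplicates
each spore into a strand pair and splits heteroduplex calls —
mother strand := parent B, daughter := parent A. The polarity is an
arbitrary global convention; every spore with at least one heteroduplex
call carries a `polarity_unknown` flag, and classifications that depend on
strand orientation (one-sided vs trans hDNA) are reported not-assessable
for such spores. Resequencing a restreaked single colony recovers the
haplotype of one strand; `phase_with_colony()` assigns the colony call to
the daughter strand (by convention) and the complement to the mother,
clearing the flag when every mixed marker resolves.

## Segmentation and event calling

`segment_chromosome()` splits each chromosome into maximal runs of
identical 8-strand vectors; columns with any missing call are excluded and
do not interrupt runs (depth gaps must not split events). Concordant 4:4
columns of *any* chromatid arrangement are labelled Mendelian — crossover
breakpoints are read from arrangement changes *between* adjacent Mendelian
segments, so a clean CO with no detectable strand transfer is still an
event (with zero interior markers).

`call_events()` groups non-Mendelian segments and breakpoints into events.
Two groups are separate only when a Mendelian segment lies between them
**and** the distance between their outermost non-Mendelian markers is at
least 1.5 kb (`min_gap`); marker-adjacent non-Mendelian segments always
share an event regardless of distance, since no 4:4 segregation separates
them. Events that touch a chromosome end without returning to 4:4 are
type "U" and excluded from all tallies.

CO and NCO counts are read from the flanking Mendelian segments: each
chromatid has a parental identity on either flank; the CO count is the
number of identity-switching chromatids divided by two (with 2:2 flanks
this number is structurally even; the odd-count branch is defensive), and
non-switching chromatids with interior non-Mendelian calls contribute NCO
involvement. Per chromosome, summed CO counts equal the number of
haplotype switches between successive Mendelian columns — except for
events whose planted structure is intrinsically ambiguous (below).

## Classification conventions

Categories follow the observational taxonomy of octad studies;
`taxonomy_fixtures()` ships one hand-built matrix per category and is the
acceptance surface for the classifier.

**Multi-DSB classes** (conservative by construction): `dCO` only for a
double reciprocal exchange affecting all four chromatids; `CO_plus_NCO`
only when the conversion lies on a third chromatid; `dNCO_sister` for
conversions on two sister chromatids (sisterhood = equal flanking parental
identity); `dNCO_overlap` for conversions on two homologues with *perfect*
overlap (identical first and last converted marker). Everything else is
`none`. A fully converted perfectly-overlapping dNCO is pattern-identical
to two crossovers on the same two chromatids within 1.5 kb; like
partially overlapping homologue conversions (which show a small
double-exchange patch), these are deliberately resolved in favour of the
noncrossover reading, so no crossover is counted for them.

**Trans-DSB evidence**: any 7:1/1:7 segment, or an 8:0/0:8 segment
adjacent (within the event) to a heteroduplex-bearing segment. Isolated
8:0 without adjacent hDNA is the signature of a premeiotic mitotic event
and raises a QC flag instead. In MMR-proficient tetrads these patterns are
unobservable and the flag is `NA`, never `FALSE`.

**CO subclasses** (single-CO events): the exchange point is estimated in
marker-index space from the two recombining chromatids — the midpoint of
max(first boundaries after each chromatid's initial left-background run)
and min(last boundaries before the terminal right-background runs).
Transferred markers are those inconsistent with the background expected on
their side; maximal transferred runs give sidedness (one- vs two-sided;
runs straddling the estimate go to the side of larger overlap, ties left),
and the set of donor alleles (the allele foreign to the local background)
gives directionality (uni- vs bidirectional). A `4:4*` segment anywhere in
the event short-circuits to `symmetric_hDNA`; no hDNA with staggered
switch points is `full_conversion`; no transfer at all (typical of sparse
marker regions) is `no_strand_transfer`.

**NCO subclasses** (CO-free events): two tract runs separated by
background = `two_sided_restoration`; a single run that is all concordant
conversion = `full_conversion`; heteroduplex with an embedded conversion
patch = `one_sided_patch`; pure heteroduplex with constant donor strand =
`one_sided`, with a polarity flip = `two_sided_trans`; conversions on two
non-sister chromatids without perfect overlap = `two_chromatid`.

**Hotspot overlap** uses the maximum possible event region (nearest
flanking Mendelian marker on each side) against half-open `[start, end)`
intervals, so a hotspot ending exactly at the region start does not
overlap; BED input is converted at the boundary (BED `(0, 100)` becomes
`[1, 101)`).

**QC across meioses** (`qc_filter()`): 8:0 events without adjacent hDNA
are dropped; 8:0 loci recurring at the same marker interval in more than
one meiosis are dropped everywhere (presumed marker-table errors); meioses
with a >100 kb 8:0 block or a whole-chromosome two-spore heteroduplex
pattern (disomy signature) are flagged `premeiotic_suspect` and should be
excluded from count statistics but may contribute tract lengths.

## Statistics

**Mid-lengths.** Event length is estimated as the distance between the
midpoints of the inter-marker intervals flanking the event; it is
undefined (`NA`) for type-U events and for clean crossovers without
converted markers, and multi-DSB events are omitted from summaries because
their length cannot be attributed to a single initiation.

**Non-exchange chromosomes.** `simulate_nonexchange()` allocates N
crossovers multinomially with probabilities proportional to chromosome
length and records zero-CO chromosomes, 10,000 replicates per N (grid
1-200 via `nonexchange_grid()`); its mean has the closed form
$\sum_i (1 - p_i)^N$, which the tests use as an analytic oracle. Observed
counts get empirical tail probabilities; the genotype-level aggregate is
median(p)^n(meioses), implemented as specified for comparability — it is
*not* a calibrated combined p-value, and the function warns accordingly.
Non-exchange defaults to zero COs; the stricter zero-CO-and-NCO tally is
reported alongside.

**Interference.** ICDs are bp distances between successive CO positions
(event-span midpoints, one per CO; chromosomes with < 2 COs contribute
none; zero distances from within-event double COs are dropped), pooled
across meioses within a genotype. `fit_gamma_mle()` maximises the profile
likelihood in the shape via `uniroot` on
$\log\alpha - \psi(\alpha) = \log\bar{x} - \overline{\log x}$ (relative
tolerance ~1e-12, Minka starting point), with the scale from the MLE
identity $\alpha\beta = \bar{x}$; near-constant data cap the shape with a
warning. Shape 1 is exponential (random placement); larger shapes mean
more even spacing. The matched random reference
(`random_icd_reference()`) draws exponential ICDs with the data's mean and
the experiment's per-cell event counts over 10,000 cells.

A known artifact: because events closer than 1.5 kb (plus their tract
extents) merge, the smallest ICDs are censored, which inflates the fitted
shape of a truly random process by roughly 0.1-0.2 at wild-type CO
densities and can make a Kolmogorov-Smirnov test against the pure
exponential reference reject. The interference acceptance check therefore
runs the generator with minimal (300 bp) tracts so that CO positioning,
not event extent, is what is being tested; with default tracts the
qualitative ordering of fitted shapes is unaffected.

**Homeostasis.** `homeostasis_trend()` is the least-squares slope of the
per-meiosis CO:NCO ratio against total detectable events; a negative slope
indicates buffering of CO numbers against DSB-number variation. Meioses
with zero NCOs are excluded with a warning, and ratios are not comparable
across MMR genotypes (NCO visibility differs).

**Hypothesis tests** are thin wrappers over R's `fisher.test` (two-sided),
`wilcox.test` (two-sided, continuity correction), `t.test` and `ks.test`,
with Benjamini-Hochberg adjustment via `p.adjust`; the test-suite checks
them against independent hand-built references (hypergeometric
enumeration, the tie-corrected normal approximation, and an exact
two-sample KS by lattice-path counting).

## The synthetic world

`sim_params()` defaults describe a wild-type meiosis of the hybrid:
74.5 COs and 30.5 NCOs per meiosis on the 16 S. cerevisiae chromosomes,
markers at 169 bp mean exponential spacing with 5.8% indels, 44x depth.
Values the source analysis does not pin down were chosen once:
sequencing error 0.002/read (Illumina-like), interference shape 2 (the
even spacing typical of wild-type yeast ICD fits), per-side tract lengths
truncated-normal(1500, 500) bp (the scale of meiotic DSB resection),
~5 multi-DSB clusters per meiosis (~5% of events) with within-cluster
spacing uniform on 100-1400 bp (inside the 1.5 kb single-event window),
a 25% chance that an MMR-deficient tract appears as full conversion (gap
repair) rather than retained hDNA, and a 50:50 conversion:restoration
split in MMR-proficient cells (a free parameter, not an empirical claim).

Crossover positions per chromosome follow a stationary renewal process
with gamma-distributed gaps (shape = interference strength, scale set so
the expected genome-wide count matches `mean_co`). Crossover partners are
chosen by **local haplotype content** — one chromatid carrying parent A
and one carrying parent B at the exchange point — rather than by original
chromatid label: a real exchange joins the two homologues, and the
content-blind choice would make a substantial fraction of later
crossovers silently invisible. Each CO deposits hDNA tracts on the two
recombining chromatids extending away from the exchange; NCOs deposit one
tract on one chromatid; multi-DSB clusters inject a second DSB on a
distinct chromatid in one of the four conservative categories.

`emit_site_counts()` converts matrices to pileup-style counts (Poisson
depth, per-read error, 50:50 strand mixtures for tetrad colonies); a
`deterministic` mode emits rounded expectations for exact round-trip
tests.

What the generator does **not** emulate: alignment artifacts and
reference bias beyond the indel-threshold asymmetry, non-allelic
(ectopic) recombination, aneuploidy and disomy (QC flags are exercised by
constructed fixtures instead), chromatin-driven hotspot landscapes
(positions are uniform given the renewal process), and recombination in
repetitive regions excluded from real marker maps. A green truth-recovery
test therefore establishes the correctness of the calling logic on the
stated generative model, not robustness to every real-data pathology.

Intrinsic ambiguities of the readout — not generator defects — bound what
any caller can recover: crossovers whose tracts run into a chromosome end
are type-U; two same-pair crossovers within the 1.5 kb window cancel at
the flanks; overlapping opposite-homologue conversions are resolved as
noncrossovers. Ground-truth observable CO counts are therefore defined as
haplotype switches between successive Mendelian columns of the finished
matrices, and exact-recovery checks restrict to chromosomes whose planted
events are pairwise separated by at least 1.5 kb.

## Numerical and degenerate-input choices

Thresholds are `>=`-inclusive exactly as written; event separation is
"separate at >= 1500 bp". Empty chromosomes yield empty segment lists;
empty length vectors and fewer than 10 ICDs are errors rather than NaNs;
Fisher tables with zero margins are rejected; the heteroduplex balance
ratio with zero reads on both alleles is false, never NaN. Coordinates
are 1-based inclusive internally; BED is converted at the I/O boundary.
All Monte-Carlo entry points take a `seed` and restore the caller's RNG
state.

## Limitations

* Mechanistic pathway assignment (SDSA vs dHJ routes and intermediate
  cartoons) is out of scope; categories are observational.
* The exchange-point estimate and run-side assignment use marker-index
  geometry; single-marker tracts exactly at the estimate are assigned by
  a deterministic tie-break and individual borderline events can be
  labelled one-sided when two-sided (or vice versa).
* dCOs involving two or three chromatids are never promoted out of
  `none`, mirroring the conservative source convention.
* The median^n aggregate and the matched-mean exponential reference are
  reproduced as specified for comparability, with their statistical
  caveats documented above.
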