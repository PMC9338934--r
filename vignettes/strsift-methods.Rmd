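---
title: "Alignment-free STR expansion screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free STR expansion screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strsift)
```

## The problem

Short tandem repeats (STRs) are tracts of repeating 1-6 nt motifs;
expansions of such tracts cause dozens of neurogenetic disorders.
Detecting expansions in short-read sequencing normally requires aligning
reads to a reference and inspecting loci. strsift instead screens the raw
reads: a read that is mostly repeat is detectable from its sequence alone,
whatever locus it came from. The package processes each sample into
per-motif summary scores and then compares samples across a cohort, either
case-control or one-versus-many.

## Per-read complexity filter

For each read we compute a compression ratio

$$C = \frac{\text{compressed bytes}}{\text{read length in bytes}},$$

using DEFLATE at its fastest setting. Repetitive sequence compresses well,
so low C flags candidate repeat-bearing reads; only candidates are passed
to the (much more expensive) repeat detector.

Numerical convention: C is computed over the **bare DEFLATE stream**
(zlib level 1, windowBits -15, memLevel 8; see `deflate_convention()`).
Container headers would shift every ratio additively and differ between
the zlib, gzip and raw encodings, so the convention is pinned in one
constant, recorded in threshold tables and run manifests, and a frozen
byte-level fixture (a 150 nt homopolymer compresses to 6 bytes) guards it
in the test suite. Input bytes are sequence bytes only - qualities never
enter the ratio.

The decision rule is inclusive (`C <= t_L` passes): a filter false
positive merely reaches the detector and is discarded there, whereas a
false negative is unrecoverable.

### Thresholds and their calibration

Thresholds are read-length dependent: per-read DEFLATE overhead is a
larger fraction of a short read, so the whole C distribution shifts with
L. `calibrate_thresholds()` simulates labelled reads, computes C for all
of them, and picks the threshold maximising Youden's J (sensitivity +
specificity - 1) over the observed C values; among ties the largest
threshold wins, again favouring sensitivity. Calibration with fewer than
1000 reads per class is refused; the built-in table
(`default_thresholds()`) was produced by this function at L = 75, 100,
124, 125 and 150 nt under the uniform background with 20000 reads per
class and seed 101.

Two negative-class designs are exposed, and the distinction matters:

* `negatives = "background"` - pure pseudorandom reads against reads
  carrying at least 45 nt of repeat tract. Under this design the classes
  are essentially separable at zero sequencing error and the calibrated
  classifier is near-perfect (sensitivity and specificity at or above
  0.99) at read lengths of 75 nt and above.
* `negatives = "labelled"` - the negative class is defined purely by the
  45-nt informative-read rule, so it also contains reads carrying 1-44 nt
  of repeat. Reads with 40-44 nt of tract are information-theoretically
  ambiguous against 45-50 nt positives; no threshold separates them. At
  L = 150 these boundary reads are a thin slice of the distribution and
  specificity stays near 0.98, but at L = 50 a 44 nt tract is 88% of the
  read and specificity drops to roughly 0.94. This is the regime in which
  the filter genuinely becomes less specific as read lengths fall below
  75 nt.

A single error-free protocol cannot exhibit both behaviours - perfect
separation and short-read degradation - simultaneously; they belong to the
two designs above, and the acceptance suite checks each claim under its
own design. We verified (by simulation, before freezing any test) that at
zero error the background design is perfectly separable at *both* 150 and
50 nt, and that the orderings above are stable across seeds.

## Exact maximal repetitions

Candidate reads are scanned for **runs**: substrings whose minimal period
p satisfies tract length >= 2p and which cannot be extended either way
while keeping period p. Detection is exact (no mismatches inside a run),
fractional trailing copies extend the tract (`AGCAGCA` is one run of
tract 7, period 3), every run is reported once with its minimal period,
and positions holding `N` belong to no run. Because detection is exact the
recorded repeat purity is identically 1; the field is kept for format
compatibility. The detector is a small C++ routine whose contract is the
runs definition itself; the test suite holds it to exact agreement with an
independent brute-force enumerator on all two-letter strings up to length
12 and on 10^4 random four-letter strings up to length 40, plus the
runs-theorem bound (at most n runs in a length-n string).

`min_tract` (default 9 nt) suppresses ubiquitous short dinucleotide runs
at the recording stage. It is intentionally far below the scoring window,
so it cannot affect scores; it only bounds profile size.

### Canonical motifs

A repeat motif is reported as the lexicographically smallest string among
all cyclic rotations of its primitive root and of the root's reverse
complement, so CAG, CTG, GCA, ... all report as AGC, and GAA/TTC as AAG.
This collapses strand and phase, which a read cannot determine. There are
2, 4, 10, 33, 102 and 350 classes for motif lengths 1-6; trimers through
pentamers total 145 classes. Runs of any period are detected, but
summarisation keeps canonical motifs up to `max_motif_len` (default 6, the
conventional STR range).

## Information scores

Per sample and motif, summarisation produces the count vector
$v = v_1 \dots v_j$ ($v_l$ = number of runs of that motif with tract
length exactly l), and the score

$$s_m = \frac{\sum_{i \le l \le j} v_l \, l}{n},$$

with n the library size (all reads, not candidates), j the read length
and i = floor(0.75 j) by default (112 at j = 150). The window keeps only
reads dominated by repeat sequence; lowering i manually permits detection
of shorter expansions at the cost of background noise.

Two numerical decisions here:

* **Single normalisation.** Counts are stored raw and divided by n exactly
  once, in the score. Dividing the stored vector by n *and* dividing again
  in the score formula would make s scale with 1/n^2, so that sequencing
  the same library twice as deeply would change every score; with a single
  division, duplicating every read leaves every s_m unchanged (a property
  the tests assert exactly). Profile files carry raw counts plus n, so
  either convention is recoverable from disk.
* **The bracket is floor.** Any deterministic rounding of 0.75 j is
  within one unit of any other; floor is used everywhere and recorded via
  the window stored in every score vector.
* The window bounds index **tract length** (the summation variable of the
  printed formula); motif length is capped separately by
  `max_motif_len`.

When several runs of one motif occur in one read, every run counts; a
read cannot support two long runs of the same motif inside the default
window (2 x 112 > 150), so the distinction only affects short-window
analyses, where counting all runs is the conservative (signal-preserving)
choice.

Cohorts with mixed read lengths must be trimmed to a common length first
(`choose_common_length()` returns the minimum of the per-sample modal
lengths); mixed windows are refused at assembly time. Reads shorter than
the trim length are kept untrimmed - trimming downsamples long reads, it
does not filter short ones.

## Cohort statistics

### Motif screening

For each motif with a nonzero score anywhere in the cohort, a one-sided
Mann-Whitney U test asks whether labelled samples have larger scores than
the rest. U is computed from midranks (ties count 1/2). The null is
permutational: when the number of label arrangements C(n1+n2, n1) is at
most `n_perm` (default 10000) it is enumerated exhaustively and the exact
p returned; otherwise `n_perm` random permutations are drawn and the
add-one estimator (1 + #{U* >= U}) / (1 + n_perm) is used, which is never
zero and is reproducible under the supplied seed. Benjamini-Hochberg
correction is applied across exactly the motifs tested, with significance
declared below `alpha` (default 0.05) on the adjusted value. The suite
checks the exact path against an independent exhaustive oracle, the
adjusted values against a literal step-up implementation on 10^4 random
vectors, and the whole screen's type-I error at the nominal level over
200 permuted-label cohorts.

### Outlier detection

One-versus-many: for each motif, the 95% confidence interval of the 95th
percentile of the background group's scores is estimated by BCa bootstrap
(bias correction from the bootstrap distribution, acceleration from
jackknife skewness; `n_boot` defaults to 9999 - odd, so percentile indices
are unambiguous). A query sample is an outlier when its score **strictly**
exceeds the upper bound. Background means the designated background
samples only, never the queries, so the bound does not depend on how many
queries carry expansions. Empirical quantiles use linear interpolation
between order statistics (R type 7) throughout - estimate, bootstrap
replicates and jackknife alike.

BCa degenerates when the bootstrap distribution collapses (e.g. an
all-zero background) or the jackknife variance vanishes; both conditions
are detected and trigger a percentile-bootstrap fallback, reported in the
`method` column. Coverage of the BCa interval for the 95th percentile is
checked by simulation against the closed-form quantiles of normal and
exponential backgrounds (n = 500, 200 replicates: observed ~93-96%
against the nominal 95%).

## The simulation subsystem

`sim_config()` fixes the study conditions; all generators are
deterministic functions of (config, arguments, seed).

* **Backgrounds** are single-nucleotide frequency vectors: uniform, plus
  presets for a human-like composition (~41% GC), a GC-rich bacterial
  genome (~72% GC) and AT-rich protozoan intergenic sequence (~13% GC).
  The named genome presets are the package's own frequency choices; no
  k-mer or positional structure is modelled.
* **Repeat reads** place a periodic tract of 1-15 nt motifs at a chosen
  or random offset. Impurity is per motif copy: with probability
  `motif_change_prob` a copy receives one random substitution. Sequencing
  error is a constant per-base substitution rate applied afterwards -
  no indels, no positional error profile, no quality values. A read is
  labelled repeat-informative at >= 45 nt of repetitive sequence.
* **Loci** are flank + tract + flank, with flanks rejection-sampled from
  the background until the package's own detector finds no run of
  tract >= 15 nt - synthetic stand-ins for repeat-masked genomic flanks,
  removing any reference-genome dependency. Reads are drawn uniformly
  across the locus at a chosen fold-coverage and labelled by their >= 45
  nt overlap with the tract.
* **Cohorts** (`simulate_cohort()`): controls are pure background read
  sets; cases additionally contain reads sampled at 30x locus coverage
  from an expansion locus, topped up with background reads to a fixed
  library size. Output is FASTA plus a manifest, byte-identical under a
  fixed seed.

What passing tests on these fixtures shows - and what it does not: the
generator reproduces the features the method actually exploits (relative
compressibility, tract-length distributions, labelling geometry), but real
sequencing data adds positional error profiles, indels, PCR artifacts,
coverage bias, diploidy and allosomal copy-number effects, none of which
are modelled. Passing the end-to-end fixture demonstrates correct wiring
and statistical behaviour under the stated model, not clinical
sensitivity on real cohorts.

## Problem sizes used in the checks

The shipped suite runs the oracle-equivalence check exhaustively on all
two-letter strings to length 12 and on 10^4 random strings to length 40;
classifier metrics use 5000 reads per class for calibration and 20000 per
class held out; the end-to-end fixture is 5 cases and 20 controls at
10^4 reads per sample with a 150 nt AGC tract; null calibration uses 200
permuted screens of 5 motifs (6 vs 6 samples, exhaustively enumerated
nulls); bootstrap coverage uses 200 replicate backgrounds of 500 values
with 1999 bootstrap replicates. These sizes are the package's chosen
trade-off between Monte-Carlo resolution and a test suite that runs in a
few minutes.

## Known limitations

* No locus localisation: a flagged motif says *that* a sample is enriched
  for long tracts of that motif, not *where*; follow-up needs an
  alignment-based tool.
* Expansions much shorter than the scoring window (i = 0.75 j) are
  invisible at default settings; lower `i` deliberately when hunting
  short expansions.
* Chromosome copy number is not modelled; allosomal expansions are
  detectable but their scores are not dosage-corrected.
* The compression filter's thresholds are only as good as their
  calibration conditions; recalibrate for unusual read lengths, base
  compositions or error rates rather than reusing the built-in table.
* SAM input is sequence-only text streaming; BAM/CRAM decoding is out of
  scope.

## A worked miniature

```{r example, eval = FALSE}
dir <- tempfile("demo")
manifest <- strsift_simulate(dir, n_cases = 2, n_controls = 20,
                             reads_per_sample = 2000, seed = 7)
man <- read_manifest(manifest)
profiles <- lapply(seq_len(nrow(man)), function(i)
  process_sample(man$path[i], sample_id = man$sample_id[i]))
cohort <- assemble_cohort(lapply(profiles, information_scores),
                          setNames(man$label, man$sample_id))
screen_cohort(cohort, "case", seed = 1)
call_outliers(cohort, "control", seed = 1)
```
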