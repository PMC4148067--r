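---
title: "Comparing bacteria-clonable and yeast-only clone libraries"
author: "clonability package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing bacteria-clonable and yeast-only clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonability)
library(dplyr)
```

## The question

The *C. elegans* genome was assembled from large-insert clones propagated
in *E. coli* (cosmids, ~30-40 kb, and fosmids), but roughly a fifth of
the genome repeatedly failed to clone in bacteria and was only recovered
in yeast, via YACs. Those "gap sequences" are an unusual natural
experiment: whatever distinguishes them from the rest of the genome is a
candidate barrier to moving DNA from a eukaryote into a prokaryote.

This package implements the comparative analysis of the two clone
classes as a reusable, fully tested pipeline:

1. **Trimming** — YACs bridge gaps but their ends overlap finished
   cosmid/fosmid sequence (anywhere from 0% to 100% of a YAC, about 7%
   on average). Every base of a YAC covered by the merged cosmid/fosmid
   set is removed, leaving *YAC-exclusive* segments; these, not the raw
   YACs, are the unit of all downstream analysis.
2. **Repeat profiling** — per-clone RepeatMasker-style summaries
   (element counts, occupied bp, percent of sequence) by category:
   retroelements, DNA transposons, rolling-circles, unclassified
   repeats, small RNA, satellites, simple repeats, low complexity;
   plus *bases masked* (the union over all categories) and *total
   interspersed repeats* (the union excluding small RNA, satellites,
   simple repeats and low complexity).
3. **Resampling nulls** — for each library, matched random clone
   libraries (same clone count, lengths drawn from the observed mean and
   SD, placed uniformly on the genome) give an empirical null for any
   library statistic.
4. **Stratification** — by chromosome quarter (the two extreme quarters,
   i.e. the repeat-rich arms, versus the two middle quarters) and by
   clone length (below versus at-or-above the median), with Welch
   t-tests for group contrasts.
5. **Gene content** — gene counts, densities per MB and length
   statistics per library and product category (CDS, ncRNA, tRNA, rRNA),
   the 21U piRNA fraction of the ncRNAs, per-chromosome counts with a
   leave-one-chromosome-out re-ratio, and the repeat-masked percent of
   named regions such as piRNA clusters.

## Data model and conventions

Everything is a tibble. Intervals carry `chrom`, `start`, `end` in
**0-based half-open** coordinates, so length is `end - start` and
adjacent intervals (`end == next start`) merge into one under coverage
semantics. The file readers convert at the boundary: BED-like tables are
already half-open, RepeatMasker `.out` and GFF3 are 1-based inclusive.
Interval sets never mix chromosomes inside an operation; everything is
per-chromosome and strand-agnostic (none of the analyses here are
stranded).

Readers are strict: malformed records are rejected with the offending
line identified, never silently skipped. Unknown repeat classes are kept
as `Unclassified` with a warning rather than dropped, so totals always
account for every annotation row.

## Statistical choices

**Per-clone summaries.** Element counts follow annotation rows (two
overlapping same-category elements count twice), while occupied bp uses
per-base unions — the same convention RepeatMasker's own summary tables
use. Elements spanning a clone boundary are clipped to the clone, since
a masker run on the clone sequence would only see the clipped part.
Library tables report mean, median, min, max and the mean over clones
with a strictly positive value ("non-zero mean").

**Matched random libraries.** Lengths are `Normal(mean, sd)` truncated
by redraw (not clipping, which would pile mass at the bounds) to
`[floor, longest chromosome]`, with a 500 bp floor because the plain
normal description leaves tiny and negative lengths unhandled.
Chromosomes are sampled proportionally to length so placement is uniform
per base, and random clones may overlap each other — at genome scale the
effect on any statistic is negligible and the simpler null is easier to
reason about. The empirical p-value uses add-one smoothing,
`p = (1 + #{null >= observed}) / (1 + R)`, right-tailed by default, so
`p` is never zero and is exactly uniform on its support under the null;
the type-I error of this construction is verified at `alpha = 0.05`
over 500 simulated null datasets in the test suite.

**Stratification.** A clone belongs to the quarter containing its
midpoint; midpoint assignment avoids double-counting spanning clones,
and the boundary is half-open (a midpoint at exactly 25% of the
chromosome falls in the middle stratum). The length split uses the lower
of the two middle order statistics as "the median" so that the split is
always realizable on integer lengths; clones strictly below it form one
group. Location histograms average the per-chromosome distributions with
equal chromosome weight by default (`weight = "pooled"` weights by clone
count instead). The two-group test is Welch's unequal-variance t-test —
the group variances of masked percentages are evidently unequal between
arms and centers — with the convention `p = 1` when both groups are
constant and equal. Which t-variant, and whether the clone or the region
is the observation unit, is left configurable because the choice is
genuinely open; clones are the default unit.

**Gene assignment.** A gene belongs to a library when its midpoint lies
in any clone of the library (`contained` and `any-overlap` rules are
available). Because the finished and YAC-exclusive interval sets are
disjoint after trimming, midpoint assignment guarantees a gene is never
double-counted between them. Densities divide by the library's merged
coverage in bp. 21U piRNA genes are recognized by the `21ur-` naming
convention or a `piRNA` biotype, only on ncRNA records; a `21ur-` name
on a non-ncRNA record is a data error and warns.

**YAC-YAC overlaps** are *not* removed during trimming: only overlap
with finished sequence is. The trimmed pieces of different YACs may
therefore share bases; library-level bp totals use per-base unions where
that matters.

## The synthetic genome

Real inputs (clone placements, RepeatMasker output, genome annotation)
require external downloads and hours of compute, so the package ships a
generator that emulates the *structure* the analysis relies on, at desk
scale, with a recorded truth file. The default configuration is:

* **5 chromosomes of 1 Mb.** Large enough for tens of clones per
  chromosome and stable stratum contrasts, small enough that the whole
  bundle generates in seconds.
* **Gap regions** (the future YAC-exclusive territory): ~10 per
  chromosome, lognormal lengths with median 23.7 kb — the median of the
  real YAC-exclusive segments — placed with 75% probability on the
  extreme quarters, mirroring the arm bias of real gaps. With these
  values a chromosome is roughly a quarter gap; the real genome is
  nearer a fifth, but at 1 Mb per chromosome the clone counts and the
  23.7 kb median are the quantities downstream tests recover, and they
  take precedence.
* **Cosmids** tile all non-gap sequence with mean length 32.5 kb (the
  real cosmid median) and random 15-25 kb overlaps; every non-gap base
  is covered, so trimming recovers the planted gaps exactly. A handful
  of fosmids ride along. **YACs** span each gap plus a Beta-distributed
  total end-overlap into finished sequence with mean 7%, split randomly
  between the two ends; three extra YACs are planted fully inside
  finished sequence, emulating the fully-covered YACs of the real
  libraries.
* **Repeats** come from a small table of families with fixed element
  lengths and per-kb densities, a 2x multiplier on the extreme quarters,
  and per-family gap multipliers (2x for DNA transposons, 3x for
  PiggyBac and unclassified repeats, 5x for satellites). The planted
  densities put cosmid-side masking near 10-14% and YAC-side masking
  near 30%, the same regime as the real libraries.
* **One piRNA cluster**: a 250 kb span inside a 330 kb gap on `chrIV`
  carrying exactly 800 21 bp 21U genes, with all repeat densities
  suppressed to 0.4x inside the cluster — dense piRNAs in otherwise
  low-repeat, bacteria-unclonable sequence. Background ncRNAs are
  planted at 500/MB outside gaps (45% of them 21U, scattered) and
  250/MB inside gaps (none 21U), so removing the cluster chromosome
  flips the direction of the YAC:cosmid ncRNA density ratio, as in the
  real data.
* Gene tracks otherwise follow the real densities per MB (protein-coding
  238 vs 182, tRNA 1.5 vs 4.2, rRNA 0.15 vs 0.45 for non-gap vs gap).

The truth file records every planted quantity. For the library-level
repeat contrasts it records *analytic expectations*, not the raw
multipliers: expected coverage of a Poisson process of rate `lambda`
with fixed element length `L` is `1 - exp(-lambda * L)`, computed per
stratum (arm/middle x gap/non-gap x cluster) and averaged over the
actually generated clone geometry. Arm enrichment plus arm-biased gap
placement make the marginal YAC:cosmid ratio larger than the gap
multiplier alone, and the truth file carries the exact planted value so
recovery can be tested at a 10% tolerance without hand-waving.

What the generator does **not** emulate: real sequence content (the
optional FASTA is uniform random bases; nothing downstream reads it),
the real repeat family spectrum and length distributions, divergence
statistics, GC structure, assembly gaps within chromosomes, and any
biology of why gaps fail in bacteria. Passing tests on synthetic data
therefore demonstrate that the *pipeline arithmetic and statistics*
recover planted structure — not that the biological conclusions
transfer to any particular real dataset.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; the generator, the
random libraries and the full pipeline are deterministic functions of
(inputs, seed), and `run_clonability()` writes byte-identical reports on
reruns, together with a JSON manifest of input digests, seed and
parameters. The test suite exercises the interval algebra against an
independent per-base bitmap oracle (1,000+ randomized instances), the
null calibration over 500 simulated datasets at `alpha = 0.05`, and
planted-contrast recovery on the default bundle; those sizes keep the
whole suite in minutes on one CPU while leaving the Monte Carlo error
well inside the tested tolerances.

## A short tour

```{r tour, eval = FALSE}
cfg <- synthetic_config(seed = 1)
bundle <- generate_synthetic_bundle(cfg, outdir = "bundle")

res <- run_clonability(
  chrom_sizes = "bundle/chrom.sizes",
  clones = "bundle/clones.tsv",
  repeats = "bundle/repeats.out",
  genes = "bundle/genes.gff3",
  outdir = "reports", seed = 1, replicates = 100,
  clusters = "bundle/cluster.bed", exclude_chrom = "chrIV")

res$table1_repeats    # per-library repeat summaries
res$stratify_tests    # Welch t-tests for the location contrast
res$chrom_exclusion   # ncRNA ratios with and without chrIV
```

## Known limitations

* The null model matches clone count and length only; no GC-, gap- or
  chromosome-matched nulls (regioneR-style covariate matching is out of
  scope).
* Repeat divergence and sequence-level analyses are out of scope; the
  pipeline consumes annotations, it does not produce them.
* Fosmids are carried through profiling but, as in the source analyses,
  location and gene comparisons focus on cosmids versus YAC-exclusive
  segments.
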