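---
title: "Assessing bisulfite conversion quality with bsqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing bisulfite conversion quality with bsqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsqc)
```

## The problem

Bisulfite treatment converts unmethylated cytosine to uracil (read as T
after PCR) while methylated cytosine is protected. Methylation calling
therefore rests on an assumption that the chemistry ran to completion: an
unconverted, unmethylated C is indistinguishable from a methylated one. In
mammalian genomes methylation is confined almost entirely to CpG
dinucleotides, which gives a built-in control: cytosines in CHG and CHH
context ("nonCGc" sites, H ∈ {A, C, T}) should read as fully converted, so
the observed conversion rate at nonCGc sites — `1 - methylation ratio` —
measures treatment completeness directly. `bsqc` builds a quality report
around that statistic before any downstream analysis is attempted.

This control is invalid for genomes with substantial non-CpG methylation
(notably plants); there the user needs positive/negative control regions
instead, and `bsqc`'s verdicts should not be trusted. That limitation is
inherent to the method, not an implementation detail.

## Chromosome-level summary

`chrom_summary()` counts the nonCGc sites (`TNCGC`), the subset with at
least 1x coverage (`TNCGCwC`), their ratio as a percentage, and the
min/quartiles/median/mean/max of conversion over the **covered** sites.
Uncovered sites carry no observation, so including them in the order
statistics would be incoherent (a chromosome with 1.4% coverage and min 0
could otherwise never show a minimum above zero); statistics over covered
sites only is therefore a fixed design choice, documented here because
per-site reports list covered and uncovered sites alike.

Quantiles use linear interpolation between order statistics
(`stats::quantile` type 7, R's default), fixed so that tabulated summaries
are bit-reproducible. The coverage percentage is rendered with three
decimals and a trailing `%` (e.g. `40.000%`), and the summary-table header
spells `25th_percentile` / `75th_percentile`.

`conversion_advisory()` splits covered nonCGc sites at conversion 0.99
into a high group A and low group B and issues a verdict from the fraction
in B: above 30% `investigate` (the treatment likely failed), below 5%
`proceed` (optionally restricting analysis to CpGs near group-A sites),
`caution` between. The three cutoffs are conventional illustrative values
and all are exposed as arguments.

## Region-level analysis and classification

When target regions are supplied (genes, CpG islands, promoter sets, or
`mspi_digest()` output), `region_summaries()` aggregates the nonCGc sites
inside each half-open interval: `N` sites, `n` covered, and the mean and
median conversion over the covered sites. Regions are then classified on
two independent axes by `classify_regions()`:

| rule | class | condition | default |
|------|-------|-----------|---------|
| conversion high | `median_bs >= B` | inclusive | `B = 0.99` |
| conversion low | `median_bs <= b` | inclusive | `b = 0.6` |
| coverage high | `n/N >= L` | inclusive | `L = 0.5` |
| coverage low | `n/N < l` | **strict** | `l = 0.1` |

The boundary semantics are deliberately asymmetric: a region with `n/N`
exactly equal to `l` is *neither*, while one exactly at `L`, `B` or `b`
takes the corresponding class. This follows the rules as conventionally
stated for this analysis, and the asymmetry is preserved literally rather
than smoothed over, so results are comparable with the original tooling.
Regions with `N == 0` are reported in a separate no-nonCGc list (class
`undefined`) rather than silently dropped; regions with `n == 0` are
coverage-low (0 < `l`) but conversion-`undefined`.

`small_group_check()` implements the triage rule: a low-metric class with
fewer than 10 regions or fewer than 0.5% of all regions is *negligible* —
the sample is probably well sequenced on that axis and the structure
comparison below is unnecessary. The pipeline still computes requested
comparisons and only logs the advisory, so output sets stay deterministic.

## Sequence structure

`region_composition()` profiles each region: %A, %C, %G, %T, %(C+G), %CGc
(plus-strand CpG cytosines), %nonCGc (plus-strand non-CpG cytosines) and
%low_count (softmasked lowercase fraction, the repeat metric of
UCSC-distributed genomes — computed from the input FASTA itself so the
package needs no external annotation; for a UCSC soft-masked reference the
two are the same thing). Conventions, each of which was a genuinely open
choice:

* CpG status is assessed on the plus strand only; the reverse-strand
  cytosine of a CpG is not double-counted. This matches counting directly
  on the reference string as distributed.
* A region-final `C` is classified by looking one base past the region
  boundary when the sequence extends that far, else it counts nonCGc.
* `N` bases count toward region length but toward no base percentage, so
  percentages may sum below 100 in N-containing regions (flagged `has_N`).
  Percentages of region length, not of non-N bases, keep the identities
  `%CGc + %nonCGc = %C` and `%GC = %C + %G` exact.

`compare_region_groups()` emits, per metric, the raw per-region values and
five-number-plus-mean summaries for the high vs low group — the data
behind the usual boxplot comparison (PNG rendering is optional). Dramatic
differences, e.g. low-coverage regions with much higher GC or repeat
content, point at library preparation or alignment causes rather than
random failure.

`mspi_digest()` reconstructs RRBS target regions in silico: MspI cuts
`C^CGG`, so a cut coordinate is placed after the first C of every `CCGG`
(case-insensitive), candidate fragments are the intervals between
consecutive cuts (terminal stretches are not fragments), and the
size-selection window keeps lengths in `[min_len, max_len]` inclusive,
default 40–220 bp. Whether the fragment intervals include the `CCGG` ends
is a representation choice; the cut-coordinate convention here is
self-consistent (fragments tile between cuts, never overlap) and is what
the tests pin down.

## Trimming

Illumina runs lose quality toward the 3' end and often carry terminal `N`
runs; unaligned low-quality reads are simply lost data. `fixed_trim()`
removes a set number of bases from each end (defaults 5' = 5, 3' = 10).
`quality_trim()` strips terminal `N`s, then trims the 3' end while base
quality is below the cutoff (default Q20, the conventional 1%-error
threshold), and repeats both passes to a fixed point. The iteration is
what makes the operation idempotent: a single pass can expose an interior
`N` at the new 3' end. Reads shorter than `min_len` are dropped and
counted, and the report always conserves `kept + dropped = input`.
Equivalence with any specific aligner's trim routine is not claimed; the
value of this rule is that it is simple and exactly documented.

## Coordinates and dialects

Internally everything is 0-based half-open. Per-site tables default to
1-based input positions (`coord_base = 1`, the common per-site report
convention) and target files to BED-style 0-based half-open, with switches
for the other convention in both cases. Per-site tables are accepted with
a header naming the six columns in any order, or headerless with an
explicit `col_names` map, since aligners differ only in column order.
An undefined methylation ratio (coverage 0) is serialised as `NA`, never
as 0 — "no data" must not masquerade as "fully converted".

## The synthetic-data generator

`simulation_spec()` fixes the study conditions; all generators are
deterministic given its seed. The model:

* **Reference**: a first-order base chain. The `C→G` transition is scaled
  by `cpg_enrichment` and the `G` probability after non-C compensated so
  the marginal GC fraction stays exactly `gc_fraction`; mammalian CpG
  depletion corresponds to enrichment well below 1. Softmasking is
  per-base Bernoulli(`repeat_fraction`).
* **Methylation table**: every C on either strand is a site; context (CG,
  CHG, CHH) follows from two-base lookahead on the site's strand, with
  lookahead off the end (or into N) defaulting to CHH. A site is covered
  with probability `covered_site_fraction`; covered sites draw
  zero-truncated Poisson(`mean_coverage`) depth; the methylated-read count
  is binomial with success probability `1 - true_conversion` at nonCGc
  sites and `cpg_methylation` at CG sites.
* **Reads**: uniform positions, qualities declining 3'-ward by
  `quality_decay` Phred/base plus Gaussian noise, clamped to [2, 40].

Defaults are chosen once to emulate a modest mammalian experiment: GC 0.41
and CpG observed/expected 0.25 (human-like), repeat fraction 0.45,
conversion 0.996, CpG methylation 0.75, 30% of sites covered at mean depth
5, and a 100 kb chromosome — which yields on the order of 10^4 covered
nonCGc sites, enough for the recovery tests to resolve conversion to ~3
standard errors. What the generator does **not** emulate: blocky repeat
structure, coverage autocorrelation and GC bias, PCR duplicates,
sequencing errors, paired ends, and CpG-island methylation bimodality.
Passing recovery tests therefore show the statistics are computed
correctly under the stated sampling model, not that real libraries are
free of those artefacts.

## Numerical and degenerate-input choices

* Quantiles: type 7 everywhere (summaries and group comparisons).
* Empty sets: a chromosome without nonCGc sites yields a flagged summary
  with undefined statistics; a region without covered sites has undefined
  mean/median and coverage fraction 0; the advisory refuses to run with no
  covered nonCGc sites at all (an error, since any verdict would be
  fabricated).
* An empty high or low group skips the structure comparison with an
  advisory instead of producing empty summaries.
* Ties at classification boundaries follow the table above exactly.
* Fragments require at least two cut sites; otherwise the digest is empty.

## Worked sizes

The test suite and the bundled acceptance script run entirely on generated
data: a 100 kb chromosome (~39,000 cytosine sites, ~12,000 covered nonCGc
sites), 100–200 target regions, 1,000-sequence property sweeps and
2,000-read trimming runs, which keeps a full run to well under a minute
while leaving the statistical checks (3-standard-error recovery bounds)
adequately powered.
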