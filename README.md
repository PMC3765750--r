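# bsqc — quality assessment for bisulfite-treated methylation sequencing

`bsqc` answers a question every bisulfite sequencing experiment must face
before methylation calling: **did the chemistry and sequencing actually
work?** In mammalian genomes, cytosines outside a CpG context (CHG/CHH,
"nonCGc" sites) are essentially unmethylated, so the conversion rate
observed at those sites,

    conversion = 1 − methylation ratio = 1 − (methylated reads / coverage),

directly measures how complete the bisulfite treatment was. The package
targets analysts holding per-cytosine methylation tables from any
bisulfite aligner (plus, optionally, the raw FASTQ and the softmasked
reference) who want a defensible QC verdict and a diagnosis when regions
under-perform.

## What it computes

* **Chromosome-level conversion QC** — counts of nonCGc sites (`TNCGC`),
  covered nonCGc sites (`TNCGCwC`), their percentage, and the
  min/quartiles/median/mean/max of conversion over covered sites, plus
  histogram data and a proceed/caution/investigate advisory based on the
  fraction of sites with conversion < 0.99.
* **Target-region analysis** — per-region mean/median conversion over the
  region's covered nonCGc sites, and classification on two axes with
  thresholds `B`, `b` (median conversion ≥ B high, ≤ b low; defaults
  0.99/0.6) and `L`, `l` (covered fraction n/N ≥ L high, < l low; defaults
  0.5/0.1).
* **Sequence-structure comparison** — %A, %C, %G, %T, %(C+G), %CGc,
  %nonCGc and %low_count (softmask repeat content) per region, compared
  between high and low classes to reveal composition-driven failure modes.
* **Read trimming** — fixed-length (defaults 5 bases at 5', 10 at 3') and
  idempotent quality-based trimming of Sanger- or Illumina-1.3-encoded
  FASTQ.
* **In-silico RRBS targets** — MspI (`C^CGG`) digestion with 40–220 bp
  size selection.
* **Synthetic fixtures** — seeded generators for softmasked references,
  methylation tables, reads and target sets with known ground truth.

## Worked example

```r
library(bsqc)

spec <- simulation_spec(seed = 42, genome_length = 50000)
ref  <- generate_reference(spec)            # softmasked FASTA-style sequence
tbl  <- generate_methyl_table(ref, spec)    # per-cytosine methylation table

cs <- chrom_summary(tbl, "chrS1")
cs$TNCGC; cs$TNCGCwC; format_percent(cs$TNCGCwC, cs$TNCGC); cs$mean
#> 19364
#> 5888
#> "30.407%"
#> 0.9954656

conversion_advisory(tbl)$verdict
#> "proceed"

regions <- generate_targets(ref, 100, c(500, 2000), seed = 43)
cls <- classify_regions(region_summaries(tbl, regions))
table(cls$bs_class)
#>      high       low   neither undefined
#>       100         0         0         0
```

Reading: of 19,364 nonCGc sites, 5,888 (30.407%) have coverage; their mean
conversion 0.9955 and the 2.2% of sites below conversion 0.99 give the
`proceed` verdict (the simulation's true conversion was 0.996). All 100
regions have median conversion ≥ 0.99, hence class `high`; with ~30% of
sites covered per region, none reach the high-coverage cutoff `L = 0.5`
and none fall below `l = 0.1`, so no coverage problem is flagged either.

The same analysis runs from files:

```r
res <- run_partial("methyl_table.tsv",
                   run_config(chrom = "chr1", prefix = "sample",
                              out_dir = "qa", targets = "targets.bed",
                              reference = "genome.fa"))
```

writing `sample.chr1.summary.table.txt`, `sample.chr1.BS.tsv`,
`sample.chr1.target.summary.table.txt`, the four
`highBS/lowBS/highCoverage/lowCoverage` `.target` and `.seq` lists and the
`seq.bisulfite.tsv` / `seq.coverage.tsv` comparison tables.

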