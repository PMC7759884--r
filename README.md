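# gsurvey

Genome survey sequencing analysis with contaminant screening, in R.

## The problem

Before investing in long-read sequencing, a genome project typically runs a
short-read *genome survey*: a single paired-end Illumina library is used to
estimate the genome size, heterozygosity and repeat content, to flag
microbial contamination, and to harvest microsatellite (SSR) markers. For
field-collected plants this is complicated by endophytic microbes: their
DNA is co-extracted, consumes sequencing volume, distorts the k-mer
spectrum (inflating the size estimate) and misleads the assembly. `gsurvey`
implements the whole desk-side analysis as a reusable, testable pipeline:

1. **Read QC** — whole read pairs are discarded when either mate contains
   an adapter substring (≥ 12 bp exact match), either mate has > 10% N, or
   more than 20% of the pair's combined bases fall below Phred 5.
2. **17-mer spectrum survey** — canonical k-mer counting and the classic
   peak-based estimators (below).
3. **Minimal assembly** — a de Bruijn unitig assembler (k = 41, low-count
   k-mers pruned) standing in for a production contig assembler, plus
   N50-style statistics and per-contig GC / mean k-mer depth.
4. **Contaminant screening** — contigs ≥ 500 bp are placed in the
   (GC%, depth) plane; contigs inside user-declared *stray regions* are
   pulled, labelled from a 12/13-column tabular hit file (best hit by bit
   score at E ≤ 1e-5), and the microbial ones seed a contaminant k-mer
   database; read pairs sharing ≥ 50% of either mate's 17-mers with that
   database are removed.
5. **SSR detection** — maximal perfect tandem repeats of primitive 1-6 bp
   motifs with minimum repeat counts 10/6/5/5/5/5, reported in standardised
   rotation- and strand-collapsed motif classes (`A/T`, `AT/AT`,
   `AAT/ATT`, ...).
6. **Simulation** — a ground-truthed generator of diploid host genomes
   (configurable SNP heterozygosity, exact-repeat fraction, GC) plus
   high-GC microbial contaminants, sequenced into error-bearing paired-end
   reads with per-pair origin labels, so every stage is verifiable against
   known truth.

## The estimators

With `species(d)` the number of distinct canonical 17-mers seen at depth
`d` and `occ = Σ d·species(d)` the total 17-mer occurrences:

    genome size     = occ / main peak depth
    error rate      = species(1) / occ
    revised size    = genome size × (1 − error rate)
    heterozygosity  = a / (17 × (2 − a)),   a = half-peak species ratio
    repetitive rate = Σ_{d > 1.8×peak} d·species(d) / Σ_{d > boundary} d·species(d)

where the *main peak* is the spectrum mode beyond the low-depth error
region (first local minimum ≥ 2), `a` is the fraction of genomic k-mer
species in the half-depth window (0.4-0.6 × peak; heterozygous k-mers of a
diploid sit at half the homozygous depth), and k-mers deeper than 1.8 ×
the peak are attributed to repeats.

## Worked example

```r
library(gsurvey)

cfg <- pipeline_config(
  simulate = simulation_config(
    host_length = 2e5, repeat_fraction = 0.4,
    contaminants = list(list(length = 5e4, gc = 0.65, abundance = 0.05)),
    coverage = 50, seed = 42),
  regions = list(stray_region(55, 85, 0, 25, label = "high_gc_low_depth")))
report <- run_pipeline(cfg)
print(report)
```

prints (computed, not typed):

```
== genome survey report ==
raw:   41667 pairs, 0.01 Gb
clean: 37084 pairs, 0.01 Gb (Q30 99.8%, GC 38.5%)
discarded: adapter=2083, n_fraction=833, low_quality=1667
pre-decontamination estimate:  depth 44x | 9938512 k-mers | size 0.23 Mb | revised 0.22 Mb | het 0.28% | repeats 34.7%
post-decontamination estimate: depth 44x | 9433064 k-mers | size 0.21 Mb | revised 0.21 Mb | het 0.35% | repeats 36.5%
assembly (post): 620 contigs | total 129373 bp | max 1443 bp | N50 238 bp | N bases 0.00%
contamination: 5.1% of clean bases removed
overestimation: 0.01 Mb (5.3%) | coverage: 62.22%
SSRs: 5
```

Reading it: ~11% of raw pairs carried an injected QC violation and were
discarded; the 5% contaminant read share was recovered (5.1% of clean
bases removed, all of contaminant origin at this seed); the
pre-decontamination genome size (0.23 Mb) overestimates the 0.2 Mb host
because contaminant k-mers inflate the occurrence total, and the
post-decontamination estimate moves back toward the truth; the repetitive
rate (~36%) tracks the simulated 40% exact-repeat fraction.

Every stage is also a CLI subcommand (`simulate`, `qc`, `kmer`,
`assemble`, `gcdepth`, `decontam`, `ssr`, `all`):

```sh
Rscript exec/gsurvey simulate --out sim --seed 5 --host_length 50000 --coverage 20
Rscript exec/gsurvey qc --fastq1 sim/reads_1.fastq --fastq2 sim/reads_2.fastq --out qc
Rscript exec/gsurvey kmer --fastq1 qc/clean_1.fastq --fastq2 qc/clean_2.fastq --out kmer
```

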