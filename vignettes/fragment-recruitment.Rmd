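---
title: "Fragment recruitment and rule-based species presence calling"
author: "frpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment recruitment and rule-based species presence calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frpkit)
```

## The problem

Shotgun metagenomes of fruit- and flower-surface (carposphere /
phyllosphere) communities are shallow, host-contaminated and dominated by
taxa with patchy database coverage. Genus-level classifiers disagree with
one another, and species-level assignment from short reads is unreliable if
it relies on a single best alignment per read without any check of *how*
the reads cover the candidate genome. Fragment recruitment plots (FRPs)
address this: every quality-trimmed metagenomic sequence read (MSR) that
survives host depletion is aligned to a curated set of candidate genomes,
each read's best hit is kept, and the reads recruited to one genome are
drawn as genome position against percent identity. A genuinely present
species recruits many reads, uniformly along the genome, at high identity;
database artifacts recruit reads into isolated islands (conserved rRNA
operons, mobile elements) or at uniformly low identity.

`frpkit` turns that visual procedure into an explicit, tested rule set.

## The statistics

For each genome with recruited reads the package computes:

* **read-based ANI** — the unweighted mean percent identity of the
  recruited reads. This is a proxy computed from read alignments, not
  genome-to-genome ANI. It is reported in bands (95–100, 90–95, 80–90,
  70–80, below 70) matching the colour legend of species-presence tables.
* **RSD**, the coverage-uniformity statistic — the genome (all contigs
  concatenated in manifest order) is divided into ten sections; RSD is the
  standard deviation of the ten per-section read counts divided by their
  mean. Uniform coverage gives RSD near 0. All reads in a single section
  give exactly `sqrt(10)` ≈ 3.162 regardless of read count, which is the
  failure mode the statistic was designed to catch.
* **two-cloud detection** — a bimodal identity histogram (one cloud from
  the database species or a very close relative, one from a more distant
  relative recruited for lack of a better reference) is flagged and
  reported as an asterisk alongside the presence call.

A species is called **present** when its genome recruited at least 1000
reads *and* RSD < 0.8 (strict). Both thresholds are configuration values;
the defaults are the study conditions this pipeline reproduces. The
reported relative abundance is the recruited read count divided by the
sample's total quality-trimmed reads (switchable to the host-depleted
denominator via `pipelineConfig(denominator = "depleted")` — the analysis
convention leaves this ambiguous, so it is explicit here).

```{r presence}
profile <- new("RecruitmentProfile", genomeId = "demo", nReads = 1500L,
               ani = 96.2, sectionCounts = rep(150L, 10), rsd = 0.5,
               identityHistogram = setNames(c(rep(0, 36), 1500, rep(0, 4)),
                                            60:100),
               twoClouds = FALSE,
               cloudSummaries = data.frame(cloud = "all", n_reads = 1500,
                                           mean_identity = 96.5))
callPresence(profile)
```

## Pipeline stages and their rules

1. **Quality trimming** (`trimRead`, `trimReads`, `trimFastq`): sliding
   window of 10 bases advancing by 4; the read is truncated at the start of
   the first window whose mean Phred quality drops below 20; then both ends
   are trimmed while the terminal base quality is below 20; reads shorter
   than 50 bases are dropped. The window scan direction (5'→3', truncation
   at the first failing window start, end-trimming second) is fixed here
   because the original tooling leaves the order unstated; fixing it makes
   the operation deterministic and testable, and a final partial window is
   evaluated over the bases it covers so a short low-quality tail cannot
   slip through. Because truncation shifts the window frame and can expose
   a new low-quality tail, the three steps are re-applied until the kept
   range stabilises — trimming an already-trimmed read then changes
   nothing.
2. **Host depletion** (`depleteHost`): a read is removed when it aligns to
   any host-plant genome with ≥ 60% identity and ≥ 60% query coverage
   (inclusive thresholds, per the "minimum" wording). Coverage is computed
   along the query (alignment length / query length), the conventional
   reading; a subject-side coverage is not available from the tabular
   alignment format without subject lengths.
3. **Database selection** (`selectGenera`, `buildManifest`): a genus enters
   the recruitment database when any classifier reports it at ≥ 0.1% in any
   sample; one representative genome per species of those genera (where
   available — representativeness is a curated input mapping, not an
   algorithm), extended with a curated list of lactic- and acetic-acid
   bacteria whose provenance is recorded in the manifest's `source` column.
4. **Recruitment** (`bestHit`, `recruitReads`): records below 60% identity
   or coverage are discarded; per read the highest bit score wins, ties
   broken by higher identity then lexicographically smallest genome id.
   The tie-break order is this package's convention (only "best hit" is
   specified by the method); it is deterministic and config-independent.
   Reads are assigned to sections by the midpoint of their subject
   interval, which is robust to reads straddling a boundary.
5. **Presence calls** (`callPresence`, `presenceTable`): as above. When two
   clouds are detected and the high cloud's mean identity exceeds 90%, the
   reported ANI band follows the high cloud, mirroring how species with a
   qualifying high-identity cloud are reported.
6. **Community statistics** (`simpsonIndex`, `pielouEvenness`,
   `brayCurtis`, `permanova`, `pairwisePermanova`, `simperAnalysis`,
   `pcaOrdination`, `diversityTable`): Gini–Simpson (1 − Σp²) is used for
   diversity — the orientation under which the least diverse sample scores
   lowest, matching how the index is tabulated; Pielou evenness uses the
   natural log and excludes zero-abundance taxa from the richness; PERMANOVA
   partitions squared Bray–Curtis distances with pseudo-F =
   (SS_between/(k−1))/(SS_within/(n−k)) and p = (1 + #{F* ≥ F})/(1 +
   permutations) under seeded label permutation (999 by default — the
   method description gives no count); SIMPER decomposes the mean
   between-group Bray–Curtis exactly into per-taxon contributions; PCA
   filters taxa below 0.9% everywhere, mean-centers without scaling
   (relative abundances share a unit; scaling is one switch), and fixes
   component signs by making the largest-magnitude loading positive.
   Pairwise PERMANOVA p-values are unadjusted by default (Benjamini–
   Hochberg available).

## Numerical and degenerate-input choices

* RSD uses the sample (n−1) standard deviation, the default of the
  numerical environment the procedure originated in; population mode is a
  single switch (`sdMode = "population"`).
* Zero recruited reads give flagged `NA` for ANI and RSD, never a number;
  `callPresence` treats missing RSD as failing the uniformity rule.
* Section boundaries are `floor(L/10)` wide with the last section
  absorbing the remainder, so counts always sum to the recruited reads.
* Cloud detection smooths the 1%-bin identity histogram with a centered
  3-bin moving average, requires each cloud basin to hold ≥ 5% of the
  recruited reads *and* ≥ 25 reads (sparse histograms cannot support a
  bimodality claim), and requires the valley between peaks to fall to
  ≤ 50% of the smaller peak's smoothed height. These thresholds automate a
  visual judgement and are all exposed in `detectClouds()`.
* PERMANOVA with all-zero distances, PCA on a zero-variance filtered
  table, and Pielou with fewer than two taxa return flagged degenerate
  results rather than numbers.
* Sample groups collected in different years are confounded with sample
  type in the study design this emulates; no correction is applied (none
  is defined for it), the comparison is simply labelled as between-type.

## What the synthetic community emulates — and what it does not

`generateGenome`/`simulateReads`/`simulateAlignments` produce multi-contig
genomes with i.i.d. uniform base composition, reads drawn uniformly (or
confined to one genome tenth, to plant RSD failures) at a configurable
substitution divergence, host-plant contamination reads, unplaceable
"no hit" reads, and matching tabular alignments whose identity equals
100·(length − substitutions)/length with the true source ranked first and
optional decoy hits to a sister genome at extra divergence.

Deliberate simplifications: substitutions only (no indels), so identity is
an exact function of the planted substitution count; no base-calling
errors are applied on top of divergence (quality strings still follow a
two-segment Phred profile — 5' plateau, linear 3' decay — whose parameters
are arguments, since no error profile is specified for the platform); no
GC skew, no homopolymer artifacts, no platform-specific error model. Reads
default to 200 ± 20 bases, a realistic single-end length for the kind of
library this emulates; library size defaults are kept in the tens of
thousands of reads per sample so the bundled study runs in seconds —
the statistics scale to millions of reads unchanged. Passing tests on this
generator therefore demonstrate the *rules* (thresholds, tie-breaks,
partition identities, recovery of planted compositions), not robustness to
real platform noise.

## The bundled demonstration study

`runPipeline()` exercises every stage on a built-in study: six microbial
genomes (40–55 kb stand-ins for real genomes), one two-contig host
genome, four samples in two groups of two with group-distinct dominant
members, 10% host reads and 10% unplaceable reads per sample, 20,000 reads
per sample by default. Stages exchange plain-text files (FASTQ, FASTA,
tabular alignments, TSV) under one output directory, each stage records
provenance (package version, configuration hash, input hashes), and reruns
with the same seed are byte-identical.

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(outdir = "frp_demo", seed = 1L)
runPipeline(cfg)
read.delim(file.path("frp_demo", "diversity.tsv"), check.names = FALSE)
```

## Known limitations

* The presence rule automates a decision that was originally made
  manually; borderline ANI cases that a curator might rescue or reject are
  decided mechanically here (the rule and its thresholds are printed with
  every call, so divergences are auditable).
* Read-based ANI from best-hit alignments is biased upward when only the
  conserved fraction of a genome recruits reads; the RSD guard exists
  precisely because ANI alone cannot catch this.
* The two-cloud detector sees the pooled identity histogram, not the
  spatial pattern; a cloud confined to one genome island raises RSD but is
  not separately localized.
* Host depletion relies on the supplied host (or proxy-host) genomes;
  reads from an unsequenced host relative below the 60/60 thresholds
  survive depletion.
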