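---
title: "Decontaminating ancient oral metagenomes with trusted k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decontaminating ancient oral metagenomes with trusted k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmersweep)
```

## The problem

DNA extracted from ancient dental calculus is a mixture: genuine ancient
oral microbial DNA sits alongside modern contamination from skin contact,
burial sediment, and laboratory handling. Reference-based decontamination
fails here twice over — many ancient oral taxa have no good reference
genome, and the contaminants themselves are diverse and poorly databased —
while control-based methods need a sequenced blank that most archaeological
projects do not have. kmersweep instead asks a reference-free question:
does a read look like the k-mer content of samples we already believe to be
oral, and unlike the k-mer content of known contaminant environments?

## The model

### Trusted oral k-mers

The starting material is a k-mer-by-sample presence matrix over a
collection of metagenomic samples labelled by environment: ancient oral
(`aOral`), modern oral (`mOral`), `Skin`, and `SedimentSoil`. From it we
keep the k-mers satisfying

> (present in any aOral sample **or** any mOral sample) **and**
> absent from every Skin sample **and** absent from every SedimentSoil
> sample.

Three preparatory filters precede the selection, in this fixed order:

1. **Row subsampling** (default 10%) — drawn first so that everything
   downstream touches a tenth of the rows; the point of the subsample is
   memory, and subsampling after filtering would forfeit that.
2. **Within-sample singleton removal** (default on) — a k-mer counted
   exactly once in a sample is more likely a sequencing error than real
   signal; the entry is cleared to absent. This step needs counts, not
   just presence, and errors out with an explanation when the matrix
   carries none.
3. **Sample prevalence** (default ≥ 3 samples) — rows surviving in fewer
   than three samples are dropped. All environments count toward
   prevalence; the filter is about sequencing reproducibility, not
   environment identity, so there is no reason to privilege oral columns.

Singletons are cleared *before* prevalence is counted, so a k-mer
present in 4 samples but a singleton in 2 of them has prevalence 2.

All k-mers are **canonical** throughout the package: a word is identified
with its reverse complement and represented by the lexicographically
smaller of the two. Sequencing reads come off either strand, so any
strand-sensitive matching would lose roughly half the signal; canonical
representation makes every decision strand-invariant (a property the test
suite checks directly). The default word length k = 31 is the field's
standard for species-level k-mer matching; k must be at least 2, and odd
k avoids palindromic self-complementary words.

### The Bloom filter

Trusted sets at production scale run to billions of k-mers, so exact
storage is replaced by a Bloom filter: a bit array of
m = ⌈−n·ln p / (ln 2)²⌉ bits with h = max(1, round((m/n)·ln 2))
hash functions, where n is the capacity and p the tolerated
false-positive rate. Inserting at most n elements guarantees a
false-positive rate at or below p and — the property everything
downstream leans on — **no false negatives**. Defaults follow the
production configuration: p = 0.001 and capacity 2×10⁹ (large enough for
a ~1.5×10⁹-k-mer trusted set); desk-scale work passes a smaller
capacity. Bits are set by double hashing (two seeded 64-bit hashes g₁,
g₂ of the canonical k-mer string; position_i = (g₁ + i·g₂) mod m), a
standard construction that is portable and reproducible across
platforms. Inserting beyond capacity degrades the bound gracefully and
warns rather than errors. Filters persist to a versioned binary format
(magic bytes, sizing, k, insert count, bit payload) and round-trip
byte-exactly.

### Two passes over the reads

**Pass 1 — anchors.** Each read is scanned against the filter; a read
with two k-mer matches at *adjacent* start positions (overlap k−1)
becomes an **anchor**. One Bloom false positive can hit any read; two
false positives at adjacent positions have probability ~p², which at
p = 0.001 is negligible, so the two-consecutive rule is both permissive
toward genuine oral reads (any error-free stretch of k+1 bases in a
trusted region suffices) and robust against filter noise. Windows
containing non-ACGT characters are skipped but keep their positions, and
adjacency requires both windows valid — an N between two matches breaks
consecutiveness. We read "consecutive" as strict adjacency of start
positions: it is the strictest natural reading, and the one under which
the single-false-positive robustness argument actually holds.

**Pass 2 — anchor proportion.** All anchor reads are k-merized into an
exact in-memory **anchor k-mer set**. This set deliberately contains
k-mers *not* in the trusted set: an ancient read anchored by its overlap
with trusted content contributes its novel flanking k-mers too, letting
the classifier extend beyond the original database — the enrichment is
the point of the second pass, and why a one-pass variant (retain anchors
directly) performs measurably worse. Every read is then scanned once
more; its **anchor proportion** is the fraction of its valid k-mer
windows found in the anchor set (0 for reads with no valid window), and
reads with proportion ≥ τ are retained. The threshold is inclusive, so
at the default τ = 0.5 a read with exactly half its k-mers matched is
kept. Non-anchor reads can be retained; anchor reads always score 1 on
themselves.

τ is the method's one real tuning parameter. The default 0.5 sits at
the knee of the ROC curve over a τ grid of 0.1–0.9 (`roc_scan()`
recomputes the curve on any labelled mixture, reusing the τ-independent
pass 1); larger τ trades sensitivity for specificity monotonically —
the retained set at a larger τ is always a subset of the retained set
at a smaller one.

At the scales this package targets, both passes run over an in-memory
read table: reads are parsed once and scanned twice in memory rather
than re-streamed from disk. The algorithm is identical either way; the
in-memory form keeps the I/O layer and the classifier independently
testable.

### Output

Retained reads are written back in their input format (FASTQ in, FASTQ
out) with four fields in each header — the sequence id, then
`ReadLen=<int> isConsecutiveMatchFound=<0|1> AnchorProportion=<4 decimals>`
as whitespace-separated key=value pairs — plus a TSV sidecar holding the
same annotation row for *every* input read, retained or not, which is
what the evaluation functions consume.

## The synthetic evaluation harness

Real evaluations of this method run on millions of archived sequencing
reads and a k-mer matrix over hundreds of labelled samples; the package
instead ships a generator producing the same *structure* at desk scale,
so every stage is testable with no downloads.

`sim_genomes()` draws one random genome per source (aOral, Skin,
SedimentSoil; default 20 kb each). `sim_reads()` samples a 1/3 : 1/3 : 1/3
labelled mixture (default 2,000 reads per source, 100 bp, uniform start
positions, random strand, substitution-only errors at 0.5% — an
Illumina-like error profile matching the provenance of real trusted
sets). With 2,000 reads of 100 bp over 20 kb, each genome is covered
~10×, deep enough that anchor reads tile it. `sim_matrix()` turns genomes
into a labelled matrix (3 samples per genome; per-sample k-mer subsets
with counts ≥ 2, plus optional count-1 noise k-mers for the singleton
filter to remove). `sim_scenario()` wires these into three designs:

* **seen** — matrix and reads share all source genomes: the best case,
  where the classifier should approach perfect recovery;
* **partially_seen** — the oral *read* source is a novel genome related
  to the matrix oral genome (a mosaic with 70% conserved sequence);
* **unseen** — contaminant read sources are novel too.

The `relatedness` mosaic fraction (default 0.7) is the one free knob
without a real-data counterpart: a truly unrelated novel oral genome
shares no k-mers with the trusted set and no reference-free method could
recover it, so "unseen" is modelled as a related strain with a conserved
core — sensitivity then degrades (only reads overlapping the conserved
core or its anchor-extended flanks are recovered) while specificity
stands, reproducing the qualitative seen > unseen ordering of the real
benchmarks. `shared_fraction` dials oral–contaminant k-mer overlap
(Jaccard-targeted via a copied-segment fraction 2J/(1+J)); the default 0
keeps sources disjoint, the realistic case for skin/soil versus oral
genomes at k = 31.

What passing these tests does **not** show: performance under aDNA
damage (C→T deamination gradients, short fragment-length distributions),
indel errors, GC bias, or genuinely mixed-environment k-mers — the
generator draws uniform random genomes, which have essentially no shared
k-mers between sources at k = 31, a cleaner separation than real
metagenomes exhibit.

## Evaluation metrics

With per-read truth labels, `score_classification()` collapses the truth
to binary (aOral = positive, everything else negative) and counts the
confusion matrix exactly: sensitivity = fraction of aOral reads
retained, specificity = fraction of non-aOral reads removed,
tpr = sensitivity, fpr = 1 − specificity, and retainment = fraction of
all input reads kept (the metric of record when no truth exists).
Fractions are reported in files; the CLI renders percentages.

## Numerical and degenerate-input choices

* The sizing formulas round up (⌈·⌉) for bits and to nearest for hash
  count, with h floored at 1.
* The double-hash stride g₂ is forced to 1 whenever g₂ ≡ 0 (mod m), so
  the h probe positions never collapse onto one bit.
* Reads shorter than k yield no windows, proportion 0, never retained at
  τ > 0 and never anchors; reads of exactly length k have one window and
  cannot anchor.
* τ = 0 retains every read (any proportion ≥ 0); τ = 1 retains exactly
  the reads all of whose k-mers are anchors.
* An empty anchor set gives every read proportion 0.
* Even k is accepted with a warning; palindromic words canonicalize to
  themselves, deterministically.
* Subsampling keeps ⌊fraction·n⌋ rows; fraction 1 is the exact identity
  (no RNG draw), and the seed is recorded in the trusted set's
  provenance.
* A matrix with no oral columns makes the selection formula degenerate
  and is rejected rather than silently returning the empty set.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data sized for a laptop: Bloom-filter contract checks at capacity 10⁵
with 2×10⁵ probes, classifier-versus-reference checks on dozens of
corpora of up to ~120 reads (k = 9 keeps toy genomes k-mer-dense), and
full-pipeline recovery on 3×2,000-read mixtures at k = 31. The method's
defaults (capacity 2×10⁹) are unchanged by any of this; only the test
fixtures are small.

## Limitations

* No damage-aware modelling: genuinely ancient reads carrying heavy
  terminal deamination lose k-mer matches and with them sensitivity;
  authentication by damage patterns is a separate, complementary
  analysis.
* The anchor k-mer set is exact and memory-resident; inputs with
  enormous anchor diversity pay for it linearly in memory.
* Pass-2 quality scores are ignored; matching is purely sequence-based.
* Paired-end mates are treated as independent reads.
* The trusted set is only as good as its matrix labels: mislabelled
  samples propagate straight into the filter.
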