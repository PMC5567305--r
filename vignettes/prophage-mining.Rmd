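---
title: "Mining prophages from bacterial genomes: signals, curation and moron screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining prophages from bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophagemine)
```

## The problem

Temperate phages integrate into bacterial chromosomes and persist as
prophages; many erode into cryptic remnants, while a minority remain
complete and inducible. `prophagemine` re-implements, as transparent and
testable R code, the desk half of a prophage-mining study of soil
*Paraburkholderia*: find candidate prophage regions in an annotated
genome, curate them, decide which could still form progeny, locate the
likely integration (attachment) site, and screen for morons —
autonomously transcribed cargo genes that may benefit the lysogen. The
validation anchor is the fully transcribed 90-ORF gene table of phage
phi437, a Myoviridae-like temperate phage of *Paraburkholderia terrae*
BS437 (packaged as `phi437_annotation()`), plus a synthetic-genome
generator with machine-readable planted truth.

## Signals and the two callers

Integrated phage DNA differs statistically from host background. The
package computes five windowed signals (`build_tracks()`):

* **GC content** and **GC skew** $(G-C)/(G+C)$ over 4,000 bp windows
  stepped by 1,000 bp — foreign insertions perturb both;
* **median predicted-protein length**, **longest same-strand run
  fraction** and **phage-gene density** over sliding windows of 20 genes
  stepped by 5 — phage genes are longer, co-oriented and cluster.

No windowing is canonical for these signals; the defaults were chosen so
that a 10–50 kb prophage spans several windows of either kind, and both
tilings are parameters of `build_tracks()`.

Gene categories come from an editable keyword lexicon
(`phage_lexicon()`, shipped as YAML): case-insensitive,
longest-match-wins, ties broken by category order. Where a best-hit text
column is available, a gene whose own annotation is uninformative
(`hypothetical` or a generic phage word) is upgraded using *specific*
categories only — a generic "phage" in a database hit never upgrades a
gene, but "major capsid" does. This mirrors how the phi437 table itself
must be read: the capsid gene's RAST annotation is "Phage-related
functions and prophages" and only its best hit names the capsid.

Two deliberately independent callers consume these signals:

* `density_caller()` — maximal runs of phage-category genes tolerating
  up to 4 intervening non-phage genes, at least 6 phage genes per run.
  Bounds are the first/last phage gene of the run.
* `signal_caller()` — a composite per-window score: the weighted sum of
  genome-wide z-scores of median protein length, strand-run fraction,
  |ΔGC| versus the genome mean, |ΔGC-skew| and phage density. Windows
  with composite ≥ 1.5 in runs of ≥ 3 become regions; because windows
  are wider than the step, runs separated by a sub-threshold gap can
  still overlap in bp and are merged. An entirely undefined signal
  (e.g. GC without a sequence) drops out and its weight is
  redistributed proportionally.

One caller is annotation-driven and one is composition-driven, so their
consensus is informative. A note on thresholds: the *number* of
signal-caller regions is not strictly monotone in the threshold — a
qualifying run can split into two qualifying runs as the threshold
rises. What is monotone, and what the tests assert, is that covered
bases never grow and every higher-threshold region is contained in a
lower-threshold one.

## Consensus, curation, completeness

`consensus_and_curate()` groups caller outputs by single-linkage ≥ 1 bp
overlap; a group survives when at least `min_callers = 2` distinct
callers support it, takes its bounds from the primary caller (the
density caller by default, being the one with gene-resolution bounds),
and is then discarded if shorter than `min_size_bp = 10000` — small
calls are overwhelmingly erosion remnants or noise. Surviving regions
are non-overlapping by construction.

`classify_completeness()` scores the hallmark core inventory —
integrase, large terminase, portal, major capsid, tail sheath, tape
measure, lysin — as found among a region's genes: `complete` needs at
least 5 of 7 including an integrase, `remnant` means ≤ 2, anything else
is `questionable`. `lifestyle_flags()` adds the lysogeny evidence:
integrase plus a repressor or antirepressor yields
`temperate-evidence`, and a tRNA within 2 kb of a bound is flagged as
the classical integration signature.

## Attachment sites

Integration by site-specific recombination leaves identical direct
repeats (attL/attR cores) at the prophage bounds, typically beside a
tRNA. `find_direct_repeats()` reports **all maximal exact common
substrings** (≥ 10 bp by default) between the two 2 kb flanks of a
region's bounds, seed-and-extend with deduplication; maximality means
not extendable at that position pair. Candidates rank by repeat length,
ties by distance to the nearest tRNA. Because the contract is purely
output-defined, the test suite carries a quadratic brute-force oracle
and asserts exact agreement on every input up to 2 kb. Note that a
planted repeat may be reported one or two bases longer than planted
when the flanking random bases happen to match — that is maximality
working as defined, not an off-by-one.

## Moron screening

A moron candidate must satisfy three criteria jointly
(`screen_region()`):

1. **not core** — its category is neither structural, packaging,
   lysogeny-control nor replication (the fitness half of the published
   criterion is not computable from sequence alone and is carried as
   free-text evidence only);
2. **autonomous transcription** — an upstream sigma-70 promoter and a
   downstream rho-independent terminator on the coding strand, both
   strand-aware;
3. **anomalous GC** — |z| ≥ 2 for the gene's GC against flank windows.

The promoter model is a consensus-derived PWM (TTGACA / TATAAT,
pseudocount 0.1 per base against a uniform 0.25 background, spacer
15–19 bp). Its default threshold of 12 bits sits two consensus
mismatches below the perfect-site score of 19.8 bits (one mismatch
costs 3.46 bits) — strict enough that clearly degenerate sites do not
qualify, permissive enough for near-consensus sites. The terminator
finder enumerates all hairpins with stems of 4–12 pairs and loops of
3–8 nt and keeps those with stem stability (GC pairs + 0.5·AT pairs)
≥ 6 and ≥ 3 T's in the 8 nt past the hairpin. Stability is a
pair-counting proxy, monotone in stem strength, not a free-energy
model; it admits marginal all-AT stems of 12 pairs, which exactly reach
the floor — the exhaustive-enumeration oracle in the tests pins this
behaviour down. The GC z-score uses sliding 500 bp windows over 5 kb
flanks with an sd floor of 0.005 and the report capped at ±20.

Criterion 3 is weakly powered on very short genes: a 200 bp gene has a
binomial GC noise of ~0.03, comparable to a planted shift of 0.08. The
screen still reports such genes with their evidence; only the verdict
is conservative.

## The synthetic generator

`generate_genome()` emulates exactly the structure the signals assume:
i.i.d. host background at GC 0.62 (a *Paraburkholderia*-like level);
one 45 kb prophage (the phi437 region is ~43.6 kb) whose GC is shifted
by −0.015 (the phage prints 60.31% vs the host's 61.78%); host genes
of mean 300 aa vs phage genes of mean 450 aa; ~90% of phage genes
co-oriented; phage annotations drawn from the lexicon pool with all
seven hallmark categories guaranteed and the canonical layout —
integrase beside the left bound next to the planted tRNA, terminase at
the far end; a 15 bp att repeat planted immediately outside the
outermost genes at both bounds; and one moron cassette (consensus
promoter 37 bp upstream, 8-pair GC stem + 7 nt U-tract downstream, gene
GC shifted +0.08) on a gene of at least 300 aa so the shift is
measurable. All randomness derives from one seed via fixed
per-component substreams; identical config + seed gives byte-identical
FASTA/GFF3/truth output.

What the generator does **not** emulate: codon structure and
oligonucleotide bias (detection here is composition- and
annotation-level), repeated elements and IS transposons in the host
background, eroded partial prophages, multi-contig assemblies, and the
two-block genome reshuffling seen in the sequenced phi437 virion.
Passing the synthetic benchmarks therefore demonstrates that the
implementation detects the signals it models, not that those signals
suffice on arbitrary real genomes.

## Problem sizes and numerical choices

The benchmark scripts and acceptance checks use 20 seeded 500 kb
genomes with one planted prophage each, 100 null genomes for
specificity, and oracle-equivalence sweeps on sequences up to 2 kb
(repeats) and 500 nt (terminators) — sizes at which the brute-force
oracles are exact and the whole suite runs in minutes on one CPU.
Division-sensitive conventions are fixed as: GC of an all-N window is
undefined (NA, excluded from z-scores); GC skew of a G+C-free window is
0; kb values round half-up (43,621 bp prints as 43.6 Kb, matching the
printed literature value); coordinates are 1-based inclusive
everywhere, with minus-strand table rows normalized to (low, high)
while preserving the printed raw pair.

## Known limitations

* Region bounds are gene- or window-resolution; no base-precise
  boundary refinement (e.g. by att-site back-propagation) is attempted.
* The lexicon is keyword-based; annotations in other languages or
  heavily abbreviated product names need lexicon edits.
* Moron criterion 1 is the computable exclusion only; whether a gene
  "benefits the lysogen" requires homology and experiment, not this
  package.
* The genome-wide published survey (209 raw regions curated to 127
  across eight genomes) depends on external genome downloads and
  third-party predictors and is out of scope here; the synthetic
  recovery study stands in as the quantitative benchmark.

## A worked micro-example

```{r example, eval = FALSE}
sim <- generate_genome(generator_config(seed = 42))
tracks <- build_tracks(sim$ann)
curated <- consensus_and_curate(
  list(density_caller(sim$ann), signal_caller(tracks, sim$ann)), sim$ann)
curated <- lapply(curated, classify_completeness)
regions_table(curated)
find_att(sim$ann$sequence, curated[[1]], sim$ann$trnas)
screen_region(curated[[1]], sim$ann)
```

The same flow over the packaged phi437 table (which has no sequence)
degrades gracefully: `run_pipeline(list(io = list(fixture = TRUE)))`
returns ORF statistics, completeness and lifestyle evidence, and logs
that the sequence-dependent stages were skipped.
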