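---
title: "Methods: RNA-DNA proximity-ligation contact analysis on circular genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA-DNA proximity-ligation contact analysis on circular genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`redcontacts` analyses RNA-DNA proximity-ligation sequencing of a **single
circular prokaryotic replicon**. In this protocol family, RNA 3' ends are
ligated to nearby restriction-digested DNA through a biotinylated bridge
adapter; paired-end sequencing of the chimeras yields, per molecule, three
mappable segments: a DNA portion (standardised to 18-20 nt by a type IIS
restriction cut), an RNA 3' portion (forward read, downstream of the bridge)
and an RNA 5' portion (reverse read, downstream of a GGG template-switch
tag). One accepted read pair is one **contact**: an RNA fragment (identified
by its 3'-end genomic coordinate and strand) observed at a DNA anchor
position.

All coordinates are 0-based, half-open, and interpreted modulo the genome
length `L`. The shortest-arc distance `min(|a-b|, L-|a-b|)` underlies every
distance rule. Multi-replicon input is rejected rather than silently
mishandled; genes wrapping the origin are supported (`start > end`).

# The filtering cascade

`process_run()` reproduces the standard cascade:

1. **Scan.** First bridge occurrence in the forward read splits it into DNA
   portion (upstream) and RNA 3' portion (downstream); the reverse read is
   cut after its first GGG. Missing bridge or GGG is a per-read rejection,
   not an error.
2. **Length gates.** DNA portion must be 18-20 nt; both RNA portions at
   least 10 nt.
3. **CATG reattachment.** The blunted NlaIII overhang is re-appended to the
   DNA portion (18-20 nt become 22-24 nt) before mapping, restoring the
   original genomic sequence at the ligation junction.
4. **Mapping.** Each portion is mapped independently by exact search over
   both strands of the circular genome (a Biostrings trusted-band
   dictionary over the origin-extended sequence). `unique` means exactly
   one occurrence counting both strands; triples survive only if all three
   portions are unique. An adapter (`read_portions_sam()`) accepts
   externally aligned portions for real data, where a gapped aligner and a
   repeat-aware notion of uniqueness are appropriate.
5. **Template-switch filter.** RNA 3' and RNA 5' portions must map within
   10 kb (circular distance) of each other and to opposite strands;
   violations indicate intermolecular template switching during reverse
   transcription and carry reason codes `far_apart` / `same_strand`.

Survivor counts per stage are returned as a monotone non-increasing
statistics table.

**CCC trimming.** The forward read is optionally truncated at the first CCC
after the bridge (`trim_ccc`): when a short RNA fragment is read through,
the read continues into the complement of the template-switch tag, and the
CCC run marks the RNA 5' boundary. The same trimming also fires on genuine
genomic CCC (expected every ~64 bp in random sequence), truncating or
destroying roughly one RNA 3' portion in seven. On real libraries that cost
is unavoidable because reads do carry tails; the synthetic reads emitted by
this package carry no tail, so the end-to-end validation runs use
`trim_ccc = FALSE`. This is a consistency choice between generator and
pipeline, not a tuning of any threshold: with tail-free reads there is
nothing for the CCC scan to find except genomic false positives.

**Anchor conventions.** The DNA anchor is the mapping position of the end of
the (reattached) DNA portion adjoining the NlaIII site: for a forward-strand
hit the exclusive right end, for a reverse-strand hit the left end. The RNA
3'-end coordinate is the first base of the RNA 3' portion in read
orientation mapped back to the genome (rightmost base of a minus-strand
hit, leftmost of a plus-strand hit); it is invariant under CCC truncation,
which only shortens the far (5') side of the portion.

# Gene assignment and contact containers

The ligation chemistry implies that an RNA 3' portion maps **opposite** to
the strand of its source gene. `assign_rna_to_genes()` therefore assigns a
contact to a gene only when the RNA 3'-end coordinate lies inside the gene
body and the portion strand is the complement of the gene strand. Points
overlapping two qualifying genes are flagged ambiguous and dropped rather
than multi-counted. Assignment, per-RNA profiles and binned maps conserve
contact counts exactly.

Contact maps are binned matrices (RNA-source bin x DNA-anchor bin,
default 100 bp). At 100 bp on a megabase-scale genome a dense matrix would
need hundreds of millions of cells, so the matrix is held sparse
(`Matrix::dgCMatrix`) and serialised as a sparse-triplet TSV whose header
records `L` and the bin size; the round trip is bit-exact. Replicate maps
are merged by element-wise summation, with the Pearson correlation of the
flattened matrices (computed from sparse cross-moments, never densified)
reported as the reproducibility score.

# Positional statistics

**Interval preference.** For an RNA with at least 500 assigned contacts,
DNA anchors are counted in four bands of circular distance from the middle
of the encoding gene: within 5 kb; 5-50 kb; 50-500 kb (both sides pooled);
and beyond 500 kb. Band membership is half-open (`[5000, 50000)` etc.;
the gene middle itself is `floor((start+end)/2)`, floor on ties, so
membership is deterministic). Counts are divided by band length and
expressed relative to the RNA's genome-average contact frequency
(total/L), so the length-weighted mean of the four relative frequencies is
exactly 1 — an identity the tests assert on every run. A mask (used for
rRNA operons, which are unmappable in real multi-copy genomes) removes
loci from both the counts and the band lengths; the identity then holds on
the masked geometry. The canonical edges need `L > 1 Mb`; shorter genomes
must supply custom edges.

**Upstream/downstream profile.** For contacts of proper-strand mRNA
portions, the signed relation between the RNA 3' end and DNA anchor is
resolved on the circle by the eight-case sign rule (sense/antisense x
sign of `rna - dna` x near/far arc) and verified exhaustively against a
circle-walking oracle. Distances fall into doubling bins
`[0,64), [64,128), [128,256), ...` capped at `L/2`; per-bin frequency is
count/width and the downstream/upstream frequency ratio quantifies nascent
transcript drag. A coincident contact (`rna == dna`) has distance 0, is
assigned downstream by convention, and is flagged so callers can drop it
(`drop_ties`).

**Cumulative operon maps.** Each operon plus flanks of half its length is
split into 24 equal bins (the operon occupies the central 12; with
half-length flanks, equal-width bins and 12-on-operon bins coincide, which
motivates the equal-width reading). Contacts with both coordinates in the
window increment a 24 x 24 matrix; matrices are summed per strand class in
genomic, unflipped orientation, so sense operons accumulate mass above the
diagonal and antisense operons below. Windows wrapping the origin are
handled modularly.

# Background-normalised noncoding-RNA statistics

Raw counts of rRNA (16S+23S+5S pooled) or 6S RNA anchors inside a
protein-coding gene body confound gene length, cross-linking, digestion and
mappability. They are normalised by the gene's **distal-mRNA background**:
contacts whose DNA anchor is in the gene body `[start, end)` but whose mRNA
3' end originates more than 250 kb away (circular distance to the gene
middle; the middle is used for consistency with every other middle-anchored
measure). Genes with background below 10 are excluded. Activity is
estimated as the gene's own-mRNA contacts within +-5 kb of its middle
(closed edge at exactly 5,000 bp). Correlations between the normalised
ratio and activity are computed on `log10(x+1)` scale by default (raw scale
available) for all included genes and for the top activity decile, with
Pearson r, p-value and the linear regression reported.

# The synthetic-data generator

The generator defines the package's reference conditions; every default is
a modelling choice made once, not a per-run dial.

* **Genome/annotation** (`simulate_annotation()`): a random-sequence circle,
  default `L` = 2.4 Mb so the >500 kb band exists. 250 operons are placed
  without overlap on both strands; genes per operon are geometric with mean
  3; gene lengths are log-normal with median 0.8 kb (the E. coli median;
  `sdlog` 0.45 keeps most genes between 0.3 and 2 kb), which makes the
  median operon ~2 kb, near the E. coli median operon length. One ribosomal
  locus (16S/23S/5S at typical bacterial lengths), 20 tRNA genes and one 6S
  gene are added. Per-operon expression is log-normal (`sdlog` 1),
  emulating the broad dynamic range of bacterial transcription.
* **Contact model** (`simulate_contacts()`): per-RNA contact counts are
  proportional to expression. An mRNA contact of gene `g` is, with
  probability `p_cis` (default 0.75), captured on the transcribed path: the
  fragment 3' end is uniform in `g`, the polymerase position uniform from
  there to the operon end (the simplest model of a polycistronic transcript
  held by the polymerase until termination, with no premature termination),
  plus Laplace capture noise of scale `lambda` = 200 bp (no capture-radius
  model is established; Laplace gives a simple heavy-ish local kernel).
  Otherwise the anchor is uniform. rRNA anchors have density proportional
  to `1 + alpha * activity` over gene bodies (`alpha` = 0.5); 6S anchors
  are thinned by `max(0, 1 - gamma * activity)` with activity normalised to
  mean 1 (`gamma` = 0.5) — mean-normalisation is what lets the clamp bind
  for strongly expressed genes and produces genuine depletion; tRNA anchors
  are uniform. Class proportions (mRNA 0.70, rRNA 0.15, tRNA 0.10,
  6S 0.05) are matched exactly by a largest-remainder rule.
* **Reads** (`emit_reads()`): forward read =
  `[DNA portion, terminal CATG removed][bridge][cDNA of the RNA fragment,
  3' end first]`; reverse read = `[GGG][transcript 5' segment in sense
  orientation]`, with the fragment 5' end 50-500 nt from the 3' end so
  valid pairs pass the proximity filter. A configurable artifact fraction
  plants far-apart or same-strand RNA 5' segments to exercise the filter,
  labelled in the truth sidecar. The bridge is a fixed 30-mer free of
  GGG/CCC runs and, with overwhelming probability, absent from a random
  genome; the real adapter sequence is configurable. Base qualities are
  constant — the pipeline never uses them.

**NlaIII snapping.** A reattached DNA portion can only map back if the
genome really carries CATG at the ligation junction (CATG is palindromic,
so one site serves both strands). At read emission each DNA anchor is
therefore snapped to the nearest CATG-compatible junction — an expected
shift of ~64 bp on random sequence, below the capture-noise scale — and the
truth sidecar records the coordinates actually emitted, keeping
exact-coordinate recovery well defined. Separately, `nlaiii_aware = TRUE`
restricts the *contact model itself* to CATG junctions, reproducing the
vertical streaking seen in real 100 bp maps; it is off by default.

What the generator does **not** emulate: PCR duplicates, base-quality
error profiles, repeat-induced multi-mapping (each simulated locus is
single-copy, unlike real multi-copy rRNA operons), restriction-fragment
length biases, and sequence-composition biases. Passing tests therefore
demonstrate the correctness of the coordinate arithmetic, filtering
semantics and statistics on data with known truth — not robustness to
every artefact of real libraries.

# Validation design and problem sizes

The test suite checks, at fixed seeds chosen in advance:

* exhaustive agreement of the circular-distance and up/down-side rules with
  brute-force circle-walking oracles (all coordinate pairs, both strands,
  circles up to L = 500);
* exact conservation identities (counts, lengths, length-weighted mean
  relative frequency of 1) on every run;
* a noiseless end-to-end run at the reference conditions (2.4 Mb, 1e5
  contacts): at least 99% of emitted contacts are recovered with exactly
  the sidecar coordinates, and the stage statistics are monotone;
* a uniform-contact null: a single RNA with 1e5 uniform contacts has all
  four relative frequencies within 1 +- 0.1; the up/down null runs on a
  16,384 bp circle with 5e5 contacts so that even the smallest doubling
  bin holds ~1,000 contacts per side, putting the 1 +- 0.15 tolerance at
  about 3.5 standard errors (on the 2.4 Mb circle the [0,64) bin would
  hold ~3 contacts and the check would be vacuous noise);
* drag recovery at 1e6 contacts: downstream/upstream ratios exceed 1 in
  every bin below the median operon length and return to 1 +- 0.15 only in
  bins beyond the *longest* operon extent — the drag model reaches to the
  operon end, so asymmetry persists to the maximum, not the median, extent;
  transition bins are not asserted;
* parameter recovery on an 8 Mb, ~3,000-gene, 1e6-contact configuration
  (the gene mass of 3,000 genes does not fit the 2.4 Mb default):
  rRNA-vs-activity correlation is ~0 at `alpha = 0`, increases
  monotonically over `alpha` in {0, 0.25, 0.5, 1}, and the 6S correlation
  is negative at `gamma = 0.5`.

`scripts/acceptance.R` re-runs the same analyses from scratch at a
caller-supplied seed and writes the headline numbers as JSON.

# Known limitations

* One circular replicon per run; no plasmids, no linear chromosomes.
* The exact-match mapper is designed for synthetic single-copy genomes; real
  data with repeated rRNA operons needs the SAM escape hatch and an
  external aligner.
* Operon definitions must be supplied (GFF features or the sidecar TSV);
  the package does not predict operons.
* No duplicate removal, quality trimming or spliced alignment.
* Interval-preference edges assume a genome longer than 1 Mb; shorter
  replicons require custom edges.
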