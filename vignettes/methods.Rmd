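---
title: "Methods: spatial whole-RNA quantification in spotrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial whole-RNA quantification in spotrna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spotrna` processes barcode-grid spatial transcriptomics data — read 1
carrying two spatial barcodes and a UMI, read 2 carrying the cDNA — into
feature-by-pixel UMI count matrices with separate exon and intron
layers, and curates compact non-coding features by a read-depth
enrichment test. This vignette documents the model behind each stage,
the tunable parameters, the numerical choices, and what the synthetic
fixture data does and does not establish.

## Read-1 parsing and the expanded-window model

A `read_layout()` declares read 1 as an ordered list of segments:
barcode slots, one UMI, literal linkers and ignorable filler. Two error
regimes matter in archival FFPE material: substitutions, and small
indels that shift everything downstream of them.

The parser handles them asymmetrically on purpose. Linkers are located
by *substitution-only* approximate search within `flank + 2` bases of
their expected offset (at most `max_linker_mismatch` mismatches, default
1, candidates ranked by mismatch count, then distance from the expected
offset, then leftmost — fully deterministic). All downstream segment
coordinates shift with the located linker, which re-synchronizes the
frame after an upstream indel. Barcode segments are then extracted as
windows widened by `flank` bases (default 2) on each side, and *all*
indel recovery inside the barcode itself is delegated to the semi-global
matcher downstream. This keeps parsing linear in read length and avoids
committing to an alignment before the whitelist is consulted. Reads are
never edited; quality strings are carried through untouched because no
stage uses them.

`flank = 2` covers two net inserted or deleted bases between any segment
boundary and the barcode, which is ample for per-read indel counts
observed in degraded libraries; raising it widens windows and therefore
raises the chance that a second whitelist entry becomes reachable, so it
trades recovery against ambiguity.

Failure taxonomy: a read shorter than the layout can ever accommodate
(even with maximal linker left-shift) fails as `read_too_short`; a
linker not found within its search radius fails as `linker_not_found`;
every discarded read increments exactly one reason counter in the demux
summary.

## Barcode calling

Each expanded window is scored against every whitelist entry by
semi-global Levenshtein distance: the barcode must be fully consumed,
the window flanks are free. This is the natural contract for "a known
8-mer sits somewhere inside a 12-mer window, possibly with indels". The
kernel is a small C++ dynamic program (row 0 zeroed, answer = minimum of
the last row); an R implementation of the same recurrence, organized
differently (batched across windows), serves as the independent oracle
in the test-suite.

Decision rule: assigned to the unique minimizer if the minimal distance
is at most `max_edit` (default 2 for 8-mers); `ambiguous` if two or more
entries attain the minimum — ambiguity is a property of the data, so
there is deliberately no tie-breaking; `unmatched` otherwise. A pixel
requires every slot to be assigned; the first failing slot names the
discard reason. `max_edit = 2` balances FFPE rescue against collision
risk: at distance 3 on an 8-mer, random whitelists begin to collide
frequently, which surfaces as ambiguity rather than mis-assignment, but
wastes reads.

The distance is computed against whole windows with free flanks, so the
matcher is insensitive to where the barcode sits inside the window —
which is exactly what the expanded-window parsing requires.

## The whole-RNA reference

Annotation sources are declared as an ordered list (order = priority)
in three dialects: GENCODE-style GTF for genes, generic GTF (including
miRBase-style `miRNA_primary_transcript`/`miRNA` types) for small RNAs,
and BED6 with a class column for interval-only sources. Everything is
normalized to a flat feature table with 0-based half-open coordinates
(GTF's 1-based closed convention is converted only at I/O boundaries),
an RNA class from a fixed vocabulary, a record kind (transcript, exon,
intron) and parent links.

**Merging.** Two records are "similar" iff they share RNA class, strand
and record kind and overlap reciprocally by at least
`min_reciprocal_overlap` (default 0.9). Similar sets are closed
transitively and collapse to the union span, keeping the
highest-priority source's name. The threshold is exposed in config
because "similar" is genuinely a modelling choice: 0.9 merges
re-annotations of the same element across databases while keeping
adjacent paralogs apart. Merging is idempotent and insensitive to row
order (the retained *name* follows source priority).

**Introns.** Per transcript, introns are the transcript span minus the
union of its exons, one feature per gap. Intron features are named after
the *gene*, not the transcript, so the count matrix has a single intron
row per gene — intron evidence is inherently about unspliced
transcription of the locus, not a specific isoform.

**miRNA arms.** Mature 5p/3p products remain separate exon-kind features
with the hairpin as parent transcript, so arm-level dominance is visible
in the matrix, and the hairpin loop becomes a derived intron.

## Overlap-score assignment

For an aligned fragment with blocks totalling `L_read` bases and a
feature of length `L_a`, with `L_o` overlapped bases and
`L_no = L_read − L_o`:

$$\mathrm{score} = \frac{L_o - L_{no}}{L_a}$$

The score rewards containment and, among features containing the
fragment, prefers the shortest — a 22 nt miRNA arm beats the retained
intron or a long host-gene exon for a read that sits in the arm. The
candidate set is every exon/intron record overlapping *any aligned
block* (never the envelope: a junction read must not collect the
skipped intron), filtered by the strand policy. `same` is the default
because stranded whole-RNA protocols place the read on the annotation's
strand; `opposite` serves dUTP-style chemistries; `both` disables the
filter. Transcript records never compete — they exist to define
structure, exon and derived-intron records carry the evidence.

Ties are compared exactly: score equality is decided by integer
cross-multiplication (`n1·d2 == n2·d1`); every product stays far below
2^53, so doubles hold them exactly. Tied features with distinct names
become a composite row (`sorted name1+name2+…`); tied records of the
same gene (two equal-scoring exons) collapse to a plain assignment. When
exon and intron records tie exactly, the read is classified exon — a
read compatible with the spliced product should not count as unspliced
evidence.

Post-alignment filters for degraded material: fragments with fewer than
`min_align_len` aligned bases (default 20) or more than
`max_softclip_frac` of the read soft-clipped (default 0.5) are dropped
as invalid, and only primary alignments are scored — one fragment, one
vote, which keeps UMI counting well defined. A maximal score of zero or
less leaves the read `unassigned` (a status, not an error).

## UMI deduplication and output

Reads collapse on exact (pixel, feature, layer, UMI) identity. Exact
collapse (rather than directional 1-edit clustering) is deterministic
and unbiased at fixture scale; a UMI error model can be layered on
without changing defaults. Deduplication happens *after* assignment,
within each (pixel, feature, layer) — so one physical molecule whose
reads straddle two features would count in both; with well-separated
annotations this is rare, and resolving it would require a cross-feature
UMI model the data cannot support.

Matrices are written as Matrix Market coordinate files with integer
entries plus feature/pixel sidecar tables and a combined long-form TSV.
The coordinate lines are emitted directly by the package because the
generic sparse-matrix writer silently downgrades all-ones matrices to
`pattern` and square matrices to `symmetric`, both of which break exact
round-tripping; reading uses the standard parser. Columns always cover
every whitelist-defined pixel so matrices from different runs align.

## Feature validation by depth enrichment

The assignment step is only as good as the annotation; tissue-specific
ncRNA catalogs over-call. The curation principle: a genuine compact RNA
shows substantially higher read depth over its body than over its
immediate flanks, while an annotation sitting in uniformly fragmented
background does not.

Concretely, for each feature of the validated classes (miRNA, tRNA,
snoRNA, snRNA, scaRNA, piRNA, Y RNA, misc RNA — mRNA genes are far
longer than fragments, so a depth *step* is not the right model for
them): count same-strand alignment midpoints inside the feature
(`in_count`) and in two flanking windows of `flank_mult × L_in` each
(default 1×), clipped at chromosome ends and masked where any other
same-strand feature lies. Midpoint counting makes each read one
Bernoulli trial, so the one-sided exact binomial test with null success
probability `p0 = L_in / (L_in + L_bg)` is exact at any depth — no
normal approximation, no per-base autocorrelation. P-values are
BH-adjusted across tested features; a feature is `valid` iff
`q ≤ alpha` (0.05) **and** fold enrichment
`(in_count/L_in)/(bg_count/L_bg) ≥ min_fold` (2) **and**
`in_count ≥ min_reads` (5). Features with no background length or no
reads at all are `untestable` and kept. Validation pools all pixels
(pseudo-bulk): per-pixel depths in FFPE data are far too sparse to test,
and the curated feature set must filter every pixel identically anyway.

The exact form of this test is this package's own construction realizing
the depth-step principle; the fold and count gates exist because with
thousands of reads the binomial test alone would flag biologically
meaningless 1.2× bumps. Curation is optional and never destructive: the
uncurated matrix is always written alongside.

## The synthetic-data generator

`simulation_spec()` defaults define the standard study conditions used
by the test-suite and the acceptance script: a 2 × 100 kb toy genome; 20
three-exon genes (200 nt exons, 150 nt introns); 10 miRNA hairpins
(70 nt) with 22 nt 5p/3p arms; 4 spurious snoRNA-class annotations; a
16 × 16 pixel grid of 8-mer barcodes with an 8 nt linker and 8 nt UMI; 6
planted pixels per expressed feature with 5 UMIs per (pixel, feature)
pair; fragments of 50 nt (gene reads split 60/20/20 into exonic /
intronic / junction); 2 antisense reads per gene; 60 background reads
per spurious feature, placed region-uniformly over body + flanks; and
zero barcode error rates. Loci are laid out round-robin across
chromosomes with 500 nt spacing so validation flanks never collide.
Feature counts and depths are deliberately toy-sized so the whole
pipeline plus oracle replay runs in seconds; the grid and per-pair UMI
depth match the structure, not the scale, of a real experiment.

Whitelists are rejection-sampled so that no entry can mimic another
inside an expanded window (pairwise Hamming distance ≥ 3 and no
shifted full-overlap agreement), which makes the zero-error run exactly
recoverable — planted truth and pipeline output must agree cell for
cell, and any discrepancy is a defect by construction. Barcode
substitution/insertion/deletion rates are per-barcode probabilities of
one edit each; recovery under corruption is then checked read by read
against the distance oracle, not against an aggregate rate.

The generator writes alignments by exact placement (the "aligner" knows
the truth, including `N`-gapped junction reads) — genome alignment is
out of scope, and unit tests must not depend on an external aligner.
One master seed drives named substreams (genome, whitelists, reads,
errors), so outputs are byte-reproducible and adding a stream never
perturbs the others.

What the fixtures do **not** emulate: realistic FFPE fragment-length and
damage distributions, sequence-composition biases, PCR amplification
noise, soft-clipping, overlapping gene models, or UMI errors. Passing
tests therefore establish the correctness of the algorithms under their
stated contracts — not end-to-end performance on real tissue, which
depends on aligner behavior and annotation quality outside this
package's control.

## Numerical and degenerate-input choices

- Score ties: exact integer cross-multiplication; no floating-point
  equality anywhere in tie detection.
- Barcode ties: never broken; ambiguous is a terminal status.
- Linker ties: broken deterministically (mismatches, then |shift|, then
  leftmost).
- Empty inputs: an empty annotation source warns and contributes
  nothing; an empty assignment stream yields a 0-row matrix that still
  carries every whitelist pixel; empty validation results leave the
  matrix unchanged with a warning.
- Windows shorter than `barcode length − max_edit` are `unmatched`, not
  errors.
- `fold` conventions: `Inf` when reads fall only inside, `NaN` only in
  the untestable no-reads case.
- Determinism: identical inputs and seeds give byte-identical outputs;
  demultiplexing is chunked at a fixed size (20,000 reads) independent
  of worker count, and chunk results are re-assembled in order, so 1 and
  n workers produce identical bytes.

## Pipeline orchestration

Stages (`build-ref`, `demux`, `assign`, `count`, optional `validate`)
each write their artifacts plus a JSON summary into the output
directory; a completed stage is skipped on rerun unless forced, and
reruns over a complete directory change no bytes. Stage summaries
conserve reads (`reads_in = barcoded + Σ discarded(reason)`;
`assigned ≤ aligned`). The reference is persisted as a merged GTF (kind
in the feature column) plus a sidecar table, and re-read from disk by
later stages — so the on-disk format is exercised on every run, not just
in round-trip tests. Pixel/UMI metadata travels either in a demux table
joined by read id or embedded in read names
(`…|PX:<x>x<y>|UMI:<umi>`); both are accepted.

## Known limitations

- Barcode calling is unweighted by base quality; a quality-aware score
  could rescue borderline ambiguous windows.
- Composite multi-mapping rows are retained, never redistributed; users
  wanting EM-style rescue must apply it downstream.
- The validation test assumes independent read midpoints; strong local
  PCR duplication that survives UMI collapse would inflate both body
  and flank counts but can still bias the fold estimate.
- Intron rows aggregate per gene; isoform-specific intron retention is
  not quantified.
- The merge rule is a declared surrogate for database-specific curation
  logic; sources with wildly different annotation granularity (e.g.
  nested precursors) may need a tuned threshold.
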