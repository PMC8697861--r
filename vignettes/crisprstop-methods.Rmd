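---
title: "Designing and quantifying stop-codon base editing with crisprstop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying stop-codon base editing with crisprstop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crisprstop` models one specific editing chemistry — a cytidine base editor
(Target-AID: PmCDA1 fused to Cas9 nickase, NGG PAM) converting C to T in a
narrow window of the protospacer — and everything the package does follows
from that model. This vignette records the model, its tunable parameters,
and the design decisions made where more than one defensible choice
existed.

## The editor model

A guide is a 20-nt protospacer whose genomic site is immediately followed
3′ by an NGG PAM. The deaminase acts on cytosines in the **editing
window**, expressed as a distance upstream of the PAM: the protospacer base
adjacent to the PAM is defined as 1 bp upstream, so window 16–19 bp
corresponds to protospacer positions 2–5 counted 5′→3′. Descriptions of
Target-AID sometimes summarise this as a 3–5-base window centred ~18 bases
upstream of the PAM; the quantitative 16–19 bp definition is what every
packaged guide's printed window reproduces, so it is the default, and both
bounds are configurable through `editor_profile(window_from, window_to)`.
The conversion chemistry (C→T on the guide strand) is fixed.

All of this is held in an `editor_profile`:

| parameter | default | meaning |
|---|---|---|
| `pam_pattern` | `"NGG"` | IUPAC PAM, matched against concrete bases only |
| `protospacer_length` | 20 nt | SpCas9 protospacer |
| `window_from`, `window_to` | 16, 19 bp upstream of PAM | the deaminase window |

`N` is allowed in genomes but disqualifies a candidate wherever it falls in
a protospacer or PAM: an unread base can be confirmed neither as an
editable C nor as PAM-compatible.

## Stop-codon design

For a CDS in frame from its first base, `design_stop_guides()` keeps a
candidate when **some** edit set over its window cytosines creates a new
in-frame stop strictly before the terminal codon. The modelled edit sets
are each single window C plus the all-C set: the deaminase edits one
target C efficiently and bystander window Cs at reduced rates, so these
are the outcomes a designer plans for. The designated target C is the
single-C edit that creates the stop — the position quantification later
counts.

By exhaustive enumeration over the genetic code, the single-edit routes
are exactly `CAA→TAA`, `CAG→TAG`, `CGA→TGA` on the sense strand, and for
antisense guides (guide-strand C→T appears as coding G→A) `TGG→TAG` and
`TGG→TGA`; the test-suite asserts this closure. Edits that recreate the
natural terminal stop are not counted as premature.

Implementation note: an edit only changes the codons it touches, so stop
detection compares exactly those codons rather than re-translating the
CDS; the test-suite's independent oracle does re-translate the full CDS
and diff the peptides.

### Coordinate conventions

All module boundaries exchange 1-based inclusive coordinates. A guide's
`cds_position` is the CDS coordinate of the **leftmost forward-strand base
of the full 23-nt site**: for a "+" guide that is the protospacer's 5′
base; for a "−" guide it is the 5′ base of the PAM as written on the
forward strand. A single left-coordinate convention (as in interval
formats like BED) keeps plus- and minus-strand sites directly comparable
and makes overlapping sense/antisense sites legible; published
plus-and-minus guide tables for the PERV genes are consistent with exactly
this reading.

Minus-strand stop-route labels are reported as the guide-strand
trinucleotide of the **pre-edit** codon — always `CCA` for a coding-strand
`TGG` — because a pre-edit label identifies the targeted codon regardless
of which of the two possible stops the edit produces.

### Row ordering

Design rows sort by stop-route class (`CAA`, `CAG`, `CGA`, then antisense
labels), then `cds_position`, ties broken "+" before "−" — the grouping a
designer scans when picking routes.

## Multi-genome intersection

`presence_matrix()` decides every cell with one rule: the guide is present
iff its 20-nt protospacer occurs exactly (configurable `max_mismatches`)
immediately followed by an IUPAC-matching PAM, on either strand, within
the gene's annotated CDS (or the whole genome when no annotation exists).
Exact matching is the strictest reading of "targets all subtypes
simultaneously": a mismatched site may still cut, but cannot be promised
to. Because proviral targets are multi-copy, occurrence counts are
reported alongside the boolean calls.

## Amplicon quantification

`quantify()` reproduces the editing-rate readout of amplicon deep
sequencing:

1. **Quality masking.** Bases below Phred 20 become `N` before alignment;
   `N` scores 0 against anything and can never be counted as converted or
   unconverted.
2. **Pair merging.** R1/R2 merge by 3′ overlap (exact 16-mer seed, full
   overlap ≥ 20 nt at ≥ 90% identity); unmergeable pairs fall back to R1
   alone, and both counts are reported.
3. **Alignment.** Global (end-gap-penalised) alignment to the amplicon
   with match +1, mismatch −1, gap open −5, extension −1 per base, against
   the read or its reverse complement, whichever scores higher; alignments
   under 70% identity over their columns are rejected (counted, not
   raised). These constants are recorded in every run report. Reads whose
   length equals the reference and that clear the identity threshold
   ungapped skip the dynamic program; agreement between the fast path and
   the full alignment is asserted in tests.
4. **Pileup.** Per-reference-position counts of A/C/G/T/N, deletions, and
   insertions (attributed to the preceding reference column).
5. **Headline statistic.** Reported editing is
   `100 × n(target-C conversion) / n(informative reads)`, where the
   denominator is aligned reads **excluding** (a) reads with an indel
   overlapping the window ± 5 bp — single-base calls beside an indel are
   alignment-ambiguous — and (b) reads whose target base is masked `N`,
   which carry no information either way. Counting masked bases as
   unconverted would make quality masking *increase* bias; excluding them
   keeps the estimator centred (verified against generator truth in the
   tests). Per-window-position percentages are also emitted so a per-site
   reading of the same data is recoverable. For a "−" guide the conversion
   is counted as G→A on the amplicon reference.

Percentages print to 2 decimals, rounded half away from zero.

Degenerate inputs: a window with no C yields an NA headline with the full
position table still emitted; reads shorter than 30 nt are rejected;
sub-threshold alignments and unmergeable pairs are counted in the run
report rather than raised.

## What the generator emulates — and what it does not

`make_provirus_family()` emulates a family of diverged proviral subtypes:
an ancestral genome with stop-free coding sequences, planted editable
sites (sense CAA/CAG/CGA or antisense TGG, with an in-frame NGG at the
spacing that puts the target C at window position 16–19), and per-subtype
divergence by random substitution. Mutations never touch a carried site
± 23 bp, never create a premature stop, and never destroy a terminal stop
(offending substitutions revert to the ancestral codon). Each planted site
sits in a low-complexity cassette (inert ATT codons, site ± 24 nt) so that
the planted guide is the *only* editable site inside its protected
neighbourhood — without this, the mutation protection itself conserves
chance editable sites next to the planted one and the planted-site truth
is no longer exact. Sites restricted to a subset of subtypes have their
PAM codon destroyed in non-carriers. Divergence draws use one uniform per
site, so divergence sweeps at a fixed seed are nested and the all-present
guide count is monotone non-increasing in divergence.

`simulate_amplicon_reads()` emulates one amplicon library over an edited
cell population: each read is edited with probability `edit_fraction`
(secondary window Cs co-convert at `co_conversion`, default 0.3 — a free
parameter standing in for reduced bystander activity, never used in
acceptance checks), receives a 1–3-nt indel within window ± 5 with
probability `indel_fraction` (default 0.01), uniform substitution error at
`error_rate` (default 0.1%, uniform over the three alternatives), and
constant Q37 qualities; `low_quality_rate` corrupts bases and tags them Q2
to exercise masking. Single-end reads cover the whole amplicon; paired
mode emits 3′-overlapping mates (default 60% of the amplicon each). The
truth file records the parameters and the realised counts an independent
recount must reproduce.

Deliberately **not** modelled: position- and quality-dependent MiSeq error
profiles, PCR amplification bias and chimeras, multi-copy provirus
heterogeneity across integration sites, and real subtype phylogeny
(divergence is i.i.d. per site). Passing tests therefore show the
estimator is correct under uniform noise at realistic rates — not that it
is robust to instrument-specific artefacts. Published no-treatment
backgrounds (~0.1–0.2%) are of the same order as, but not identical to,
what uniform error produces; no background subtraction is performed.

## Problem sizes and determinism

Parameter-recovery runs use 50,000 reads (sampling SE ≈ 0.22 points at
50% editing, so the ± 0.75-point recovery band is ≈ 3 SE plus error-bias
allowance); distribution-level properties use 20,000-read runs and 4–6
replicates; the binomial goodness-of-fit check uses 50 seeds × 1,000
reads. Every stochastic step takes an explicit seed, restores the caller's
RNG state (`withr`), and is byte-reproducible: identical seed and
parameters give identical FASTQ bytes, and `run_pipeline()` reruns are
byte-identical per output file.

## Known limitations

- No guide-efficiency or off-target scoring: presence/absence is literal
  sequence occurrence, and design ranks by route and position, not by
  predicted activity.
- The antisense route label (`CCA`) is this package's convention;
  published tables sometimes label minus-strand rows by post-edit codons
  instead.
- The GenBank reader handles single-interval `a..b` /
  `complement(a..b)` CDS locations only; spliced (`join`) genes fall back
  to the longest-ORF rule (≥ 900 nt, logged, flagged inferred).
- Pair merging relies on an exact terminal 16-mer seed; a sequencing error
  in that seed demotes the pair to R1-only (counted in the run report).
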