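---
title: "Auditing CRISPR gene-correction outcomes: models and methods"
author: "crisprAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing CRISPR gene-correction outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprAudit)
```

## The problem this package addresses

Therapeutic genome editing in hematopoietic stem and progenitor cells
(HSPCs) must deliver precise homology-directed repair (HDR) while keeping
unintended outcomes — on-target indels from nonhomologous end joining
(NHEJ), off-target mutations, vector integrations, inversions, large
deletions and translocations — to a minimum. A paired-nickase arrangement
("spacer-nick": Cas9^D10A^ with two PAM-out sgRNAs nicking opposite strands
200–350 bp apart, combined with an AAV6 donor carrying ≥ 800-bp homology
arms outside each nick) is designed to achieve exactly this separation of
HDR from NHEJ.

Verifying such a claim requires a multi-assay audit, each assay with its
own read structure and classification rules:

* **Amplicon sequencing** of on- and off-target sites, classifying each
  read as WT, NHEJ (indel) or HDR and deriving HDR:NHEJ ratios, per-site
  indel rates, dsODN tag counts, and an in-silico restriction (RFLP)
  estimate of HDR.
* **Tag-junction assays** — GUIDE-seq (a blunt 34-nt dsODN captured at
  double-strand breaks) and AAV-seq (AAV ITR as the tag) — where reads run
  from the tag into flanking genomic sequence; the pipeline trims the tag,
  places the junction, deduplicates molecules, aggregates integration
  sites and annotates them as on-target, known off-target (within 5000 bp
  of a predicted site) or novel.
* **LAM-HTGTS** — linear-amplification-mediated sequencing across the
  break site from a nested primer placed 50–100 bp from the cleavage site,
  with the linear-amplification primer outside the homology arms so
  residual AAV donor cannot be amplified. Reads are classified against
  in-silico expected-outcome amplicons into WT, HDR, indel, nick-to-nick
  deletion, inversion, AAV integration or translocation.

The package implements all three classifiers, the design model they share,
and a synthetic read simulator with per-read ground truth. The simulator
matters because the kind of primary HSPC sequencing such studies rest on
is generally not redistributable: every pipeline stage here is therefore
validated against simulated data whose true labels are known exactly.

## Coordinate and design conventions

All intervals are Bioconductor `GRanges` (1-based, closed). A guide's
**nick coordinate** is the plus-strand position immediately 5′ of the cut;
SpCas9(n) cuts between protospacer positions 17 and 18, i.e. 3 nt 5′ of
the NGG PAM. Published work rarely states which coordinate printed
guide-pair distances refer to (nick-to-nick, protospacer end-to-end or
PAM-to-PAM); this package defines **spacer distance** as the absolute
difference of the two nick coordinates and uses that definition
consistently, so all distances in inputs and outputs are internally
coherent. PAM orientation is classified from the strands of the two
guides: a pair is PAM-out exactly when the upstream guide lies on the
minus strand and the downstream guide on the plus strand.

The donor model anchors the left homology arm so it ends at the upstream
nick and the right arm so it starts one base after the downstream nick —
homology arms never extend into the nick-to-nick interval, whose sequence
could otherwise act as an unintended "mini-homology" template. The payload
replaces that interval; in the bundled demonstration design it is the WT
segment carrying silent substitutions plus a diagnostic Sal I site
(GTCGAC), so the HDR allele is equal-length and RFLP-diagnosable. Payloads
encoding insertions or ablated segments are equally supported.

The expected-outcome amplicons are the shared contract between simulation
and classification: WT is the reference window; HDR substitutes the
payload; DELETION is the precise nick-to-nick join; INVERSION
reverse-complements the nick-to-nick segment in place; AAV_INTEGRATION
joins the ITR at each nick in both orientations. Small indels at a single
nick are deliberately *not* enumerated as amplicons — they form a
continuum and are generated by the simulator and detected by break-site
alignment analysis instead, which keeps the amplicon set finite.

## Alignment machinery

All alignments go through `Biostrings::pairwiseAlignment` with defaults
match +1, mismatch −4, gap open −6, gap extend −1 (a gap of length *k*
costs 6 + *k*). Gaps are penalized heavily on purpose: junction assays
need crisp breakpoints, not gap-scattered alignments. N bases count as
mismatches everywhere. Two well-characterized fast paths bypass dynamic
programming — exact containment, and equal-length reads within 2
substitutions, where a gapped alignment cannot outscore the substitution
alignment under this scheme; everything else is aligned in batched DP
calls. The test suite checks the resulting scores against an independent
pure-R affine-gap (Gotoh) oracle.

`bestGenomicHit()` implements the "perfectly mapped" contract used
throughout the junction and translocation logic: an exhaustive
substitution-only scan of both strands (default 0 mismatches,
configurable), reporting a placement only when it is *uniquely* best — a
second placement within 5 score units (i.e. within one substitution)
makes the read ambiguous. Ambiguous and unmapped reads are counted and
reported, never silently dropped. The test suite compares whole outcomes
(status, coordinate, strand, mismatch count) against an exhaustive
shifted-slice Hamming scan.

## The classifiers

**Amplicon reads** are profiled against the WT and HDR amplicons. A read
is HDR when every donor diagnostic variant is present and no indel
overlaps a quantification window (±10 nt around each nick by default — a
standard amplicon-indel practice choice, as no canonical window width
exists); HDR with a window-overlapping indel is HDR_IMPERFECT; a
non-HDR read with a window-overlapping indel is INDEL; otherwise WT.
Substitutions never count toward indel calls. Reads below 85% identity to
both amplicons (or shorter than 50 nt) are AMBIGUOUS with a reason code.
For three-way reporting, NHEJ pools INDEL, DELETION, INVERSION and
HDR_IMPERFECT: an indel-bearing allele is not a precise repair, so
imperfect HDR belongs with NHEJ in WT/NHEJ/HDR summaries while remaining
visible as its own category. The HDR:NHEJ ratio is flagged and computed
with pseudocount 1 when no NHEJ read exists — a real possibility for
spacer-nick conditions at small read counts.

**Tag-junction reads** must begin with the expected tag-primer suffix
(either tag orientation, ≤ 1 substitution); the genomic remainder is
placed under the perfectly-mapped contract. The junction coordinate is
the tag-adjacent end of the placement, defined so both read orientations
of one integration event agree on the coordinate. The Tn5 protocol
carries no UMIs, so molecules are identified by the (junction,
orientation, shear point) triple — the standard proxy — with raw read
counts retained alongside. Sites are single-linkage merges of junctions
within 25 nt, reported at ≥ 2 unique molecules (both config-exposed; no
canonical values exist for either). Annotation follows the 5000-bp window
rule: on-target within 5000 bp of the nick interval, else the nearest
predicted off-target record within 5000 bp (ties broken by smaller
mismatch count, then leftmost), else novel. AAV-seq runs the identical
code path with the ITR as tag.

**LAM-HTGTS reads** pass a strict priority cascade, mirroring the assay's
processing order: priming check (nested primer, ≤ 1 substitution — the
tolerance is not standardized, one substitution accommodates primer-synthesis
and sequencing error without admitting mispriming) → ITR detection (local
alignment, ≥ 20 nt span at ≥ 80% identity) → perfect-prefix assignment
against the expected amplicons (ties resolved HDR > WT > DELETION >
INVERSION; an HDR call additionally requires the read to span a
diagnostic variant, and every perfect call requires the read to reach
past the proximal nick window, otherwise it is UNINFORMATIVE) →
break-site analysis (indels overlapping a nick window → INDEL; a deletion
stretching from one nick window to the other → DELETION) → translocation
(read trimmed at the proximal nick, distal segment placed uniquely, and
called TRANSLOCATION only within 5000 bp of a predicted off-target
record; everything else is AMBIGUOUS and never counted as a
translocation). "Perfect" means zero mismatches and indels over the
read's aligned span — not the full amplicon span, since reads are
primer-anchored prefixes; a relaxed substitution tolerance is
config-exposed. Every read receives exactly one terminal label and label
counts sum to the input. The WT:mutated ratio is
WT / (INDEL + DELETION + INVERSION + AAV_INTEGRATION + TRANSLOCATION);
HDR reads are excluded from both terms (no canonical definition settles
whether HDR belongs in the denominator; excluding it makes the ratio a
pure precision-vs-damage contrast and is documented here as this
package's definition). 5′ and 3′ enrichments are independent
runs combined only at reporting.

## The simulator and what it does (not) emulate

The simulator is first-class, tested code — the oracle for the whole test
suite. One integer seed drives a single R random stream;
same-implementation reproducibility is byte-exact (FASTQ and TSV outputs
are identical across re-runs of one config + seed).

* **Mini-genome**: one random contig with the locus embedded once and a
  configurable number of planted off-target sites for a chosen guide,
  each carrying a recorded number of substitutions in the PAM-distal
  protospacer region (NGG intact), spaced ≥ 10 kb apart so the 5000-bp
  window rule is exercisable without collisions. This replaces
  genome-scale mapping with a desk-scale contract.
* **Amplicon reads**: multinomial over WT / HDR / HDR_IMPERFECT / INDEL;
  indels are geometric-sized (1–20 nt) insertions or deletions at a
  uniformly chosen nick; per-base substitution errors at a configurable
  rate (≤ 0.1).
* **Tag-junction reads**: tag-primer suffix plus genomic flank from the
  integration point to a Tn5 shear point drawn uniformly 100–600 nt away
  — consistent with ~0.5–1.5 kb tagmentation fragments after accounting
  for the sequenced read; both tag orientations; configurable tag-free
  background reads and PCR duplication (background fraction and
  duplication level are not standardized anywhere, so both default low
  and are config-exposed).
* **HTGTS reads**: primer-anchored prefixes of the per-class templates
  for either enrichment side; translocation reads join the proximal
  segment to a planted off-target or, optionally, to a random locus
  (for testing the 5000-bp rejection rule); FREE_AAV reads are random
  donor fragments, which by construction lack primer anchoring and must
  be fully rejected at the priming check.
* The dsODN is a fixed 34-nt constant and the ITR a fixed ~130-nt
  constant shipped in code — only their lengths and detectability matter
  to the pipeline; any sequences may be configured. Base qualities are
  constant Q30; the pipeline ignores qualities, and no quality-decay,
  PCR-bias or chimera model is included. Paired-end mates are not
  simulated; every classifier here operates on single reads.

Because the simulator draws errors as independent substitutions and
indels only at nicks, passing tests demonstrate the *logic* of the
classifiers — exact recovery of truth on clean reads, graceful
degradation under substitution error, correct window rules — not
robustness to the full error structure of real libraries (context-
dependent errors, chimeras, mapping artifacts at repeats).

## Study conditions used in the checks

The bundled demonstration locus uses a 250-bp spacer (inside the 200–350
recommendation), 800-bp homology arms, and three planted off-targets with
2–5 mismatches. The matched-condition comparison simulates NHEJ at 42%
(Cas9-like) versus 1.6% (spacer-nick-like) with HDR at 40% in both —
the characteristic contrast between these regimes — and verifies that the
recovered HDR:NHEJ ratio improves by well over an order of magnitude.
Problem sizes in the tests (2000–5000 amplicon reads, 3500 HTGTS reads,
tens of junction molecules per site, ≤ 50-kb oracle genomes) were chosen
as the smallest sizes at which the statistical bounds (3–4 standard
errors) are meaningful.

## Numerical choices and degenerate inputs

* Multinomial class draws use `rmultinom`, so truth counts follow the
  exact requested distribution.
* Zero-denominator ratios (HDR:NHEJ with no NHEJ; WT:mutated with no
  mutated reads) are flagged and reported with pseudocount 1 rather than
  NA, keeping comparison tables computable.
* Empty inputs error early (`quantifyOutcomes`, `summarizeHtgts`) or
  return typed empty tables (`dedupeMolecules`, `aggregateSites`).
* Site/record ties in annotation break by distance, then mismatch count,
  then leftmost coordinate — deterministic across runs and orderings.
* The demonstration locus scrubs chance occurrences of the diagnostic
  recognition site from the WT window, as a designer would choose an
  enzyme absent from the amplicon; `rflpHdrEstimate` warns if the site is
  present in WT (non-diagnostic design).

## Known limitations

* The mini-genome is a single contig; multi-contig genomes work
  throughout the API, but the demonstration designs do not exercise
  inter-chromosomal translocations.
* `bestGenomicHit` is an exhaustive scan — exactly right at mini-genome
  scale and for oracle comparisons, but not an indexed mapper;
  genome-scale data should be mapped externally and imported.
* Off-target *prediction* is out of scope: predicted off-target lists are
  consumed as BED input (or planted by the simulator), never computed.
* Sanger-trace decomposition, T7EI modeling and gel densitometry are out
  of scope; the RFLP estimate here is the in-silico analogue of the
  restriction assay, not a gel model.
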