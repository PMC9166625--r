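# crisprAudit

Multi-assay auditing of CRISPR gene-correction outcomes, for groups
developing precise editing protocols (e.g. paired-nickase / "spacer-nick"
gene repair in hematopoietic stem and progenitor cells) who need to
quantify not just HDR but *everything else* an editing experiment can
produce: on-target NHEJ indels, off-target mutations, dsODN and AAV vector
integrations, inversions, nick-to-nick deletions and translocations.

The package implements three read-level classifiers plus the design model
and read simulator they share:

* **Amplicon sequencing** — per-read WT / NHEJ / HDR classification
  against in-silico expected amplicons, with HDR:NHEJ ratios
  (pseudocount-flagged at zero denominators), window-based indel rates,
  dsODN tag counts, and an in-silico RFLP (restriction digest) estimate
  of HDR.
* **Tag-junction assays** (GUIDE-seq with a 34-nt dsODN; AAV-seq with
  the AAV ITR, one shared code path) — tag trimming, perfectly-mapped
  junction placement, shear-point molecule deduplication, site
  aggregation, and annotation under the 5000-bp rule: a site within
  5000 bp of a predicted off-target record is a known off-target,
  otherwise novel.
* **LAM-HTGTS** — a strict priority cascade over primer-anchored reads:
  priming check → ITR detection → perfect assignment against
  expected-outcome amplicons (WT, HDR, deletion, inversion) → break-site
  indel/deletion analysis → translocation calling, where a distal segment
  is a translocation only when uniquely placed within 5000 bp of a
  predicted off-target record.

## The core model

A locus design is a guide pair with nick coordinates (Cas9 cuts 3 nt 5′
of the NGG PAM, between protospacer positions 17/18), a PAM orientation
class (PAM-out / PAM-in / tandem), a spacer distance
*d* = |nick_B − nick_A| (spacer-nick designs use 200 ≤ *d* ≤ 350 bp), and
a donor whose homology arms (≥ 800 bp) anchor entirely outside the
nick-to-nick interval, with a payload replacing that interval. From a
design the package renders one sequence per expected outcome class —

    WT        : reference window
    HDR       : window with payload substituted between the nicks
    DELETION  : precise nick-to-nick join   (length = WT − d)
    INVERSION : nick-to-nick segment reverse-complemented in place
    AAV       : ITR joined at each nick, both orientations

— and both the simulator and every classifier work against these shared
amplicons. Since studies of this kind rarely deposit their primary HSPC
sequencing, the simulator is a first-class module: it emulates all four
library structures on a mini-genome with planted off-target sites and
emits per-read ground truth, which is the oracle for the entire test
suite.

## Worked example

```r
library(crisprAudit)

loc <- demoLocus(seed = 1)     # mini-genome + validated design + off-targets
loc$design
#> LocusDesign demo_locus
#>   window: chr1:3111-5140
#> NickPair: sgA + sgB | spacer 250 bp | PAM_OUT
#>   donor: 250-nt payload, HAs 800/800 bp

amp <- buildExpectedAmplicons(loc$design, loc$genome, region = "amplicon")
sim <- simulateAmpliconReads(loc$design, loc$genome,
  simulationConfig("AMPLICON", proportions = c(WT = .2, HDR = .4, INDEL = .4),
                   nReads = 2000, errorRate = 0.001, seed = 1))
profile <- quantifyOutcomes(classifyAmpliconReads(sim, amp))
profile
#> OutcomeProfile: 2000 reads; WT=414, HDR=782, INDEL=804
#>   WT/NHEJ/HDR = 0.207/0.402/0.391  HDR:NHEJ = 0.973  WT:mut = 0.515
```

The design is a PAM-out pair at a 250-bp spacer distance with an 800-bp-arm
donor. The simulation requested 20/40/40% WT/HDR/NHEJ; classification
recovers 20.7/39.1/40.2% and an HDR:NHEJ ratio of 0.97 — the Cas9-like
regime, where nearly every non-WT allele that isn't HDR is an indel. The
`WT:mut` figure is the WT:mutated ratio (WT over indels, deletions,
inversions, integrations and translocations; HDR excluded from both
terms).

The same objects drive the junction caller
(`callIntegrationSites(reads, design, genome, offTargets, tag = "dsodn")`)
and the HTGTS cascade
(`classifyHtgtsReads(reads, design, genome, side = "5p")` +
`summarizeHtgts()`), and `runPipeline()` wraps simulation, analysis and
TSV/JSON reporting per stage with a manifest (config hash, seed, package
version) per run directory. See the methods vignette
(`vignettes/crisprAudit-methods.Rmd`) for the models, conventions,
parameter defaults and limitations.

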