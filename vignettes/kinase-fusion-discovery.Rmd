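---
title: "Kinase fusion discovery from chimeric RNA-seq evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase fusion discovery from chimeric RNA-seq evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kinfuse implements a heuristics-driven pipeline for discovering activating
kinase gene fusions in tumour RNA-seq cohorts. It consumes read-level
chimeric evidence (a documented TSV dialect modelling the chimeric output
of a spliced aligner), calls candidate fusions per sample, removes false
positives at cohort scale, and annotates the survivors with the functional
criteria an expert reviewer would apply. This vignette explains the model
behind each stage, the tunable parameters, the numerical choices, and what
the synthetic cohort used in the tests does and does not demonstrate.

## Evidence model

Two read-level evidence classes support a fusion transcript:

* **chimeric pair** — a sequenced fragment whose two ends align to
  different genes; it brackets a junction without locating it;
* **split read** — a single read spanning the junction, aligning partly to
  each partner, with an *overhang* (aligned length) on each side. Split
  reads define the breakpoint at base resolution.

Each record carries the two aligned loci (chromosome, position, strand,
span) and, for split reads, the junction coordinate on each side plus both
overhangs. Positions are 1-based in all files; internally the package
uses the 1-based inclusive convention of `IRanges`/`GenomicRanges`
throughout, converting only at BEDPE output (0-based half-open, that
format's native convention). Using one interval machinery end to end
avoids the off-by-one ambiguity that plagues coordinate-mixing pipelines.

## Per-sample detection

**Gene assignment.** Each locus is assigned to the gene whose exon union
(the union of exons over all transcripts) it overlaps by the most
nucleotides. Intergenic loci and exact ties are discarded and counted; a
tie cannot be resolved without double counting.

**Strand concordance.** A genuine 5'→3' fusion transcript reads the 5'
partner in its transcription direction into the 3' partner in its
transcription direction. A fragment sequenced from the *sense* strand of
that transcript yields segments aligned on each gene's own strand, with
the 5' partner first; a fragment from the *antisense* strand flips both
aligned strands and the traversal order. These are the only two
configurations kept: one segment sense and the other antisense is
strand-discordant and rejected, and any unstranded (`*`) value leaves both
orderings open, so the observation is rejected as ambiguous. This gives a
deterministic orientation for all 16 strand configurations.

**Split admissibility.** A split read counts toward split support only
when *both* overhangs reach `min_overhang` (default 15 nt, matching the
junction-overhang minimum the upstream aligner would have enforced).
Sub-overhang split reads are excluded entirely — they are not recycled as
chimeric pairs, because the two evidence classes are counted as distinct
physical observations.

**One fragment, one vote.** A read id contributes at most once per gene
pair; if the same fragment is represented both as a split and as a pair,
the split (the more informative representation) wins.

**Tiered support.** A gene pair is retained when its support reaches the
tier matched to its split-read count: at least 5 chimeric pairs with 2 or
more split reads, at least 10 with exactly 1, and at least 20 with none.
All three thresholds sit in `fusion_filter_config()` and are boundary-tested.

**Homology screen.** Fusions between homologous partners are the classic
alignment artifact. Two genes are called homologous when the shared
fraction of distinct 24-mers between their canonical transcript sequences
(maximum over both directions) reaches 5%, or when a user-supplied paralog
table lists the pair. Both parameters are configurable; the k-mer
criterion is this package's operationalisation of a filter whose exact
form is rarely published. Pairs that are homologous *and* genomically
overlapping get an additional flag. No genomic-distance or read-through
filter is applied: genuinely proximal fusions (e.g. tandem-duplication
promoter fusions between neighbouring genes) must survive detection.

**Breakpoints.** The reported junction is the modal split-read junction;
ties break first toward the junction with the greatest summed overhang,
then toward the smallest genomic coordinate. Purely deterministic.

## Cohort filters

* **Improbable frequency.** A pair present in strictly more than 95% of a
  cohort's samples is biologically implausible and flagged. A pair whose
  partners are *each* involved in at least two distinct fusion pairs
  cohort-wide and in fusions in strictly more than 25% of samples is
  flagged as promiscuous. The published wording of the promiscuity clause
  is ambiguous about whether ">1 fusions" counts within a sample or
  across the cohort; this package counts distinct partner pairs
  cohort-wide and applies the sample-prevalence clause separately, which
  is the stricter and more auditable reading. Flagged candidates are
  retained in output with their flags (flag-then-review), but are
  excluded from recurrence counting.
* **Panel of normals.** Gene pairs detected — by the identical procedure
  and configuration — in 5 or more normal samples are removed outright.
* **Recurrence.** Only kinase fusions observed in at least 2 tumour
  samples pooled across *all* cohorts proceed to annotation. The default
  counting mode (`"kinase"`) aggregates a kinase's fusions across
  partners, mirroring how recurrently fused kinases are tabulated across
  cancer types; `"pair"` mode counts the ordered gene pair instead.

## Functional annotation

**Junction class.** `exon_exon` when the 5' breakpoint is a donor
boundary (transcription-wise exon end) and the 3' breakpoint an acceptor
boundary (transcription-wise exon start) of annotated exons;
`exon_cryptic` when exactly one side coincides; `unresolved` otherwise or
without split reads. A cryptic exon is operationalised simply as a
junction off the annotated boundaries — no splice-motif model is imposed.

**Fusion transcript and frame.** The chimeric transcript is built from
the canonical transcript of each gene (longest CDS, ties by lexicographic
transcript id — one protein product per fusion must be chosen, and this
rule is deterministic). The frame call is:

* `promoter_fusion` — the 5' partner contributes only untranslated
  sequence and the complete 3' CDS lies downstream: the intact gene is
  placed under the partner's promoter. This configuration *satisfies* the
  in-frame criterion for driver classification, since the full wild-type
  protein is expressed; it is reported distinctly so reviewers can see it.
* `in_frame` — the retained 5' coding length joins the 3' CDS in its
  native phase *and* translating the constructed transcript from the 5'
  start codon reaches the 3' gene's own stop codon with no premature
  stop. The translation scan catches cases phase arithmetic alone would
  miss (e.g. a 5' breakpoint downstream of the 5' gene's stop codon).
* `out_of_frame` / `no_cds` — everything else.

The partner contribution is reported as whole codons (9 retained coding
nt = 3 aa).

**Kinase domain.** The registry supplies the catalytic-domain interval in
protein coordinates (domain discovery by HMM search is out of scope; the
registry is an input). For a 3' kinase, the first fully native retained
residue is computed from the skipped coding length; the domain is
`complete`/`truncated`/`absent` according to how much of the interval the
retained region covers. Only `complete` is compatible with an activating
fusion. The check is monotone: moving the 3' breakpoint upstream never
degrades the status. Regulatory domains (e.g. N-terminal autoinhibitory
regions of Ser/Thr kinases) are deliberately *not* required — their loss
is often the activating event itself — so only the catalytic interval is
tested.

**Coiled-coil motifs.** Partner dimerization potential is scanned with
the classic sliding-window heptad method: a 28-residue window (four
heptads), the geometric mean of per-residue propensities at the best of
the seven registers, per-residue scores as the maximum over covering
windows, and a probability from the ratio of two Gaussian densities
(coiled-coil vs globular, with a 30:1 prior on the globular class).
The shipped propensity table is **synthetic**: it encodes the
hydrophobic-core logic of heptad repeats (apolar residues favoured at
positions a/d, charged and polar residues outside, helix breakers
penalised everywhere) rather than reproducing a published matrix, and the
file is named accordingly. The score statistics (coiled mean 1.507, sd
0.101; globular mean 0.885, sd 0.123) were calibrated once by simulation
on that table — random-composition sequences for the globular reference,
noisy ideal heptads for the coiled reference. Published tables can be
supplied to `coils_parameters()` together with their own statistics.
Other dimerization motifs (e.g. LisH) are reported from a user-extensible
motif-interval table when the partner's retained segment fully contains
them; no profile search is performed.

**Artifact flags and verdict.** `homologous_repeat` marks partner
homology. `trans_splice_suspect` requires the joint signature of
template-switching library chimeras: an expression z-score of either
partner at or above 3 within the sample's cohort, *and* zero split reads,
*and* an unresolved junction — high expression alone never flags a call.
z-scores use the unbiased (n−1) standard deviation over the cohort. The
verdict is `artifact` when any flag is set; `candidate_driver` when the
fusion is recurrent with an intergenic junction, an in-frame or
promoter-fusion coding prediction and a complete kinase domain; and
`passenger` otherwise. Promoter-fusion overexpression is reported as
corroborating evidence (the partner expression z-score), never used as a
gate.

## The synthetic cohort

`sim_config()` defines the study conditions: 20 tumour samples in one
cohort, 10 normals, 40 genes (14 kinases) on two chromosomes. Genes have
3–6 exons on mixed strands; the first exon is pure 5'UTR, the CDS starts
at exon 2, coding exons are whole codons drawn from sense codons (so
constructed in-frame fusions contain no spurious stops), and the last
exon carries the coding tail, stop codon and 3'UTR. Whole-codon exons
make every exon–exon junction phase-compatible; frame intents are then
enforced by construction — `out_of_frame` plants shift the donor
breakpoint one nucleotide into the exon, and `domain_truncated` plants
use an exon-3 acceptor on a kinase whose registry domain starts at
residue 10, upstream of any exon-3 junction residue.

The default planted grid holds 6 drivers (4 in-frame, 2 promoter
fusions), 2 frameshifted and 2 domain-truncating passengers, 2 artifacts
recurring in exactly 5 normals, 1 trans-splicing artifact (20 chimeric
pairs, no split read) and 1 homologous decoy, each carried by 2 of the 20
samples; background noise pairs stay below every support tier.
Expression is log-normal (FPKM-like); the trans-splice pair is driven
~1000-fold in its first carrier — in a 20-sample cohort the unbiased
z-score of a single outlier is bounded by \((n-1)/\sqrt{n} \approx 4.25\),
so a two-carrier symmetric inflation could never cross the z ≥ 3
threshold; the second carrier gets only a mild (3×) rise and its call is
excluded as a passenger rather than an artifact. Evidence records are
emitted in a random mix of sense and antisense representations so the
orientation logic is exercised in both directions.

What passing the end-to-end test shows: the filter cascade separates the
planted classes exactly (precision = recall = 1 on the drivers) under
evidence whose statistical structure matches the filters' assumptions.
What it does not show: robustness to mapping noise, multi-mapping reads,
fragmented breakpoints, annotation errors, or real expression
distributions — the generator writes clean records at the evidence level
and plants exact support counts, by design (the pipeline consumes
evidence records, so read-level simulation would add nothing the package
can test).

## Numerical and design choices

* Coordinates: 1-based inclusive internally (the IRanges convention);
  GTF native on input, BEDPE 0-based half-open on output.
* Sequence input is a genome FASTA rather than transcript FASTA:
  cryptic-exon breakpoints need coordinate arithmetic against the
  chromosome, and transcript sequences are spliced on demand.
* Canonical transcript: longest CDS, ties lexicographic.
* Breakpoint ties: modal junction → largest total overhang → smallest
  coordinate.
* Prevalence comparisons are strict (`>`); normals and recurrence
  thresholds are `>=`, matching the published wording of each rule.
* Degenerate inputs: empty evidence files and empty cohorts return empty
  tibbles/zero summaries; zero expression variance yields z = 0 with a
  warning; a registry without a domain interval yields `absent` with a
  warning; a breakpoint outside the canonical transcript's exons aborts
  annotation for that candidate with a warning rather than guessing.
* Problem sizes in the shipped tests — a 7-gene hand-specified toy
  annotation for exact oracles, the 20-sample default cohort for the
  end-to-end property, ~150-record evidence sets for tally oracles and
  ≤500-residue sequences for the coils oracle — were chosen so each
  brute-force oracle is feasible and exact.

## Limitations

* The homology criterion (k = 24, 5% shared) is a pragmatic
  operationalisation, not a phylogenetic method; supply a paralog table
  for curated control.
* Junction classes rely entirely on the input annotation; unannotated
  isoforms will surface as cryptic junctions.
* The coiled-coil table is synthetic (see above); motif probabilities
  should be read comparatively, not as calibrated structure predictions.
* Cohort statistics from real tumour compendia (fusion burden per cancer
  type, recurrence rates) depend on controlled-access data and are not
  reproduced by the synthetic cohort; the package reproduces the *rules*,
  not the cohort.
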