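---
title: "Methods: G-quadruplex screening and partner nomination in lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G-quadruplex screening and partner nomination in lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgrscan)
options(qgrscan.quiet = TRUE)
```

## The problem

Long non-coding RNAs (lncRNAs) fold into higher-order structures, among them
RNA G-quadruplexes (G4s): four-stranded arrangements of stacked G-quartets
stabilized by monovalent cations (K⁺ far more than Li⁺). Dysregulated,
G4-bearing lncRNAs are candidate cancer biomarkers, and their protein
partners — notably G4-resolving helicases such as DHX36 — point at the
pathways they touch. Experimentally testing every transcript is infeasible,
so the screening is done in silico: scan transcripts for putative
quadruplex-forming sequences (PQS), consolidate transcript variants into
gene-level clusters, nominate protein partners from two independent evidence
channels, require subcellular colocalization, and only then validate the
shortlist with biophysical assays (CD spectroscopy, thioflavin T
fluorescence, reverse-transcriptase stop). `qgrscan` implements that
pipeline plus the desk-scale analytics for the assay readouts.

## The PQS model and the G-score

A QGRS candidate is a parse of four equal-size G-groups (tetrad size
*t* ≥ `min_g_group`) separated by three loops of `loop_min`–`loop_max`
nucleotides, with a total span of at most `max_length`. Defaults are the
settings under which the bundled reference oligonucleotides were scored:
`max_length = 45`, `min_g_group = 3`, loops 1–14, and hits must score
strictly above 60. Groups may sit anywhere inside maximal G-runs, loops may
themselves contain guanines, and zero-length loops are excluded by
`loop_min = 1`.

Competing parses are ranked by an integer G-score. For tetrad size $t$ and
loop lengths $\ell_1,\ell_2,\ell_3$ with $L=\ell_1+\ell_2+\ell_3$:

$$
\mathrm{gscore} = 15\,t + 27 \;-\; \max\!\left(0, \left\lfloor
\tfrac{7\,(L-10)}{10} \right\rfloor\right) \;-\;
\mathbf{1}\!\left[\ell_{(1)}=\ell_{(2)} < \ell_{(3)}\right]
$$

where $\ell_{(1)}\le\ell_{(2)}\le\ell_{(3)}$ are the sorted loops. The three
terms implement the usual QGRS ranking principles — more tetrads score
higher, longer loops score lower — and a small adjustment for the loop
pattern in which the two shortest loops are equal while the third is longer.

**Calibration.** The literature G-scores of the six reference
oligonucleotides bundled with the package (`study_table("oligos")`) serve as
the calibration oracle; the formula reproduces all six exactly under the
default parameters:

```{r calibration}
oligos <- study_table("oligos")
data.frame(name = oligos$name,
           computed = vapply(oligos$sequence,
                             function(s) best_parse(s)$g_score, integer(1),
                             USE.NAMES = FALSE),
           reference = oligos$reference_g_score)
```

Those six published scores are not jointly consistent with *any* score that
is monotone in the sorted loop vector (one oligo with sorted loops
$(2,4,4)$ scores 72 while another with $(3,3,4)$ scores 71), which is why
the equality-pattern adjustment exists: it is the minimal structure that
fits all six values while preserving the property that lengthening any
single loop — without changing which loops are equal — never raises the
score (verified exhaustively over all loop triples in the tests). The
formula is deliberately confined to one function (`score_qgrs`) so that
recalibration against a different reference set touches a single place. It
does not depend on `max_length`; the calibration is tied to the 45-nt
setting and other settings reuse it unchanged.

## Hit selection

All scoring parses above the threshold compete for the transcript.
Overlapping candidates are first reduced to the best parse per interval,
then the reported hit set is the *exact* maximum-total-score collection of
pairwise non-overlapping intervals (weighted interval scheduling by dynamic
programming), with deterministic tie-breaks: ties on total score prefer the
earlier interval; ties within an interval prefer the larger tetrad size. An
exact selection was chosen over greedy highest-score-first because the two
can disagree (a single long high-scorer can block two disjoint hits whose
combined score is higher), and the exact rule is the one the brute-force
oracle in the test suite can state unambiguously.

Transcripts can be thousands of nucleotides long, so the scanner streams
sliding windows of `2 * max_length` with `max_length` overlap. Every
candidate (span ≤ `max_length`) lies entirely inside at least one window;
duplicates across seams are removed and selection runs once on the merged
candidate set, so windowing is invisible in the output (a property the
tests check by splitting sequences at hit-free gaps).

A reported motif is additionally annotated with a stricter, independent
cross-check: `canonical_motif_check` asks whether the motif matches
`G{t} N{1–7} G{t} N{1–7} G{t} N{1–7} G{t}` for some `t ≥ 3`. This mirrors a
second validation layer with a tighter loop bound than the scanner; it
annotates, never filters. Note that a scanner hit need not pass it — loops
of 8–14 nt are scanner-admissible but fail the 1–7 bound.

## Clusters

Transcript variants are consolidated by *exact sequence identity*:
byte-identical sequences within a gene merge (provenance tags are unioned),
and a transcript id reported with two different sequences is dropped
entirely as low-confidence. Alignment-based reconciliation of
near-duplicates is deliberately excluded — exact identity keeps the
operation deterministic and oracle-checkable, and the upstream use of
alignment in this screening context is precisely to spot redundant or
conflicting entries. A cluster is then a gene with all its surviving
variants; its summary counts PQS-containing isoforms and the maximum hit
G-score, and attaches the expression label (upregulated / downregulated /
differential) when one is provided. Functional-isoform status is an input
column, not an inference: it comes from literature curation, which a
package cannot reproduce.

## Partner evidence channels

* **Top-down** — interaction-score tables are ranked by descending score
  with lexicographic tie-breaks. The scores' units and derivation vary by
  resource, so they are treated as ordinal only.
* **Bottom-up** — RF/SVM interaction-probability pairs pass only if *both*
  classifiers exceed the threshold (default 0.5, strict inequality, so a
  score of exactly 0.5 fails). Both-pass was chosen because the evidence
  tables report both classifiers and treat them jointly; `mode = "either"`
  is available. The classifiers themselves are consumed, never trained.
* **Colocalization** — binding requires convergent compartments. Because
  localization resources mix granularities (nucleoplasm vs nucleus, cytosol
  vs cytoplasm), convergence is evaluated after mapping sub-compartments to
  their parents: nucleoplasm/nucleoli → nucleus, cytosol/perinuclear →
  cytoplasm. Unknown symbols warn and yield `NA` (no evidence, pair kept).

`call_partners` takes the union of pairs across channels and counts the
supporting channels (0–3). Covariation between a lncRNA and a candidate
partner is plain Pearson correlation (the heatmap language this emulates is
explicitly *linear* correlation) over shared finite samples, with zero
variance treated as an error rather than a silent 0.

## Localization

The relative concentration index is
$\mathrm{RCI} = \log_2\frac{c + p}{n + p}$ with cytoplasmic expression $c$,
nuclear expression $n$ and pseudocount $p = 0.01$; the pseudocount keeps the
index defined at zero expression and is small against typical expression
units. Assignment uses a neutral band of 0.5 log2 units: below −0.5 →
nucleus, above +0.5 → cytoplasm, inside the band → dual resident. The band
acknowledges that transcripts near parity are observed in both compartments
(as is described for cytoplasmic-and-perinuclear lncRNAs); the upstream
resources report compartments qualitatively without a cutoff, so the band
default is this package's own choice and is configurable.

## Assay analytics

* **CD topology.** Parallel G4s show a positive band near 265 nm and a
  trough near 240 nm; antiparallel ones +295/−260 nm. Each signature is the
  smaller of its peak and trough amplitude within ±5 nm windows, compared
  to a noise floor of 3× the MAD of the 330–350 nm tail (where G4 CD signal
  has decayed). Both signatures above the floor → `mixed`; neither →
  `none`. The windows and the MAD floor are this package's quantitative
  stand-in for what is usually expert inspection; classification is
  invariant under uniform rescaling of the spectrum.
* **ThT fold enhancement** is the ratio of group means over the dye-only
  blank, with replicates retained for testing.
* **Significance** uses an unpaired Welch *t*-test by default (replicate
  variances are rarely equal or known; a pooled-variance mode exists) with
  stars at p ≤ 0.05 / ≤ 0.001 / ≤ 0.0001. Two constant, equal groups return
  t = 0, p = 1 rather than an error.
* **RT-stop** quantification consumes band-intensity tables from any gel
  software (densitometry itself is out of scope) and reports
  `stop / (stop + full_length)` per lane, undefined (error) when both bands
  are zero.

## Synthetic data: what it emulates, what it does not

The generators produce every input format the pipeline reads, with planted
ground truth, under a single seed that fans out to per-generator sub-seeds
(`seed * 1000 + k` mod 2³¹−1), so each fixture is reproducible on its own.

* `gen_transcript` plants a PQS of chosen geometry inside G-free
  (`{A,C,T}`) flanks, making the planted parse provably the unique
  candidate — recovery can therefore be asserted exactly. Hostile mode adds
  decoy G-runs spaced further than `loop_max` from everything, so they can
  never complete a four-group candidate. Random batches keep planted loop
  sums ≤ 25 nt so every plant scores above the reporting threshold.
* `gen_evidence_tables` emulates the four-lncRNA × eight-protein shape of
  the validated study set, with one pair planted to pass all three evidence
  channels and one planted to fail the bottom-up filter.
* `gen_spectrum` builds Gaussian bands (amplitudes +10/−5 mdeg, σ = 6 nm)
  at the canonical CD positions on a 220–350 nm grid; at 5 % noise the
  classifier recovers the planted topology in ≥ 95 % of seeds.

What the fixtures do **not** emulate: real lncRNA base composition and
G-run clutter beyond the planted/decoy structure, sequencing or measurement
error models, cell-line-specific localization tracks, and real spectral
baselines. Passing tests therefore demonstrate algorithmic correctness
against the stated model, not recall on transcriptome-scale data.

## Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open; every report is 1-based
inclusive and says so in its header. Scores are integers, so selection ties
are real and resolved by the documented preference order. Empty FASTA files
are empty inputs, not errors; malformed FASTA, unknown schema columns,
unparseable numeric cells, IUPAC ambiguity codes, negative expression,
zero-variance correlation and zero-denominator stop fractions are errors
that name the offending record, row or position.

## Problem sizes in the test suite

The oracle-equivalence property runs 500 random sequences of ≤ 60 nt
against a brute-force enumerate-and-select oracle, planted-parse recovery
runs 100 seeded fixtures, and the CD Monte-Carlo runs 200 seeds — sizes at
which the brute-force oracles are exact and the whole suite stays
interactive (well under a minute).

## Known limitations

The G-score calibration rests on six published values that are themselves
not perfectly self-consistent across their source tables; where tables
disagreed, the per-oligo values were taken as authoritative. No
thermodynamic competition with other secondary structures is modeled, no
intermolecular (multimeric) G4s, no antisense scanning, and no
genome-coordinate liftover — scanning is transcript-space only. Partner
nomination aggregates external evidence; it performs no docking, motif-level
binding-site prediction, or literature mining.
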