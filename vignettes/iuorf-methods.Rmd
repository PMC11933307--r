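---
title: "Detecting internal upstream ORFs that repress truncated proteoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal upstream ORFs that repress truncated proteoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iuorfscan)
```

## The model

Scanning ribosomes load at the 5′ cap and initiate at the first start
codon in a favourable context. Two escape routes generate N-terminally
truncated proteoforms from internal, in-frame AUGs: *leaky scanning*
(the ribosome skips a suboptimal first start) and *reinitiation* (a
ribosome that has terminated a short ORF resumes scanning). A short ORF
placed inside the coding sequence, in a different reading frame, can
intercept ribosomes that leak past the canonical start and thereby
repress initiation at a downstream internal AUG — an **internal
upstream ORF (iuORF)**. Its repressive potential is governed by three
cis-features, the same ones known for classical 5′-leader uORFs:

* the sequence context of its start codon (how many scanning ribosomes
  it captures),
* its length (longer ORFs make reinitiation less efficient),
* the intercistronic distance from its stop codon to the downstream TIS
  (too short a spacer prevents reinitiation).

The screen encodes exactly this geometry. For a transcript with
canonical start `cTIS`, a candidate is a pair (short ORF, internal
in-frame TIS) with

* `frame(iuTIS) != 0` and `frame(ntTIS) == 0` relative to `cTIS`
  (frames are `(pos - cTIS) mod 3`),
* iuORF length at most `max_codons` coding codons (stop excluded),
* *upstream* class when `1 <= ntTIS - iuSTOP_end <= max_spacer`,
  *overlapping* class when `iuSTOP_end > ntTIS`.

At most one candidate is reported per mRNA: the short ORF with the
highest ribosome-profiling initiation score.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `max_codons` | 100 | coding codons | the screen's definition of "short" ORF; the stop codon is excluded from the count (the common convention; the source filter does not specify) |
| `max_upstream_spacer_nt` | 30 | nt | distances beyond ~30 nt permit efficient reinitiation, defeating repression |
| `start_codons_denovo` | `AUG` | — | de-novo near-cognate scanning (CUG/ACG/…) would flood the screen; near-cognate starts are admitted only through explicit TIS calls, which carry experimental evidence |
| `mode` | `tis-calls` | — | in `de-novo` mode every AUG is a potential start and initiation scores are unavailable, so the tie-break starts at the spacer |
| `len_tol_codons`, `dist_tol_nt` (conservation) | 2, 6 | codons, nt | "conserved" for quantitative features is an artifact definition; codon and context-tier features require exact agreement |

Spacer sign convention: `spacer = ntTIS − iuSTOP_end`, so the wild-type
worked-example geometry (stop at 466, internal AUG at 480) gives +14 nt
and an overlap appears as a negative spacer. A consequence of frame
arithmetic worth knowing: with the ntTIS in frame 0, upstream spacers
satisfy `spacer mod 3 != 1` and overlaps satisfy `overlap mod 3 != 2`;
a "31-nt spacer" can only be probed at the filter level, never built
into a transcript.

## Kozak tiers

The consensus for efficient initiation is `RNN RNN AUG G`; the decisive
residues are the purine at −3 and the G at +4, and `GCCACC` is the
textbook perfect box. The literature uses informal labels ("perfect",
"strong yet imperfect", "suboptimal", "weak"); this package fixes an
explicit four-tier scheme:

* `optimal` — positions −6..−1 equal `GCCACC` and +4 is G (any start
  codon: a CUG inside the perfect box is still `optimal`);
* `strong` — purine at −3 **and** G at +4, not optimal;
* `adequate` — exactly one of the two (covers "CCC AUG G": favourable
  +4 G, pyrimidine −3);
* `weak` — neither;
* `indeterminate` — −3 or +4 missing (window off the transcript end) or
  `N`.

Only the optimal/strong boundary depends on residues other than −3/+4,
a property the test suite asserts over random windows.

## Conservation analysis

Orthologs are compared by global pairwise alignment (Needleman–Wunsch,
match +1, mismatch −1, linear gap −2, deterministic tie-break) rather
than a guide tree: for two or three species, selecting the candidate
with maximal alignment identity is equivalent to "closest homolog in
the tree" and far simpler. Reference anchors (cTIS, iuTIS, ntTIS) are
projected through the alignment; the short ORF is then *re-extended in
the target species*, so its length and spacer are species-specific
observations, not copies. The short-ORF peptide identity (translated,
stop excluded, minimum over species) separates conservation of the
*geometry* from conservation of the *encoded peptide* — a repressive
iuORF needs the former but not the latter.

## Screen statistics and the initiation index

Ratios from an overexpression plate screen are gated by a Shapiro–Wilk
normality test (delegated to `stats::shapiro.test`, cross-checked in
the tests against an independent implementation), then converted to Z
scores against the mean and sample SD of the **entire** screened set
(control wells excluded from centre/scale, still scored), two-sided
normal P values, and Benjamini–Hochberg adjusted values. Because hits
themselves inflate the set's SD, power per spiked entry at the default
synthetic world (184 entries, 8 spikes at +2.5 SD) is ≈ 0.57 — the test
suite asserts that calibration rather than an idealized one.

The translation-initiation index for harringtonine ribosome-protection
qPCR is `2^-(ΔCt_target − ΔCt_ref)` with `ΔCt = Ct(TIS) − Ct(background
site)` on the target and reference mRNAs respectively — a doubly
background-corrected ΔΔCt. The named method fixes the arithmetic on the
log (cycle) scale; linear-scale background subtraction was considered
and rejected as a different estimator than the method named by the
protocol.

## The synthetic world

`generate_transcript()` builds a ~600-nt mRNA (50-nt leader, canonical
ORF to near the 3′ end) and plants the requested geometry: default an
iuORF of 35 coding codons in an `adequate` ("CCC AUG G"-like) context
with a 14-nt spacer — the wild-type worked-example configuration — with
initiation scores 50/5/2 for cTIS/iuTIS/ntTIS, reflecting that most
initiation occurs at the canonical start and internal initiation is
weak. Decoy transcripts (`klass = "none"`) still carry an internal
in-frame TIS so the pairing logic is exercised against negatives.
Accidental AUGs and premature stops are removed by rejection-resampling
of unprotected residues with a hard iteration cap; generation then
*certifies* by brute force that the only start codons present are the
planted ones, which is what makes "sensitivity 1.0, zero extras" a
meaningful assertion rather than a tautology.

What the generator does **not** emulate: real codon-usage and GC
structure, 3′ UTR regulatory content, near-cognate initiation, multiple
competing iuORFs per mRNA, transcript isoforms, or noise in TIS calls.
A green plant-then-recover test therefore establishes the correctness
of the screen's geometry and bookkeeping — not its behaviour on noisy
experimental TIS datasets.

The ortholog generator mutates only outside feature anchors and reverts
substitutions that would truncate the iuORF, emulating the observed
pattern "geometry conserved, encoded peptide not conserved". The screen
generator draws truncated-positive normal ratios (baseline 0.04 ±
0.015, the empty-vector scale of the motivating screen); the Ct
generator draws per-well Gaussian cycle noise around values whose
noiseless ΔΔCt equals the requested index.

## Numerical and design choices

* Coordinates are 1-based inclusive on the mature mRNA everywhere,
  including GFF3 output.
* ORFs lacking an in-frame stop before the transcript end are
  discarded, not truncated.
* When several ntTIS qualify for one short ORF, the nearest (smallest
  `ntTIS − iuTIS`) is paired; the source procedure is silent on this.
* Tie-breaks beyond the initiation score (|spacer|, then 5′-most iuTIS)
  exist purely to make output deterministic.
* `N` is allowed in sequences: codons containing `N` are neither starts
  nor stops, and contexts with `N` at −3/+4 are `indeterminate`.
* The TIS-table dialect (strict five-column TSV) is defined by this
  package; no community standard for TIS calls exists.
* Transcripts whose canonical TIS is not flagged in the TIS table are
  excluded and counted, mirroring the screen's first filter.

## Known limitations

* No frameshifting, stop-codon readthrough, or selenocysteine handling.
* No quantitative initiation-efficiency model (no PWM scoring); tiers
  are ordinal.
* Conservation uses reference-anchored pairwise alignments, not a full
  MSA; for deep species panels a progressive aligner would be
  preferable.
* Initiation scores are inputs; the package does not call TISs from raw
  ribosome-profiling reads.
* The headline transcriptome-scale result of the motivating study
  depends on an external curated TIS dataset and is reproduced here
  only structurally, on certified synthetic data.
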