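---
title: "Models and conventions behind suptrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind suptrna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suptrna)
```

This vignette documents the scientific models the package implements,
the conventions it fixes where the underlying definitions are ambiguous,
and what its synthetic-data tests do and do not demonstrate.

## The tRNA model

A tRNA gene is stored CCA-less (genomic tRNA genes lack the 3′ CCA; the
mature tail is appended only on output) as a sequence plus an explicit
cloverleaf segmentation: acceptor-stem halves, D-arm, anticodon-stem
halves, anticodon loop (always 7 nt), variable region, T-stem halves
(5 nt each), T-loop and discriminator. Each nucleotide carries a
canonical position label supplied by the annotation sidecar — a
simplified Sprinzl-style map. We deliberately do **not** infer the
segmentation by structure prediction: all design edits are addressed by
canonical labels, every scaffold a user supplies must come with its map,
and folding inference would add a failure mode without adding
information the engine uses. Internally all coordinates are 0-based and
half-open; canonical labels are opaque tokens (the variable region of
the serine scaffold is labelled `V01..V14`), which avoids off-by-one
drift against the 1-based conventions of the literature.

The shipped serine scaffold is a reconstruction: the two combined
design variants are known as full sequences (they are printed as 85-nt
hybridization probes, tRNA + CCA on the reverse strand), and the
scaffold is obtained by reverting the template edits and the anticodon
swap. The segmentation was chosen so that every stem is Watson–Crick
paired and the anticodon loop centers positions 34–36 — the unique
assignment consistent with standard cloverleaf geometry. The arginine
and glycine scaffolds are fully synthetic 71-nt cloverleaves that carry
the documented identity elements of their families; they exist to
exercise the identity validator, not to represent real genes, and their
files are labelled accordingly.

## Suppressor design

The suppressor anticodon for a stop codon is its reverse complement
(UGA→UCA, UAG→CUA, UAA→UUA); the engine refuses non-stop targets since
it designs PTC suppressors only. A mismatch control — the anticodon for
a different stop than the one assayed — is built with `mismatch_to=` and
flagged, mirroring standard experimental controls.

Edit templates are data, not code: `set-pair` writes both bases of a
canonical base pair, `graft-segment` replaces a whole segment. After a
template is applied the two halves of each stem must have equal length;
a graft that changes length relabels the segment with generated opaque
tokens and shifts downstream intervals. Repeated writes to the same pair
are last-write-wins, so template application is idempotent in the
natural sense.

### eEF1A binding score

Elongation-factor binding is modelled additively over the three T-stem
base pairs 49–65, 50–64 and 51–63: each (position class, base pair)
combination contributes a tabulated ΔΔG (kcal/mol) and the variant's
score is the sum. Two conventions are fixed here because they are
genuinely open:

* **Reference.** Contributions are relative to the scaffold's wild-type
  pair at each position class, so an unedited T-stem scores exactly 0
  and scores are comparable across scaffolds. Negative = more stable
  eEF1A interaction.
* **Per-pair, not per-variant.** The additive per-pair decomposition is
  a modelling decision; it makes the score of a multi-pair edit the sum
  of its single-edit scores, which the tests verify against a
  brute-force enumeration of the three classes.

The shipped energy table (`tstem_ddg_synthetic.tsv`) is an illustrative
stand-in patterned on the measured per-pair contributions of the
bacterial EF-Tu–tRNA complex (the eukaryotic and bacterial factors share
their tRNA-binding sites): zeros at the serine-scaffold wild-type pairs,
destabilizing values for the `T2`/`T5`-style edits and the most
stabilizing value for the `T6` edit, so the qualitative ranking of the
variant families is reproduced. The engine never hard-codes energies —
users with measured values edit the TSV.

Identity elements are validated, never silently enforced:
`enumerate_variants()` reports violations on every emitted variant and
only drops violators in `strict` mode. One case deserves note: the
arginine family's identity elements include the anticodon bases C35 and
U/G36, which no UGA suppressor (anticodon UCA, A at 36) can satisfy.
The validator reports this honestly and leaves the warn-versus-fail
policy to the user; it is a real tension in the biology, not a bug.

## Readthrough quantification

### Conventions fixed by this package

* **Footprint position.** Reads of 25–32 nt are assigned at
  `start + floor((length − 1)/2)` — the middle nucleotide, and for
  even lengths the nucleotide 5′ of the middle. A single convention for
  all parities is used because the two natural readings of
  "middle/upstream-of-middle" contradict each other for one parity;
  the choice is configurable via the offset-map interface.
* **A-site mode.** Alternatively, per-length 5′ offsets are learned
  from the start-codon metagene (the offset that puts the most reads on
  the first CDS nucleotide) and used in place of midpoints; lengths
  with fewer than `min_reads` informative reads fall back to the
  midpoint offset with a warning. Both modes are provided because
  published analyses differ in which they use for the tissue-level
  screen.
* **RRTS orientation.** RRTS = extension density / CDS density, both as
  reads per kilobase. Higher = more readthrough. The extension region
  runs from the nucleotide after the natural stop codon to the next
  in-frame stop (exclusive), scanned codon-by-codon in the CDS frame;
  regions separated by fewer than 4 nt from the natural stop are
  excluded (with whole-codon extensions the shortest admissible region
  is 6 nt). Reads whose assigned position falls inside the natural stop
  codon count to the CDS — an unambiguous partition. Transcripts with
  zero CDS reads are excluded rather than scored; zero extension reads
  give RRTS 0.
* **Expression filter.** Whole-transcript RPKM strictly greater than
  0.1; RPM/RPKM use every read passed in as the library size, so RPM
  sums to 10⁶ exactly when each read is assigned to one transcript.
* **Canonical transcript.** Longest CDS per gene, ties by longest
  transcript, remaining ties lexically by id — fully deterministic.
* **Calling threshold.** "A transcript underwent readthrough" is
  threshold-dependent; the default call is RRTS > 0 with ≥ 2
  extension-region reads, and `compare_conditions()` reports counts per
  stop identity under whatever threshold is configured rather than
  pretending a canonical cutoff exists.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
and only that: CDS footprint counts are Poisson with mean λ·L(CDS) and
positions uniform over the CDS; extension counts are Poisson with mean
ρ·λ·L(ext) and uniform over the extension. Under this model the
expected RRTS is exactly ρ, which is what makes the recovery tests
sharp. Defaults, chosen once as realistic for a tissue footprint
library: λ = 0.2 reads/nt (a well-covered library), ρ = 0.01 (basal
readthrough is rare), footprint lengths 25–32 nt peaked at 28–29, CDS
300–1500 nt, stop-identity mixture 38.5/40.4/21.1% (UGA/UAG/UAA, the
reported identity frequencies of disease-causing PTCs), and 20% of
transcripts without any next in-frame stop so the exclusion path is
always exercised. Every generator is bit-reproducible under a fixed
seed and writes its ground truth to a sidecar table so tests never
re-derive truth from generator internals.

What the generator does **not** model — and therefore what passing
tests do not show about real data: codon-level dwell-time variation and
pausing at the stop codon, uneven coverage (5′ ramps, ligation bias),
sequencing errors, multi-mapping, NMD-driven changes in transcript
abundance, and frame-dependent footprint structure. Recovery of ρ here
demonstrates the estimator is correct under its own model, not that
tissue libraries satisfy that model.

Assay simulations are deliberately minimal: reporter signals are
(readthrough fraction × reference mean × lognormal noise), Ct tables
encode a chosen fold change through ΔΔCt, and arrays have constant
spike-ins with a chosen decay profile — at zero noise each
normalization recovers its truth exactly, closing the loop.

## Assay normalizations

Reporter readthrough is 100 × mean(PTC signal)/mean(reference signal).
In dual-luciferase mode the FLuc/RLuc ratio is formed **per well**
before averaging (ratio-of-means versus mean-of-ratios matters at high
well-to-well variance; per-well ratios are standard dual-reporter
practice). The reference is either the pooled wild-type construct or
the sense-control wells of the same treatment (whose mean maps to
100%). Mock-background subtraction is available but off by default,
since published percentages do not state whether it was applied.
Dispersion is the s.e.m. of per-well percentages; significance testing
is left to standard routines (`t.test` et al.) — it is not a
contribution of this package.

ΔΔCt: technical duplicates are averaged per sample before analysis;
fold = 2^(−ΔΔCt), so log₂ fold is linear in ΔΔCt and fold(A vs B) ×
fold(B vs A) = 1.

Microarray stability: per block, (1) scale so the median spike-in
channel ratio is 1, (2) divide each suppressor-tRNA probe signal by the
median spike-in signal, (3) express as percent of the reference
timepoint's mean. Replicate blocks are normalized independently and
pooled afterwards. The spike-in contract makes the output invariant to
any per-block global rescaling, which the tests assert directly.

## Problem sizes and tolerances

The test suite checks RRTS against a literal per-position oracle on 10
toy transcripts × 10³ reads at 10⁻¹² relative tolerance, and rate
recovery on 200 transcripts × 3 seeds per ρ ∈ {0.001, 0.01, 0.1} with
λ = 0.7 (≥ 200 expected CDS reads per transcript), asserting that the
true ρ lies inside the 95% sampling interval of the mean RRTS. The
stratified comparison tests use 300 transcripts and a binomial test at
α = 0.05 on per-identity call counts. These sizes keep the default
suite under a minute while leaving the stochastic assertions
well-powered; users can scale `sim_config()` up freely.

## Known limitations

* The cloverleaf parser requires intron-less tRNA genes and does not
  model modified nucleosides.
* The ΔΔG model is additive by construction; cooperative effects
  between T-stem pairs are not representable.
* `find_next_inframe_stop()` requires transcript sequences; models
  without sequence can only be used for metagene and quantification.
* The A-site calibration uses a single global offset per read length;
  it does not model per-transcript or per-frame heterogeneity.
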