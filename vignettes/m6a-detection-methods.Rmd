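---
title: "Motif-stratified random-forest detection of m6A from nanopore fraction-modified tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-stratified random-forest detection of m6A from nanopore fraction-modified tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Aforest)
```

## The problem

Direct RNA nanopore sequencing preserves base modifications: an
N6-methyladenosine (m6A) perturbs the ionic current as the surrounding bases
pass through the pore. Signal-level preprocessing (Tombo-style de novo
detection) summarizes this per reference position as a *fraction-modified*
value in [0, 1] — the fraction of reads whose current deviates from the
canonical model — together with a read-coverage track. Because the per-base
error rate of the platform is high, these per-position statistics are noisy:
across candidate windows they average around 0.5 even at truly unmodified
positions, and single-molecule calling is out of reach. The signature of a
genuine m6A site is instead a local *spike* in the fraction-modified track,
concentrated 1–3 nt on the 5′ side of the methylated adenosine's motif,
visible against that noisy baseline.

`m6Aforest` turns this signature into site-level calls. Almost all mRNA m6A
falls inside the degenerate 5-mer consensus DRACH (`[AGT][AG]AC[ACT]` in DNA
form, 18 resolved 5-mers, with the methylated A at position 3). Restricting
candidates to DRACH positions both shrinks the search space by orders of
magnitude and makes the calls specific to m6A rather than to other
modifications. Because the pore reads a ~5-nt context, every 5-mer has its
own signal response, so one random-forest classifier is trained *per
motif* rather than one global model.

## From tracks to feature windows

A candidate site is every central A of a DRACH occurrence in the reference
(cDNA/transcriptomic references scan the sense strand; genomic references
can scan both strands, configurable because annotation-strand restriction is
a pipeline choice, not a property of the method). For each candidate we
collect the fraction-modified values at offsets −`flank`…+`flank` from the
A — 21 values at the default `flank = 10` — ordered 5′→3′ in transcript
sense, so minus-strand windows reverse the genomic offset order.

Two filters apply:

* **Coverage** — the read count at the central A must be at least
  `min_coverage = 5`; below that the fraction-modified statistic is
  dominated by the error rate. The filter applies at the central A only: the
  window text speaks of filtering windows, not positions, and the
  completeness requirement below already guards the flanks.
* **Completeness** — a value must exist at *every* offset. Positions absent
  from a track are treated as missing, not as 0.0 (a measured zero is
  data; absence of signal is not), and missing-value windows are dropped
  rather than imputed, because the forests need complete fixed-length
  vectors and any imputation scheme would invent signal exactly where the
  classifier looks for it.

Dropped windows are tallied by reason (out-of-bounds, low coverage,
incomplete signal) so a run can report what it discarded.

Truth labels come from orthogonal single-base m6A maps (CLIP-derived BED
intervals): a window is *positive* when its central A falls inside a truth
interval on the same reference (and strand, when the truth set carries
strands), under 0-based half-open coordinate conventions. Everything else is
*negative* — which is known to be wrong for a fraction of sites, since the
truth maps are incomplete. This asymmetry is a central feature of the
problem, not a nuisance: the point of the classifier is to recover exactly
those mislabeled true sites.

## Training protocol

Per motif, with `n` labeled positives:

1. `round(0.7 · n)` positives are drawn into the training set; the remaining
   ~30% are held out as test positives.
2. The training negatives are an equal-size sample, without replacement, of
   the negative windows — balancing matters because negatives outnumber
   positives heavily and a forest trained on the raw imbalance would learn
   the prior.
3. All remaining negatives join the test set.
4. Ten forests are fit, each on a freshly resampled balanced negative set
   (the positive split stays fixed, so run accuracies are comparable), and
   the run with the highest training accuracy is kept; ties go to the lowest
   run index.

"Training accuracy" here is the out-of-bag accuracy on the balanced
training set. A random forest's plug-in accuracy on its own training rows
saturates near 1.0 for every run, which would make best-of-10 selection a
coin flip; the out-of-bag estimate is computed on the same training rows but
only from trees that did not see each row, so it varies meaningfully across
negative resamples while still being a training-set quantity.

The forests use 100 trees, unconstrained depth and terminal-node size 1 —
standard defaults for ~21 features, recorded in the persisted model file
along with the flank, the seed and a format-version tag. Loading a model
whose flank differs from the prediction request is an error, preventing a
silent feature-shape mismatch. All sampling is seeded (positive split under
`seed`, run *r* under `seed + r`), so training is exactly reproducible;
persisted models reproduce identical predictions after reloading.

## Evaluation and motif qualification

Three test-set metrics at the default call threshold of 0.5 (majority vote
of the forest):

* **CLIP detection rate** — the fraction of held-out known sites called
  positive. This is the protocol's headline "accuracy": it is computable
  even though the negative labels are contaminated.
* **Precision** — TP/(TP+FP) over the pooled test set.
* **ROC AUC** — threshold-free, over the same pool.

Precision and AUC are systematically *understated* on real data because
unannotated true sites sit in the negative pool and every one the model
correctly flags is scored as a false positive. The qualification rule
accepts a motif only when all three metrics clear strict thresholds —
detection rate > 0.7, precision > 0.85, AUC > 0.67 — and on real data four
motifs clear them (AGACT, GGACA, GGACC, GGACT), which is why the prediction
step defaults to that whitelist. On synthetic data with a known truth
fraction the same contamination effect is visible and quantifiable: with 30%
of true sites unlabeled, pooled precision sits near 50% even when the
classifier separates the planted classes almost perfectly (manifest-truth
AUC ≈ 1), so qualification against CLIP-style labels is deliberately
conservative.

Prediction writes both calls (`m6A` at probability ≥ 0.5, `not_m6A` below)
to BED6 — name `motif:call`, score `round(1000 · probability)` — because the
downstream perturbation analysis needs the negative class too; a
positive-only switch restricts output.

## Isoform-level assignment

When reads are aligned to a cDNA reference, every call is transcript-
resolved. Lifting the central A through the transcript's exon structure
(from a GTF; 0-based half-open internally, ordered 5′→3′, strand-aware)
gives its genomic coordinate. Genomic positions covered by ≥ 2 isoforms are
classified by agreement: `never` (no isoform methylated), `consistent` (all
methylated), `isoform_specific` (mixed) — the three categories partition the
multi-isoform positions. Motif identity is recorded but not required to
match across isoforms, since exon-boundary contexts can legitimately differ.
Only the central A is lifted; windows whose 21-nt span crosses an exon
junction are flagged, because their signal context (transcript) and genomic
context diverge and any genomic interpretation of the flanks would be
wrong. Transcripts present in the reference but absent from the GTF are
reported and skipped loudly rather than silently dropped.

## Perturbation sensitivity

Knocking down the m6A writer (METTL3) or overexpressing the eraser (ALKBH5)
lowers the fraction-modified spike at genuine sites. A site is *sensitive*
when its mean signal over the peak offsets is strictly greater in the
baseline condition than in the perturbed one; exact ties are not sensitive,
and swapping the conditions inverts the verdict except on ties. The peak
offsets default to −5…−3 relative to the central A — the three bases
immediately 5′ of the motif's first base, reading "1–3 nt upstream of the
motif" literally; they are configurable per run because the alternative
anchoring (relative to the central A itself) cannot be excluded from the
published signal plots alone.

Under a real perturbation the predicted-m6A class should be sensitive far
more often than the not-m6A class; under a null perturbation (an independent
redraw of the same noise) each site is sensitive with probability ½, so both
classes sit at 0.5 within binomial error — a calibration check the test
suite runs. Sites surviving the coverage filter in only one condition are
excluded from the fractions and counted; an empty class reports an undefined
fraction, never 0.

## The synthetic generator

`generate_fixture()` produces self-contained fixtures with the statistical
structure the classifier assumes: random DNA references with DRACH motifs
planted at recorded positions (methylated sites and unmethylated decoys),
fraction-modified tracks `clip(0.5 + spike + N(0, 0.1²), 0, 1)` with a
+0.3 spike at offsets −5…−3 of methylated sites, uniform coverage on 5–50,
a perturbed condition with an independent noise redraw and the spike
attenuated (fully removed by default), and a truth BED listing a random 70%
of the methylated sites — deliberately incomplete, to mimic the coverage of
CLIP maps. Defaults are 20 sequences of 2,500 nt carrying 500 methylated
sites and 500 decoys over the four whitelisted motifs.

Choices worth noting:

* **Gaussian noise with clipping, not Beta.** The baseline is characterized
  only by its level (~0.5) and spread; a clipped Gaussian is the simplest
  model with those two knobs, and nothing downstream depends on the exact
  tail shape.
* **Planted sites are spaced ≥ 2·flank+5 apart**, so no window overlaps
  another site's spike.
* **Accidental DRACH occurrences are scrubbed** from the random background
  by mutating one base outside any planted footprint. Without this, chance
  motifs adjacent to planted sites would inherit spike signal from their
  neighbours and blur the planted classes; spacing alone cannot control
  them. As a consequence the fixture's candidate set equals its manifest
  exactly, which the tests exploit.
* **Determinism:** equal seeds give byte-identical files.

What the generator does *not* emulate: per-read signal, basecalling error,
coverage gradients along transcripts (3′ bias of direct RNA runs), motif-
dependent signal shapes, correlated noise between neighbouring positions,
or partial methylation stoichiometry. Passing the synthetic recovery tests
therefore shows that the pipeline's machinery — scanning, filtering,
training, selection, calling, sensitivity — implements its contracts and can
recover a planted effect of realistic size from realistic noise; it does not
certify real-data accuracy, which depends on signal phenomenology the
generator idealizes.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally everywhere; the only
  conversions happen at file boundaries (wiggle is 1-based on disk; GTF is
  1-based closed). BED and bedgraph are already 0-based half-open.
* `U` is normalized to `T` on input; any `N` inside a 5-mer disqualifies
  the occurrence (it cannot be resolved to one of the 18 models).
  Overlapping motif occurrences are all retained — there is no suppression
  rule to justify dropping one.
* Qualification thresholds are strict (`>`); the call threshold is
  inclusive (probability ≥ 0.5 calls m6A); sensitivity is strict
  (ties are not sensitive).
* Overlapping bedgraph intervals are rejected rather than summed: the
  emitters produce disjoint intervals, so overlap indicates corruption.
  Signal values outside [0, 1] and truth intervals with `end ≤ start` are
  validation errors, with line numbers where the parser has them.
* Splits with no test positives (train fraction 1.0), single-class training
  sets, fewer negatives than needed for balancing, and whitelisted motifs
  without a model are configuration errors, not silent degradations. An
  empty test-positive set makes the metrics undefined rather than zero.
* Where generalization against a fixture's full manifest is measured
  (`manifest_auc`), sites that entered any model's training set are excluded
  by default; forests memorize their training rows, and including them
  biases a null-signal AUC well above chance.

## Problem sizes in the test suite

The packaged tests run the full protocol at the generator's default scale
(1,000 planted sites, 10 training runs, 100 trees) for the recovery checks,
ten repetitions of that scale for the null-peak and perturbation seed
sweeps, and reduced scales (tens to hundreds of windows, 2–3 runs) for the
contract tests, keeping the whole suite around a minute on one CPU. The
brute-force scanner equivalence runs on 1,000 random 200-nt sequences.

## Known limitations

* Site-level only: the method reports whether a site is methylated in
  aggregate, not the fraction of molecules methylated — the per-read error
  rate of the current pore chemistry does not support stoichiometry.
* Motifs outside the qualifying whitelist are scanned and trainable but not
  called by default; their real-data signal is too weak for the pore to
  resolve.
* Sites whose windows span exon junctions are flagged, not resolved; a
  principled treatment would need genome-aware signal extraction upstream.
* The truth-label model treats CLIP intervals as point evidence at the
  central A; interval-scale evidence (peak widths) is reduced to
  containment.
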