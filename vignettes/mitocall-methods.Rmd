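---
title: "Methods: mitogenome characterization and call parameterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterization and call parameterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocall)
```

This vignette documents the models, conventions and numerical choices
behind each analysis stage, what the synthetic-data generators emulate,
and what the package's tests do and do not demonstrate about real data.

## Coordinates and strands

All genomic coordinates are 1-based and inclusive, the convention of
GenBank feature tables and of published mitogenome organization tables;
conversion to 0-based half-open intervals happens only inside format
readers/writers. Strands are `H` (heavy, the reference orientation) and
`L` (light); L-strand features are stored with H-strand coordinates and
reverse-complemented on extraction, so every downstream computation sees
coding-sense sequence. Features spanning the circular origin are
rejected with an error rather than silently mishandled: vertebrate
mitogenome annotations conventionally place position 1 at the start of
tRNA-Phe, and no feature wraps the origin in such tables. `N` bases are
allowed; they count toward lengths but are excluded from every
composition denominator.

## Organization table

For each feature the table reports size (`end - start + 1`), start/stop
codon class, and *continuity*: the signed count of nucleotides strictly
between consecutive features in coordinate order,
`start - prev_end - 1`. Zero means abutting genes, negative values
overlaps (the ATP8/ATP6 overlap of a typical vertebrate mitogenome is
-43), positive values intergenic spacers. The first row's continuity is
its offset from position 1. Continuity is computed in genome coordinate
order regardless of strand, because L-strand tRNAs participate in the
same chain in published tables. A telescoping identity follows —
summed sizes plus summed continuities equal the last feature's end
coordinate — and is asserted in the tests.

Stop codon class follows the CDS length modulo 3: remainder 0 means a
complete terminal codon, which must belong to the vertebrate
mitochondrial stop set (TAA, TAG, AGA, AGG) or the row is flagged;
remainder 2 is the truncated `TA`, remainder 1 the truncated `T`. These
incomplete stops are completed to UAA by post-transcriptional
polyadenylation in vivo; the table reports them as annotated and never
"repairs" them, since translation is out of scope.

## Composition and skew

AT skew is `(A - T)/(A + T)` and GC skew `(G - C)/(G + C)`, both defined
as 0 when the denominator vanishes. Contents (`A+T`, `G+C`, `A+G`) are
percentages of unambiguous bases, reported to two decimals. Because
published "average PCG A+T content" values rarely state whether they are
the unweighted mean of per-gene percentages or the composition of the
concatenated genes, `pcg_composition_summary()` reports both. Reverse
complementation negates both skews and preserves contents exactly; the
tests assert this identity without tolerance.

## Codon usage (RSCU)

Codons are counted over the 13 protein-coding genes on coding sense,
dropping each gene's trailing incomplete codon. The genetic code is
fixed to the vertebrate mitochondrial code (NCBI translation table 2):
AGA/AGG are stops, ATA is Met and TGA is Trp, so Met and Trp each form
two-codon synonymous families. Two counting conventions were genuinely
open and are resolved as follows: *all* codons that are stops under
table 2 are excluded from the usage table wherever they occur (not just
terminal ones), and start codons are counted as ordinary codons. RSCU
for codon *c* in a family of size *k* is
`count(c) * k / sum(family counts)`; a family with no observations gets
RSCU 0 throughout. The family mean of RSCU is therefore 1 for every
observed family, an exact conservation law the tests assert.

## tRNA cloverleaf assignment

Free-energy minimization is deliberately avoided: mito-tRNAs are short
and degenerate, and an MFE fold is neither deterministic across
parameter sets nor easy to test. Instead the fold is a constrained
template search. The 7-nt anticodon loop is anchored at an occurrence of
the annotated anticodon (loop positions 3-5); the anticodon stem is
extended greedily (target 5 bp, at least 4 required); the termini are
paired into a 7-bp acceptor stem (at least 6 pairs, at most 1 mismatch,
with or without a 3' discriminator base); the 5' flank is searched for a
D-arm (3-4 bp stem, 4-12 nt loop) and the 3' flank for a T-arm (4-5 bp
stem, 4-9 nt loop). Wobble G:U pairs count as pairs — standard for tRNA
stems — while the single tolerated mismatch is confined to the acceptor
stem; unlimited mismatches would make "canonical" vacuous. If the
anticodon occurs more than once, the occurrence yielding the most paired
bases wins, ties going to the 5'-most. Arms searched but not found are
reported absent and the structure flagged non-canonical — the behavior
expected of mt tRNA-Ser(AGY), which lacks the D-arm in mammals.

The synthetic constructor `synth_trna()` builds cloverleafs arm by arm
with loop and spacer bases drawn from {A, C} only: no allowed pair joins
two of A/C, so single-stranded regions cannot spuriously pair and the
planted layout is the structure the folder recovers. A draw that
nevertheless admits an alternative fold is redrawn.

## Distances and trees

p-distances use pairwise deletion (sites with a gap or ambiguity in
either sequence of a pair are excluded from that pair only), matching
the default of the software mitogenome papers typically use for such
tables. Model-corrected distances are closed-form maximum-likelihood
estimators: JC69 `-(3/4) ln(1 - 4p/3)`; K2P from the
transition/transversion partition; TN93 from the two transition classes
with base frequencies averaged over the pair. Published tables of "ML
distances" usually do not name the model; the default here is TN93 (the
family such software defaults to), with JC69/K2P selectable, and the
model name is stamped into every output. Saturated pairs yield `Inf`
with a warning rather than an error. The test suite verifies all three
estimators against an independent implementation (`ape::dist.dna`) to
1e-9 and the JC69 closed form analytically.

Neighbor joining runs on the standard agglomeration; negative branch
lengths are clamped to zero with the deficit moved to the sister branch,
preserving tip-to-tip path lengths. On additive matrices NJ provably
recovers the generating topology; the tests check this against a
brute-force least-squares fit over *all* unrooted topologies for up to
five taxa. Bootstrap support resamples alignment columns with
replacement, rebuilds the NJ tree per replicate, and reports per-split
percentages on the point-estimate tree; everything is reproducible for a
fixed seed. Bayesian inference and full ML tree search are out of scope;
distance trees with bootstrap are the supported approximation.

## Call parameterization

Commercial call-analysis software does not document its measurement
definitions, so absolute agreement with any particular program is not
claimable; instead every definition here is explicit and configurable
(`call_config()`):

* **Detection** runs on a band-limited RMS envelope (4th-order
  Butterworth band-pass, default 20-60 kHz — bracketing the 29-35 kHz
  sweeps of barbastelle-type type-I calls; 0.25 ms RMS window). Regions
  above the per-recording peak envelope minus 24 dB are detections;
  runs shorter than 0.5 ms are dropped *before* merging so clusters of
  noise blips cannot fuse into a pseudo-pulse, and surviving regions
  closer than 5 ms are merged.
* **Spectrogram**: Hann window of 256 samples zero-padded to a
  1024-point FFT at 87.5% overlap (hop 32 samples). At the 384 kHz
  default rate this gives 0.375 kHz bins and an 83 µs hop; a 1024-sample
  analysis window would span ~2.7 ms — longer than a typical 2.4 ms
  pulse — so the shorter window with zero-padding keeps time resolution
  while retaining the fine frequency grid.
* **Per pulse**: the spectral ridge is the per-frame power maximum with
  parabolic bin interpolation; frames whose ridge power is within 20 dB
  of the window maximum are included. Peak frequency is the maximum of
  the mean included-frame spectrum. Pulse edges are refined on the
  envelope at the same -20 dB cutoff, and the sweep endpoints are read
  from a power-weighted polynomial fit of the ridge track evaluated at
  those edges — a single edge frame carries spectral jitter at low SNR
  that the fit averages out, without biasing linear sweeps.
* **Summary**: sample SD (n-1 denominator), matching "mean ± SD" table
  conventions; the inter-pulse interval is onset-to-onset (at
  ~250 ms intervals versus ~2.4 ms pulses, the distinction from
  offset-to-onset is immaterial, but the convention is fixed and
  recorded).

Bandwidth is reported as the ridge-frequency extent over included
frames. Note that published "frequency bandwidth" values can exceed the
start-minus-end difference (energy above the start or below the end of
the nominal sweep), so bandwidth is a descriptive output here and not a
recovery target.

The generator `gen_fm_call()` produces descending linear or hyperbolic
(1/f linear in time) sweeps with raised-cosine on/off ramps of 5% of the
pulse duration per edge — long enough to bound spectral splatter
(~4 cycles at 31 kHz), short enough that the envelope's -20 dB extent
stays within one analysis frame of the nominal duration — plus white
Gaussian noise at a chosen SNR (peak signal power over noise power).
Defaults follow the free-flight call table of the Caspian barbastelle:
33.15 to 29.82 kHz, 2.43 ms pulses, 246.57 ms intervals.

## Synthetic mitogenomes

`generate_mitogenome()` lays features out at the exact coordinates of
its spec (the default spec is the 38-row organization of a
*Barbastella*-style 16,933 bp genome shipped as a TSV), so planted
overlaps, truncated stops and codon classes reproduce a published table
field for field. Start/stop codons of every PCG are pinned into the
sequence first; tRNAs are written as constructed cloverleafs that adapt
to bases already fixed by earlier features (stem partners
re-complemented); remaining positions are drawn from a base-composition
bias (default A 0.33, C 0.25, G 0.13, T 0.29, an A-rich, G-poor
mammal-mitochondrion-like H strand); finally a repair pass removes
in-frame stop codons from every PCG reading frame, never touching
pinned or tRNA-locked bases. Overlap regions keep the earlier-starting
gene's sequence; a spec whose constraints cannot be satisfied (e.g. a
fully pinned stop codon in another gene's frame) is rejected as
infeasible rather than silently altered.

The generator emulates coordinate structure, codon constraints,
composition bias and tRNA foldability. It does **not** emulate
evolutionary processes (no substitution model along a tree), real codon
usage preferences beyond the base bias, strand-asymmetric mutation
pressure, or sequencing error. Tests passing on synthetic genomes
therefore demonstrate the correctness of coordinate arithmetic, strand
handling, counting and folding logic — not biological realism of any
inferred quantity.

## Problem sizes and determinism

Every stochastic component takes an explicit seed and is exactly
reproducible. The test suite exercises: the full 38-feature default
genome; 100 seeded random genome specs (4 PCGs, 5 tRNAs, ~2-4 kb each)
through the generate-then-tabulate round trip; the JC69 closed form on a
grid over p in [0, 0.7]; NJ topology recovery on random 4- and 5-taxon
additive matrices against the brute-force oracle; bootstrap determinism
at 25-100 replicates; and 50 seeded call-parameter draws spanning the
published call-table ranges at 20 dB SNR with three pulses each. These
sizes keep the whole suite under a minute while leaving each property
statistically meaningful.

## Known limitations

* The GenBank reader covers the flat-file subset organelle submissions
  use (single sequence, simple or complement locations); joins and
  origin-spanning features are rejected.
* "Canonical/non-canonical" tRNA classification depends on the stated
  stem/loop search ranges; structures outside them (e.g. extreme
  variable arms) would be misclassified.
* TN93 distances use pair-averaged empirical base frequencies, the
  common plug-in choice; alignment-wide frequencies would differ
  slightly.
* Call measurements are validated against the package's own generator,
  not against field recordings or any commercial analysis chain.
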