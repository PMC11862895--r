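# mitocall

Characterize a small circular mitochondrial genome and parameterize
frequency-modulated echolocation calls — the two computational halves of
a "first record + first mitogenome" species paper — as reusable,
testable R functions.

Mitogenome announcements for bats and other vertebrates revolve around
a small set of standard computations: the gene organization table
(sizes, start/stop codon classes, intergenic spacers and overlaps),
nucleotide composition with AT/GC skew, relative synonymous codon usage
over the 13 protein-coding genes, cloverleaf secondary structures for
the 22 tRNAs, pairwise marker-gene distances with distance trees, and a
table of per-pulse call parameters from field recordings. These are
usually produced by hand across several GUI programs and are hard to
re-check. `mitocall` implements each stage with explicit, documented
definitions, and pairs every stage with a seeded synthetic generator so
correctness is testable with no external data.

## Methods at a glance

* **Organization table** — size `end − start + 1`; *continuity* between
  consecutive features `start − prev_end − 1` (negative = overlap,
  positive = spacer); stop-codon class from CDS length mod 3
  (complete / truncated `TA` / truncated `T`).
* **Composition** — AT skew `(A−T)/(A+T)`, GC skew `(G−C)/(G+C)`;
  contents as percentages of unambiguous bases.
* **Codon usage** — vertebrate mitochondrial code (translation
  table 2); `RSCU(c) = k·n_c / Σ_family n`, so the family mean is 1.
* **tRNA folding** — deterministic cloverleaf template search anchored
  on the annotated anticodon (acceptor 7 bp ≤1 mismatch, D-stem 3–4 bp,
  anticodon stem ≥4 bp, T-stem 4–5 bp, G:U wobble allowed); a missing
  arm flags the structure non-canonical.
* **Distances & trees** — p-distance with pairwise deletion;
  closed-form JC69 `−¾ ln(1 − 4p/3)`, K2P and TN93 estimators;
  neighbor-joining with negative-branch clamping; column-resampling
  bootstrap support.
* **Bioacoustics** — band-limited envelope detection; Hann STFT ridge
  tracking with parabolic interpolation; start/end frequency, peak
  frequency, bandwidth, duration, onset-to-onset inter-pulse interval;
  `mean ± SD` (n−1) summaries.
* **Synthetic data** — annotated mitogenomes generated at exact
  template coordinates (pinned codons, planted overlaps, truncated
  stops, foldable tRNAs) and FM pulse trains with known sweep
  endpoints, duration, interval and SNR.

See `vignettes/mitocall-methods.Rmd` for the full conventions and the
reasoning behind every numerical choice.

## Worked example

```r
library(mitocall)

# the packaged annotation table of a 16,933 bp vespertilionid mitogenome
g <- read_feature_tsv(system.file("extdata",
       "bcaspica_mtgenome_features.tsv", package = "mitocall"))
summary(build_table(g))
#> Organization table: 38 features (13 PCG, 22 tRNA, 2 rRNA, 1 control)
#>   PCG total 11408 bp | tRNA total 1520 bp | rRNA total 2528 bp | genome 16,933 bp

# a synthetic genome on the same layout, with ground truth attached
gm <- generate_mitogenome(genome_spec(seed = 1))
summary(codon_usage(gm$genome))
#> codon usage: 3792 codons counted; 30 of 60 sense codons with RSCU > 1
#>   most frequent: AAA-K (144), AAU-N (138), AUA-M (132), UUA-L (121), ACA-T (115)
fold_all(gm$genome)$n_canonical
#> [1] 22

# a synthetic 10-pulse call train at the published call-table means,
# measured back by the analysis chain
rec <- gen_fm_call(33.15, 29.82, 2.43, 246.57, n_pulses = 10,
                   snr_db = 30, seed = 1)
summarize_calls(measure_all_pulses(rec))
#> call summary over 10 pulses
#>   Initial frequency (kHz)     33.09-33.12    33.10 +/- 0.01
#>   Terminate frequency (kHz)   29.84-29.89    29.87 +/- 0.01
#>   Frequency bandwidth (kHz)    2.79-3.49      3.03 +/- 0.26
#>   Main frequency (kHz)        31.49-31.50    31.49 +/- 0.00
#>   Duration time (ms)           2.42-2.42      2.42 +/- 0.00
#>   Interval time (ms)         246.56-246.58  246.57 +/- 0.01
```

The summary recovers the planted 33.15 → 29.82 kHz sweep, 2.43 ms
duration and 246.57 ms interval to within the spectrogram's frequency
bin (0.375 kHz) and frame hop (0.083 ms).

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mitocall.R", package="mitocall"))')" \
    profile --features features.tsv --out out/
```

Subcommands: `profile`, `codons`, `trna`, `dist`, `tree`, `calls`,
`simulate`, `simulate-calls`. Every output file carries a header with
the package version, the exact options used and their hash; all
randomness flows from `--seed`.

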