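---
title: "Methods: models and design choices in nanoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in nanoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each analysis, the parameters that
matter, the synthetic generator the test suite leans on, and the places where
the design was genuinely open and a choice had to be made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Dual-strand alignment and error labelling

A substitution error is a property of the *sequencing* event: the pore read a
base where the template had another. If a reverse-strand read is
reverse-complemented before alignment (the default of most aligners), the
aligned labels describe the complementary strand: a genome-`A`-read-as-`C`
event surfaces as `C/G`. `nanoscape` therefore expects the dual-strand
protocol: reads aligned once against the forward genome and once against its
reverse complement, with read reverse-complementing disabled (for minimap2,
the `--for-only` flag together with `--secondary=no --sam-hit-only`; the
package consumes the SAM, it never runs the aligner). Each read keeps the
alignment with the lower global error rate.

Choices made here:

* **"Best alignment" criterion.** Left open by the protocol; decided as the
  minimal global error rate with ties broken toward the forward orientation.
  This is deterministic and independent of aligner scoring schemes.
* **Coordinates.** Internally 0-based half-open; SAM's 1-based convention is
  translated only at the I/O boundary. Reverse-orientation reads keep their
  columns in the oriented (reverse-complemented) frame; position `p` maps to
  `L − 1 − p` on the forward genome for window/region aggregation.
* **Clips.** Reads whose clipped length exceeds half the read are discarded
  (strictly greater; a half-clipped read survives). Hard clips count like
  soft clips — both are unaligned read sequence.
* **`N` bases.** Columns pairing an `N` count in alignment length but are
  neither matches nor mismatches (no defined base identity); they are
  excluded from substitution matrices. They are tallied separately so the
  match/mismatch/indel/ambiguous partition is exhaustive.
* **Indel runs** count column-wise: a 3-base deletion contributes 3 deletion
  errors. Insertions anchor to the preceding reference base (leftmost
  convention; an insertion before the first aligned base anchors to the
  alignment start).

## Error rates: per read versus pooled

Global rates are pooled column counts (total mismatches over total alignment
length). Figures binned "per read" — error versus read GC, retention — use
unweighted means of per-read rates, so a long read does not dominate a bin.
Both views are exposed; they answer different questions.

The transition/transversion comparison is run at the read level: for each
read with at least one substitution, the per-pair A↔G rate (pooled fraction
over its two ordered pairs) and the mean per-pair transversion rate (over the
eight ordered transversion pairs) enter a Welch two-sample t-test. The
per-pair scaling makes the null (substitutions uniform over the twelve pairs)
have equal means, which the test suite verifies by simulation; the read as
sampling unit is the only choice whose degrees of freedom can produce the
extreme p-values deep datasets show.

## Quality model

Phred: `P = 10^(−Q/10)`. Observed calibration is measured on sliding
100-read-base windows: the window's arithmetic mean Phred (rounded to 0.1)
against its error rate, where enclosed deletion columns add errors but carry
no quality. The default stride is 25 bases — full base-by-base sliding is
available (`stride = 1`) but only increases window count, not bin means.
Whether a window's "mean quality" should be arithmetic or probability-domain
(`−10·log10` of mean `P`, the domain basecallers use for read scores) is not
settled usage; both are implemented, arithmetic is the default and the one
used everywhere in the test suite.

The quadratic calibration model `E(%) = aQ² + bQ + c` is a weighted least
squares fit (weights = window support) restricted to `Q ∈ [7, 30]`, the range
where nanopore scores are informative; the fit is on the percent scale.

Retention: for thresholds 7–12 on per-read mean quality, the kept fraction
(relative to the lowest threshold) and the mean error of kept reads; the
(read-loss, error-loss) pair between thresholds 7 and 10 summarises the
trade-off. The pipeline's default analysis threshold is mean quality 10,
mirroring common basecaller filtering practice; reads below it are excluded
from analyses but still counted in retention.

## Low-complexity repeats

Definitions: homopolymer = maximal run of `k ≥ 2` identical bases;
heteropolymer = maximal run of `k ≥ 2` copies of a two-base unit `XY`,
`X ≠ Y`, length `2k` (a trailing odd base is ignored: `ACACA` is `AC`×2);
trinucleotide repeat = `k ≥ 2` copies of a 3-base unit, excluding the pure
single-base unit `XXX`, counted per phase so rotated motifs each yield their
own maximal occurrence. For heteropolymers one occurrence is reported per
maximal period-2 region (left-aligned); symmetric units (`AC`/`CA`) are
pooled in distribution tables.

Assessment of a read's rendering is *run-based*: the observed homopolymer
length is the maximal run of the motif base in the read overlapping the
occurrence. This makes the measure invariant to where the aligner gauge
placed indels inside the run, at the cost that same-base context created by a
flanking substitution or insertion can extend the observed run — which is
faithful: such a read genuinely shows a longer run. "Correct" means observed
length equals reference length (for multi-base units, additionally that the
read segment under the occurrence is exactly the unit repeated). Occurrences
not fully spanned by a read's aligned interval are skipped, since their full
length cannot be judged.

Error attribution: an error belongs to a homopolymer iff its forward-genome
anchor lies in a homopolymer interval; insertions also count when anchored at
the base immediately left of the interval, because aligners place boundary
insertions ambiguously. The H/A table reports, per error type, homopolymer
errors (H), all errors (A) and their percentage ratio.

## Perfect k-mers and harmful k-mers

The longest error-free stretch (consecutive match columns) of each read
bounds usable seed sizes; `seed_size_at_confidence(lengths, 0.95)` is the
largest `k` such that 95% of reads contain a perfect stretch of at least `k`
(floor-convention quantile). Distribution asymmetry is summarised with the
Pearson skewness coefficients `SCP_mode = (mean − mode)/sd` and
`SCP_median = 3(mean − median)/sd`; the mode uses unit-width histogram bins
with smallest-value tie-break.

Harmful k-mers are the `k = 5` read bases (gaps skipped) immediately before
or after an error position — read bases, not reference, because the
basecaller sees only the read; a reference-context mode is a one-line change
left to downstream users. `k = 5` matches the number of bases shaping the
pore signal in the R9.4 chemistry. A run of consecutive deletion columns is
one gap event (one context extraction) even though each column remains one
deletion error elsewhere — double-counting contexts would overweight long
deletions. Contexts truncated by read ends are skipped; errors inside
reference homopolymers can be excluded to isolate sequence-specific effects.

The retained top-10 k-mers per dataset feed a layered automaton: a prefix
trie whose states are merged when their residual suffix languages coincide
(right-language equivalence — the minimal deterministic layered automaton;
any published merged graph is consistent with but does not dictate this
rule, so the minimal construction was chosen). Edge weights are supporting
k-mer counts per GC class; before pruning, each layer's edge weights sum to
the total weight and the language equals the input set — both are invariants
in the test suite. The display threshold (total node weight ≥ 4) is applied
at export only; the full automaton is retained.

## Translocation speed

`S = N/E × R`: `N` reference bases, `E` raw samples, `R` = 4000 samples/s.
Windows are 25 *reference* bases (reference-anchored: deleted bases carry
event samples in a resquiggled table and still count toward `N`); speed bins
are 50 bases/s wide. The module consumes a per-base event-count TSV; signal
segmentation itself is out of scope.

## The synthetic generator

The generator exists so every analysis has a known truth to recover. Per
read: a quality level `q ~ Normal(q_mean, q_sd_read)` (clamped) sets the
total per-column error probability `p = 10^(−q/10)`; `q_mean` is calibrated
numerically so `E[p]` equals the nominal rate sum exactly. Columns are then
i.i.d.: insertion with `p·w_ins`, deletion with `p·w_del`, mismatch with
`p·w_sub` (weights = nominal rates normalised), with substitution targets
drawn under a configurable transition multiplier, and a per-read additive GC
slope on `p`. Emitted qualities are `round(−10·log10 p) + offset`: offset 0
is perfectly Phred-calibrated by construction; `q_integer = TRUE` rounds the
level first so the calibration is exact bin-by-bin (used by the calibration
property tests); a positive offset reproduces the overevaluated-quality
signature. Read lengths are log-normal, median 10 kb, truncated to
[500, 100 kb]; reads sample both strands uniformly and the reverse-strand SAM
is written against the reverse-complemented genome, never the
reverse-complemented read.

Homopolymer runs of length ≥ 5 in the sampled segment replace the column
process with a length-resampling model: observed length
`max(0, L + delta)`, `delta` the difference of two Poissons with intensities
growing in `L − 4` (deletion-dominant, so long runs are underestimated), plus
a small geometric overestimation tail. Shorter runs see ordinary column
errors. The ≥ 5 cutoff keeps the runs under the length model to ~1.5% of
genome columns at 50% GC, so pooled rates stay within a few 10⁻⁴ of nominal —
inside the ±0.002 recovery tolerance the acceptance suite checks.

Truth records carry exact per-read error counts (byte-identical to what the
SAM round-trips to) and, for a configurable read subset, the true observed
length of every homopolymer run fully inside the read — measured on the
generator's own columns, including flank-merging effects, so the
accuracy-by-length curve the pipeline measures through SAM parsing, repeat
finding and assessment can be compared occurrence-by-occurrence against an
independently bookkept truth.

What the generator does *not* emulate: realistic pore physics, k-mer-specific
signal levels, basecaller-specific artefacts, structural variation, or any
particular organism's repeat spectrum. Passing recovery tests therefore
demonstrates that the measurement chain is correct, not that real data will
match any particular curve.

### Default study fixture and problem sizes

`default_fixture()` is the package's reference run: a 5 Mb genome with
block-wise GC heterogeneity (Normal(50%, 8%) per 10 kb block), 13 000 reads
(~30X), transition multiplier 4, GC-error slope 4·10⁻⁴ per GC percent, seeded
end-to-end. The acceptance test suite runs it at full size; unit tests and
the acceptance script use proportionally scaled versions (the `scale`
argument), chosen so each check retains comfortable statistical power —
e.g. ±0.002 on pooled rates needs ~10⁶ aligned columns, and the homopolymer
curve needs ≥ 500 assessments per length, both amply covered at the sizes
used.

## Numerical and degenerate-input conventions

* Empty alignments reject (`error_counts` denominators undefined).
* GC fractions exclude `N` from the denominator; a base-free sequence gives
  `NaN`.
* Windows without coverage emit missing rates rather than zeros.
* `sd = 0` perfect-k-mer distributions flag the skewness coefficients as
  undefined instead of dividing by zero.
* All randomness flows through explicit integer seeds (Mersenne-Twister,
  inversion normals); identical seeds reproduce every emitted file
  byte-identically.

## Known limitations

* One reference sequence per run; multi-contig references must be profiled
  per contig.
* Repeat assessment cost grows with reads × occurrences; the pipeline caps
  assessed reads (default 2000, configurable) rather than streaming.
* The read-GC error figure uses aligned bases only (clipped sequence is not
  retained in the alignment container).
* Heteropolymer occurrences are counted once per maximal period-2 region;
  tools counting both phases will report roughly twice as many occurrences
  of symmetric units.
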