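---
title: "Measuring translation termination with riboterm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring translation termination with riboterm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboterm)
library(data.table)
```

## The measurement problem

Ribosome profiling reads out, at nucleotide resolution, where ribosomes
sit on mRNAs. Around the normal termination codon (NTC) two phenomena
compete: terminating ribosomes dwell on the stop codon (a *terminal
pause*, visible as a density peak at the NTC), and a small fraction of
ribosomes *read through* the stop codon, continuing in frame into the
3′UTR until the next in-frame stop codon. Compounds that promote
readthrough of premature termination codons — candidates for treating
nonsense-mutation diseases — also perturb these genome-wide quantities,
and the direction of the perturbation distinguishes mechanisms: an
aminoglycoside that promotes readthrough *depletes* the NTC peak and
*fills* the proximal 3′UTR, while a compound that inhibits termination
by prolonging the terminal pause *raises* the NTC peak without
populating the 3′UTR.

`riboterm` quantifies both effects per transcript and condition.

## Coordinate frame and regions

All coordinates are 0-based, half-open, in transcript space, running
5′→3′. Strand is resolved once, when genomic annotation is flattened to
transcript models (`load_transcript_models()`), and never reappears.
The CDS interval *includes* the NTC as its last codon, so "density at
the stop codon" and "CDS density" live in a single frame; whether the
NTC should instead sit outside the CDS is a genuine convention choice
(annotation dialects differ), and because the RRTS numerator and
denominator are both affected only marginally by 3 nt of a ≥ 300 nt
CDS, the package fixes the inclusive convention rather than exposing a
knob that would fragment provenance.

Each valid transcript model yields four regions (`derive_regions()`):

| region      | interval                              | role |
|-------------|---------------------------------------|------|
| `cds`       | `[cds_start, cds_end)`                | RRTS denominator |
| `cds_body`  | `[cds_start + 15, cds_end − 12)`      | pause-score denominator |
| `stop_codon`| `[cds_end − 3, cds_end)`              | pause-score numerator |
| `extension` | `[cds_end, next in-frame stop)`       | RRTS numerator |

The CDS body excludes the first 15 and last 12 nucleotides so that the
initiation peak and the terminal pause itself do not contaminate the
elongation-density denominator. The two scores deliberately use
*different* denominators — the body for the pause score, the full CDS
for the RRTS — because they estimate different ratios: NTC dwell time
relative to elongation, and readthrough flux relative to overall CDS
occupancy. Transcripts whose CDS is shorter than 30 nt have an empty
body and are flagged pause-ineligible; transcripts with no in-frame
3′UTR stop have no extension and are RRTS-ineligible but keep their
pause score. A zero-length extension (an in-frame stop immediately
after the NTC) is kept and scores RRTS 0 — excluding such transcripts
would silently censor the lowest-readthrough class.

## From footprints to density

Footprints pass through three explicit stages, each reporting its drop
counts: UMI deduplication (one record per unique transcript / 5′
position / length / UMI key; empty UMIs are never collapsed), size
selection (closed interval, default 15–35 nt, the usual gel window),
and P-site assignment. P-site offsets are a configured table; the
default maps 25–31 nt footprints to +12 nt — the conventional mammalian
offset — and drops other lengths, because a length with no calibrated
offset has no confident P-site. Both choices are surfaced in every
output's provenance header. Density is raw P-site counts per
nucleotide; every normalization happens inside the metrics, so there is
exactly one place where "density" is defined.

## Scores and metagene

For one transcript with density track $c(p)$:

$$\text{pause} = \frac{\overline{c}(\text{stop codon})}{\overline{c}(\text{CDS body})},
\qquad
\text{RRTS} = \frac{\overline{c}(\text{extension})}{\overline{c}(\text{CDS})},$$

with $\overline{c}$ the mean count per nucleotide over a region. Both
are scale-free: multiplying a transcript's counts by any $k > 0$
changes neither (a tested invariant). There are **no pseudocounts**; a
zero denominator makes the transcript ineligible with a reason code
instead of producing a biased finite score, because a pseudocount in
the RRTS denominator would systematically drag low-coverage transcripts
toward 0. Eligibility additionally requires `min_cds_reads` P-site
counts in the CDS (default 32): ratio estimates from a handful of reads
are dominated by Poisson noise, and the threshold — which is reported
in provenance and freely settable — keeps the per-transcript score
distributions interpretable. Densities are always reported even for
ineligible rows, so nothing is hidden.

The metagene (`metagene()`) aligns transcripts at the first NTC
nucleotide (position 0), divides each eligible transcript's track by
its own mean CDS density, and averages position-wise with equal weight
per transcript. This normalization makes a uniformly covered transcript
contribute exactly 1 everywhere, so the uniform profile is a fixed
point (tested to 1e-12) and the NTC peak height reads directly as a
pause multiplier. The default ±100 nt window covers the terminal CDS
region and proximal 3′UTR where both signatures live; transcripts
shorter than the window contribute only to positions they cover, with
per-position `n_transcripts` reported.

## The hypothesis tests

Condition contrasts use two tests, implemented in the package from
first principles with two modes each:

* **Wilcoxon signed-rank** on paired per-transcript pause scores
  (pairing by transcript on a shared transcriptome), two-sided. Zero
  differences are dropped (Wilcoxon's original convention) and counted;
  absolute differences are ranked with average ranks for ties.
* **Mann–Whitney U** on RRTS distributions, direction stated explicitly
  by the caller — nothing is inferred from labels or file names.

For small samples (n ≤ 12 nonzero pairs, or pooled n ≤ 12) the null is
*enumerated*: all $2^n$ sign assignments, or all $\binom{n_1+n_2}{n_1}$
relabelings, of the observed rank vector, which stays exact under ties.
Beyond that, a normal approximation with tie correction and continuity
correction is used. The cutoff of 12 keeps enumeration instantaneous
(≤ 4096 or ≤ 924 outcomes) while the approximation is already accurate
there; the suite cross-checks the two modes at the boundary (agreement
within 0.03) and the whole implementation against R's `wilcox.test` on
tie-free data. Two-sided p-values are `min(1, 2·min(tails))`, matching
the exact-test convention. Empirical type-I error at α = 0.05 over
2,000 null replicates falls within [0.035, 0.065] for both tests (an
acceptance-tested property).

`ecdf_points()` and `box_stats()` provide the descriptive companions:
cumulative histograms for pause scores, and box statistics with type-7
(linear interpolation) quartiles, McGill notches
(median ± 1.57·IQR/√n, the usual 95% comparison interval), and whiskers
at the most extreme data point within 1.5·IQR of the quartiles. Both
the quartile convention and the notch constant admit variants, so they
are fixed and documented here.

## The generative simulator

`simulate_transcriptome()` + `simulate_footprints()` encode an explicit
model of termination-zone footprint data:

* Transcript lengths: CDS uniform over multiples of 3 in 300–900 nt,
  5′UTR 15–60 nt, 3′UTR 120–300 nt — typical mammalian mRNA scales,
  large enough for stable CDS densities. A configurable fraction
  (default 0.9, reflecting that most annotated 3′UTRs contain a nearby
  in-frame stop) carries a designated second stop placed uniformly in
  the usable 3′UTR; extension codons are drawn from the 61 non-stop
  codons, so the designated codon is provably the *first* in-frame stop
  and no rejection sampling is needed.
* Expression: per-transcript rate λ ~ Gamma(shape 2, scale 1), mean 2
  counts/nt — overdispersed across transcripts (negative-binomial
  marginal) as in real ribo-seq, while per-position noise stays
  Poisson.
* Termination knobs: position-level Poisson means are λ across the CDS,
  πλ on the 3 NTC positions, rλ on the extension, π₂·rλ on the second
  stop, and 0 in the 5′UTR and beyond the second stop. Hence
  E[pause] ≈ π and E[RRTS] ≈ r up to a CDS-density correction of order
  3(π−1)/CDS-length (~0.5% at defaults), and readthrough is uniform
  over the extension — the simplest profile consistent with
  constant-rate elongation after the NTC; a within-extension drop-off
  is deliberately not modeled.
* Reads: each P-site count becomes a record with a length drawn from a
  unimodal 25–31 nt distribution peaked at 28 nt and a 5′ end
  back-computed from the configured offset table, so the pipeline
  recovers the intended P-site exactly under the same table — simulator
  and pipeline cannot drift apart. UMIs (10 nt, mirroring a 4 + 6 nt
  two-adapter design) are drawn uniquely within each duplicate-defining
  key, and PCR duplicates are injected with identical UMIs at a
  configured rate, so deduplication must remove exactly the injected
  rows — a bookkeeping identity the tests assert per seed.

The default three-arm design places a vehicle-like condition at
π = 1, r = 0.005; an aminoglycoside-like condition at π = 0.5,
r = 0.08; and a terminal-pause-inducer-like condition at π = 3,
r = 0.005, on one shared transcriptome with independent noise — the
sharing is what makes the paired signed-rank contrast meaningful. The
true effect sizes in real treated cells are unknown (published analyses
report test statistics, not π or r), so these values are chosen for
clear mechanistic separation, not biological calibration.

**What passing tests do and do not show.** The simulator has
independent per-position noise, no sequence-dependent readthrough
(stop-codon identity and +4 context famously matter), no frame
periodicity, no ligation/PCR sequence bias, and no NMD-coupled
abundance changes. Green tests therefore demonstrate that the *pipeline
arithmetic and inference machinery* are correct under a known
generative model — not that any particular biological effect size will
be recovered from real libraries.

## Numerical and degenerate-input choices

Empty region → density 0 (not NaN); zero denominators → ineligibility
with reason codes (`short_cds`, `low_cds_reads`, `zero_body_density`,
`zero_cds_density`, `no_inframe_stop`); all-zero paired differences →
a hard "degenerate test" error; an empty metagene → a hard error naming
the condition. Score tables are emitted in sorted transcript order and
the simulate→score→compare path is byte-reproducible under fixed seeds;
every output TSV carries a `#` provenance header including a hash of
the analysis settings (paths excluded, so the same settings hash
identically anywhere), and `check_config_hash()` warns on mismatches.

Problem sizes used by the validation suite — 2,000 transcripts for
parameter recovery, 1,000 per arm for the signature contrast, 200
replicate pairs of 200 short transcripts for null calibration of the
paired pipeline, 2,000 replicates for test calibration — are the
package's chosen balance between statistical resolution of the bands
being checked and a suite that runs in a few minutes on one core.

## Plate-assay module

The screening companion implements the printed normalization formulas:
`% Activation = 100·(signal − neg)/(pos − neg)` with per-plate control
means; the hit threshold as mean(test) + 3·SD(negative controls);
`Z′ = 1 − 3(σ₊ + σ₋)/|μ₊ − μ₋|` with a reliability flag at 0.5; S/B,
S/N and %CV; `% viability` on low/high cytotoxicity controls;
RLU/µg protein; `Papp = ΔQ/(Δt·A·C0)` (unit-consistent inputs required,
no inference) and the B→A / A→B efflux ratio. All control statistics
use the sample SD (n − 1): the convention is stated because published
screen summaries rarely specify it. Whether a hit threshold should use
per-plate or campaign-pooled negative-control SDs is left to the
caller, who passes whichever activation vectors they intend.

## Known limitations

* P-site offsets default to a single +12 nt rule rather than per-length
  calibration from periodicity; the table is fully configurable.
* One model per transcript ID: canonical-isoform selection is the
  caller's job upstream.
* Codon-level pause analysis along the CDS, frame-periodicity QC and
  dose–response (logistic) fitting are out of scope.
* BAM ingestion is a convenience interface for transcriptome-aligned
  reads with UMI-in-read-name; it is not exercised by the core tests.
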