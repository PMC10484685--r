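---
title: "Methods: four-base DMS-MaP analysis in fourbase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-base DMS-MaP analysis in fourbase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
package, the tunable parameters and their defaults, the numerical choices
that pin down otherwise ambiguous conventions, and what the synthetic-data
generator does and does not emulate.

## The measurement model

DMS methylates the Watson–Crick face of accessible (predominantly
unpaired) A, C, U and G nucleotides; at G it additionally methylates N7 at
much higher rates, essentially independently of pairing. MaP reverse
transcription converts adducts into mutations, with different chemistries
producing different mutational signatures: N1-G methylation is read out as
G→C and G→T substitutions, N7-G methylation as G→A, and
reverse-transcription artifacts as indels and multi-nucleotide mutations.
The package treats the per-read parsed mutation list (read span plus
`left|right|ref|alt` events) as its raw datum; alignment and mutation
parsing are upstream concerns.

### Signature filter

`classify_events(mode = "dms")` sets to *no data*: G→A single-nucleotide
mismatches, multi-nucleotide mismatches whose reference span contains at
least one G, and insertions and deletions at all nucleotides. Everything
else is retained. Two conventions needed fixing:

- "G multi-nucleotide mismatch" is read as *containment*: any multi
  mismatch whose reference span includes a G, the conservative reading
  when no anchor position is defined.
- A no-data event clears read validity over its own reference span only.
  Some upstream pipelines exclude a ±k neighborhood around ambiguous
  events; that is an alignment-level concern we deliberately do not
  re-implement, and the contract (exactly the event span) is what the
  brute-force counting oracles test.

In `unfiltered` mode every event is retained (including indels, which
then count as mutations), reproducing traditional DMS-MaP counting; the
filtered/unfiltered contrast throughout the tests is one flag.

### Rates and normalization

The DMS modification rate is `treated_rate − untreated_rate`, or the
treated rate alone without a control. Negative background-subtracted
rates are retained, not clamped — they carry information about noisy
positions — but the >0.001 subset used in normalization excludes them by
construction. Quality masks default to effective depth ≥ 1000 (the
conventional MaP depth floor) and untreated rate ≤ 0.05; both are
arguments, and masked positions never enter any percentile, mean or fit.

The per-nucleotide normalization factor is
`N_n = max{ mean of rates in [P90, P95], P75 of rates > 0.001 }`.
Pinned conventions:

- Percentiles interpolate linearly between closest ranks
  (`quantile(type = 7)`), applied uniformly everywhere.
- The band mean averages all values v with P90 ≤ v ≤ P95 (inclusive); if
  ties and interpolation leave that set empty, the interpolated 92.5th
  percentile is used instead, so the factor is defined on all inputs.
- If no rate exceeds 0.001 the band mean alone is used.
- The 0.001 floor applies to the background-subtracted rate — the
  quantity being normalized — not the raw treated rate.
- Factors are computed per RNA; a `factors` argument allows pooled
  factors across transcripts when profiles are too short alone.

### Expected structural information

Each position is paired (b) or unpaired (u) with no-data prior 0.5. The
class likelihoods p̂(r|b), p̂(r|u) are double-gamma mixtures per
nucleotide type with a point mass at r ≤ 0 (normalized profiles contain
zeros and negatives; the zero mass is the empirical nonpositive
fraction). The posterior is the equal-prior density ratio, SI(r) = 1 −
H(s|r) in bits, and ESI is the mean SI over unmasked positions. In
two-base mode (`bases = c("A","C")`) G and U positions contribute SI = 0
but remain in the denominator, which makes two-base and four-base ESI
directly comparable on the same RNA and implies four-base ESI ≥ two-base
ESI. A density floor of 1e−12 before the posterior avoids 0/0 where both
mixtures vanish; at that floor the posterior is 0.5 and SI is 0, which is
the correct "no information" limit.

### Gamma-mixture EM

`fit_gamma_mixture()` requires ≥ 50 values with ≥ 20 positive, estimates
the zero mass empirically, and runs EM on the positive part: restarts
initialized by quantile splits (0.95, 0.5, 0.3, 0.7, 0.6 by default,
further splits drawn uniformly), weighted gamma MLE per component by
Newton iteration on log a − ψ(a), tolerance 1e−6 on mean log-likelihood,
at most 2000 iterations, components ordered by mean. Two deliberate
choices:

- The first restart is near-degenerate (95/5 split). On data actually
  drawn from a single gamma the likelihood surface is flat in the split,
  and a later restart only replaces the incumbent when it improves the
  log-likelihood by more than the convergence tolerance — so nested data
  yield a collapsed fit (one dominant weight) rather than an arbitrary
  even split.
- Non-convergence after all restarts returns the best fit with a warning
  rather than failing, because downstream potentials should degrade
  gracefully on marginal bases.

### PAIR analysis

Windows are 3 nt at every start position; a window is *modified* in a
read if ≥ 1 retained mutation falls in it and *covered* if all three
positions are valid after filtering. For all window pairs with
`j ≥ i + 3`, reads covering both windows are cross-tabulated and tested
with a 2×2 likelihood-ratio G-test (df = 1, no Williams correction).
Conventions:

- Pairs need n11 ≥ 10 co-modification events to be considered.
- The Bonferroni family is *every evaluable window pair* (both windows
  unmasked), not the post-cutoff subset. This keeps the co-modification
  cutoff a pure filter: raising it can only remove PAIRs. Correcting
  over the post-cutoff subset would let a higher cutoff shrink the
  correction factor and admit new PAIRs, which is both surprising and
  untestable as a monotone property.
- Significant pairs must be sequence complementary: ≥ 2 of 3
  Watson–Crick or GU matches in antiparallel register.
- Classification: minor requires both windows' mean normalized
  reactivity ≥ 0.2; principal requires ≥ 0.4 and that the two windows
  are mutually each other's strongest significant candidate partner (by
  G statistic). The source convention orders the two thresholds
  ambiguously; we gate the stronger class (principal) at the higher
  threshold, consistent with strength-based prioritization, and note
  that released single-molecule pipelines may differ in the exact
  statistic, window phasing and correction.
- Windows overlapping masked reactivity positions are excluded entirely.

Scoring against an accepted structure: a PAIR is correct if any of its
three implied antiparallel base pairs matches an accepted pair allowing a
one-position register shift; sensitivity is the fraction of accepted
helices (≥ 3 bp, fully inside data-covered regions) hit by at least one
correct PAIR.

### Structure comparison

`compare_structures()` uses the field's ppv/sens conventions: all pairs,
one-position register shifts, singleton pairs (no stacked neighbor)
removed from both structures first, masked positions excluded from
numerator and denominator. Shift matching is one-to-one — each accepted
pair can be claimed by at most one predicted pair — and the assignment is
resolved by maximum bipartite matching (augmenting paths seeded in 5′
order) rather than greedy claiming. Greedy claiming depends on the order
in which shift neighbors are probed and can drop a valid global
assignment (a prediction claiming its neighbor's only match); optimal
matching is order-independent and keeps the swap symmetry between ppv
and sens exact. With zero predicted pairs ppv is `NA`, never 0.

### Pseudo-energy potentials

`fit_potentials()` refits the same mixture family per (base, class) on a
normalized profile with known structure and serializes it as a
plain-text dists-style table (header, one line per base and class with
weights, shapes, scales, zero mass; `ABSENT` markers for unfittable
bases). The grammar is this package's own documented dialect;
byte-compatibility with any particular folding engine's table format is
out of scope, and `log_likelihood_ratio()` exposes the quantity a
folding engine would consume.

## The synthetic-data generator

`simulate_reads()` draws, per molecule: an ensemble state (weighted
structures over one sequence); per-position adducts as independent
Bernoulli events at rates set by nucleotide type and that state's pairing
status; detection per adduct class; a mutation type from the class
signature; and background errors. Defaults encode the probing regime the
pipeline is designed for:

| parameter | default | meaning |
|---|---|---|
| unpaired adduct rate A, C | 0.02 | Watson–Crick-face methylation per molecule |
| unpaired adduct rate U | 0.006 | |
| unpaired adduct rate N1-G | 0.001 | |
| paired rates | unpaired / 10 | protection factor; a configurable default, not a measured value |
| N7-G rate | 0.5 (all G) | pairing-insensitive, mid-range of the 0.2–0.8 regime |
| detection | 1.0 (A/C/U/N1-G), 0.02 (N7-G) | MaP read-out efficiency per adduct class |
| N1-G signature | G→C/G→U, 50/50 | |
| N7-G signature | G→A, 100% | |
| background substitution / indel | 0.001 / 0.002 per position | typical MaP background |

The product N7-G rate × detection ≈ 0.01 reproduces the observed
structure-blind G→A rate; the N1-G rate 0.001 with full detection via its
signature reproduces the informative channel an order of magnitude below
it. A and C unpaired rates (~0.02) and U (~0.006) are the rates such
experiments measure. The 10-fold paired/unpaired protection is the one
number not pinned by measurement — published rates aggregate both
classes — so it is an explicit parameter; every conclusion the tests
draw is directional in it.

Precedence when multiple events hit one position in one read:
informative adduct > N7-G > background substitution > background indel,
one event per position, so every emitted event traces to exactly one
cause (the `cause` column, which is how the filter-discrimination tests
are truth-traced). Molecules are full-length by default; `read_length`
switches to a uniform-window fragment model. An untreated control is the
same generator with all adduct rates zero.

What the generator does *not* emulate: sequencing-quality error models,
PCR duplicates, alignment artifacts, reverse-transcriptase drop-off,
multi-nucleotide mutations from adducts, and neighborhood effects of
ambiguous indel placement. Passing tests therefore demonstrate that the
algorithms are correct under the stated chemistry model, not that real
libraries meet that model; on real data the filter's benefit depends on
enzyme-specific signatures, and the two-state planted-helix fixtures are
a deliberately favorable regime for PAIR detection (a single melting
helix in an otherwise static structure).

## Problem sizes and runtime choices

The test suite runs the full stack at the scales the methods are meant to
operate at while staying desk-sized: mutation-rate convergence at 100 000
reads over a 150-nt toy; filter discrimination (≥ 95 % N7-G removal /
N1-G retention, truth-traced, plus the filtered-versus-unfiltered AUROC
direction at G) at 100 000 reads; PAIR null calibration at 50 000 reads;
planted-helix recovery at 300 000 reads × 5 seeds over an 80-nt two-state
RNA — 300 000 being the coverage at which single-molecule PAIR detection
becomes reliable; mixture recovery on 5 000 draws and 8 000–10 000-nt
synthetic training structures. Simulation and window counting are
blocked matrix operations (difference-array tallies, crossproducts over
read × window indicator blocks) sized to a few million cells per block,
so the whole suite runs in a couple of minutes on one core.

## Known limitations

- The exact internals of the reference single-molecule PAIR
  implementation (statistic variant, window phasing, correction) are not
  published alongside the thresholds this package adopts; the variant
  here is pinned and fully tested but may differ from released code.
- ESI depends on the fitted likelihoods; with fewer than ~50 usable
  positions per base and class the models (and hence ESI at those bases)
  are unavailable rather than extrapolated.
- Normalization assumes enough dynamic range per nucleotide type; on
  uniformly unreactive types the P75 term vanishes by design, and the
  band mean of near-zero rates will inflate reactivities — the
  low-depth/low-signal masks are the guard rails.
- The dists output is a documented dialect, not a drop-in replacement
  for any folding engine's data table.
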