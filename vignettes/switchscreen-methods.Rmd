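---
title: "Methods: quantifying and screening switch-like brain-specific splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and screening switch-like brain-specific splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscreen)
```

## The problem

High-throughput RT-PCR panels interrogate thousands of alternative splicing
events (ASEs) at once: for each event, a primer pair spans the alternative
region, so the reaction yields a *long* product (alternative region included)
and a *short* product (excluded), separated and quantified by capillary
electrophoresis. From such panels one can ask which events are *switch-like*
in a tissue — flipping from one predominant isoform to the other between, say,
brain and every other tissue — and whether the same switch, in the same
direction, is present in distantly related vertebrates. `switchscreen`
implements that screen end to end: peak-table quantification with a purity
quality gate, switch detection on percent-spliced-in (PSI) matrices,
cross-species conservation calls through an ortholog map, exact enrichment
testing of event types, and time-course characterisation of splicing dynamics
during neural differentiation. A seeded synthetic-data generator plants known
ground truth so every stage is testable without external data.

## From peaks to PSI

A capillary electropherogram is reduced by the instrument to a table of peaks
(fragment size in nt, mass concentration). Fluorescent mass signal is
proportional to base pairs of double-stranded product, so products are
compared *per molecule* by dividing mass by length:

$$\text{molarity} = \frac{\text{mass conc.}}{\text{size (nt)}},$$

with any instrument constant cancelling in every downstream ratio
(`peak_molarity()`).

Peaks are assigned to the expected short and long product sizes by a nearest
match within `max(2 nt, 3%)` of the expected size — typical capillary sizing
accuracy; both numbers are arguments (`match_peaks()`). Each expected size
takes at most one peak; exact-distance ties go to the smaller observed size,
and the short product is assigned first (the two windows never overlap for
realistic amplicon pairs). Then

$$\text{purity} = \frac{\text{matched molarity}}{\text{total molarity}},
\qquad
\psi = 100\cdot\frac{M_\text{long}}{M_\text{long} + M_\text{short}},$$

and a lane passes QC iff purity is **strictly** greater than 0.75 and PSI is
defined. Numerical edge cases are fixed as follows:

* PSI is undefined (missing), not zero, when neither product is found; a lane
  with only one expected band is a *fully switched* lane (PSI 0 or 100),
  provided purity passes.
* A lane with zero total molarity has undefined purity and fails QC.
* Purity exactly 0.75 fails (strict rule).

PSI is kept on the percent scale everywhere — in memory, on disk, in every
statistic. All the screen's thresholds (50-point shift, 75% purity as 0.75 on
the fraction scale, 10-point onset detection) are quoted against that one
scale, which removes a whole class of unit bugs that a mixed
fraction/percent representation invites.

## The switch screen

Events missing a QC-passing PSI in any tissue are excluded from every count
(`qc_filter()`). For a complete event, the shift statistic is the distance
from the reference tissue (brain) to its *nearest* comparator:

$$s = \min_{t \neq \text{ref}} \left|\psi_\text{ref} - \psi_t\right|,$$

so a switch call (`s > 50`, strict) means brain differs by more than 50
points from **every** other tissue. The direction is the sign of
$\psi_\text{ref} - \overline{\psi}_\text{others}$. The threshold is an
argument; raising it can only shrink the switch set.

Event-type enrichment among hits uses a 2×2 table (switch / non-switch ×
cassette exon / other) and Fisher's exact test computed in-package by
hypergeometric enumeration: the two-sided p is the sum of point probabilities
not exceeding the observed table's (the point-probability rule, matching
`stats::fisher.test`; one-sided alternatives are available behind a flag
because the sidedness of such screens is often left unstated). The reported
odds ratio is the sample odds ratio $(ad)/(bc)$, undefined when $bc = 0$;
degenerate margins give $p = 1$. Heat-map displays use agglomerative
clustering (Euclidean distance, average linkage, via `stats::hclust`); only
the dendrogram leaf order is part of the tested contract, with ties broken
deterministically by input order.

No multiple-testing correction is applied across events: the screen is a
ranked discovery filter with a fixed effect-size threshold, not a field of
per-event hypothesis tests.

## Conservation across species

An ortholog map links event ids across species (one member per species per
group; paralog fan-outs are out of scope). A group is *evaluable* only if
every required species contributes a QC-complete call, and *conserved* iff
the event is switch-like in every required species **with the same direction
sign** — the same isoform must be the brain-specific one everywhere. We
require direction consistency even though qualitative "band reversal"
readings of confirmation gels do not always state it: a switch of opposite
orientation is a different regulatory outcome, not a conserved one. The
third-species stage applies the same strict 50-point rule as the others
(configurable), rather than a weaker qualitative criterion.

`staged_screen()` chains the stages — discovery-species hits, orthologs
assayed in the validation species, complete there, switch-like versus all its
tissues, confirmed in the third species — and each stage's count is at most
the previous one's.

## Splicing dynamics

For an ordered PSI series over differentiation days (or hours post
fertilisation), the switch statistic is the **net** first-to-last shift, not
the range: switch-like developmental events move in one direction, and a
transient excursion that returns to baseline should not count. The range is
reported alongside for diagnostics, so a caller who prefers a range or
any-pair rule can re-derive it. The pivot interval is the consecutive pair of
time points with the largest absolute PSI change (earliest pair on ties), and
the onset time is the first time the *brain-specific* isoform's PSI strictly
exceeds a detection threshold (default 10 points — gel-band appearance has no
numeric analogue, so this is a package choice). Onset requires the caller to
state the orientation (`brain_isoform = "long"` or `"short"`); guessing it
silently would flip onsets for events whose brain form is the short product.

## What the generator emulates

`sim_config()` defaults encode the study conditions of a three-species
screen; they were fixed once, from the printed design of such a screen, and
are not tuned per run:

| parameter | default | why |
|---|---|---|
| `n_ases` | 1329 | discovery panel size (all simple ASEs of a RefSeq-scale catalogue) |
| `fraction_switch` | 93/809 | switch events as a fraction of robust assays |
| `fraction_conserved` | 0.145 | of switch events, switch-like in all 3 species; 0.145 · (second-stage survivors) reproduces a 15 → 9 confirmation step after attrition |
| `fraction_switch_second` | 0.097 | switch in the validation species but not the third |
| `ortholog_rate` | 89/93 | orthologs assayable in a later species |
| `psi_noise_sd` | 5 points | replicate PSI noise; no published value for this assay class, so a field-typical magnitude chosen once |
| `spurious_peak_rate` | mouse 0.257, human 0.099, fish 0 | see calibration below |
| `spurious_mass_fraction` | 0.30 | one off-target peak carrying 30% of lane mass |
| `event_type_probs` | cassette 0.673, alt5′ 0.131, alt3′ 0.134, complex 0.062 | composition of robust assays |
| `switch_type_probs` | cassette 0.839, … | cassette excess among switch events |
| `timepoints`, `pivot_interval` | 0/2/6/10/14 d, (6, 10) | stem-cell differentiation sampling and pivot window |
| `tc_n_series`, `tc_n_switch` | 89, 13 | time-course panel and planted switch count |

Planted switch events are near-complete isoform reversals (reference tissue
uniform in [85, 100], comparators in [0, 15], or mirrored), matching what
"switch-like" means on a gel; non-switch events keep every comparator within
40 points of the reference — a 10-point guard band below the 50-point
threshold so that zero-noise recovery is exact and unambiguous. Observed PSI
is truth plus Gaussian noise, clamped to [0, 100].

**Contamination calibration.** The generator contaminates a lane with one
off-target peak carrying 30% of the lane *mass* at a size at least
`max(2 nt, 5%)` away from both expected sizes (so it can never be matched).
Because the purity gate works on *molarity*, a 30%-mass contaminant exceeds
25% of lane molarity only ≈59% of the time under the default size
distributions (a large fragment carries little molar amount). The per-species
rates are therefore target per-lane failure ÷ 0.593, with the targets taken
from the study design's completeness: $1-(809/1329)^{1/3}=0.152$ for a
three-tissue discovery stage and $1-(62/89)^{1/6}=0.0585$ for a six-tissue
validation stage, giving 0.257 and 0.099; the third species' confirmation
assays are modelled contamination-free. This also means contaminated lanes
*can* pass QC — exactly those whose planted molar fraction stays below 25% —
and the generator records the planted molar fraction per lane so the gate can
be checked against truth.

**Time courses.** Switch series follow a logistic curve with steepness 2 per
time unit, amplitude drawn from [60, 90] points with a random sign, and
midpoint drawn uniformly in the pivot interval *shrunk by a 12.5% margin at
each end*. The margin makes the pivot identifiable at the sampling
resolution: with a midpoint interior to an inter-sample interval and a steep
curve, the largest consecutive PSI jump provably falls in the interval
containing the midpoint, so zero-noise pivot containment is a property of the
construction, not of luck. Dropout is applied to non-switch series only (at a
rate reproducing a 56/89 completeness), so the planted switch count remains
exact ground truth; dropping switch-series points would silently convert
planted positives into exclusions.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: raw fluorescence traces and peak calling;
amplification bias between short and long products; heteroscedastic or
PSI-dependent measurement error (real PSI noise shrinks near 0 and 100);
correlated failure of lanes within a plate; paralogous cross-amplification;
partial, graded tissue differences (the planted world is bimodal by design);
and biological replicate structure.

## Problem sizes and determinism

One seeded stream per generator call, with stage-specific offsets derived
from the master seed; the seed is recorded in every manifest, and a rerun
with the same configuration is byte-identical on disk. The test suite runs
the generator at 60–500 events and 20 seeds per property (noise-degradation
and conservation-recovery checks average over 20 panels), the exact-test
oracle enumerates every 2×2 table with total ≤ 30, and the quantification
oracle re-derives every lane of a 120-event contaminated panel; the
acceptance script runs the full 1329-event pipeline once plus twenty
500-event recovery panels. These sizes were chosen to exercise every code
path at comfortable interactive latency.

## Known limitations

* The S1-style supplementary reader maps the fixed a–am column layout by
  position; other layouts are rejected rather than guessed.
* The exact test is for 2×2 tables only; the screen does not test
  higher-dimensional event-type associations.
* `staged_screen()` assumes one-to-one orthology; gene-family fan-outs must
  be resolved to a single member upstream.
* The dynamics stage characterises observed series; it does not fit
  parametric trajectories to real (noisy, incomplete) time courses.
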