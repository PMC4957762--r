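---
title: "Methods: single-locus replication profiling on combed DNA fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-locus replication profiling on combed DNA fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, reading rules, estimators and design
choices behind `replicomb`. It is the package's methods reference: every
empirical statement here is computed by the test suite or by
`scripts/acceptance.R`, not asserted from memory.

# The assay and its coordinate frame

Two sequential 30-minute pulses of halogenated nucleotides label nascent
DNA (`P1` = IdU, first pulse; `P2` = CldU, second pulse). Fibers are
stretched at a constant 2 kb/μm and imaged at 0.16125 μm/pixel, so one
pixel is 0.3225 kb; all package-internal computation is in region-relative
kb (0-based, half-open intervals), converting from pixels or μm at load
time. A locus is described by a `locus_map`: a genomic anchor, three
non-overlapping probe intervals whose two gaps D1 and D2 differ by more
than the matching tolerance, a gene interval inside the central probe, and
the repeat position inside the gene. The bundled `fxn_locus()` covers
~834 kb around *FXN*; probe extents are configuration values derived from
BAC end coordinates, not measured quantities, and can be edited in the
YAML config.

## Orientation

A fiber is informative when it shows at least two probe signals.
`orient_molecule()` matches observed signal lengths and inter-signal gaps
to the probe template in both reading directions within a relative
tolerance `tol_frac` (default 0.10, matching combing stretch
variability). Terminal signals may be truncated by the invisible fragment
end, so they are only required not to exceed the template length, and the
anchor is fit by least squares on reliable landmarks — midpoints of
interior signals and the inner edges of the terminal ones. Ties between
the two readings (common for two-probe fibers, where a single gap cannot
distinguish D1 read forward from D2 read backward) are resolved by the
far-red co-label of the central probe; if the flag was not observed the
molecule is rejected, never guessed.

# The forward simulator

`simulate_molecules()` is a generative model of the assay with complete
ground truth, used for estimator validation and power analysis. Its
defaults define the simulated study conditions:

* **Fragments**: normal(450, 150) kb truncated at 50 kb, placed uniformly
  over the region; each molecule uses an independent deterministic RNG
  substream so extending `n_molecules` never reshuffles earlier fibers.
* **Origins**: candidate sites every 60 kb at efficiency 0.4 (mean fired
  spacing 150 kb, in the range reported for lymphoblastoid cells),
  excluding the gene interval. Sites fire in locally synchronized
  replicon clusters: 300-kb blocks (random per-molecule phase) each draw
  one firing time uniform over −60 to +30 min around the first pulse,
  and member origins add Gaussian jitter (SD 8 min). We first implemented
  fully independent firing times; with a 90-minute window and 150-kb
  spacing that model converts nearly every molecule into a fully merged
  chain of silent forks, unlike the patterns the assay scores, and the
  clustered model (consistent with replicon-cluster/factory organization)
  was adopted instead. An origin is suppressed if an earlier fork has
  already replicated its position.
* **Fork kinematics**: a fork-level rate is log-normal (mean 1.4 kb/min,
  CV 0.4) with a small per-arm jitter (CV 0.05). Placing the variance at
  the fork level keeps sister arms nearly synchronous: fully independent
  arm rates at CV 0.4 would make roughly a fifth of all events
  asynchronous under the 2-fold reading threshold — far above the
  observed 1–7% — and would displace P1-midpoint origin estimates by
  several kb.
* **Pauses** are arrest-like: Poisson per kb traveled (8 × 10⁻⁴ /kb) with
  exponential durations (mean 40 min), so their visible signature is a
  missing second-pulse segment (the scored "paused/arrested" pattern)
  rather than a diffuse rate reduction. An optional hotspot adds a pause
  where an arm crosses the repeat.
* **Unidirectional forks** are origins with one arm permanently stalled
  from firing (probability 0.15 per origin) — the minimal generative
  model of a pattern whose biology is unresolved.
* **Dormant origins** (expanded allele only): with probability 0.2 per
  gene-covering molecule, an origin fires uniformly inside the gene.
  Its firing time falls in the ~45 minutes before incoming forks would
  replicate the position passively — rescue-origin timing: a dormant
  origin that fired synchronously with its neighboring cluster would
  usually be suppressed or instantly merged, contradicting the definition
  of the parameter as a realized firing probability.
* **Measurement**: labels shorter than one pixel (0.3225 kb) are
  invisible; probes clipped below 10 kb are lost and others drop out
  independently (probability 0.05); endpoints get Gaussian noise (SD
  1 kb); each fiber is read in a random direction.

What the generator does *not* emulate: spurious/background fluorescence,
fiber breakage at replication structures, optical merging of unrelated
fibers, stretch heterogeneity along a molecule, repeat-length instability,
and genome-scale replication-timing structure beyond the single locus.
Passing recovery tests therefore demonstrate correctness of the analysis
pipeline under idealized measurement physics, not robustness to every
real-world artifact.

# Reading rules (classification)

Tracks are grouped into structures wherever gaps are ≤ `gap_tol_kb`
(default 3 kb ≈ 1.5 μm, a typical within-signal gap). The rules, in
order:

1. **Bidirectional origin** — a P1 with P2 on both sides (origin at the
   P1 midpoint), or two facing P1 ends across an unlabeled center ≤
   `max_pair_gap_kb` = 250 kb (origin at the center midpoint; the silent
   center is pre-pulse synthesis). Facing P1s are only paired when their
   lengths are within `pair_p1_ratio_max` = 2.5-fold — sister arms
   labeled over the same interval have comparable P1 extents.
2. **Paused/arrested** — an origin arm whose distal P2 is missing;
   unilateral or bilateral (one event either way, since both reflect a
   single firing), pause mapped at the truncated P1 end. A single
   `P2–P1` (or `P1–P2`) structure with other replication signals but no
   same-direction support is also read this way (the blue-only
   disambiguation: paused if the rest of the molecule shows active
   replication).
3. **Asynchronous** — sister P2 lengths differing more than
   `async_ratio` = 2-fold (a free threshold; "different rates" is never
   quantified in the field). The call only requires the *shorter* arm to
   be certified complete, since truncation of the longer arm can only
   increase the true ratio.
4. **Unidirectional** — a lone P1+P2 arm whose direction matches another
   structure's direction on the same fiber; its origin position is
   undefined by construction.
5. **Termination** — a P2 shared by two converging forks, or a blue-only
   track bridging two facing P1 ends (a pulse-1 merge). A bridge is the
   fused P1 of the two inner arms, so each bridge half participates in
   facing-P1 pairing with its outer flank: the two flanking origins are
   thereby mapped at their silent-center midpoints. An arm facing a
   bridge that could not be paired is excluded (`termination_flank`)
   rather than mistaken for a unidirectional fork.
6. Everything else is excluded with a reason (`red_only`, `isolated`,
   `not_framed`, ...). Events are kept only when their mapped position
   lies within the span framed by the observed probe signals; arms may
   extend beyond it because a contiguous labeled run is itself evidence
   of an uninterrupted filament.

Degenerate inputs: empty track lists yield empty event tables; unoriented
molecules are a contract violation; tracks below one pixel are rejected
at parse time.

# Estimators

**Fork rate.** Profile statistics follow the field convention: per-arm
rate = P2 length / 30 min over complete bidirectional forks only, with
the event rate the mean of its two arms (both N values — arms and
complete events — are reported, since printed Ns are ambiguous between
the two). An arm is *complete* when its P2 is unshared and its distal tip
ends strictly inside the visible signal extent; a tip that is itself the
outermost signal may have been cut by the invisible fragment end. This
convention is right-censored in disguise: fast forks preferentially merge
or run off the fragment, so the complete-arm mean underestimates the
population mean. `fork_rate_estimate()` therefore also reports (i) a
Kaplan–Meier mean treating uncertified tips as right-censored, and (ii) a
censored log-normal MLE over P1-based arm rates of paired origins — for
an origin that fired before pulse 1 an intact P1 arm spans exactly
rate × 30 min regardless of the fork's later fate, and bridge halves,
paused arms and pulse-1 anomalies enter as right-censored lower bounds.
The MLE is the preferred estimator of the population mean; censoring
depends on where a fork sits on the fragment, not on how fast it moves.

**Inter-origin distances** use all origin-generating events (each paused
or asynchronous event also reflects one firing). An interval containing a
structure whose origin could not be placed (unidirectional or excluded)
is not measured — an unmapped origin could hide there and the distance
would span more than one replicon. The corresponding ground-truth
estimand is the IOD distribution over origins *active during the labeling
window* (those leaving any labeled segment): an origin whose forks fully
merged before the first pulse is invisible to any labeling assay and
belongs to no meaningful recovery target.

**Dormant-origin frequency** is the fraction of replicating molecules
whose observed span covers the whole gene interval and that carry an
origin-generating event inside the gene; the exact binomial CI of the
estimate is compared with the simulated probability. The all-replicating
denominator variant is also reported by `truth_summary()`.

**Kind agreement** (`match_events_to_truth()`) is evaluated over
ground-truth origins that are *interior* (no arm cut by a merge or the
fragment end) and *pattern-decidable* under the reading rules, with
per-kind decidability computed from kinematics alone: for instance, a
contiguous blue track over an origin cannot reveal which sister paused,
facing P1 stubs of grossly unequal length cannot be paired, and a lone
arm with no same-direction, well-separated support cannot be called
unidirectional by any reader. The matching radius is 15 kb — small
against the 150-kb origin spacing, wide enough to absorb midpoint shifts
from sister-arm asymmetry. The strict ±2 kb origin-position property is
verified separately in the synchronous-kinematics regime (no arm jitter,
no pauses), which is the regime where midpoint mapping is exact.

# Timing and SNS statistics

Timing tables use the binomial (Wald) SE, `100·√(p(1−p)/n)`, which
reproduces the published percentage cells (the shipped count fixture is
verified cell-by-cell in the tests; five SE cells differ by exactly 0.01,
i.e. one unit in the last printed digit). Percentages are suppressed when
a substage column holds ≤ 10 cells. Chi-square comparisons are Pearson
without continuity correction on pattern × sample counts, reported under
both category options ({SS, SD, DD, OTHER} and without OTHER) because the
published bounds do not state which was used; the mid-S-phase comparison
pools the S1 and S2 sorted fractions, the reading under which both
options clear the stated p < 0.001 bound. The nucleus simulator draws two
independent alleles per nucleus with a per-fraction completion
probability, a detection-failure branch (→ OTHER) and a per-fraction
substage row modeling sorting contamination.

SNS quantification fits `Ct = slope·log10(copies) + intercept` per primer
set over triplicate 6-point 1:3 dilution series from 4.5 × 10⁴ genomic
equivalents (efficiency `100·(10^(−1/slope) − 1)`; non-negative slopes
are an assay failure). Scheme A divides by the mean of the chromosome-9
control sites (the normalized control values average exactly 1 by
construction); scheme B divides by the non-origin site and then by the
mean LAMIN B2 origin enrichment fold, so 1.0 marks origin-level
enrichment; folds outside the plausible 5–119 quality-control range raise
a warning. Scheme B is invariant under rescaling all quantities of a
sample. Ct noise in the plate simulator is additive normal (SD 0.25
cycles by default); the unidirectional-length CV uses the population SD.

# Problem sizes and determinism

The tests and the acceptance script simulate 200–300 molecules per
condition (the scale of the per-line fiber counts in this kind of study),
which keeps the whole suite under a minute while leaving ≥ 40 measured
IODs and ≥ 20 decidable events for the recovery checks. All randomness
flows from explicit integer seeds; per-molecule substreams are derived
arithmetically from the root seed.

# Known limitations

* Pattern ambiguities are intrinsic, not implementation artifacts: a
  silent gap between diverging arms reads as one origin even when it is
  two origins whose inner forks merged before labeling; a contiguous
  `P2–P1` arm cannot be distinguished from a unilaterally paused origin
  without context. The decidability protocol makes these limits explicit
  rather than hiding them in error rates.
* The complete-fork rate convention is biased low under heavy merging;
  use the censored estimators for population-level statements.
* Dormant-origin detection degrades when the dormant origin fires close
  in space and time to a flanking cluster; the binomial CI check absorbs
  this at the simulated study size, but per-seed estimates fluctuate.
* The published per-fiber fork-rate, IOD and unidirectional-length
  means/medians from the original image data are not reproduction
  targets; the package replaces them with simulation-recovery properties
  and the qualitative expanded-allele contrast (shorter, more dispersed
  unidirectional forks).
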