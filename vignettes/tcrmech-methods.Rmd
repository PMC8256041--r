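---
title: "Models and methods behind tcrmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrmech)
```

`tcrmech` quantifies two biophysical signatures of TCR mechanosensing: the
occupancy of interdomain contacts in molecular-dynamics trajectories of TCR
ectodomains, and the force dependence of single TCR–ligand bond lifetimes
measured in an optical trap. This vignette documents the models, the
tunable parameters, the synthetic-data generators used for validation, and
the numerical choices made where the design was genuinely open.

## Contact detection and windowed occupancy

A **hydrogen bond** is declared between a donor hydrogen (a hydrogen
covalently attached to N, O or S) and an acceptor (N, O or S) when their
Euclidean distance is strictly below `hbond_cutoff` (default **2.4 Å**).
The criterion is distance-only; an optional donor–H···acceptor angle gate
exists (`hbond_angle_min`) but is off by default, since a hydrogen found
that close to an acceptor in an MD frame is almost always oriented
favourably, and the distance-only rule keeps the statistic simple and
reproducible. A **nonpolar contact** is declared between two residues on
opposite sides of an interface when at least one atom pair — both atoms
with |partial charge| strictly below `charge_threshold` (default
**0.3 e**) — lies within `nonpolar_cutoff` (default **3.0 Å**).

Contact granularity differs on purpose: hydrogen bonds are counted per
(donor-H, acceptor) atom pair, nonpolar contacts per residue pair. Nonpolar
cutoff criteria are met by many atom pairs simultaneously wherever two side
chains pack, so atom-pair counting would inflate nonpolar counts severalfold
relative to hydrogen bonds and make the per-interface bar charts
uninterpretable; residue-pair aggregation keeps both statistics in
comparable units of "one interaction". A `np_granularity = "atom"` switch
restores atom-pair counting.

**Occupancy** is the fraction of frames within a time window in which a
contact satisfies its criterion. Windows deliberately overlap by 50%: a
contact whose presence straddles a window boundary would otherwise appear
at half its true occupancy in both windows. Two constructions are provided.
Given a window *count* n over \[t0, t1\], the width is 2(t1−t0)/(n+1) and
the step is half the width, so the windows tile the interval exactly — for
the default 100–300 ns interval and n = 10 this yields 36.36-ns windows
starting every 18.18 ns (100.0–136.4, 118.2–154.5, …, ending exactly at
300 ns). Given a *width* instead, windows advance by width × (1 − overlap)
while their start lies below t1 − step, and the final window is clamped to
end at t1.

An interface is summarised by the number of contacts per window with
occupancy **strictly greater** than `occupancy_threshold` (default 0.8),
split by kind, with the mean and SD over windows. The SD is the population
SD (divide by n) by default — the windows are a fixed decomposition of one
trajectory, not a sample from a population; a `sd_type = "sample"` switch
exists. A contact present in every frame produces identical counts in all
windows and hence an SD of exactly zero. Construct comparisons use a
two-sided Welch two-sample t-test on the per-window counts. Overlapping
windows are not independent, so the nominal p-value is optimistic; this is
noted rather than corrected, because the windowed counts are descriptive
statistics of one trajectory and any correction would impose an arbitrary
effective sample size.

## Buried surface area

Solvent-accessible surface area uses the Shrake–Rupley construction: each
atom's solvent-expanded sphere (van der Waals radius + probe radius,
default probe 1.4 Å) is sampled with a deterministic golden-spiral point
set (default 960 points — relative discretisation error well below 1% for
protein-sized atoms, and doubling the count changes totals by <1%), and
points falling inside any neighbouring expanded sphere are discounted.
Radii are the Bondi element set, with no force-field dependency; unknown
elements are an error rather than a silent default. The buried area
between groups A and B is SASA(A) + SASA(B) − SASA(A∪B), each term
computed with only its own group as context. Both the total and the
half ("per side") convention are reported explicitly, because published
buried-surface figures use either convention and a silent factor of two is
the classic error in this calculation.

## Trace segmentation and event detection

A force-clamp trace has three phases: a loading ramp (the piezo stage moves
at constant velocity, so force rises linearly), a dwell at the clamp force,
and rupture — the bead snapping back to the trap center (separation 0 nm).
Conformational transitions during the dwell appear as smaller steps toward
the trap center.

Steps are found on a running-median-smoothed trace (window
`smooth_window`, default 9 samples; 21 for single-molecule-on-cell traces,
which relax more slowly) as locations where the offset difference of
smoothed levels drops by at least `min_step` (default 3 nm), refined to the
steepest single-sample drop in the raw signal. A step whose post-step
median lies within `baseline_tol` (default 3 nm) of zero *and* whose
pre-step level was genuinely elevated is the rupture; steps whose post-step
level stays above baseline are transitions, with the distance reported as
the difference of pre/post running medians over `level_window` (default
50) samples. Candidates within the smoothing support of the dwell edges
are discarded: they are the loading kink or the rupture's own partial
drop, not resolvable transitions. Detections closer together than one
level window are merged, keeping the largest.

The clamp onset is estimated by intersecting the fitted loading-ramp line
with the measured plateau level. The plateau median is refined iteratively,
excluding samples before the current onset estimate: a single-pass estimate
includes late-ramp samples and systematically deflates the plateau, which
biased lifetimes upward by tens of milliseconds in development testing.
With the iteration, segmentation is exact on noise-free traces and
unbiased (sub-millisecond mean error) at 2 nm bead noise.

The bond **lifetime** runs from clamp onset to rupture — the total dwell,
including any post-transition dwell, which is recorded separately per
transition. Whether the physical clock should restart at a conformational
transition is an open interpretive question; total dwell is the
convention here because it is what a force–lifetime plot of tether
survival measures. Censored traces (no rupture observed) are flagged and
excluded from lifetime means by default; the model fit can use their
survival contribution.

## The dual-pathway bond model

Lifetimes are modelled as exponential with force-dependent rate

k(F) = k_c · e^(−F·x_c/k_BT) + k_s · e^(+F·x_s/k_BT),

the minimal two-pathway form in which load suppresses dissociation through
a catch pathway (k_c, x_c) and accelerates it through a slip pathway
(k_s, x_s). It has a closed-form lifetime peak at
F\* = k_BT·ln(k_c·x_c/(k_s·x_s))/(x_c + x_s), which makes parameter-recovery
testing exact. k_BT defaults to 4.114 pN·nm (298 K).

Fitting is by maximum likelihood in log-parameters. Because the
log-likelihood is concave in (k_c, k_s) for fixed distances, optimisation
first profiles a coarse grid over (x_c, x_s) with an inner two-parameter
search, then refines all four parameters by Nelder–Mead; this reliably
finds the global optimum where naive multistart stalls in local basins. A
bond is classified **catch** when (i) the fitted curve has an interior
lifetime maximum within the sampled force range, (ii) the peak lifetime
exceeds the lifetime at the lowest sampled force by ≥ 1.5×, and (iii) a
likelihood-ratio test against the nested slip-only model (2 fewer
parameters, χ² with 2 df) is significant at α = 0.05. The boundary
position of k_c = 0 makes the χ² reference conservative, which only lowers
the false-catch rate. Non-convergence falls back to the slip-only fit with
a flag.

A caveat on identifiability: the zero-force amplitudes k_c and k_s are
exponential extrapolations from the sampled force range, so their sampling
error is intrinsically large — for a design with 200 events per 2.5-pN bin
over 5–25 pN and a catch bond peaking at 15 pN, the Cramér–Rao bound on
σ(log k_s) is ≈ 0.29, i.e. ~20% typical error for *any* unbiased
estimator. The barrier distances, the peak force and the fitted lifetime
curve over the sampled range are far better determined (≈ 4–7%), and those
are the quantities a practitioner should interpret.

Force–lifetime curves bin events by clamp force (default 2.5-pN bins from
5 to 30 pN — narrow enough to resolve a 15-pN peak, wide enough for tens
of events per bin at realistic yields) and report mean, SEM = SD/√n, and
n; empty bins are kept so curves built on shared edges stay aligned. The
**sensitivity index** is the per-bin ratio of specific to nonspecific mean
lifetime with first-order error propagation; bins empty on either side, or
with a zero nonspecific mean, are omitted with a warning.

## Synthetic-data generators

The generators define the study conditions under which the package is
validated.

**Trajectories.** Planted contacts switch ON/OFF per frame — iid Bernoulli
at the target occupancy by default, or a two-state Markov chain with
stationary occupancy and a configurable correlation time, since real MD
contacts are autocorrelated and the occupancy estimator should be stressed
under both. ON places the pair at its detection cutoff − 0.3 Å, OFF at
cutoff + 1.0 Å; all other atoms get 0.1 Å Gaussian jitter. Frames default
to 20-ps spacing.

**Traces.** The stage loads at `load_rate` (default 20 pN/s) to the clamp
force, the dwell is drawn from the dual-pathway kinetics, an optional
competing-exponential transition steps the bead `transition_distance`
(default 8 nm) toward the trap center and rescales the subsequent rate
(evaluated at the reduced post-transition force), and rupture returns the
separation to zero. White Gaussian bead noise (default SD 2 nm) is added
per sample. Trap stiffness defaults to 0.25 pN/nm and sampling to 1 kHz —
typical for a single-beam gradient trap on a micron-scale bead. Noise is
white rather than Ornstein–Uhlenbeck because the trap corner frequency is
not a modelled quantity here; detection thresholds are therefore validated
against a slightly pessimistic noise spectrum. The dwell is censored at
`max_dwell` (120 s).

Two demo parameterisations anchor the tests: **"wt"** (slip-only, k_s = 2
s⁻¹, x_s = 0.5 nm; lifetime 0.148 s at 10 pN) and **"chimera"** (dual
pathway with x_c = 1.5 nm, x_s = 0.8 nm and amplitudes solved analytically
so the true curve peaks at exactly 5 s at 15 pN). All generators are
bit-reproducible from their seed, via an isolated RNG scope that does not
disturb the caller's stream.

What the generators deliberately do *not* emulate: tether elasticity
(worm-like-chain compliance of the DNA linker), trap anharmonicity,
instrument drift, cell-surface viscoelasticity in the on-cell assay, and
correlated MD dynamics beyond the two-state contact model. Passing tests
therefore demonstrate correctness of the estimators under the stated
models, not robustness to every artefact of real hardware; the
`detect_params()` thresholds are the knobs to retune on real data.

## Problem sizes in the test suite

The suite validates detection against a brute-force all-pairs oracle on
100 seeded fixtures of up to 100 atoms; occupancy recovery on 1,820-frame
windows at planted occupancies 0.1–0.95; segmentation on 120–200 noisy
traces per scenario; classifier error rates on 100 seeded slip-only
replicates (25 events per force); and full trace-pipeline parameter
recovery at 200 traces per force over 5–20 pN. These sizes give each
statistical assertion a comfortable margin over its Monte-Carlo noise
while keeping a full run to a few minutes.

## Known limitations

- The hydrogen-bond criterion is geometric only; no energetic or angular
  validation is attempted by default.
- Transition distances are bead-position step magnitudes; converting to
  molecular extension would require the series compliance of the linkage,
  which is not modelled (a correction hook exists in the event records).
- The Welch comparison treats overlapping windows as independent samples;
  its p-values are descriptive, not strictly calibrated.
- Censoring is handled by exclusion (default) or survival terms in the
  fit; no Kaplan–Meier curve estimator is exposed for the binned means.
- Zero-force amplitudes of the bond model carry large sampling error by
  the nature of exponential extrapolation (see above); interpret the peak
  and the curve, not k_c/k_s in isolation.
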