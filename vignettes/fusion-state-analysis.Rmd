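---
title: "Morphometric classification and kinetics of synaptic vesicle fusion intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric classification and kinetics of synaptic vesicle fusion intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfusion)
```

## The analysis problem

Timed in situ cryo-electron tomography can freeze synapses a few
milliseconds after an action potential, so that single tomograms contain
synaptic vesicle (SV) fusion events arrested mid-course. On 2D cross
sections through the active zone (AZ), membrane rearrangements fall into
seven morphometric categories: AZ invagination below a tethered round SV
(state 1), stalk formation by a droplet-shaped SV (2), closed fusion pore
(3), open fusion pore (4), dilating pore (5), collapsing pore (6), and
residual membrane bumps (7). `svfusion` implements the full quantitative
pipeline around this scheme: a seeded generator of synthetic profile
images with the measured state geometries, the morphometric measurements,
the rule-based state classifier, population census statistics with exact
contingency-table tests, a continuous-time Markov chain (CTMC) fitted to
the per-state event counts, and a reduced-fidelity coarse-grained
Brownian-dynamics (BD) simulator of SV recruitment.

Everything is exercised on synthetic data; no tomograms are downloaded.
What passing tests demonstrate is therefore internal consistency — that
each stage recovers what the generator put in under the stated
conditions — not performance on real tomograms, which are noisier,
carry reconstruction artifacts (missing wedge, CTF) and require manual
membrane tracing.

## Synthetic membrane profiles

`profile_spec()`/`render_profile()` draw each bilayer as two Gaussian
ridges at the leaflet density peaks, separated by 3.5 nm, on a 200 x 200
grid at the 12.28 Å pixel of 4x-binned tomograms. Two conventions matter:

* **Membranes are intensity-HIGH.** The line-scan gap statistic reads the
  cytosolic gap between two membranes as an intensity *minimum*; real
  data recorded membrane-dark must be inverted on ingestion
  (`read_profile(..., invert = TRUE)`).
* **Boundary annotations are required inputs.** The generator returns its
  leaflet-peak polylines as ground truth; for real slices they would be
  manual traces. Automatic membrane segmentation is out of scope.

The leaflet ridge width is derived from the apparent bilayer thickness
(default 5.4 nm, giving a ridge sigma of about 0.8 nm). This value is a
deliberate compromise: much sharper ridges leave the intensity between
the two leaflets so dark that a membrane interior becomes
indistinguishable from a true inter-membrane gap under the mean-minus-SD
run rule, while much blurrier ridges fill the 4 nm stalk gap with glow.
The thickened top membrane of collapsing pores and bumps is rendered as
one merged broad ridge whose width is calibrated numerically so that the
*measured* thickness ratio (full width at half maximum against the AZ
bilayer) equals the requested factor of 1.5 — matching the compacted
appearance of these membranes in tomograms.

State geometries default to the measured means: state-1 SV-AZ distance
6.4 nm with a 2.6 nm invagination; stalk gap 4 nm; dilating pores
48.4 nm tall by 37.4 nm wide; collapsing pores 29.6 by 50.4 nm with the
1.5x thickened top; bumps 7.7 nm tall. Open-pore widths default to 8 nm.
`make_fixture_set()` draws per-profile geometry from truncated normals
around these means. The emulated state geometries are summarised by
means and standard errors, not full distributions, so the spread is our
choice: the SD of each drawn field equals the per-state SEM, truncated
at 2 SD. This keeps every draw on the correct side of every classifier
threshold, which is what makes a 100% noise-free recovery the correct
expectation rather than an accident.

## Morphometric measurements

`measure_event()` computes the geometric quantities between leaflet-peak
traces (a: widest extent; b: height above the interpolated AZ baseline;
c: SV-AZ gap; d: invagination height; e1/e2: circle-fit deviations at
the SV top/bottom; g: closed-neck height; i: open-pore width) and the
intensity-based quantities from the rendered image (f and h: gap ratios
of the axial and neck line scans; k1/k2: membrane thickness at the event
top versus the AZ).

The gap statistic: compute the scan mean and SD, find contiguous runs at least 1 nm long below mean - SD,
average 1 nm around the deepest minimum and around the highest flanking
maxima, and call a gap when min/max < 0.6 (strict); no detectable run
means ratio 1. Two practical notes:

* Run and window lengths are defined in physical nm and converted by
  the actual pixel size, so the statistic is portable across export
  scales (a fixed pixel count would not be).
* The mean-minus-SD rule assumes the scan is membrane-dominated. When
  more than about half the scan is background (very wide open pores,
  roughly 13 nm lumen and beyond), mean - SD drops below the background
  level, no run is found, and the statistic saturates at 1 — the same
  saturation the ratio-1 convention assigns to an undetectable minimum.
  The fixture generator draws pore widths 5-11 nm, inside the valid
  regime; this limit is a property of the method, not of the renderer.

The neck scan (h) is only defined where a neck exists, i.e. where the
outer-border separation drops clearly below the widest extent of the
event. Dilating/collapsing pores and bumps have straight or inward walls
with no width minimum, so h is undefined for them and they can never
satisfy the closed-pore criterion. Outward curvature at the neck (state
4 vs 5) is detected from the signed turning of the 3 nm-smoothed outer
polyline inside the neck band: a flared neck wrapping into a wider head
shows turns of both signs; straight or inward walls do not.

The least-squares circle fit minimises squared radial residuals
(Gauss-Newton refinement of the algebraic estimate). The droplet ratio
e2/e1 uses a 0.25 nm floor on e1 so perfect spheres have a defined,
non-droplet ratio.

## The classifier

`classify_event()` is a total, deterministic cascade at the standard
thresholds (all strict where the wording is strict): exclusion flags
first; detached SVs (gap c defined) are stalks when the droplet ratio
exceeds 1.3, state 1 when round with an invagination of at least 1.2 nm
(about one binned pixel; the floor itself is our choice) within the 4-8 nm distance band, and tethered SVs
otherwise. Membrane-continuous protrusions are closed pores when *both*
continuity scans show no gap (f >= 0.6 and h >= 0.6); otherwise outward
curvature gives open pores; otherwise an unthickened top gives dilating
pores; thickened events are collapsing pores above 10 nm height and
bumps at or below it. The one point where we had to interpret: a single
guard "f >= 0.6" cannot route open-pore states, because an axial scan
through an open lumen always reports a gap; the closed-pore state is the
only one that requires membrane continuity, so it is the only state that
consults f.

For multi-event synapses the overall state is the event closest to state
4, ties broken toward the higher (more advanced) state — the tie
direction is our convention and is configurable. Synapses count as
"ongoing fusion" with at least one event in states 2-6 (state 1 counts
as preceding fusion, bumps as post-fusion), and as multivesicular
release with at least two events in 2-6.

## Census statistics

Distance pools are half-open with the upper edge included (a 6.0 nm SV
is membrane-proximal). Fisher tests are exact: 2x2 by hypergeometric
enumeration with the point-probability two-sided rule; r x c by complete
enumeration of all margin-fixed tables when there are at most 1e6 of
them, otherwise by seeded Monte Carlo over `r2dtable` draws.
Benjamini-Hochberg correction delegates to `p.adjust`. The
non-releasing-synapse fraction implements the natural two-component
mixture decomposition f = (muN - muF)/(muT - muF) on mean proximal SV
counts. Which synapse groups enter each mean is a modelling choice left
to the caller; the helper implements only the decomposition itself.

## The Markov state model

The chain runs 1 -> 2 -> 3 -> 4 -> 5 -> 6 -> F (full fusion, absorbing)
with a reversible first transition; tight-docking variants insert a
docked state D before or after stalk formation. Observed per-state event
counts are modelled as one multinomial snapshot of the chain at the
freezing time T = 2 ms *conditioned on not yet being absorbed*:
category probabilities p_i(T) / sum_j p_j(T) over the transient states.
This likelihood is the package's own explicit modelling choice; the
observation time is configurable, and a time-averaged-window variant
would be the natural alternative.

Two identifiability facts shape the fitting defaults:

* The exit rate of the last transient state (6 -> F) only drains
  probability and rescales the conditioning; the likelihood is flat in
  it. It is pinned, by default, to the mean of the fitted forward rates
  (a neutral data-driven convention applied in a second pass); any fixed
  value can be supplied instead.
* Even then the free rates outnumber the multinomial degrees of freedom,
  so the maximum-likelihood set is a ridge. A weak parsimony penalty
  (1e-3 times the sum of rates) resolves it deterministically in favour
  of the slowest kinetics consistent with the counts. Without such a
  resolution, dwell times and waiting times would be optimizer
  artifacts.

Under these conventions the fitted baseline on the observed counts
(10, 22, 6, 7, 8, 12) gives its longest mean dwell among states 2-6 in
state 2 (stalk formation as the kinetic bottleneck), and both docking
variants, fed a docked-state count of 1, give mean 1 -> F waiting times
beyond the 2 ms observation window — the package's quantitative
restatement of the finding that tight docking is an unlikely
intermediate. These are qualitative conclusions of a convention-resolved
fit, not measured rate constants.

## The docking simulator

`cgdock` is deliberately reduced-fidelity. Membranes are triangulated
two-particle-per-thickness meshes (icosphere SV above a periodic patch);
bending is the dihedral potential lambda (1 - cos(theta - theta0)) with
lambda = 2 sqrt(3) kappa, which reproduces the Helfrich sphere energy
8 pi kappa in the continuum limit for near-equilateral triangulations
(+3.5% on icospheres; verified against the closed form in the tests). A
stiff harmonic volume term conserves the SV volume to well under 1%.
Tethers are fixed-length rods whose activation adds a torque-like
potential (linear in the cosine of the tether's elevation) that pulls
the SV toward the AZ; SNAREs are 4-bead chains with register-matched
short-range attraction; curvature-inducing proteins are membrane-tagged
particles whose Metropolis-sampled masks impose a preferred signed
curvature of 1/(25 nm), toward the SV, on the surrounding dihedrals once
the SV-AZ gap falls below 6 nm. Kappa = 0.8e-19 J, viscosity 2.21 cP,
temperature 310 K, SV 42.5 nm, patch 180 nm and the 6 nm trigger are the
measured experimental constants of the system; interaction stiffnesses, SNARE bead geometry, the
tether torque scale (1500 pN nm, chosen so recruitment completes at desk
scale) and the protein excluded-volume shape (two-bead uprights, 3 nm
tall when inactive) are ours and marked as such.

Three numerical choices deserve emphasis:

* **Timestep.** The nominal 0.1 ns step presumes an implicit,
  hydrodynamically coupled membrane integrator. The simplified
  explicit Euler-Maruyama scheme used here is only stable while
  mobility x stiffness x dt < 1; the discrete bending stiffness at 2 nm
  mesh and kappa = 0.8e-19 J is 2-3 nN/nm, so the reduced preset
  integrates at 0.01 ns. Transient hard-contact force spikes are capped
  at half a nanometre of deterministic displacement per step; persistent
  capping or any single step beyond 1 nm aborts with an instability
  diagnostic.
* **Noise.** Thermal noise is counter-based: each (step, particle, axis)
  deviate is a hash of the run seed. Runs are reproducible through
  `set.seed`, and — because appended particles do not shift anyone
  else's stream — simulation arms that differ only in protein copy
  number share identical noise on all common particles. Copy-number
  comparisons are therefore paired (common random numbers), which is
  what makes a five-seed median comparison meaningful at desk scale.
* **Reduced preset.** 20 nm SV over a 60 nm patch, 0.1 us relaxation
  plus 1 us production at 0.01 ns steps (about a 110k-step budget),
  sampled every 10 ns. The full preset (42.5/180 nm, 5 + 100 us) is
  configured but is cluster-scale and never run by the tests.

Inactive curvature proteins sit low on the membrane (below the trigger
gap), so before activation they act only as weak crowders; with many
copies the crowd and the curvature it later induces impede the final
approach, and recruitment with 30 copies is never faster than with 0 —
the qualitative copy-number ordering, reproduced as a paired-median
comparison over five seeds.

## Problem sizes used by the tests

The test suite renders the 86-profile fixture set twice (noise-free and
at 10% contrast noise), checks the low-level statistics against
independent oracles (direct arithmetic on 1000 random scans; grid-search
circle fits; exhaustive 2x2 enumeration for all tables with totals up to
40; O(n^2) neighbor scans; 1e5-path Gillespie ensembles), fits the CTMC
to 2000 simulated events for parameter recovery, and runs ten reduced
docking simulations (five seeds per protein copy number). These sizes
were chosen so the whole suite completes comfortably on one CPU while
every statistical comparison retains 3-sigma resolution.

## Known limitations

* The generator emulates clean, annotated, centre-slice profiles;
  missing-wedge anisotropy, CTF effects, membrane-adjacent densities and
  tracing errors of real tomograms are all absent.
* The gap statistic saturates for very wide open pores (see above), and
  the classifier inherits that limit.
* The snapshot likelihood ignores the spread of freezing times (2-5 ms
  after light onset); T is treated as fixed at 2 ms and configurable.
* The BD model omits hydrodynamic coupling, membrane area exchange
  (no barostat), electrostatics, and fusion itself — the simulation ends
  at docking; fusion is out of its scope by design.
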