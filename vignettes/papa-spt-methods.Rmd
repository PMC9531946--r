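---
title: "Models and methods behind papaspt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind papaspt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papaspt)
library(dplyr)
```

`papaspt` simulates and analyzes proximity-assisted photoactivation
single-particle tracking (PAPA-SPT). This vignette is the package's own
account of its models: what is assumed, which knobs matter, what the
synthetic data do and do not emulate, and where design choices were
genuinely open.

## Photophysics: bright, dark, bleached

Each receiver fluorophore is a three-state Markov chain — BRIGHT, DARK
(reversible, "shelved"), BLEACHED (absorbing) — advanced frame by frame.
All light-driven kinetics are first order in the delivered dose: a rate
constant `k` (per ms) and a per-frame dose `d` (ms) give a transition
probability `1 − exp(−k·d)`. Doses are short (≤ 7 ms within a 7.48 ms
frame), so this discrete-frame approximation is accurate; exactness is not
claimed. At most one transition occurs per molecule per frame, and a
transition driven by the doses of frame `f` takes effect at frame `f + 1`
— a molecule reactivated by a pulse at frame `p` is first countable at
`p + 1`, which is also why post-pulse analysis windows start at `p + 1`
and exclude the pulse frame itself (the pulse frame may carry different
illumination, so counting begins conservatively at the next frame).

Key structure:

- Only a fraction of receivers (`shelvable_fraction`, default **0.10**)
  can enter the dark state at all; the rest photobleach directly. This
  housing of the experimental observation that roughly a tenth of
  receivers are recoverable keeps the recoverable pool and the bleached
  background separate.
- Red light shelves (`k_shelve_red`) and bleaches (`k_bleach_red`) bright
  molecules in competition. Defaults 0.015 and 8e-4 per ms make the
  dark-vs-bleach branching ratio 95% for shelvable molecules, so the
  recoverable dark pool is close to the shelvable fraction, and make the
  weak 1 ms measurement pulses of the kinetics protocol only mildly
  perturbing (~1.5% loss per frame) while a 400-frame, 7 ms-per-frame
  shelving phase is saturating. A single intensity scale underlies the
  dose model: rates are per ms of light regardless of which phase delivers
  it. Real experiments vary laser power between phases; that refinement is
  deliberately out of scope.
- Violet reactivates dark receivers at `k_dr_violet` (default 0.5/ms: a
  7 ms pulse reactivates 97% — saturating, as in saturating-violet
  controls). Green reactivates at `k_papa_green` (0.3/ms) only while the
  molecule's sender is attached and unbleached, and at the residual
  `k_papa_bg_green` (0.002/ms) otherwise. The physical mechanism of PAPA
  is deliberately not modeled — only an effective per-ms rate.
- Dark molecules spontaneously reactivate at `p_spont_per_frame`
  (1e-4/frame), and senders bleach under green light
  (`k_sender_bleach_green`, 0.01/ms).
- Dark-to-bleached conversion is off by default (`k_dark_bleach_red = 0`):
  both reactivation routes recover the *same* dark state, which is what
  produces mutual occlusion — a saturating violet train empties the pool a
  subsequent green pulse would draw on.

State histories are stored as an event log (initial state plus
transitions), not a dense molecule × frame matrix; `state_matrix()`
materializes the dense view for small problems and `bright_intervals()`
gives the run-length view the trajectory simulator consumes.

## Motion and localization

Molecules are bound (`d_bound`, default 0.01 µm²/s) or free (`d_free`,
8.3 µm²/s), assigned statically per molecule with probability `f_bound`
(optional bound↔free switching with stationary occupancy `f_bound` is
available via `k_switch`; the displacement variance within an interval
then uses the state at the interval start — adequate when switching is
slow relative to the frame time). Per-axis displacements over `g` frames
are Normal(0, 2·D·Δt·g); motion continues through dark periods. The square
field of view reflects at its edges, implemented exactly by folding the
free path (reflected Brownian motion is the triangle-wave image of free
Brownian motion). Observed positions add Normal(0, σ²) per axis with
σ = 0.035 µm.

Localizations are emitted on frames where the molecule is bright *and*
the frame carries red excitation (`emit_on_red = TRUE`): the receiver
emits only under red light, so violet-only stimulation frames yield no
localizations. Consecutive localized frames form one trajectory; any
larger gap starts a new one unless `max_gap > 0`.

The camera model and tracking stage exist to close the loop on synthetic
movies (integrated-Gaussian PSF, Poisson noise, DoG detection with
sub-pixel Gaussian fits, greedy distance-sorted linking). Densities are
sparse by design; the tracker makes no claim of parity with any specific
published tracker, only of functional equivalence on such data. Linking
ties are broken by detection coordinates rather than input row order, so
results are invariant to within-frame permutations. Defaults: pixel
0.16 µm, PSF σ = 1 px, `max_disp_um = 1.5` (beyond 4 SD of a
D = 8.3 µm²/s jump at 7.48 ms), `max_gap = 0`. The instrument-level
values (pixel size, localization precision, photon counts) are typical
for the live-cell HILO instrument class and are configuration-exposed.

## Classification into PAPA and DR

`post_pulse_windows()` returns half-open ranges `[p + 1, p + 1 + w)` per
pulse, default `w = 30` frames; a window that would contain another
reactivation pulse is an error rather than a silent overlap.
`split_trajectories()` keeps, for each trajectory, the localizations
inside each window — a trajectory straddling a window boundary is clipped
to its in-window portion, and one long-lived molecule may contribute
segments to several windows (each gets a fresh segment id referencing its
source pulse). Whether the original analyses re-split trajectories at
window boundaries or required them to start inside the window is not
documented anywhere we could rely on; clipping is this package's choice
and is stated openly. Segments with fewer than two localizations carry no
displacement information and are discarded with a logged count.
`balance_classes()` subsamples the larger class uniformly without
replacement so PAPA and DR spectra are compared at equal trajectory
numbers.

## Diffusion spectra

For a trajectory in state `D`, each consecutive-frame squared 2-D
displacement is exponential with mean `b = 4(D·Δt + σ²)`; jumps within a
trajectory are treated as independent given the state (the standard
state-array approximation), and gap-spanning displacements are excluded.
`infer_spectrum()` fits a mixture over a fixed ascending grid (default
100 log-spaced states, 0.01–100 µm²/s) by expectation–maximization over
per-trajectory responsibilities, starting uniform, with a symmetric
Dirichlet(`prior_alpha`) prior (default 1 = flat, i.e. maximum
likelihood; `max_iter = 1000`, `tol = 1e-6` on occupations). The
log-posterior is non-decreasing by construction and is recorded per
iteration; tests assert it. `fit_reduced()` runs the same EM on a small
fixed state set such as {0.01, 8.3} µm²/s.

σ is a fixed, known input — not estimated. States slower than about
σ²/Δt ≈ 0.16 µm²/s are therefore unresolvable from one another: truly
immobile molecules and slowly diffusing ones alike pile up at the grid
floor (0.01 µm²/s), which is why the floor state is read as "bound".
`fraction_bound()` sums occupations strictly below 0.15 µm²/s.
No defocalization correction is applied (the simulated world is a single
2-D plane) and no motion-blur correction (stroboscopic red pulses);
passing tests on synthetic data therefore say nothing about how real
out-of-focus loss would reshape spectra.

This estimator is a MAP-EM point estimate, not a posterior sampler; no
numerical parity with any external state-array implementation is claimed.

## Unmixing and fold enrichment

`fit_mixture()` solves `min ‖t − (f·A + (1−f)·B)‖₂` over the simplex in
closed form. One numerical subtlety: because the jump likelihood is
nearly flat across neighboring slow grid states, the EM's allocation of
mass *within* the slow region is weakly determined, and raw per-state
occupations of two estimated spectra can differ in shape even when the
underlying populations match. The default therefore compares cumulative
occupations, which integrate out that degeneracy; `on = "occupation"`
fits the raw vectors. With cumulative fitting, simulated compositions of
0.95/0.50/0.25 are recovered as 0.947/0.503/0.240.

`component_ratio()` and `fold_enrichment()` compose the fractions into
the enrichment of the double-labeled component by PAPA; ratios are
reported to 2 significant figures in summaries, and an exactly-zero
second component is flagged rather than silently propagated. Only two
components are supported — the solver generalizes to a k-simplex NNLS but
is untested beyond k = 2 — and the nonspecific PAPA background is not
modeled explicitly.

## Ensemble analytics

`pulse_response()` measures, per pulse at frame `p`, the mean intensity
over the `w_post` frames after minus the mean over the `w_pre` frames
before (defaults 10 and 10; a window colliding with another pulse is an
error). The window length is a genuine free parameter: longer windows
average down Poisson noise but run into re-shelving decay; 10 frames
balances the two at the default kinetics and is configuration-exposed.
`papa_dr_ratio()` (mean green increase / mean violet increase) is
invariant to overall gain, which is the point of the normalization — it
cancels cell-to-cell labeling differences. Rate fits go through the
origin (`y = ax`, inverse-variance weighted; through-origin R² is
`1 − SS_res/Σy²`).

The five-phase kinetics analysis computes fractional reactivation
`(i5 − i3)/(i1 − i3)` from the summed intensities of the three weak-pulse
measurement phases. The phrase that defines this quantity in the
experimental literature is grammatically ambiguous between a subtraction
and a normalization; a ratio is implemented because the quantity is
called *fractional* reactivation, and this reading is flagged rather than
silently assumed. With saturating violet the plateau estimates the
recoverable dark pool; under the default rates the measured plateau is
≈ 0.091 for a shelvable fraction of 0.10, the ~9% shortfall coming from
re-shelving during the measurement phases (readout perturbation of the
single-intensity dose model, quantified above). Mutual occlusion is
quantified on green-triggered reactivation events from the simulator's
event log, because immediately after a saturating violet train the
intensity baseline decays steeply and biases the windowed step estimator.

## FLIM

`fit_monoexponential()` maximizes the multinomial likelihood of binned
arrival times under an exponential truncated to the record length, with a
delta-function instrument response — a documented idealization of real
TCSPC. The MLE is found by golden-section search on τ with tolerance
1e-10 of the record length, so exact (noise-free) histograms are
recovered to numerical precision. `nuclear_mask()` is an Otsu threshold
plus largest connected component. `fret_efficiency()` is `1 − τ/τ₀` with
clipping to [0, 1] flagged; τ₀ is an input (donor-only lifetime) and its
uncertainty is not propagated.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use simulation sizes chosen to
make each check's sampling noise small relative to its tolerance while
keeping a laptop-scale run: 2,000 trajectories for two-state recovery,
10,000 molecules for the mixture-enrichment experiment, 12,000–30,000
molecules for ensemble kinetics, 1e5 photons or jumps for the
distributional checks. Every stochastic function takes a `seed` and
restores the RNG state afterwards; identical (parameters, seed) pairs are
bit-reproducible, and `run_pipeline()` records seeds and artifact
checksums in its manifest, invalidating cached stages whose recorded
hashes no longer match.

## Known limitations

- Effective kinetics only: no triplet intermediates, no intensity
  saturation, one intensity scale across phases.
- 2-D world: no defocalization, no 3-D PSF, no EMCCD gain statistics; the
  sender channel is simulated kinetically, never imaged.
- Static (or slowly switching) diffusion states; no within-trajectory
  Hidden-Markov state changes in the estimator.
- Mixture unmixing assumes exactly two components and reference spectra
  measured on the same grid.
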