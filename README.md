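# papaspt

Simulation and analysis of **proximity-assisted photoactivation
single-particle tracking (PAPA-SPT)** experiments in R.

## The problem

Rhodamine dyes such as JFX650 can be driven ("shelved") into a reversible
dark state by intense red light. Two routes bring them back: violet light
reactivates them directly (**DR**, direct reactivation), while exciting a
nearby "sender" dye such as JF549 with green light reactivates them only
when the two fluorophores are in proximity (**PAPA**). In live-cell
single-particle tracking this gives a label-free readout of molecular
interaction: trajectories that appear right after a green pulse are
enriched for molecules whose sender is attached — i.e. for double-labeled
complexes — while trajectories after a violet pulse sample the whole
labeled population.

`papaspt` provides, as composable tidyverse-style functions:

- **Synthetic data with ground truth** — a per-molecule
  bright/dark/bleached Markov model driven by programmable illumination
  sequences (per-frame transition probability `1 − exp(−k·dose)`), two-state
  Brownian motion with localization error, camera rendering with Poisson
  noise, ensemble "sawtooth" intensity traces, and TCSPC decays.
- **Tracking** — spot detection (difference-of-Gaussians + sub-pixel
  Gaussian fits) and greedy nearest-neighbor linking for sparse movies.
- **Classification** — splitting trajectories into PAPA and DR segments by
  post-pulse windows (default 30 frames), class balancing by subsampling,
  and single-molecule reactivation scoring at fixed positions.
- **Diffusion spectra** — for each trajectory the squared 2-D jump `r²` is
  exponential with mean `b = 4(DΔt + σ²)`; a mixture over a fixed
  log-spaced grid of diffusion coefficients (default 100 states,
  0.01–100 µm²/s) is fitted by EM, giving the occupation distribution
  ("diffusion spectrum"), reduced fixed-state fits (e.g. `D ∈ {0.01, 8.3}`
  µm²/s), and the fraction bound below `D = 0.15 µm²/s`.
- **Unmixing** — simplex-constrained least squares decomposing a spectrum
  into two reference spectra, component ratios, and the fold enrichment of
  the double-labeled component between PAPA and DR trajectories.
- **Ensemble analytics** — pulse responses, the PAPA/DR ratio, linear
  rate fits (`y = ax`), five-phase fractional-reactivation kinetics, and
  single-exponential dose-response fits.
- **FLIM** — truncated mono-exponential lifetime fits of TCSPC histograms
  by maximum likelihood, Otsu nuclear masks, and FRET efficiency
  `E = 1 − τ/τ₀`.

## Worked example

Simulate a two-component mixture in which freely diffusing "NLS-like"
molecules carry both dyes while chromatin-bound "H2B-like" molecules carry
the receiver only, then ask how strongly PAPA enriches the double-labeled
component:

```r
library(papaspt)
library(dplyr)

protocol <- parse_protocol(
  "10 cycles of 250 R [2 ms], 1 V [7 ms], 500 R [2 ms], 1 G [7 ms], 250 R [2 ms]",
  pre_shelving_s = 10)

labeling <- labeling_model(c(5000, 5000), c(1, 0), c("NLS-like", "H2B-like"))
states <- simulate_photophysics(photophysics_model(), labeling, protocol, seed = 2002)
motion <- list("NLS-like" = motion_model(f_bound = 0),
               "H2B-like" = motion_model(f_bound = 1))
tracks <- simulate_trajectories(motion, states, seed = 2003)

segments <- split_trajectories(tracks, protocol) |> balance_classes(seed = 2004)
#> discarded 244 segment(s) with < 2 localizations (PAPA: 65, DR: 179)

dr <- filter(segments, class == "DR")
basis_a <- infer_spectrum(filter(dr, component == "NLS-like"))
basis_b <- infer_spectrum(filter(dr, component == "H2B-like"))
fit_papa <- fit_mixture(infer_spectrum(filter(segments, class == "PAPA")),
                        basis_a, basis_b)
fit_dr   <- fit_mixture(infer_spectrum(filter(segments, class == "DR")),
                        basis_a, basis_b)
enrichment_report(fit_papa, fit_dr)
```

```
# A tibble: 1 × 5
  f_papa  f_dr ratio_papa ratio_dr enrichment
   <dbl> <dbl>      <dbl>    <dbl>      <dbl>
1  0.967 0.464         29     0.87       33.3
```

`f_papa`/`f_dr` are the estimated fractions of the double-labeled
component among PAPA and DR trajectories, `ratio_*` their component
ratios (2 significant figures), and `enrichment` the fold enrichment of
double-labeled molecules by PAPA. Here nearly every PAPA trajectory comes
from the double-labeled component, so the fold enrichment is large; the
DR fraction sits near the 50/50 composition of the simulated mixture (the
slight deficit reflects faster bleaching of the component that is
reactivated by both pulse colors).

The worked arithmetic for published best-fit fractions is one call:

```r
fold_enrichment(c(0.91, 0.09), c(0.53, 0.47))
#> [1] 8.966457   # "approximately ninefold"
```

`autoplot()` methods draw sawtooth traces, diffusion spectra, pulse
responses, and decay histograms; `tidy()`/`glance()` methods return the
fitted quantities as tibbles.

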