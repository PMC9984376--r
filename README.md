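# spheroflim

Label-free metabolic imaging analysis of three-dimensional tumor spheroids
from multiphoton fluorescence lifetime (FLIM) data.

Tumor spheroids embedded in collagen shift their energy metabolism —
between glycolysis and oxidative phosphorylation — as they grow, remodel the
matrix and invade it. The autofluorescent coenzymes NAD(P)H and FAD report
on this shift without any label: their free and enzyme-bound states have
distinct fluorescence lifetimes, so time-correlated single-photon-counting
(TCSPC) imaging of their decays resolves the bound fractions pixel by pixel.
`spheroflim` implements the full analysis chain for such experiments, for
microscopists and image analysts who want a tested, reproducible pipeline
from raw decay histograms to population-level metabolic statements.

## The model

Each pixel of a TCSPC image holds a photon-arrival histogram `I(t)` over
`T` temporal bins. The underlying decay is modelled as bi-exponential,

    m(t) = alpha1 * exp(-t / tau1) + alpha2 * exp(-t / tau2),
    alpha1 + alpha2 = 1,

with fast and slow lifetime components `tau1 <= tau2` (ns) and fractional
amplitudes `alpha_i`. The measured signal is the convolution of `m(t)` with
the instrument response function (IRF), scaled by a free amplitude:
`F(t) = A * [IRF (*) m](t)`. Fits minimize the sum of squared residuals
under box constraints (`0.02 <= tau_i <= 100` ns, `0 <= alpha_i <= 1`) with
random-restart initial guesses. For NAD(P)H the slow component is the
enzyme-bound state; for FAD the assignment is reversed. The per-pixel
optical redox readout is the fluorescence lifetime imaging redox ratio

    FLIRR = alpha2_NAD(P)H / alpha1_FAD,

the bound-NAD(P)H fraction over the bound-FAD fraction; higher values
indicate a shift towards oxidative phosphorylation, lower values towards
glycolysis.

Condition-level comparisons pool the FLIRR values of replicate samples,
estimate their probability density on a fixed grid (0.2 to 1.3 in steps of
0.01) with a Gaussian-kernel, log-boundary-corrected KDE, and quantify the
difference between two conditions with the overlap index — the integral of
the pointwise minimum of the two densities (1 = identical, 0 = disjoint) —
plus a two-tailed t-test on per-sample medians. Spatial metabolic gradients
are profiled by exact Euclidean distance transforms: 15 µm bins from the
spheroid edge (beyond 75 µm counted as the core) for intact spheroids, and
125 µm bins from the (former) spheroid center for migrating samples, with
linear gradients reported in FLIRR/mm.

Because raw spheroid FLIM datasets are rarely public, the package ships a
first-class phantom module that generates synthetic spheroid scenes with
known ground-truth parameter fields and simulates TCSPC acquisition (IRF
convolution, Poisson photon noise), so every stage of the pipeline is
testable end to end.

## Worked example

Simulate an intact spheroid with a known edge-to-core metabolic gradient,
push it through segmentation, lifetime fitting and FLIRR spatial profiling:

```r
library(spheroflim)

irf_n <- make_irf(339, n_bins = 256, bin_width_ps = 12500 / 256)  # NAD(P)H
irf_f <- make_irf(396, n_bins = 256, bin_width_ps = 12500 / 256)  # FAD

# ground truth: bound-NAD(P)H fraction 0.72 at the edge, 0.40 in the core;
# constant bound-FAD fraction 0.8  ->  FLIRR 0.9 (edge) to 0.5 (core)
scene_n <- make_phantom("intact", size = 224, pixel_size_um = 0.8,
                        radius_px = 100,
                        gradient = list(alpha2 = c(edge = 0.72, core = 0.40),
                                        tau1 = c(0.4, 0.4),
                                        tau2 = c(2.5, 2.5)))
scene_f <- scene_with_gradient(scene_n, list(alpha2 = c(0.2, 0.2),
                                             tau1 = c(0.3, 0.3),
                                             tau2 = c(2.0, 2.0)))
dk_n <- simulate_decay_image(scene_n, irf_n, 100, channel = "NADH", seed = 21)
dk_f <- simulate_decay_image(scene_f, irf_f, 100, channel = "FAD", seed = 22)

mask <- segment_intact(intensity_from_decay(dk_n))
lt_n <- fit_image(spatial_temporal_bin(dk_n, mask), irf_n, seed = 31, stride = 4)
lt_f <- fit_image(spatial_temporal_bin(dk_f, mask), irf_f, seed = 32, stride = 4)
fl   <- compute_flirr(lt_n, lt_f)
bin_flirr_by_distance(fl, distance_from_edge(mask))
```

```
<binned_flirr_profile> edge binning, 6 bins
      bin bin_low_um bin_high_um   n median   q25   q75    p5   p95
1  [0,15)          0          15 675  0.853 0.830 0.877 0.802 0.922
2 [15,30)         15          30 555  0.792 0.771 0.815 0.746 0.840
3 [30,45)         30          45 420  0.716 0.692 0.738 0.663 0.763
4 [45,60)         45          60 279  0.634 0.618 0.655 0.596 0.679
5 [60,75)         60          75 133  0.568 0.554 0.582 0.524 0.600
6    core         75         Inf  19  0.520 0.510 0.531 0.498 0.543
```

The recovered profile descends monotonically from the edge bin (median
0.853, imposed edge value 0.9 minus the expected half-bin and windowing
attenuation) to the core bin (median 0.520 against an imposed 0.5) — the
imposed metabolic gradient is recovered through the entire segmentation,
fitting, FLIRR and distance-binning chain.

A whole condition grid (cell line x collagen density x day, n replicates
each, with pooled PDFs, overlap indices and median t-tests) runs through
`run_pipeline()`; see `?pipeline_config` and the thin command-line wrapper
in `inst/cli/spheroflim.R` (`init` and `run` subcommands).

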