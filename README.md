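# flimfish

Combinatorial spectral and fluorescence-lifetime phasor decoding for spatial
transcriptomics.

## The problem

Single-molecule FISH resolves individual mRNA transcripts as
diffraction-limited puncta, but a conventional microscope only separates 3–4
fluorophores by colour. Adding the *time* domain changes the economics: with
a pulsed laser and time-resolved detection, each pixel carries a photon
arrival-time histogram whose shape encodes fluorescence lifetime, an
intrinsic property of the dye. Tagging each transcript species with an
unordered **pair** of fluorophores drawn from a panel of N dyes — dyes that
may share a spectrum but differ in lifetime, or vice versa — yields

    C(N, 2) = (N² − N) / 2

distinguishable codewords: 10 targets from 5 dyes, 66 from 12. Decoding
works in **phasor space**: the fit-free first-harmonic Fourier projection of
each pixel's decay histogram gives a lifetime phasor (G, S), the analogous
transform of its spectral histogram gives a spectral phasor, and every
punctum becomes a point in a 4-D space where pure dyes sit at known
positions and 1:1 mixtures sit at chord midpoints. Gaussian-mixture
clustering with one extra component for autofluorescence assigns each
punctum a codeword with a posterior probability, and two rejection rules
supply built-in error detection: signal in only one spectral channel
(incomplete labelling, nonspecific binding, autofluorescent specks) is
*undetermined*; signal in more than two channels (several transcripts packed
inside one point-spread function) is *overlapping*.

The package is aimed at groups building or analysing spectral-FLIM smFISH
experiments: it provides the full decoding pipeline plus a ground-truth
synthetic-data generator, so every stage is testable against simulations
before an instrument is involved.

## What is implemented

- **phasor** — lifetime/spectral phasor transforms of 5-D photon stacks
  (`photon_stack()`, `phasor_transform()`), closed-form single-exponential
  positions on the universal semicircle, phase-lifetime projection.
- **codebook** — fluorophore panels, pair/singleton codewords, expected 4-D
  signatures, YAML round-trip (`build_codebook()`, `expected_signatures()`).
- **simulate** — synthetic stacks with 3-D Gaussian puncta (σ_xy = 200 nm,
  σ_z = 500 nm, peak intensity 1 ± 0.3), Poisson photons split between the
  codeword's dyes, plus nuclear-stain volumes (`simulate_experiment()`).
- **detect** — 3-D blob detection: median background, matched filter,
  26-neighbourhood maxima, per-punctum size/brightness/prominence/channel
  measurements (`detect_puncta()`).
- **classify** — GMM fitting in 2-D or 4-D phasor space with an
  autofluorescence component, Hungarian component-to-codeword matching,
  posterior-gated decoding with undetermined/overlapping rejection,
  multicomponent chord fractions (`classify_stack()`, `decode_puncta()`,
  `component_fraction()`).
- **cells** — Otsu nucleus segmentation, surface-seeded Voronoi-like
  territory growth, per-cell counts and volume normalisation
  (`segment_nuclei()`, `grow_territories()`).
- **crowding** — the analytic isolated-fraction model
  `n/N = (1 − v_i/V_T)^(N−1)`, its numerical inversion for the true count,
  loss intervals over a PSF-volume range, and a Monte-Carlo check
  (`estimate_true_count()`, `overlap_interval()`, `simulate_crowding()`).

Results come back as tibbles; fitted models support `tidy()`/`glance()`;
`autoplot()` methods cover phasor clouds, mixture components and crowding
curves. A thin CLI (`exec/flimfish`) exposes `simulate`, `pipeline` and
`crowding` subcommands.

## Worked example

Simulate a 10-plex experiment (ten genes encoded by pairs from five dyes)
and decode it:

```r
library(flimfish)

panel <- demo_panel()
codebook <- build_codebook(panel, c("BRCA1", "BRCA2", "CENPF", "CKAP5",
                                    "POLR2A", "KI67", "MTOR", "NCOA1",
                                    "NCOA2", "NCOA3"))
cfg <- simulation_config(codebook, volume_um = c(8, 8, 3),
                         n_time_bins = 64L, counts_per_target = 3L,
                         seed = 42L)
sim <- simulate_experiment(cfg)
sim$stack
#> <photon_stack> 10 x 80 x 80 voxels (z,y,x), 5 channels, 64 time bins
#>   voxel 0.1 x 0.1 x 0.3 um, repetition 78 MHz, 802317 photons total

res <- classify_stack(sim$stack, codebook, seed = 1L)
res$summary
#> # A tibble: 13 × 4
#>    group        target count percent
#>    <chr>        <chr>  <int>   <dbl>
#>  1 assigned     <NA>      21      84
#>  2 undetermined <NA>       1       4
#>  3 overlapping  <NA>       3      12
#>  4 target       BRCA2      3      12
#>  ...
```

Of the 30 simulated transcripts, 25 puncta are detected (the rest are lost
to crowding and edges at this density); 21 decode to a target — every one of
them matching the nearest ground-truth transcript — one is rejected as
undetermined and three as overlapping. The crowding model quantifies that
loss analytically. With the detected count and imaged cellular volume of a
real 10-plex experiment (n = 13,500 puncta in 68,000 µm³) and a PSF volume
between 0.1 and 0.3 µm³:

```r
overlap_interval(13500, 68000, c(0.1, 0.3))
#> # A tibble: 2 × 5
#>   psf_volume_um3 n_detected n_true loss_pct loss_pct_true
#> 1            0.1      13500 13776.      2             2
#> 2            0.3      13500 14384.      6.6           6.1
```

i.e. an estimated 2.0–6.6 % of puncta are lost to optical crowding
(`loss_pct` is relative to the detected count; relative to the true count it
is 2.0–6.1 %).

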