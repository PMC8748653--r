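---
title: "Combinatorial spectral/lifetime phasor decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial spectral/lifetime phasor decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimfish)
```

This vignette is the package's account of the science it implements: the
phasor model, the combinatorial encoding, each pipeline stage's assumptions
and tunables, the synthetic-data generator, and the numerical choices made
where the design was genuinely open.

## The phasor model

A pulsed laser at repetition frequency $f$ (here 78 MHz, period
$T = 1/f \approx 12.8$ ns) excites the sample; time-resolved detection
accumulates, per pixel, a histogram of photon arrival times within the
period. Rather than fitting exponential decay models, the package uses the
fit-free phasor transform: the first-harmonic Fourier projections

$$G = \frac{\sum_k c_k \cos(2\pi h\, t_k / T)}{\sum_k c_k}, \qquad
  S = \frac{\sum_k c_k \sin(2\pi h\, t_k / T)}{\sum_k c_k},$$

with $c_k$ the counts in bin $k$, $t_k$ its centre time and $h$ the harmonic
(1 by default). The transform characterises the *shape* of the decay, not
its size, so it is independent of the photon count. A single-exponential
species of lifetime $\tau$ lands at the closed-form position

$$G = \frac{1}{1 + (\omega\tau)^2}, \qquad
  S = \frac{\omega\tau}{1 + (\omega\tau)^2}, \qquad
  \omega = 2\pi h f,$$

which lies on the *universal semicircle* of radius $\tfrac12$ centred at
$(\tfrac12, 0)$. Crucially the transform is linear in photon fractions: a
pixel containing two species sits on the chord between their positions, at
the photon-weighted fraction. This is what makes combinatorial pairs
decodable and what `component_fraction()` inverts (orthogonal projection
onto the chord, clamped to $[0,1]$).

A spectral detector yields a second histogram per pixel — photons per
wavelength channel — and the analogous transform maps channel $c$ of $C$ to
the unit-circle angle $\theta_c = 2\pi h (c - \tfrac12)/C$. The exact
normalisation of the spectral transform is a convention; the one above
(half-integer channel centres over the full detector range) is a local
choice, stated here so that signatures are reproducible. Together the two
transforms give every voxel four phasor coordinates plus intensity.

### Discretisation

Time bins default to 256 per period with bin-centre convention
$t_k = (k - \tfrac12) T / B$. At 256 bins the discrete transform of an ideal
periodic exponential agrees with the closed form to better than $10^{-3}$
phasor units for $\tau \in [0.3, 10]$ ns at 78 MHz (the tests sweep this
range); the bias grows roughly quadratically as the bin count shrinks and
exceeds $10^{-3}$ at 64 bins, which is why the default stays at 256. Voxels with fewer than `min_photons = 10` photons
are marked invalid rather than transformed: below that the phasor estimate
is noise-dominated and would contaminate clustering. Invalid voxels carry
`NA` coordinates and are excluded by construction from every downstream
stage (no NaN propagation).

## Combinatorial encoding

Each target is assigned an unordered pair of panel fluorophores, giving
$\binom{N}{2}$ codewords from $N$ dyes. Pair signatures assume an equal
(½:½) photon split — the midpoint of the chord — because a transcript
carries the same number of probe binding sites for both dyes; real
stoichiometry deviations show up as position along the chord and are handled
by the mixture model's covariance, not by the codebook. Singleton codewords
are allowed but must be requested explicitly (`allow_singletons = TRUE`):
the decoder normally rejects single-channel puncta as undetermined, and a
singleton codeword disables that rejection for exactly its channel set, so
mixing singleton and pair codebooks trades error detection for plexity. Both
behaviours are selectable because published designs use both (a pairs-only
10-plex, and a minimal 6-plex mixing singletons with a same-channel pair).

## The pipeline

`classify_stack()` composes the stages; each is exported separately.

**Background and matched filter.** The background is a voxelwise median
over a window 10× the expected punctum size (default 0.25 µm, the
diffraction limit), converted to voxels per axis and rounded to odd, with
reflect padding; a window larger than the stack falls back to the global
median with a warning. The prominence map is Gaussian smoothing (σ = punctum
size in voxels per axis, anisotropy respected) of the background-subtracted
stack, clipped at zero.

**Maxima.** Local maxima are strict 26-neighbourhood maxima — the discrete
fixed points of zero gradient with negative divergence on a voxel grid —
with equal-valued plateaus reduced to their centroid voxel. The default
prominence threshold is five times the robust noise scale of the filtered
map. Because the map is clipped at zero, a plain MAD would underestimate the
noise (over half the voxels can be exactly zero), so the scale is estimated
from the median of the strictly positive values via the half-normal relation
$\hat\sigma = \mathrm{med}(v_{>0}) / 0.6745$.

**Measurement.** Brightness is the background-subtracted photon sum over a
2σ ellipsoid; size counts voxels above half the peak prominence; channel
presence requires a per-channel Poisson SNR of at least 3 over the local
background *and* at least 5% of the punctum's background-subtracted photons.
The second criterion is needed because a bright punctum reaches an absolute
SNR of 3 in a neighbouring channel through spectral cross-talk alone; how
"appears in a channel" should be quantified is not settled in the
literature, so both thresholds are exposed as parameters. Edge-clipped
puncta are retained and flagged.

**Clustering and decoding.** Puncta-mean phasors (intensity-weighted over
the valid voxels of the 2σ ellipsoid) are clustered with a Gaussian mixture
with full covariances and one component more than there are signatures, the
extra component absorbing autofluorescence and noise. Fitting is delegated
to mclust (EM, `VVV` model) with its deterministic model-based
initialisation run on a seeded 2000-point subset — this plays the role a
seeded k-means++ would play: a deterministic, reproducible start. Components
are matched to codeword signatures jointly by Hungarian assignment on the
Euclidean distance between component means and expected signatures, which
removes EM label-switching ambiguity; the unmatched component is labelled
autofluorescence. Posteriors for new data are computed by direct Bayes rule
from the fitted parameters (components may be empty in new data, so a
pretrained model can be applied to later acquisitions). Decoding applies, in
order: more than two channels → *overlapping*; fewer than two channels with
no codeword on exactly that channel set → *undetermined*; otherwise the
maximum-posterior component consistent with the channel set, accepted when
the posterior reaches 0.5 (default), with autofluorescence assignments,
inconsistent channel sets and low posteriors all *undetermined*.
Low-confidence puncta keep their posterior in the output instead of being
dropped, and category counts are conserved at every stage. The rule order is
a reconstruction (the original bookkeeping is not enumerated anywhere), so
it is kept configurable. When too few puncta exist to fit EM
(fewer than 10 per component), `signature_model()` substitutes a prior
mixture centred on the expected signatures with isotropic sd 0.01 — the
typical experimental phasor scatter.

When only a few discrete channels exist, spectral phasors add little over
channel-presence logic; `mode = "lifetime"` clusters on the lifetime pair
alone, which is how the minimal 6-plex design operates.

## Cells

Nuclei are segmented by a single global two-class histogram split (Otsu's
criterion — the standard concrete form of "hard splitting" a bimodal
histogram), 26-connected components, and a minimum nucleus volume of
30 µm³ to reject debris. Territories grow from the nucleus *surfaces* by
simultaneous 3×3×3 dilation until the volume is tiled, so each interface
approximates the plane bisecting the gap between the two nearest nucleus
edges — a Voronoi tessellation seeded by surfaces rather than points.
Voxels reached by two labels in the same iteration go to the nucleus whose
surface is nearest in *physical* distance (anisotropic voxels are honoured),
with exact ties to the lower cell id. Because the discrete wavefront
advances in chessboard rather than Euclidean distance, up to three
boundary-refinement passes re-evaluate interface voxels with the same
nearest-surface criterion; the tests compare the result against a
brute-force nearest-surface oracle on a 32³ grid and require ≤ 2% of voxels
to differ, all on boundaries. Counts are reported per territory, and also
volume-normalised (counts divided by total imaged cellular volume times a
nominal 3000 µm³ mean cell volume) for thin slabs where territories
under-represent whole cells; the two are different estimands and both are
returned without asserting equivalence.

## Optical crowding

With $N$ puncta placed independently and uniformly in volume $V_T$, a
punctum is resolvable when no other falls inside its exclusion volume $v_i$
(the instrument PSF volume, since transcripts are sub-diffraction), so the
expected isolated fraction is

$$\frac{n}{N} = \left(1 - \frac{v_i}{V_T}\right)^{N-1}.$$

$N$ cannot be isolated analytically; `estimate_true_count()` inverts
numerically by bracketed bisection on $[n, N^\*]$ where
$N^\* = 1/\ln\!\big(1/(1 - v_i/V_T)\big)$ maximises the left side — the
larger root beyond $N^\*$ corresponds to a volume nearly tiled with puncta
and is unphysical at realistic densities. The relative tolerance is
$10^{-8}$. The headline loss is reported relative to the *detected* count,
$100 (N - n)/n$: this is the definition that reproduces both endpoints of
the published interval (2.0% at $v_i = 0.1$ µm³ and 6.6% at 0.3 µm³ for
$n = 13{,}500$, $V_T = 68{,}000$ µm³), whereas the loss relative to the true
count gives 6.1% at the upper endpoint; both are emitted.

The Monte-Carlo check places $N$ points uniformly in a cube and calls a
point isolated when no other lies within the *radius* of the sphere whose
volume is $v_i$ — so the exclusion volume around each point equals $v_i$,
exactly as the analytic derivation assumes. (A merge distance equal to that
sphere's diameter would imply an exclusion volume of $8 v_i$ and could not
match the formula.) Distances are periodic (minimum-image) by default: the
model describes a homogeneous medium, and clipping exclusion spheres at the
walls of a test-sized box would bias the observed fraction upward by more
than the Monte-Carlo error; `periodic = FALSE` restores the plain box. The
test grid runs ≥ 10 densities × 12 iterations — a scaled-down version of the
20,000-iteration design the simulation emulates — and requires agreement
within three standard errors.

## The synthetic-data generator

`simulation_config()` defaults encode the reference simulation conditions:
transcripts as 3-D Gaussians with σ_xy = 200 nm and σ_z = 500 nm, peak
intensity Normal(1, 0.3), voxels of 100 × 100 × 300 nm in a stack of
1000 × 1000 × 33 voxels, 78 MHz repetition, 256 time bins. The stated
source conditions are internally inconsistent — a 10 × 10 × 10 µm cube
cannot be 1000 × 1000 pixels of 100 nm — so the voxel size and grid are
taken as authoritative, making the default volume 100 × 100 × 9.9 µm.
Two quantities have no canonical values and are generator choices, fixed
once: the photon budget (300 expected photons in the peak voxel of a
unit-intensity transcript — a realistic confocal smFISH punctum then
integrates to order 10⁴ photons) and the background (0.1 photons per voxel,
uniform over channels and time bins). The intensity normal is truncated at
0.1 by redrawing, avoiding non-positive intensities. Rendering integrates
the Gaussian over voxels (no nearest-voxel stamping), truncates profiles at
4σ for cost, splits photons ½:½ between the pair's dyes (configurable),
draws spectral channels from the dye's Gaussian emission integrated over the
channel edges, arrival-time bins from the periodic exponential decay, and
all counts as Poisson. Transcripts are placed with no exclusion, so optical
crowding arises naturally at high density.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: no instrument response function (decays
are ideal periodic exponentials; real IRFs rotate phasor positions), no
detector afterpulsing or dead time, no optical aberrations or depth-dependent
PSF, no photobleaching, no structured autofluorescence (an optional uniform
background stands in), and dye emission spectra are Gaussian. Parameter
recovery on these simulations demonstrates the pipeline's correctness, not
instrument-level accuracy; on a real instrument the expected signatures
should be measured from single-dye controls rather than computed from
nominal lifetimes.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `harmonic` | 1 | — | Fourier harmonic of both transforms; higher harmonics reserved for multicomponent unmixing |
| `min_photons` | 10 | photons/voxel | phasor validity threshold |
| `puncta_size_um` | 0.25 | µm | expected punctum size: sets the median window (10×), the matched filter σ, and measurement ellipsoids |
| `min_prominence` | 5 × robust σ | filtered units | detection threshold |
| `channel_snr_threshold` | 3 | — | per-channel presence (Poisson SNR) |
| `channel_fraction_threshold` | 0.05 | — | cross-talk guard on presence |
| `posterior_threshold` | 0.5 | — | minimum posterior for assignment |
| `covariance_floor` | 1e-6 | phasor² | EM degeneracy regularisation |
| `min_volume_um3` | 30 | µm³ | nucleus debris rejection |
| `mean_cell_volume_um3` | 3000 | µm³ | volume normalisation of counts |

## Problem sizes

The test suite and examples run simulations at reduced scale — volumes of a
few hundred µm³ with tens of transcripts, 64–256 time bins, Monte-Carlo
grids of ≤ 500 points × 12 iterations, tessellation oracles on 32³ grids —
chosen so that every stage is exercised end-to-end with seeded, reproducible
fixtures. All scale-dependent checks (phasor convergence, recall, crowding
agreement) are formulated so their expected values are scale-free.

## Conventions and limitations

Arrays are indexed `(z, y, x)` internally; R-facing tables use 1-based voxel
indices (the R idiom) alongside physical coordinates in µm with the origin
at the centre of the first voxel. CSV output is UTF-8, `.` decimal, comma
separator. Stacks read/write as 32-bit float multi-page TIFF with a YAML
sidecar declaring layout and acquisition metadata; counts round-trip
bit-exactly, and reading without metadata is an explicit error.

Known limitations: no resolution of multiple codewords within a single
punctum (overlapping events are counted, not unmixed); no IRF deconvolution
or FRET modelling; no k > 2 codeword combinations; pixel-level clustering is
retained for pseudo-colour display but decoding operates on puncta-mean
phasors; the crowding correction is reported as an adjustment estimate and
never silently applied to counts.
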