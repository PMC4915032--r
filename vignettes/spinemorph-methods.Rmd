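---
title: "Synthetic STED spine morphometry and compartmentalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic STED spine morphometry and compartmentalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## What this package models

Dendritic spines compartmentalize synaptic biochemistry: a bulbous head is
connected to the dendrite by a thin neck that throttles diffusional
exchange. Super-resolution (STED) imaging resolves the relevant dimensions
— head width around 0.4–0.5 µm, neck width 0.1–0.2 µm — that confocal
imaging cannot. A standard summary of the diffusional isolation of a spine
is the compartmentalization factor

$$\mathrm{cf} \;=\; \frac{V\,L}{A},$$

where $V$ is the head volume, $L$ the neck length and $A$ the neck
cross-sectional area. For a molecule with cytosolic diffusion coefficient
$D$, $\tau = VL/(AD)$ is the time constant of diffusional re-equilibration
of the head after a step change of concentration in the dendrite, in the
regime where the neck's own volume is small ($AL/V \ll 1$).

spinemorph implements the full measurement chain on synthetic data: it
generates ground-truth spine populations, renders them as STED-like image
stacks, re-measures the morphology from the images with the same operators
a microscopist would use (curvature-following length, Gaussian-fit FWHM
widths), computes per-spine cf and $\tau$, and compares groups with a
normality-gated two-group test plus a two-sample Kolmogorov–Smirnov test
against a reference group. Because every stage is seeded, the whole
experiment is reproducible and the measurement operators can be validated
against known ground truth — the central point of the package.

## The synthetic spine population

`sample_spine_population()` draws per-spine features from truncated normal
distributions (physical floor 0.05 µm) and builds an explicit geometry for
each spine: a capsule neck (optionally curved as a circular arc with a
configurable sagitta), a spherical head, and an attachment point on a
straight dendrite shaft (radius 0.30 µm) at jittered-regular spacing set
by the linear spine density.

Two presets are built in, emulating a wild-type and an APP/PS1 transgenic
group of CA3 pyramidal-cell spines:

| feature | wt | appps1 | sd (both) |
|---|---|---|---|
| spine length (µm) | 0.82 | 0.81 | 0.20 |
| head width (µm) | 0.44 | 0.49 | 0.09 |
| neck width (µm) | 0.160 | 0.173 | 0.05 |
| density (per 10 µm) | 11.5 | 8.7 | Poisson per branch |

Design choices worth stating explicitly:

* **Neck length is derived, not sampled.** The path runs from the dendrite
  base through the neck and across the full head, so
  `neck_length = spine_length − head_width`. Sampling neck length
  independently would routinely violate `spine_length ≥ neck_length`.
  The implied preset neck lengths are 0.38 µm (wt) and 0.32 µm (appps1):
  the transgenic group has a larger head and a shorter, wider neck.
* **Dispersions are population sds chosen by the package**, at values that
  give realistically overlapping distributions and reproduce the
  qualitative group contrast this design emulates: with these sds and
  ~250–300 spines per group, head width and neck width separate clearly in
  a KS comparison while spine length does not. Reconstructing sds from
  rounded group-level standard errors is too coarse to pin this behaviour
  down, so the package treats dispersion as an explicit modelling choice.
* **The neck-width preset of the transgenic group (0.173 µm)** is set so
  that, under the sphere/disc models below, the increase of head volume and
  the shortening/widening of the neck cancel in cf — the two groups differ
  in several features but not in compartmentalization. This cancellation is
  asserted to 1e-12 in the tests as an algebraic property.

## Rendering

`render_stack()` produces a 3D stack the way the emulated acquisition
would: 40 nm pixels, 10 z-sections 192 nm apart. The scene is rasterized as
an occupancy grid at 4× sub-pixel resolution laterally (10 nm), convolved
with an anisotropic Gaussian PSF (FWHM 50 nm lateral, 600 nm axial —
lateral-only resolution gain, confocal-like z), scaled so the brightest
voxel equals `photons_per_peak` (default 200 over a background of 10,
giving per-spine SNR above 10), and Poisson-noised.

Two numerical details matter:

* **z anti-aliasing.** The z grid (96 nm sub-steps) is coarser than the
  structures: a 0.1 µm neck is thinner than one z cell. Binary inside/out
  sampling makes apparent widths jump discontinuously with true width (and
  can drop thin necks entirely when they fall between sample planes), so
  occupancy is stored as the fractional z-coverage of each sub-cell
  (4 samples per cell). With this, the rendered lateral profile of a neck
  agrees with the 1D forward model (chord profile of a filled cylinder
  convolved with the lateral PSF) to within a few percent across
  0.10–0.30 µm.
* **Thin structures are dim.** A neck thinner than the axial PSF
  contributes fewer photons per column than the head or shaft; necks render
  at roughly half the peak brightness of heads. This is physical, and it is
  why the tracer's threshold defaults to a low 5% of the local dynamic
  range.

The renderer deliberately does not model STED depletion physics,
photobleaching, sample drift, or out-of-plane spines (the scene lies in the
stack mid-plane; real dendrites project spines in all directions, and a
fraction of them would be unmeasurable laterally). Passing measurements on
these synthetic stacks therefore validates the measurement operators under
controlled conditions; it does not certify performance on every real-image
pathology.

## Morphometry

All measurements are taken on the lateral maximum-intensity projection
(`project_stack()`): the z sampling is coarse and the widths of interest
are lateral.

**Tracing.** `trace_spine_path()` is a reproducible stand-in for manual
tracing: the image is smoothed (σ = 1 px), thresholded relative to the
local background, and the path is the intensity-weighted geodesic
(Dijkstra, 8-connected, edge cost ∝ 1/(I − background)) from a seed at the
dendrite edge through a hint inside the head. From the hint, the path is
extended to the most distal above-threshold point of the head, where
"distal" is the projection onto the seed→hint axis so the endpoint is the
far pole of the head rather than a lateral corner. Annotated points are
snapped to the nearest above-threshold pixel within 2 px (annotations
placed on the rim of a structure can land on a partially covered, dim
pixel).

**Neck/head boundary.** Local profile widths (direct half-max crossing) are
scanned along the path; the boundary triggers where the width first exceeds
1.5× the running median of the neck estimate, then walks back along the
rising flank (to 1.15×) so the boundary sits where widening begins rather
than where it is confirmed. A geometric cap supplements the ratio rule:
because the path terminates at the distal head edge, the head occupies
roughly one apparent head-diameter of terminal arclength, which bounds the
boundary for stubby spines whose neck is shorter than the ratio rule's
warm-up. Both rules are configurable in `morph_options()`.

**Lengths.** `spine_length()` is the polyline arclength from the dendrite
base to the distal head edge, following the neck's curvature;
`neck_length()` is the arclength up to the boundary.

**Widths.** `neck_width()` averages Gaussian-fit FWHMs of (by default 3)
profiles drawn orthogonal to the local path tangent at evenly spaced neck
positions; `head_width()` fits the profile through the head's intensity
maximum (sub-pixel refined by centroid), orthogonal to the neck axis at the
boundary. The Gaussian fit (`gaussian_fwhm()`) anchors its offset to the
cleaner of the two profile tails and restricts the fit to the contiguous
block above 15% of the amplitude around the central peak: profiles near the
base of a tilted spine can graze the dendrite shaft, and an unconstrained
fit would be dragged by that shoulder. Near the base, profile length also
shrinks adaptively with arclength for the same reason. On an exact Gaussian
profile the fit recovers σ to machine precision, and
`fwhm = 2\sqrt{2\ln 2}\,σ` holds exactly by construction.

**Width calibration.** A fluorophore-filled cylinder (or sphere) imaged
with coarse axial sampling projects a chord-length profile — a semicircular
bump whose half-max width is $\sqrt{3}/2 \approx 0.866$ of the true
diameter, not the diameter itself. By default both width operators divide
the fitted FWHM by this factor and report the diameter of the object that
would project the observed profile (`width_model = "projected_chord"`).
`"raw_fwhm"` reports the uncorrected apparent width instead, which is what
imaging studies typically print; the choice only rescales both groups
equally and does not affect any group comparison. A separate, optional
quadrature PSF correction ($w^2 = w_\mathrm{meas}^2 - w_\mathrm{PSF}^2$)
is available but off by default — with the chord calibration in place it
over-corrects mid-range necks.

With defaults, on 50 rendered wild-type-like spines at SNR ≳ 10, median
absolute relative errors are about 3–4% (spine length), 6–9% (neck length),
9–13% (neck width) and 5–8% (head width), with ≥ 48/50 spines traced; the
acceptance suite asserts the 10%/10%/15%/10% envelope. Residual biases are
dominated by pixel quantization (features are 3–5 px wide) and by the
boundary rule's arclength granularity.

## Compartmentalization

`head_volume()` uses a sphere on the head width, $V = (\pi/6)d^3$;
`neck_cross_section()` a disc on the neck width, $A = (\pi/4)w^2$. Both are
stated models, not measurements — real heads are not spheres — so absolute
cf values depend on this convention and the package validates cf through
invariance and oracle properties rather than absolute scale:

* cf is exactly invariant under the constructed head-up/neck-shorter-wider
  transformation (to 1e-12);
* cf scales as length² under isotropic rescaling (dimensional bookkeeping);
* the diffusion interpretation is checked against
  `simulate_diffusional_recovery()`, an explicit finite-difference solver
  for 1D diffusion along the neck (≥ 50 grid cells, stability bound
  $dt \le 0.2\,dx^2/D$ enforced) coupling a well-mixed head (initial
  concentration 0) to a Dirichlet dendritic reservoir (concentration 1).
  Over a 3×3×3 grid of (V, L, A) with $AL/V \le 0.1$, the fitted
  single-exponential τ (`fit_exponential_tau()`) matches $VL/(AD)$ within
  10%. For $AL/V \gtrsim 1$ the one-compartment reduction breaks down and
  the deviation exceeds 10% — asserted as a documented regime limit, not
  hidden.

The default $D = 0.45\ \mu m^2/s$ is a typical small-dye cytosolic value,
used only for the τ column and always user-overridable.

## Statistics

The two-group workflow mirrors common practice in this literature:

1. `normality_gate()` runs the D'Agostino–Pearson omnibus test
   ($K^2 = Z_\mathrm{skew}^2 + Z_\mathrm{kurt}^2 \sim \chi^2_2$),
   implemented in-package and cross-checked against an independent
   reference implementation; samples below n = 8 are declared
   not-applicable and routed to the nonparametric branch.
2. `compare_two_groups()` uses a two-sided unpaired Student's t test
   (equal-variance classic variant; Welch by flag) when both samples pass
   the gate, otherwise a two-sided Mann–Whitney test (exact for small
   tie-free samples, normal approximation with tie correction otherwise).
   Two-sidedness and the equal-variance default are conventions, stated
   here because the emulated workflow does not pin them down.
3. `ks_two_sample()` compares each sample against the designated reference
   group: $D = \sup|F_1 - F_2|$ with the asymptotic Kolmogorov p-value at
   effective size $n_1 n_2/(n_1+n_2)$, or exhaustive permutation when
   $n_1 + n_2 \le 16$.

Small-sample correctness is tested against brute-force enumeration (all
$\binom{8}{4}$ Mann–Whitney assignments; all $\binom{12}{6}$ KS
permutations), and the gated test's type-I error is checked to be
0.05 ± 0.01 over 10,000 seeded null simulations. A paired exact Wilcoxon
signed-rank wrapper (`wilcoxon_matched_pairs()`) completes the workflow
for within-cell comparisons. Multi-factor ANOVA with post-hoc corrections
is intentionally out of scope — the pipeline exports tidy group tables that
any stats environment can consume.

## Scalar quantification indices

`normalize_timecourse()` divides EPSC amplitudes by the mean of an 8 min
pre-induction baseline and reports LTP magnitude as the mean normalized
amplitude 30–40 min after induction, ×100 (window configurable). Amplitude
signs are ignored throughout (raw inward currents are negative).
`paired_pulse_ratio()`, `nmdar_ampar_ratio()`, `tonic_current_shift()`,
`displacement_index()` ($T_\mathrm{novel} \times 100 /
(T_\mathrm{novel}+T_\mathrm{familiar})$), `novel_arm_fraction()` and
`specific_binding()` (total − non-specific, per mg protein, duplicates
averaged, negative values clipped with a flag rather than erroring —
duplicate noise can legitimately cross zero) are direct implementations of
their definitions, with degenerate inputs raising classed errors.

The paired generators (`generate_ltp_series()`,
`generate_behavior_trials()`, `generate_binding_points()`) exist so each
index can be tested end to end: exploration times are gamma draws sharing a
scale, which makes the expected displacement index exactly the preference
parameter (the index is Beta-distributed); binding points are lognormal
duplicates around a target density.

## The full experiment and reproducibility

`run_full_synthetic_experiment()` chains everything: per group, branch
spine counts are Poisson around the density (20 µm branches by default, so
branch-to-branch density variation mimics sampling several dendrites),
every branch is rendered and measured, cf/τ are added, and the stats table
holds one KS row and one gated-test row per variable (five morphological
variables plus per-branch density). A single master seed is fanned out to
per-stage child seeds through a fixed affine map, so identical
configurations give byte-identical outputs and different stages never share
a stream. `write_result_bundle()` writes the tables as CSV plus a manifest
carrying a hash of the configuration; stacks go to 16-bit multi-page TIFF
with a JSON voxel-size sidecar, configurations round-trip losslessly
through YAML.

At the default scale (250 spines per group; ~27 branches in total) the full
experiment takes on the order of a minute or two on one CPU; the validation
suite uses 50 spines for the recovery study and the default scale for the
group-contrast check. These sizes were chosen to give stable medians and
clearly resolved KS outcomes while keeping a full run interactive.

## Known limitations

* The sphere/disc V and A models make absolute cf values conventional;
  only comparisons and invariances are interpretable.
* Measured widths are apparent widths calibrated under the package's own
  forward model; on real images with unknown PSFs the chord factor is an
  approximation.
* The generator places all spines in the lateral plane and does not model
  overlapping spines from densely innervated stretches beyond what random
  spacing produces; real tissue is harder.
* Tracing is a stand-in for manual annotation: it is deterministic and
  validated on synthetic truth, but it inherits the seed/hint quality just
  as a human tracer would.
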