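---
title: "Spatial correlation analysis of segmental axon architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial correlation analysis of segmental axon architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vncorr)
```

## The problem and the model

The embryonic *Drosophila* ventral nerve cord (VNC) is a segmentally repeated
structure whose longitudinal connectives are built from fasciculated axon
bundles. In Fasciclin 2 (Fas 2)-stained stacks these bundles are organised,
per hemiside, into three compact fasciculated units (medial, intermediate,
lateral). Their three-dimensional arrangement is not uniform along the
anterior–posterior (AP) axis: at one position per segment — the *3D node* —
the fascicles adopt a compact, stereotyped transverse configuration, while
between nodes they disperse. vncorr quantifies this architecture from
calibrated confocal stacks by asking, for every pair of transverse sections,
how similar the two sections are after the best rigid alignment.

The analysis chain is:

1. **Preprocess** (`rescale_isotropic()`, `crop_vnc()`, `bin_and_project()`):
   the stack is made isotropic, cropped to the cord, split into AP bins of
   fixed physical length (default 1.65 μm — eleven planes on a 0.15 μm
   isotropic grid) and each bin is reduced to one transverse section by a
   maximum-intensity projection.
2. **Register and score** (`register_rigid()`, `correlation_score()`): every
   unordered pair of sections is rigidly registered — centre-of-mass
   prealignment, then Nelder–Mead refinement of a mutual-information metric
   (convergence tolerance 1e-6, at most 500 iterations) — and scored by the
   Pearson correlation over the in-field overlap, clipped to [0, 1].
3. **Matrix and traces** (`self_correlation_matrix()`, `detect_nodes()`,
   `extract_trace()`, `align_traces()`, `average_traces()`): scores assemble
   into an n × n matrix whose periodic bands are the segmental repeat. Nodes
   are the prominent maxima of the mean off-diagonal row correlation; the
   profile anchored at each node is the mean of the three rows centred on it
   (diagonal excluded), and profiles are aligned by integer-bin offsets in a
   reference window (default 25–57 μm) before averaging.
4. **Architecture metrics** (`internodal_metrics()`): node positions,
   internodal distances, and the AP offset from each node to the correlation
   minimum of its internode.
5. **Asymmetry statistic** (`spatial_gradient()`, `resample_r()`,
   `test_r_zero()`): the internodal profile is summarised by
   \[ r = \frac{\max(g) - |\min(g)|}{(\max(g) + |\min(g)|)/2}, \]
   where \(g\) is the spatial derivative of the correlation along AP. In the
   wild-type architecture the descent posterior to the node is steeper than
   the recovery, so \(r < 0\); \(|r| \le 2\) always.
6. **Fluorescence quantification** (`integrated_density()`,
   `segment_density()`, `masked_density()`): Fiji-style integrated densities
   over fixed-size ROIs, whole segments, or threshold-defined 3D masks.

## The phantom: known ground truth in place of raw images

No raw embryo stacks ship with the package; instead `generate_phantom()`
renders a synthetic cord whose architecture is known exactly, so that every
pipeline stage can be verified quantitatively end to end. The phantom places
three Gaussian-tube fascicles per hemiside (mirrored about the ML midline)
along AP, with:

* **nodes** every `period` μm at which the tubes pass exactly through their
  anchors;
* a **piecewise-linear dispersion envelope** between nodes: zero at the node,
  rising to `dispersion_amp` at `min_offset` μm posterior to it, then decaying
  linearly to the next node. `dispersion_asymmetry` blends the peak position
  between the internode midpoint (0) and `min_offset` (1);
* **wander directions** forming a zero-sum triad per internode (one random
  orientation, fascicles 120° apart) modulated by a smooth common rotation
  field with ~3 μm knots. This construction is deliberate: magnitudes follow
  the envelope exactly and the vector sum is zero, so rigid registration
  cannot cancel the dispersion by translation, the correlation minimum stays
  pinned at the envelope peak, and sections decorrelate within an internode
  (coherently displaced internodes would otherwise masquerade as nodes);
* **node-enriched intensity** (`node_enrichment` ≥ 1 inside
  `node_halfwidth` windows), PSF blur, then Poisson and Gaussian noise, in
  that order (photon noise before read noise).

Presets encode the three study conditions: `wildtype` (28 μm period, minimum
9 μm posterior, distinct minima), `puc_like` (33 μm period, raised dispersion
with a saturated — "fading" — minimum, stochastic loss of the lateral
fascicle, noisier sections) and `zfh1_like` (33 μm period, symmetric
flattened dispersion). The wild-type `dispersion_amp` (2 μm) is calibrated so
that the internodal correlation minimum (~0.35) stays above its saturation
floor — in the wild-type architecture the minimum is distinct, and only
mutant conditions show it fading;
the mutant presets deliberately exceed it. Absolute intensities are not
calibrated to anything — correlation is scale-free.

What the phantom does *not* emulate: cell bodies, glia, commissures,
photobleaching, embryo-to-embryo anatomical variability beyond the RNG seed,
or tissue deformation. Passing tests therefore demonstrate that the
*measurement chain* recovers a known architecture under realistic blur and
noise; they do not validate biological conclusions about real embryos.

```{r phantom, eval = FALSE}
ph <- generate_phantom(phantom_preset("wildtype", seed = 1))
arch <- node_architecture(ph$volume, bin_length = 1.65)
glance(arch)
autoplot(arch$matrix)
autoplot(arch$mean_trace)
```

## Numerical choices

* **Coordinates.** 0-based voxel indices; the physical position of voxel
  *i* (1-based) is (i − 0.5) · pitch; AP increases anterior → posterior, which
  fixes the sign of "posterior offset".
* **Binning.** The realised bin is `round(bin_length / pitch)` planes; a
  trailing partial bin is dropped, not padded, to avoid a systematically
  dimmer final section.
* **Matrix score.** Correlation matrices are conventionally displayed on a
  0–1 colour scale without a named score; here an entry is the post-registration Pearson
  correlation over the overlap, clipped below at zero. The optimiser's
  mutual-information value is kept as a transform attribute for comparison.
  Undefined pairs (overlap below 50%, or zero variance) are missing values,
  never errors, and never abort a matrix.
* **Registration determinism.** Prealignment is deterministic; the angle is
  seeded from a coarse ±20° sweep because the histogram-MI surface is locally
  flat in rotation; Nelder–Mead is deterministic given its start. Of the
  prealigned and optimised transforms, the one with the better Pearson score
  is returned, so registration never scores below prealignment.
* **Node detection.** In the manual workflow node regions are identified by
  eye; detection here is automated as prominence-filtered maxima
  (default prominence 0.05, separation half the expected period) of the mean
  off-diagonal row correlation. Manual node indices can be passed straight to
  `extract_trace()` to mirror the manual workflow.
* **Trace alignment.** Integer-bin shifts only (sub-bin shifts would
  interpolate scores); candidate shifts must keep at least half the reference
  window covered, and the pipeline bounds shifts at half a period — aligning
  periodic profiles is otherwise degenerate modulo the period.
* **Extremum localisation.** Node positions are plateau centroids (within
  0.02 of the peak): correlation stays near 1 while the dispersion is below
  the tube width, so peaks are locally flat-topped. Internodal minima are
  located by intersecting least-squares lines fitted to the descent and
  recovery limbs, which averages out per-bin noise that would otherwise bias
  a raw argmin into the shallower (posterior) limb. At the 1.65 μm bin
  resolution these estimators carry a residual bias of up to about one bin,
  which is the quoted precision of the recovered metrics.
* **Resampling.** Each replicate draws every trace position from
  N(mean, sd), clipped to [0, 1] since correlations are bounded. The
  "best linear fit" summary of a resampled profile is ambiguous between a
  global fit and per-limb fits; the default splits each internode at its
  minimum and
  fits a line per limb (the finite-difference global-extrema variant is
  available via `method = "finite_diff"`).
* **Testing r against zero.** The conventional choice is a Mann–Whitney
  test; the one-sample analogue implemented as `mann_whitney` compares the
  replicate r values with their sign-flipped mirror. Because both "groups"
  reuse the same draws, the true variance of the U statistic is about twice
  the independent-samples null variance and the test is anti-conservative
  under an exactly symmetric null (empirically ~15% rejection at α = 0.05).
  It remains the default for comparability; `signed_rank` is the calibrated
  one-sample alternative and is the one to use when type-I control matters.
* **Thresholds.** Otsu (single global threshold) by default for cropping,
  VNC length and masks, with a fixed-value override; ROI densities are not
  background-subtracted by default.

## Problem sizes

The bundled analyses run at desk scale: presets generate 6-segment phantoms
at 0.55 μm isotropic voxels (three planes per 1.65 μm bin, exactly the
reference bin arithmetic), giving roughly 100 AP bins and ~5,000 registered
pairs per matrix — a few minutes on one core. Unit tests use 3–4 segment
phantoms at 0.8–1.1 μm voxels. The measured-data calibration of the original
workflow (0.15 μm isotropic, 50 bins of eleven planes) is supported
unchanged; only the phantom sizes are reduced.

## Known limitations

* Rigid in-plane registration only (translation + rotation); no deformable
  model, no 3D volumetric registration, no multi-resolution pyramid.
* Hemisegment-wise and full-width matrices answer slightly different
  questions; both are supported (`hemiside` argument), full width being
  the default.
* The r statistic's sign convention is fixed by this package's axis
  convention (posterior-steeper ⇒ r < 0); only |r| and difference-from-zero
  should be compared across conventions.
* Integrated densities follow the Fiji IntDen convention (sum × pixel area);
  no flat-field or background correction is applied.
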