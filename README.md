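# vncorr

Spatial 3D correlation analysis of segmental axon architecture in the
embryonic *Drosophila* ventral nerve cord (VNC).

The VNC's longitudinal connectives — Fasciclin 2-positive fascicles organised
in three compact units per hemiside — are compacted once per segment at
stereotyped *3D nodes* and disperse between them. `vncorr` measures this
architecture from calibrated confocal stacks: it bins the
anterior–posterior (AP) axis into fixed-length transverse sections, rigidly
registers every pair of sections (centre-of-mass prealignment, then a
mutual-information optimiser with tolerance 1e-6 and at most 500 iterations)
and scores each registered pair by its Pearson correlation on a 0–1 scale.
The resulting self-cross-correlation matrix exposes the segmental repeat;
from it the package detects nodes, extracts node-anchored correlation traces,
and measures:

* **internodal distance** — AP spacing of successive nodes (wild-type: 28 μm);
* **node → minimum offset** — AP distance from a node to its internode's
  correlation minimum, measured posteriorly (wild-type: 9 μm);
* **the asymmetry statistic** of the internodal profile,

  r = (max(g) − |min(g)|) / ((max(g) + |min(g)|) / 2),

  where g is the spatial derivative of the correlation along AP, estimated by
  a 500-replicate in-silico resampling of the averaged trace and tested
  against zero (Mann–Whitney-style mirror test or one-sample signed-rank);
* **integrated fluorescence densities** (Fiji IntDen convention) over
  fixed-size node/internode ROIs, whole segments, or threshold-defined 3D
  masks, plus VNC length.

No raw embryo stacks are bundled; instead the package
includes a first-class synthetic phantom generator (`generate_phantom()`)
that renders VNC-like stacks with known ground truth — periodic nodes,
asymmetric internodal dispersion, node-enriched intensity, PSF blur, Poisson
and Gaussian noise — so the whole pipeline is verifiable quantitatively.
Presets encode the wild-type and two mutant-like architectures.

## Worked example

```r
library(vncorr)

ph   <- generate_phantom(phantom_preset("wildtype", seed = 1))
arch <- node_architecture(ph$volume, bin_length = 1.65)
arch
#> <vnc_architecture> 6 nodes over 101 AP bins
#> <node_metrics> 6 nodes; mean internodal distance 27.86 μm; mean node-to-minimum offset 10.09 μm
glance(arch)
#> # A tibble: 1 × 4
#>   n_nodes mean_internodal_distance sd_internodal_distance mean_node_to_min_offset
#>     <int>                    <dbl>                  <dbl>                   <dbl>
#> 1       6                     27.9                  0.700                    10.1
```

The phantom planted nodes 28 μm apart with the dispersion maximum 9 μm
posterior to each node; the pipeline recovers one node per segment, a
27.9 μm mean internodal distance and a 10.1 μm posterior offset — both within
one 1.65 μm bin of the planted values, which is the method's grid resolution.
`autoplot(arch$matrix)` draws the 0–1 correlation heatmap,
`autoplot(arch$mean_trace)` the averaged trace with green node bars, and

```r
st <- resample_r(arch$mean_trace, n_reps = 500, seed = 7)
st
#> <gradient_stats> r = -0.566 (500 reps, limb_fit), max grad 0.0355, min grad -0.0636 /μm, p = 5.86e-165 (mann_whitney)
```

returns the resampled asymmetry statistic: the negative r reflects the
steep posterior descent of the internodal profile (its magnitude depends on
the mirror-test caveat discussed in the vignette; `test = "signed_rank"`
gives the calibrated one-sample p-value).

A thin command-line front end is installed at `inst/cli/vncorr`
(`generate`, `correlate`, `nodes`, `asymmetry`, `density` subcommands).

## Package tour

| Stage | Functions |
|---|---|
| Phantom | `phantom_params()`, `phantom_preset()`, `generate_phantom()`, `expected_trace()` |
| I/O & preprocessing | `read_stack()`, `write_stack()`, `rescale_isotropic()`, `crop_vnc()`, `split_hemisegment()`, `bin_and_project()`, `vnc_length()` |
| Registration | `reg_options()`, `com_prealign()`, `register_rigid()`, `correlation_score()` |
| Matrices | `self_correlation_matrix()`, `cross_correlation_matrix()`, `write_corr_matrix()` |
| Traces & metrics | `detect_nodes()`, `extract_trace()`, `align_traces()`, `average_traces()`, `internodal_metrics()` |
| Asymmetry | `spatial_gradient()`, `asymmetry_r()`, `resample_r()`, `test_r_zero()` |
| Quantification | `project_ventral()`, `roi_spec()`, `integrated_density()`, `segment_density()`, `masked_density()`, `normalize_to_reference()` |
| Pipeline | `node_architecture()`, with `tidy()`/`glance()`/`autoplot()` methods throughout |

The methods vignette (`vignettes/vnc-spatial-correlation.Rmd`) documents the
model, the phantom's design and its limits, and every numerical choice.
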