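---
title: "Methods: group morphometry, TFCE inference, and structural covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group morphometry, TFCE inference, and structural covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package computes

`ctcov` implements a two-part gray-matter analysis for case–control studies
of substance use disorders (or any grouped morphometry study):

1. **Element-wise group morphometry.** Per-subject scalar fields — cortical
   thickness in mm on a surface mesh, or gray-matter volume on a masked
   voxel lattice — are compared between groups with a full-factorial
   general linear model, and inference uses threshold-free cluster
   enhancement (TFCE) with max-statistic permutation family-wise error
   (FWE) control. A parallel parcel-level ("ROI") analysis tests mean
   thickness per parcel with Benjamini–Hochberg FDR control.
2. **System-level mapping.** Significant thinning patterns are mapped onto
   intrinsic connectivity networks (ICNs): parcels carry Yeo-style network
   labels and are counted per network family; structural covariance seed
   maps are built from group correlation matrices seeded at the thinning
   peaks; and their concordance with functional network templates is
   quantified as an overlap percentage.

Because clinical MRI datasets of this kind are typically access-restricted,
the package ships a synthetic cohort generator with the same statistical
structure, so the full pipeline is exercised and validated end-to-end in
code.

# The data model

A **domain** is the discretized spatial support: a subdivided icosahedral
sphere (`build_mesh_domain`, `10 * 4^level + 2` vertices) standing in for a
registered average cortical surface, or the in-mask voxels of a lattice
with 6-connectivity (`build_lattice_domain`). The element adjacency is the
single structure both smoothing and TFCE operate on, so the two modes are
interchangeable everywhere downstream. Element ids are 0-based and
contiguous in all on-disk TSV formats; in-memory R objects use 1-based
indices.

A **parcellation** assigns every element to one of K parcels (K = 200 in
the Schaefer-style convention; synthetic runs here default to K = 50, see
*Problem sizes*). Parcel names follow the
`<NETWORK><subnetwork>_<Region>_<index>` dialect, e.g.
`"SAL/VANb_Insula_2"`; `parse_label()` maps a name to its network and
network family (DMN, ECN, SAL/VAN, DAN, SMN, Limbic, TemporoParietal,
Visual) and round-trips through `format_label()`. Both the
`"Temporparietal"` spelling that appears in printed parcel tables and the
regular `"Temporoparietal"` are accepted.

# Smoothing

Surface-based pipelines smooth thickness with a Gaussian kernel (12 mm
FWHM is conventional for thickness, 8 mm for volume). Geometry-faithful
heat-kernel smoothing on a real cortical mesh is out of scope here; what
the statistics need is *controllable smoothness*. `smooth_field()`
therefore applies iterated symmetric neighbor averaging with the operator

$$ W = I - \frac{1}{2\,d_{\max}} L, $$

where $L$ is the graph Laplacian and $d_{\max}$ the maximum degree. $W$ is
symmetric and doubly stochastic, so the field mean is preserved *exactly*
and the spectrum lies in $[0, 1]$, so variance never increases. On a path
graph $W$ is the classical $(\tfrac14, \tfrac12, \tfrac14)$ stencil. One
iteration adds impulse-response variance $\approx \ell^2/2$ for mean edge
length $\ell$, so the iteration count for a requested FWHM is
$t = \lceil 2(\mathrm{FWHM}/2.3548)^2/\ell^2 \rceil$. The empirical FWHM of
the impulse response tracks the request to within a discretization error
of order one edge length; at the coarse default mesh (about 12 mm edges)
a 12 mm kernel is a single iteration.

# The group model

The design is a cell-means ("full factorial") coding: one column per group
plus mean-centered nuisance covariates, with a single pooled error
variance per element ($\sigma^2$ estimated from all rows of the design —
the simplest model consistent with a four-group factorial; per-pair
variance pooling is a documented alternative we did not take). Age is
always a covariate for thickness; TIV is added only in volume mode,
because thickness does not scale linearly with head size; sex and
education are never modeled. Contrasts are
$t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top (X^\top X)^{-1} c}$,
which on a covariate-free two-group design reduces to the classic pooled
two-sample t — the closed form the test suite checks to 1e-10.

# TFCE and permutation FWE

The enhanced statistic integrates component extent and height over all
supra-threshold levels on the grid $h_k = k\,\mathrm{d}h$:

$$ \mathrm{TFCE}(p) = \sum_{k\,:\,h_k \le t(p)} e(h_k, p)^{E}\, h_k^{H}\,
   \mathrm{d}h, $$

with defaults $E = 0.5$, $H = 2$ — the standard TFCE parameterization used
by the common neuroimaging toolboxes; they are explicit configuration, not
constants, because published analyses rarely print them. The step defaults
to $\max|t|/100$ and is recorded in the result. Negative values are
enhanced on the negated map and returned with negative sign. The
implementation sweeps thresholds from the top with an incremental
union-find (Rcpp); its *correctness criterion* is an independent
brute-force oracle that recomputes connected components from scratch at
every threshold, to which it is compared on random graphs at 1e-9 relative
tolerance.

FWE inference permutes under the Freedman–Lane scheme: the nuisance-only
model (intercept + covariates) is fitted, its residual rows permuted, the
nuisance fit re-added, and the full-model contrast t-map enhanced; the
image-wide maximum forms the null distribution, and

$$ p_{\mathrm{FWE}}(p) = \frac{1 + \#\{b : \max_b \ge
   \mathrm{TFCE}_{\mathrm{obs}}(p)\}}{n_{\mathrm{perm}} + 1}. $$

With no covariates the reduced model is the intercept alone, which for
contrast statistics is equivalent to plain label permutation, so one code
path serves both cases. P-values are therefore multiples of
$1/(n_\mathrm{perm}+1)$ and bounded below by it. Group contrasts default
to a one-sided (positive) tail because directional hypotheses
(controls > patients) are the norm in this design; `tail = "both"` uses
the maximum absolute enhanced value.

# Parcel-level tests and network bookkeeping

`parcel_means()` averages the *unsmoothed* fields per parcel (mirroring
the convention of extracting ROI values in native space before smoothing),
`roi_group_test()` applies the same contrast machinery with one-sided
p-values and BH-FDR at q = 0.01, and `network_summary()` counts
significant parcels by network family and hemisphere. Deduplication by
(name, hemisphere) is exposed because published label tables can list the
same parcel under several headings; with it, the bundled thinning-label
table yields family counts DMN 9, ECN 8, SAL/VAN 6 over the union of the
"common" and "AUD-exclusive" sets.

# Structural covariance and concordance

For a group's subjects: subtract each subject's mean parcel value (this
removes global thickness — and, in the synthetic model, exactly the
subject-level intercept), residualize each parcel against age, and
correlate parcels across subjects. Seeds are the parcels containing the
peak enhanced vertices of the significant clusters, one per cluster, ties
broken toward the lowest element id. A seed map collects every other
parcel with a *positive* correlation significant at uncorrected p < 0.05,
one-sided — one-sided because the procedure selects positive covariance
partners; no multiplicity correction is applied at this step, matching
standard practice for these exploratory maps. The seed parcel itself is
excluded from the member list but included when the map is rendered to
elements.

Concordance renders the covariance map to elements via the parcellation
(because the comparison is between voxel/vertex counts), thresholds the
functional template at r > 0.2 (strict inequality), and reports
$100\,|A \cap B| / |\mathrm{ref}|$ with the smaller map as the 100%
reference, alongside the symmetric Dice coefficient.

# The synthetic cohort generator

The generator's defaults *are* the study conditions the pipeline is
designed for: groups CON/PSU/AUD/OUD of sizes 21/21/65/27; control mean
thickness 2.52 mm with between-subject SD 0.07 mm; group ages (mean, SD)
of (45.3, 8.3), (43.7, 11.1), (41.8, 9.5), (45.6, 11.9) years; TIV
1493 (106) cm³; BIS-11 impulsivity scores per group; and an age slope of
−0.005 mm/year, a typical magnitude for adult cortical thinning, applied
relative to the cohort mean age.

Thickness decomposes as baseline + age term + planted group effects + a
subject-level global intercept + spatially smoothed noise:

- **Group effects** are planted at parcel granularity (a thinning in mm on
  listed parcels for a listed group) so that recovery tests have
  unambiguous ground truth.
- **Noise** is element-wise i.i.d. Gaussian (SD 0.25 mm before smoothing),
  smoothed by `smooth_field` to 12 mm FWHM — the simplest model with
  controllable spatial autocorrelation, which is what TFCE's behavior
  depends on — then mean-centered within subject.
- **The subject intercept's** SD is calibrated so that the SD of control
  subject-mean thickness equals 0.07 mm after accounting for the age
  slope; because the spatial noise is mean-centered per subject, the
  calibration is exact in expectation.
- An optional **latent factor** adds a shared subject-level loading on one
  network family's parcels, giving structural covariance a recoverable
  target: after subject centering, parcels of that family co-vary
  positively while others anti-correlate with them, which is exactly the
  structure seed maps should detect.

Functional templates (the stand-in for seed-correlation maps from large
resting-state samples) are per-family indicator maps at level 0.6 plus
N(0, 0.01) noise, clipped to [−1, 1]; thresholding at r > 0.2 recovers the
family's parcels with a wide margin.

What the generator does *not* emulate: cortical folding geometry,
scanner/site effects, spatially varying noise, non-Gaussian thickness
distributions, or correlated covariates (e.g. age–group confounding).
Passing recovery tests therefore demonstrate the statistical machinery is
correct and calibrated under its stated assumptions — not that effect
sizes of real cohorts will be recovered at these rates.

# Numerical and design choices

- TFCE thresholds use a fixed grid `h_k = k dh`; the observed map fixes
  `dh` so that observed and permuted maps are enhanced on the same grid.
- The diffusion smoother guarantees exact mean preservation; tests assert
  it to 1e-10 relative.
- Ties at cluster peaks resolve to the lowest element id; equal-size maps
  resolve the "smaller" overlap reference to the first argument.
- Degenerate inputs error early with specific messages: empty masks,
  rank-deficient designs, constant covariates, zero-variance scores,
  empty parcels, empty reference maps, too-few subjects for correlation
  tests.
- Zero-variance parcels in a covariance matrix are flagged (`undefined`)
  rather than silently propagated.
- All randomness flows through explicit `rng_seed` arguments; the
  pipeline derives stage seeds from the global seed by fixed offsets
  (parcellation +11, cohort +23, templates +77, inference +100+i), so
  whole runs are byte-identical under a fixed config.

# Problem sizes

The package's own validation runs at a deliberately desk-sized scale: a
level-3 mesh (642 vertices), K = 50 parcels, 200-permutation inference for
calibration studies (200 null cohorts), and 20-seed recovery studies. The
pipeline default of 500 permutations (`pipeline_config`) is a scaled-down
stand-in for the 10,000-permutation convention of production analyses; all
of these are configuration, and the code paths are identical at full
scale.

# Known limitations

- The surface smoother matches a Gaussian kernel only to first order in
  edge length; on very coarse meshes a requested FWHM below one edge
  length collapses to a single averaging iteration.
- The icosphere stand-in has near-uniform vertex density; real registered
  surfaces do not, and parcel sizes here are more homogeneous than real
  parcellations.
- Seed-map significance is uncorrected by design; members near the
  alpha boundary are unstable under resampling.
- Volume mode shares all statistical machinery but the bundled generator
  produces surface cohorts; lattice cohorts can be simulated by passing a
  lattice domain and its parcellation.
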