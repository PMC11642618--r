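---
title: "finmorph: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{finmorph: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`finmorph` implements a standardized measurement and reporting workflow for
X-ray/μCT skeletal phenotyping of zebrafish and other small laboratory
fishes. This vignette explains the underlying models, the conventions the
package fixes where the field's practice is ambiguous, the tunable
parameters and their defaults, what the synthetic generators do and do not
emulate, and the known limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate and unit conventions

A `voxel_grid` is a 3D array of isotropic cubic voxels. Array dimension 1
runs cranial→caudal, dimension 2 dorsal→ventral, dimension 3 left→right.
Files carry no anatomical orientation (vendors differ), so the orientation
of an imported volume is the user's assertion; projections are exported
anterior-left, dorsal-up, the display convention of the field. Coordinates
are voxel-center based and zero-based: position (μm) = index₀ × voxel size.
Anisotropic volumes are rejected rather than resampled, because every
thickness and volume definition below assumes one edge length. Densities
are reported in mg HA/cm³ throughout (unit conversion happens at I/O via
`normalize_units()`), lengths in μm, standard length in mm.

## Density calibration

μCT gray values are mapped to attenuation-equivalent hydroxyapatite
concentration by an affine model

    density [mg HA/cm³] = slope · raw + intercept,

fitted by ordinary least squares to at least two calcium-hydroxyapatite
phantoms scanned with the same parameters as the specimens. Two phantoms
(the conventional 250/750 mg HA/cm³ pair) determine the line exactly; more
phantoms give a genuine regression and an informative r². The affine form
is the package's choice — routine μCT practice, and the minimum phantom
count of two implies a line; no beam-energy-dependent or medium-dependent
correction is modeled (the scanning medium is reported as metadata only,
since no correction model is established).

Calibrated values are *not* clamped at zero: dehydrated soft tissue or
trapped air legitimately produce negative attenuation-equivalent densities,
and clamping would hide a quality problem. Negative BMD is instead flagged.

For 2D radiographs only relative areal density is possible; the package
maps ROI mean gray values through an aluminum step-wedge line and labels
the result "relative", in mm Al equivalent. It is never expressed in
mg HA/cm³.

## BMD, TMD, BV/TV

* **BMD** is the mean calibrated value over *all* voxels of the ROI — bone
  and soft tissue alike. The ROI volume is the denominator, so BMD is an
  ROI-dependent quantity; a smaller ROI around the same bone gives a higher
  BMD. This is why the reporting standard requires the ROI description.
* **TMD** is the same mean restricted to segmented bone voxels. Enlarging
  the ROI by sub-threshold voxels leaves TMD unchanged.
* **BV/TV** is the bone voxel count over the ROI voxel count (volumes are
  count × h³).

These satisfy the exact decomposition

    BMD = BV/TV · TMD + (1 − BV/TV) · mean(non-bone ROI voxels),

which `density_report()` asserts at 1e-9 relative tolerance on every call —
an internal consistency check, and a property test quantified over
randomized grids in the suite.

No partial-volume correction is applied: a voxel containing both bone and
soft tissue contributes its mixed value. The bias this causes at bone
boundaries is real and acknowledged; the mitigation is scan resolution (see
the voxel-adequacy rule), not post-hoc correction.

## Segmentation and thresholding

ROIs rasterize by voxel-center inclusion (boundary inclusive); contour ROIs
fill per-slice simple polygons by the even-odd rule at voxel centers.
Thresholds are **inclusive** (`value ≥ t`): the convention had to be fixed
for reproducibility and is asserted by tests. Global thresholds are
expressed in mg HA/cm³ on calibrated volumes only. The specimen-specific
("auto") threshold is Otsu's 256-bin between-class-variance maximizer over
the ROI histogram — chosen as the canonical parameter-free method, since
published fish work names "semi-automatic algorithms" without specifying
one. When the histogram has an empty gap between modes, the maximal
between-class variance is a plateau; the package takes the plateau's middle
bin so the threshold falls centrally between the modes. The chosen
threshold is always printed, satisfying the reporting rule.

Multiplexed (bulk) scans acquired in air are separated by thresholding the
tissue envelope and labelling 26-connected components (26-connectivity
avoids splitting thin diagonal bone bridges); components below a volume
floor are discarded and the rest are returned ordered left→right. If fewer
components than expected are found the bodies have likely merged, which is
a warning, not an error.

Two QC rules: `qc_voxel_ratio()` implements the minimum recommended
feature-size/voxel-size ratio of two (inclusive at exactly 2);
`qc_cupping()` fits annulus means against (r/R)² in a nominally uniform
cylinder and reports the fitted center/edge ratio, flagging |1 − ratio|
beyond a tolerance (default 0.05). The signed ratio is returned so both
polarities of radial artifact are visible.

## Local thickness

Structure thickness follows the maximal-inscribed-sphere model: each bone
voxel is assigned the diameter of the largest sphere that fits inside the
structure and contains it, and the structure's thickness is the unweighted
mean of this map over bone voxels (each voxel counts once; the definition
in the literature does not specify a weighting, so the simplest one is
fixed here).

Implementation: an exact Euclidean distance transform gives each bone voxel
its distance r(q) to the nearest background voxel center (the grid is
padded by one background layer, so structures touching the volume edge stay
finite — a choice that errs toward underestimating thickness at the field
of view boundary). Sphere painting then propagates
`max { r(q) : |p − q| ≤ r(q) }` to every covered voxel p; squared distances
are integers, so coverage decisions are exact. The reported diameter is

    thickness(p) = (2 · max r − 0.5) · h.

The half-voxel diameter correction is a deliberate calibration of the
discrete estimator, decided by measurement during development: distances
run center-to-center, so the raw model overestimates — a wall of an odd
number of voxels reads one voxel too thick while even widths read exactly,
a +0.5 voxel bias on average that is substantial for the 3–8-voxel walls
typical at recommended resolutions. Subtracting a full voxel (the
"distance to the boundary face" model) symmetrically *under*-estimates
curved shells and digital balls by 5–15%. The half-voxel correction
centers the estimator; the residual ±0.3 voxel lattice oscillation is
inherent to voxelized shells. Consequences the tests pin down: digital
balls of diameter ≥ 11 voxels measure within 5% of truth, and an isolated
one-voxel plate reads 1.5 voxels — the model's documented bias at the
thinnest scale, which is one reason the adequacy rule demands features of
at least 2 (preferably ≥ 3) voxels. An exhaustive brute-force
sphere-search oracle implementing the same model verifies the
transform+painting path exactly on all masks up to 12³ in the suite.

## The vertebral measurement suite

Landmark-based measures (lengths, angles, canal areas) are computed from
user-supplied points (CSV; automatic atlas-based landmarking is out of
scope). Angles are undirected, in (0°, 180°], via the arccosine of the
normalized dot product — the figures in common use do not disambiguate
reflex angles, so the package fixes the convention. Canal areas project
the polygon onto its best-fit plane (SVD) and apply the shoelace formula;
non-coplanar or self-intersecting polygons are rejected rather than
silently projected. Centrum radius is available both as half the centrum
height (the standard approximation, tagged "approximated") and as a direct
canal-center→endplate distance (tagged "landmark").

One deliberate unit decision: centrum thickness is a length and is reported
in μm, consistent with every other thickness measure, even though one
printed table in circulation gives μm² for it — treated as a typo.

Vertebral volume VV and whole-vertebra thickness V.Th are computed on the
union of the element masks; CTV (centrum total volume, including soft
tissue and surrounding bone) requires an explicit ROI because the
convention does not say whether it is a convex hull or a fitted cylinder —
the package records whatever ROI the user supplies rather than guessing.
Fields whose inputs are missing are absent from the record (with a log
message), not errors, so partial analyses remain representable.

Trabecular indices (trabecular number/separation, connectivity density,
structure model index) are intentionally not implemented: zebrafish bone
is predominantly compact and these measures are considered uninterpretable
for it.

## Axial atlas

The default atlas encodes the modal wild-type column of 31 vertebrae:
Weberian v1–v4, abdominal (synonym "precaudal") v5–v14, transitional v15,
caudal v16–v29, caudal-fin v30–v31. The printed modal composition
"4 + 10 + 14 + 3 = 31" and the per-region ranges cannot both be read as a
partition — they overlap at v29, because the most posterior caudal
vertebra is also modified to support the fin. The package resolves this by
keeping the region ranges non-overlapping (every index maps to exactly one
region) and exposing the fin-supporting range v29–v31 separately via
`supports_caudal_fin()`, whose modal count is 3. Custom atlases take
per-region counts literally, in canonical order, warning when the
transitional count differs from the typical 1. The 32 skull bones
recognizable on μCT are shipped as an ordered label list, in the
spelling of the anatomical source nomenclature.

## Allometric normalization

Growing fish confound developmental stage with size, and μCT measures
scale with standard length (SL) approximately as a power law
y = c·SL^α. `normalize_by_length()` divides by SL^α (α = 1 is plain SL
division); `fit_power_law()` estimates α by ordinary least squares in
log-log space — the power-law form is established usage, the estimator is
the package's choice (robust variants out of scope). A negative fitted α
(e.g. neural arch angle, which decreases with SL) triggers a warning when
SL division is requested, since dividing by SL is then counterproductive.
The choice between plain SL, power-law, or an alternative covariate
(orbit diameter, for "stumpy" growth mutants where SL no longer stages the
fish) is left to the user and recorded, because no decision threshold is
established.

## Synthetic generators: what they emulate, and what they do not

Every generator is a pure function of its spec and seed (bit-reproducible),
and every geometric parameter has a closed-form ground truth, so measured
vs. true comparisons are exact science, not snapshot tests.

The **vertebra phantom** idealizes an amphicoelous vertebra as a hollow
tube (the centrum: outer radius CH/2, wall `wall_um`) whose endplates flare
outward via a linear taper of both radii (the radial wall is constant, so
the thickness truth is the wall scaled by the taper cosine over the flared
fraction); neural and haemal arches are pairs of capsule struts meeting at
a spine tip placed to realize the specified arch angle against the
cranial-caudal axis. Defaults follow reported adult zebrafish values:
wall and strut thickness 60 μm (reported range 50–80 μm), bone density
500 mg HA/cm³ (reported TMD range 400–600), centrum length 500 μm, height
400 μm, arch angles 110°, voxel size 10 μm. Rasterization averages
occupancy over `supersampling`³ sub-samples per voxel (default 2), giving
partial-volume values `occ·bone + (1−occ)·soft`; the bone mask is
occupancy ≥ 0.5 and a separate `core` mask holds fully-interior voxels.
TMD equals the nominal bone density exactly on the core mask; on the full
bone mask it is lower because rim voxels are partial-volume mixtures —
which is the real phenomenon, reproduced rather than corrected.

The phantom is amphicoelous only in silhouette: no biconcave endplate
cones, no trabecular-like plates, no ribs, no notochord remnants. Noise is
additive Gaussian on values (a detector-noise proxy; Poisson photon
statistics and reconstruction streaks are not modeled). Cupping is a
multiplicative radial field `1 − γ(1 − (r/R)²)` — a descriptive model of
the artifact's shape, not a polychromatic beam simulation; by
construction `qc_cupping()` on a uniform cylinder then reports a
center/edge ratio of 1 − γ. A green phantom-recovery test therefore
establishes that the measurement chain is unbiased on clean, known
geometry at adequate resolution — not that it is robust to motion
artifacts, streaks, or anatomy the phantom lacks.

**Density phantoms** are uniform cylindrical rods at the raw values
implied by inverting the target calibration — uniform interiors, no
partial-volume rim — so a noiseless two-phantom fit must recover the line
to machine precision (and does, as a test). **Multiplex arrays** place
ellipsoidal soft-tissue bodies with embedded dense sphere chains
equidistant from the scan center (the mounting recommendation) on an air
background, sized so component separation is unambiguous at the default
spacing.

## Reporting compliance

The two manifest schemas mirror the minimal reporting tables row by row
(each schema entry records the table row it represents; a test asserts the
counts). All rows are required for a passing report; `--lenient` demotes
the strain/sex/controls rows to warnings. Conditional rows apply only when
triggered (filter type only if filtering was used; multiplexed count only
if multiplexing; BMD ROI description only if BMD is examined; landmark or
segmentation details only for the modes actually used). The bundled 2D
detector row ("detector size and megapixel count") is kept as one
free-text field. Completeness is the fraction of required rows present and
well-typed for the declared modality. Unit normalization converts reported
strings to the canonical units (kV, μA, ms, s, μm, mm, cm, mg HA/cm³) and
round-trips exactly.

## Numerical choices, degeneracies, tolerances

* Threshold comparison: inclusive (≥). Voxel-center ROI inclusion:
  boundary inclusive. Adequacy ratio: inclusive at 2.
* Otsu: 256 bins; plateau tie-break at the middle bin.
* Connected components: 26-neighborhood.
* Coplanarity tolerance for canal polygons: singular value ≤ 1e-6 of the
  polygon extent. Parallel arch segments: angle 0 with a degeneracy
  warning, not an error.
* Decomposition identity: 1e-9 relative. NRRD round-trip: bit-exact values,
  spacing to 1e-9 relative. Header/argument voxel-size disagreement beyond
  1e-6 relative is an error.
* Two-phantom calibration r² is reported as exactly 1 (the line
  interpolates); duplicate densities, zero raw spread, and single phantoms
  are errors.
* Empty bone mask after thresholding is a warning (the report carries an
  NA TMD and a flag); an empty ROI is an error.

## Known limitations

* No DICOM or vendor formats; NRRD and baseline uncompressed TIFF only,
  with minimal readers implemented in-package (validated against an
  independent reader in development).
* Storage orientation cannot be inferred; the user asserts it.
* Thickness at 1–2 voxel scales carries the documented discretization
  bias; the package reports it rather than resampling.
* Areal BMD from radiographs is relative by construction; no 2D-to-3D
  inference is attempted.
* No medium- or energy-dependent calibration correction; no motion
  artifact detection (visual inspection remains the recommendation).
* The atlas ships zebrafish defaults only; other species are supported
  through custom atlases but without shipped compositions.
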