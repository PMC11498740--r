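---
title: "Metric landmarks from a sphere of oriented photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric landmarks from a sphere of oriented photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbimetry)
```

## The measurement problem

Pinned insects and similar small specimens resist mesh-based 3D
digitization: structured-light scanners smooth away setae and thin
wing membranes, and photogrammetric meshes drop the finest structures
even when the photographs themselves resolve them. An alternative is
to keep the photographs and skip the mesh. A motorized rig photographs
the specimen from a dense, approximately spherical set of viewpoints;
a bundle adjustment (run upstream, in a photogrammetry suite) recovers
each camera's intrinsic and extrinsic parameters. Against those
oriented images one can click a landmark in two or more views,
back-project each click to a 3D ray, and intersect the rays: the
result is a metric 3D landmark without any surface reconstruction.
`orbimetry` implements this computational core and the statistics used
to compare such measurements against a reference modality such as
micro-CT.

## Camera model

Each view is a pinhole camera with Brown–Conrady lens distortion. A
pose maps world to camera coordinates, $X_c = RX + t$, so the optical
center is $C = -R^\top t$; the camera frame is right-handed with $+z$
forward and $y$ down, and pixel coordinates are 0-based with origin at
the top-left corner. Projection divides by depth, applies the radial
$(1 + k_1 r^2 + k_2 r^4 + k_3 r^6)$ and tangential $(p_1, p_2)$ terms
on normalized coordinates, then maps through the focal lengths and
principal point. All five distortion coefficients default to zero;
files that omit them describe an ideal pinhole. These conventions
match the common photogrammetry export format, and the
`import_calibration()` dialect flag converts camera-to-world exports
on the way in.

Back-projection inverts this pipeline. The only non-trivial step is
undistortion, solved by fixed-point iteration starting from the
distorted value, with tolerance $10^{-10}$ and a 100-iteration cap.
For the moderate coefficients of real lenses the iteration contracts
strongly (the round-trip tests reproject to well below $10^{-6}$ px);
the cap only triggers for pathological coefficients, and then the
error is raised rather than returning a bad ray.

## Triangulation

A landmark observed in $n \ge 2$ views yields rays with origins $o_i$
and unit directions $d_i$. The landmark estimate is the point
minimizing the sum of squared perpendicular distances to all rays,
obtained in closed form from the $3 \times 3$ normal system

$$\sum_i (I - d_i d_i^\top)\, x = \sum_i (I - d_i d_i^\top)\, o_i .$$

This "closest point to all rays" formulation is what sphere-of-images
measurement tools describe, and it is symmetric in the rays: view
order never changes the result, and all views carry equal weight (no
per-view weighting information is available from a click). The system
matrix is rank-deficient when all rays are parallel; we reject the
solve whenever its smallest eigenvalue falls below $10^{-9}$ times the
largest, a conservative cutoff for double precision. An optional
Gauss–Newton refinement of the pixel reprojection error (at most 20
iterations) is available behind `refine = TRUE`; it is off by default
so that the default output is exactly the linear least-squares point,
and on realistic geometry the two agree to well under the pixel noise
floor. Quality is reported as the RMS reprojection error in pixels.

## Scale and measurement

Bundle adjustment fixes geometry only up to scale. A calibration token
of known size — the packaged defaults assume a hexagonal bead whose
reference points are 6.69 mm apart — is landmarked like any other
feature; `calibrate_scale()` sets $s = \text{known mm} / \text{model
distance}$ and rescales every landmark. Internally all arithmetic is
carried at full double precision; rounding to 0.01 mm (the precision
of a digital caliper) happens only at the reporting layer, with ties
rounded away from zero so exported tables are bit-stable. Rounding
earlier would corrupt downstream statistics that are computed from the
measured values.

## View navigation

The pseudo-3D viewer semantics reduce to nearest-neighbor retrieval
on the unit sphere: the sphere center is the centroid of the camera
centers (the acquisition is near-uniform, so the centroid is a robust
center estimate), each camera is a unit direction from that center,
and a query direction returns the camera with the maximum dot product.
Ties break to the lexicographically smallest camera id so regression
output is deterministic. Six named standard views (frontal, posterior,
superior, inferior, left/right lateral) can be bookmarked per project.

## Comparison statistics

To compare measurement techniques, each inter-landmark distance is
measured in replicate (three times by each of two operators in the
packaged tables) and summarized on the percent scale against a
reference technique, conventionally micro-CT:

- difference to reference:
  $100\,(\overline{x}_{tech} - \overline{x}_{ref}) / \overline{x}_{ref}$;
- inter-operator difference:
  $100\,(\overline{x}_A - \overline{x}_B) / \overline{x}_B$;
- dispersion: $100\,(\max - \min) / \text{mean}$ over the pooled
  replicates of both operators.

Per-specimen aggregates average the signed differences over distances;
the global summary pools every (specimen, distance, operator) cell of
a technique into a cumulated absolute difference and its mean. For
long repeatability runs, `repeatability_summary()` reports the mean,
the sample (n−1) standard deviation, the signed difference of means to
the reference run, the dispersion, and a 95% interval
$\bar x \pm t_{0.975,\,n-1}\, s$. The $t$-based interval describes
where individual repeated measurements fall; it reproduces the
intervals such comparison studies print, where a normal-quantile
standard-error interval does not.

```{r stats}
meas <- read_measurements_csv(orbimetry_example("landmark_measurements.csv"))
global_absolute_summary(meas, "multiview")
aggregate_differences(meas, "Eupholus", "multiview")
```

The packaged fixture tables are replicate values transcribed at
printed precision (0.01 mm). Statistics recomputed from them therefore
match a source computed from unrounded raw data only to about
±0.01 on the printed scale, which is the tolerance the reproduction
tests use; a handful of published summary cells (one repeatability
difference and some pooled dispersions) are not recomputable from
rounded inputs at all, and the tests assert only the recomputable
cells.

## The synthetic scene generator

Validation never requires real imagery. `generate_scene()` builds a
virtual acquisition with known ground truth: cameras on a Fibonacci
lattice over the sphere (antipodally paired for even counts, so the
centroid of the camera centers is the sphere center to machine
precision), all posed to look at the origin; landmark points sampled
in an ellipsoidal specimen volume; a token pair separated by exactly
the requested physical distance; and observations formed by
projecting every point into every camera that sees it in-frame, plus
optional isotropic Gaussian pixel noise. Defaults describe a full
acquisition: 180 views at radius 10 model units around a specimen of
extent 1 unit (5 mm per model unit, i.e. a centimetre-scale insect),
a 20 Mpx-class sensor with a long lens and mild radial distortion,
and a 6.69 mm token. The generator is deterministic in its spec,
seed included.

What the generator emulates is the *geometry* of an acquisition. It
does not render images, so it cannot model human clicking behaviour,
focus-stacking distortion, blur-dependent localization error, or
correlated residuals from an imperfect bundle adjustment — its noise
is i.i.d. Gaussian in pixel coordinates. Passing tests therefore
demonstrate that the geometric pipeline is correct and
well-conditioned, not that any particular hardware reaches a given
accuracy on real specimens.

```{r scene}
scn <- generate_scene(scene_spec(n_cameras = 30, n_points = 8,
                                 pixel_noise_sigma = 0.5, seed = 1))
recovery_report(scn$project, scn$ground_truth)$summary
```

## Numerical choices and test problem sizes

- Project JSON is written with 17 significant digits, so a
  write–read round trip reproduces every double exactly.
- Undistortion: fixed point, tol $10^{-10}$, cap 100 iterations.
- Triangulation degeneracy: relative eigenvalue cutoff $10^{-9}$.
- Reported measurements: half-away-from-zero rounding at 0.01 mm,
  applied only at the reporting/CSV layer.
- Nearest-view ties: smallest camera id.

The validation suite exercises spheres of 5–100 cameras and the noise
study uses 30-camera spheres at 0.5 px noise over 10 seeds — small
enough to run in seconds while leaving the error regime (median
relative distance error well below 1%) clearly resolved. An
independent brute-force grid search (zooming to a $5\times10^{-6}$
step) serves as the oracle for the closed-form triangulation.

## Known limitations

- No outlier rejection: a grossly wrong click degrades the landmark
  rather than being detected (RANSAC is out of scope).
- No covariance propagation onto landmark positions.
- Semi-landmarks, curves and surfaces are not supported; export is a
  plain labelled coordinate table.
- The importer's file dialects are documented conventions, not a
  reverse-engineered proprietary format; the versioned JSON project
  schema is canonical.
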