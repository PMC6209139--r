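---
title: "Quantifying posture from dorsal-outline landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying posture from dorsal-outline landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturegm)
```

## The problem

Animal posture — the configuration of the upper body outline — is a candidate
welfare indicator in horses, but most assessments are subjective. posturegm
implements a landmark-based geometric-morphometrics pipeline for posture
photographs: a horse is photographed in profile, 30 points are digitized
along the dorsal outline from the first coccygeal vertebra (tail base) to the
rostral end of the facial crest, and shape analysis quantifies postural
differences between populations (here, riding schools) while removing
position, scale and orientation.

Three method variants differ in how the 30 digitized points are treated:

* **landmarks** — 9 fixed anatomical landmarks only (the 7 clay-marked
  skeletal cues, the medial eye canthus, and the middle of the neck upline);
* **mixed** — 8 fixed landmarks plus the 22 remaining outline points as
  sliding semilandmarks;
* **ssl** — only the eye canthus fixed; the other 29 points slide.

Each variant can be applied to the whole dorsum (points 1–30), to croup +
back only (1–15), or to neck + head only (15–30), with or without
*derotation* of the neck. The package's central question is methodological:
which variant discriminates populations best?

## Superimposition

`gpa()` performs generalized Procrustes analysis in the partial-Procrustes
convention: every configuration is centered, scaled to unit centroid size,
and rotated to the consensus; the consensus (coordinate-wise mean,
renormalized to unit centroid size each iteration) is recomputed until its
RMS change falls below `tol` (default 1e-8, `max_iter` 100, consensus
initialized from the first configuration). Optimal 2-D rotations are
computed in closed form from the cross-covariance phase, which can never
produce a reflection — appropriate because all photographs are normalized to
one facing direction before analysis (`mirror_configs()`).

Full-Procrustes scaling (rescaling each specimen to the consensus) is
available via `scale_to_unit = FALSE`; unit-size scaling is the default
because it is the dominant convention in the geometric-morphometrics
toolchain this workflow follows.

## Neck derotation

The neck balances during locomotion, and under least-squares
superimposition a rotating landmark subset smears variance onto stable
landmarks (the Pinocchio effect). `derotate()` removes the articulation: the
angle drawn by outline points 1 (tail base), 15 (withers vertex) and 30
(facial crest) is measured per photograph, and all points distal to the
vertex are rigidly rotated about it so every specimen shares one reference
angle. Design choices:

* the reference angle defaults to the circular mean of the measured angles
  over the sample, contexts pooled (a per-context reference is available by
  passing `reference_angle` explicitly); no published value of the fixed
  angle exists, and the circular mean changes the sample least;
* derotation is applied to raw configurations *before* superimposition and
  sliding, keeping the sliding reference free of articulation nuisance;
* the rotated subset is `vertex + 1 .. k`; the vertex itself is the shared
  landmark between the two rigid sets.

Angles are summarized with `circular_mean()` / `circular_sd()` because the
measured angle sits near ±180° for this anatomy and naive statistics wrap.

## Semilandmark sliding

Sliders are positioned by minimizing thin-plate-spline bending energy
(`bending_energy_matrix()`, kernel `U(r) = r^2 log r^2`). In each pass,
every slider of every specimen moves along the chord through its two
outline neighbors (one-sided chord at curve ends), and the displacement
vector solves one small linear system per specimen — the exact minimizer of
the bending energy of the consensus-to-specimen deformation restricted to
tangent directions. Combinations of tangent moves that approximate affine
fields are null directions of that system, so the solve uses a truncated
pseudo-inverse (minimum-norm minimizer) rather than a ridge.

The outer loop (`slide_until_converged()`) alternates sliding with GPA
re-superimposition. A subtlety discovered during development: with
specimen-own tangents the pass-level minimization has no exact fixed point —
each pass lowers energy against the *current* consensus, but the consensus
follows the mean slide and total energy can creep upward across iterations.
(Consensus-side tangents have an exact fixed point but settle at a higher
energy, and they let sliders leave the specimen's own outline when the
articulation is large, so they were rejected.) The loop is therefore a
monotone descent: a pass is accepted only if the ensemble's total bending
energy, measured against the re-superimposed consensus, decreases; the trace
is non-increasing by construction and the loop typically stops after 2–3
passes (`stop_reason` records whether movement tolerance, the energy
plateau, or `max_iter` ended it; defaults `tol = 1e-6` shape units,
`max_iter = 10`).

Two practical limits are worth knowing. First, an open curve whose points
are *all* sliders (e.g. the `ssl` scheme restricted to croup + back, where
the only fixed point — the eye — is outside the subset) is ill-posed: the
endpoints slide freely and energy decreases indefinitely; the monotone stop
terminates gracefully, but such subsets are better analyzed with the
anchored `mixed` scheme. Second, sliding removes *per-specimen* arbitrary
spacing — re-spaced specimens return to their evenly spaced twins — but the
sample-mean component of spacing lands in the consensus and is statistically
confounded with shape; no within-sample procedure can remove it.

## Shape PCA, retention and deformation grids

`shape_pca()` is an SVD of the flattened aligned coordinates centered at
their mean: PCA on the covariance of Procrustes coordinates (coordinates
share units, so no correlation scaling). All `min(n - 1, 2k)` components are
kept — superimposition suppresses the four similarity dimensions only to
second order, and keeping the full basis preserves exact reconstruction and
percent variances that sum to 100. Loadings get a deterministic sign (the
largest-magnitude entry is made positive) so PC orientation is reproducible.
`retained_components()` implements the ≥10% retention rule: leading
components explaining at least the threshold are kept (at least one), and
analysis stops at the first sub-threshold component.

`deformation_grid()` maps a square lattice (default 24 × 24, bounding box
padded by 15%) through the TPS warp from the consensus to a PC extreme
(`pc_extreme_shape()` at the observed minimum / maximum score, the package's
default reading of "extremum"). Grids are emitted as node coordinates; any
plotting layer can draw the superimposed consensus/min/max grids.

## The mixed-model ANOVA harness

Population effects on posture are tested per retained PC and per context
(standing, walking analyzed separately, matching the separate per-context
variance tables): `fit_mixed_anova()` fits `score ~ factor + (1 | horse)` by
REML and reports the Wald F for the factor with containment denominator
degrees of freedom `n_horses - (df_num + 1)`. For a between-horse factor in
a balanced design this F coincides with the one-way ANOVA on per-horse mean
scores, which is exposed as `method = "horse_means"` and doubles as a
cross-check; the Monte-Carlo type-I error at the 5% level is within
simulation error of nominal (see the acceptance script). Identity
covariates (equid type, proportion class, sex; age as a single-df
continuous term) are handled by `identity_parameter_table()`. Raw p-values
are reported at the 5% level; no multiplicity correction is applied, by
design, since the harness compares F magnitudes across method variants
rather than screening hypotheses.

## The synthetic-data generator

No photograph archive accompanies the study design this package targets, so
`sample_dataset()` generates articulated dorsal outlines with known
structure. `make_template_outline()` builds a smooth closed-form profile:
the body section (unit length along x) is a flat baseline plus Gaussian
bumps for the croup rise (height 0.10 body lengths at s = 1/7), back hollow
(depth 0.05 at s = 4/7) and withers peak (0.08 at s = 1); the neck rises
from the withers vertex at 50° and eases into a flatter head segment
(lengths 0.55 + 0.18). Per photograph, the generator adds, in order: a
per-school shape offset (smooth raised-cosine bump in a named region,
school coefficients spanning ±amplitude), a per-horse random field (croup /
back / neck bumps with sd `horse_sd`), a deterministic neck-lowering
rotation of 10° in the walking context, a Normal neck-rotation nuisance
about the withers vertex, and i.i.d. digitization noise.

Defaults mirror the study's sampling design — 11 schools × 8 horses ×
(10 standing + 20 walking photographs) — and the remaining scales are the
package's one-time choices of realistic magnitudes: group amplitude 0.03
and per-horse sd 0.015 body lengths (subtle postural differences comparable
between populations and individuals), neck rotation sd 15°, digitization
noise 0.005 body lengths (≈0.5% of body length, a generous bound on
click error). Covariates echo the study population (50:35 geldings:mares,
ages 7–20 with mean 13, pony:horse 40:60, proportion classes 15/65/20) and
carry no shape effect unless injected. Everything is reproducible from the
seed via R's default Mersenne-Twister generator.

What the generator does *not* emulate: perspective distortion, digitizer
drift or autocorrelated click error, within-bout temporal correlation of
postures, limb or head-yaw variation, and any coupling between covariates
and shape. Passing tests therefore validate the machinery and the method
comparison's logic on data whose generating process is known — not the
biological claims themselves.

## The method-comparison experiment

`method_comparison_table()` runs each variant (scheme × subset × derotation)
per context through derotation → GPA → sliding → PCA → mixed ANOVA and
tabulates F and p per retained PC (at most 3). The headline validation
rebuilds the qualitative published finding — removing the neck's balance
movement sharpens discrimination of riding schools — as a paired simulation:
a fixed back-shape contrast is injected between two halves of the schools
(`inject_known_groups()`, amplitude 0.05 body lengths, i.e. ±0.025 around
the mean against a per-horse sd of 0.015) on top of the 15° neck nuisance,
and the school-factor F on PC1 is compared between the derotated and raw
dorsum pipelines. In this regime the raw PC1 is dominated by the nuisance
(≈84% of variance) while derotation lets the back contrast lead, and the
derotated F wins in ≈95–100% of replicates. The comparison is
regime-dependent: with a contrast comparable to the per-horse sd (amplitude
0.03) the school signal reaches PC1 for neither variant and the PC1-F
comparison is near chance — worth remembering when interpreting PC-wise F
tables on real data.

Problem sizes used by the test suite and acceptance script — e.g. 880
standing photographs per replicate, 50 paired replicates for the headline
comparison, 500 null replicates for ANOVA calibration, 20 alignment pairs
against a 0.001-radian brute-force grid — were chosen as the smallest
designs that estimate each quantity stably.

## Numerical choices and degenerate inputs

* GPA: closed-form complex-phase rotations; convergence on RMS consensus
  change; non-convergence warns and flags, never silently succeeds.
* TPS: exactly coincident reference points are an error naming the
  offending indices; exactly collinear references make the affine block of
  the bordered system rank-deficient (a kernel ridge cannot repair this),
  so regularization uses the Moore–Penrose pseudo-inverse with a logged
  message, or errors when `regularize = FALSE`.
* Procrustes distance is computed as the residual norm after optimal
  rotation (not `sqrt(2 - 2cos)`), which keeps full precision near zero.
* Derotation requires `ray_a <= vertex < ray_b` and errors when a ray point
  coincides with the vertex.
* Slider triples at curve ends encode the one-sided chord as
  `before == after`; a zero-length chord is an error naming the specimen
  and slider.
* `retained_components()` always keeps at least PC1, even below threshold.

## Known limitations

2-D profiles only (no 3-D superimposition, no missing-landmark estimation);
sliding is linearized along tangent chords without re-projection onto a
fitted curve; the consensus's along-curve parameterization after sliding is
weakly identified on open curves; PCs are analyzed separately (no
multivariate test, no between-group PCA or CVA); and published F/p values
from the original photograph archive are not reproducible because the
photographs are not deposited — validation is property- and
simulation-based.
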