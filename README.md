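# posturegm

Geometric morphometrics of animal posture from two-dimensional
dorsal-outline landmarks.

Equine behaviour and welfare studies quantify posture by photographing
horses in profile and digitizing ~30 points along the upper body outline,
from the tail base to the facial crest. posturegm is a toolkit for the full
analysis chain behind that approach, aimed at researchers comparing horse
populations (e.g. riding schools) and, more generally, at anyone doing
2-D outline morphometrics with an articulated subset:

* **I/O** — tpsDig-style landmark files (`read_tps()` / `write_tps()`),
  YAML point-scheme files (`load_scheme()`), covariate tables
  (`read_metadata_table()`);
* **Superimposition** — generalized Procrustes analysis (`gpa()`):
  configurations are centered, scaled to unit centroid size *S* =
  √Σᵢ‖xᵢ − x̄‖², and rotated to the iteratively recomputed consensus;
* **Neck derotation** — `derotate_set()` fixes the angle drawn by outline
  points 1–15–30 (tail base, withers vertex, facial crest) to the sample's
  circular mean, rigidly rotating all points distal to the vertex; this
  removes the balance movement of the neck and the Pinocchio effect it
  causes under least-squares alignment;
* **Sliding semilandmarks** — `slide_until_converged()` positions outline
  points by minimizing thin-plate-spline bending energy *dᵀBd* (kernel
  U(r) = r² log r²) along tangent chords, alternated with Procrustes
  re-superimposition under a monotone energy-descent rule;
* **Shape PCA and deformation grids** — `shape_pca()` on the Procrustes
  coordinates, the ≥10% variance retention rule
  (`retained_components()`), extreme shapes per PC and TPS deformation
  grids (`deformation_grid()`);
* **Method comparison** — `method_comparison_table()` ranks scheme
  variants (9 fixed landmarks vs mixed vs all-sliding; whole dorsum vs
  croup+back vs neck+head; derotated or not) by the mixed-model ANOVA
  F statistic of a population factor on each retained PC, with horse as a
  random intercept: score ~ factor + (1 | horse), Wald F with containment
  denominator df;
* **Synthetic data** — `sample_dataset()` generates articulated outlines
  with known group structure (11 schools × 8 horses × 10 standing + 20
  walking photographs by default) so every stage is testable without the
  original photographs, which are not deposited.

## Worked example

Simulate a standing-context dataset with a known back-shape contrast
between school groups plus a 15° neck-rotation nuisance, then compare the
all-sliding (`ssl`) and 9-landmark variants with and without derotation:

```r
library(posturegm)

sim <- sample_dataset(simulation_params(n_schools = 6, horses_per_school = 6,
                                        photos_standing = 10, photos_walking = 0,
                                        seed = 42))
sim <- inject_known_groups(sim, "back", 0.05)
sim
#> posture_sim: 360 photographs, 36 horses, 6 schools

tab <- method_comparison_table(sim, schemes = c("landmarks", "ssl"),
                               subsets = "dorsum", derotate = "both",
                               contexts = "standing")
tab[, c("method", "derotated", "pc", "percent_variance", "F", "p")]
#>      method derotated pc percent_variance      F        p
#> 1 landmarks     FALSE  1             87.4  0.265 9.28e-01
#> 2       ssl     FALSE  1             79.2  0.722 6.12e-01
#> 3       ssl     FALSE  2             10.4 33.985 1.73e-11
#> 4 landmarks      TRUE  1             72.5 35.223 1.10e-11
#> 5       ssl      TRUE  1             54.4 32.540 2.97e-11
#> 6       ssl      TRUE  2             21.8  0.520 7.59e-01
```

Reading the table: without derotation, PC1 (79–87% of variance) is the
neck's balance movement — a nuisance — and the school effect is invisible
on it (F ≈ 0.3–0.7, p ≈ 0.6–0.9); at best it surfaces on a later PC (raw
`ssl` PC2). After derotation the injected back contrast leads PC1 and the
school factor is detected decisively (F ≈ 33–35 on 5 and 30 df,
p ≈ 10⁻¹¹). That is the package's headline methodological point: removing
the articulation concentrates population signal on the first component.

A thin CLI wraps the same functions
(`Rscript inst/cli/posturegm simulate|align|slide|pca|anova|run ...`), and
`run_method_comparison()` writes a full report bundle (variance and ANOVA
tables, deformation-grid coordinates, JSON manifest, log) reproducibly
from a config and seed.

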