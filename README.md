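# cephmorph

Landmark-based analysis of lateral cephalograms: from raw digitized landmark
replicates to **cephalometric morphology templates (CMTs)** — cluster-derived
mean landmark configurations used as diagnostic archetypes for dentofacial
deformities — with discriminant classification, a rule-based diagnostic
layer, and pre/post treatment-change evaluation.

## Who this is for

Orthodontic/craniofacial researchers and methodologists who work with
digitized 2-D cephalometric landmarks and want a tested, scriptable pipeline
for:

- **Ingest & calibration** — each landmark digitized up to three times; the
  replicate mean is used, and a landmark is flagged for recalibration when
  the maximum pairwise distance between its three replicates exceeds twice
  the minimum (strict inequality). Magnification is corrected by dividing by
  the image scale factor.
- **Registration** — every case is moved by a rigid transform (rotation +
  translation, determinant +1) into the standard cephalometric frame: sella
  S at the origin, the sella–nasion line SN as the x-axis with nasion on the
  positive side, +y inferior. Inter-landmark distances are preserved exactly.
- **Measurement** — a declarative catalog of the classical angular and
  linear measurements (SNA, SNB, ANB = SNA − SNB, MP/SN, U1/SN, overjet,
  overbite, Wits, lip-to-E-line distances, face heights, ...) built from
  seven geometric primitives. The full 135-name measurement inventory is
  registered; entries without a standard construction evaluate to `NA`
  rather than a silent number.
- **Clustering & templates** — Ward clustering (Euclidean, raw mm
  coordinates) of the registered coordinate vectors, silhouette-based
  selection of the number of groups, pruning of groups smaller than 5, and
  per-group mean-coordinate templates with wireframe SVG rendering.
- **Discriminant classification** — per-class linear score functions
  `Y_g = a0 + a1·x1 + ... + an·xn` (classification-function LDA with
  coefficients `a_g = S⁻¹ μ_g`, intercept `a0 = −½ μ_gᵀ S⁻¹ μ_g + log π_g`),
  optional Wilks'-Λ stepwise variable selection, and leave-one-out
  cross-validation; a new case goes to the class with the largest score.
- **Rule-based diagnosis** — the 21-template criterion table (skeletal class
  from ANB, vertical type from MP/SN, lip protrusion against the esthetic
  line, deep overjet ≥ 8 mm, anterior-crossbite severity, incisor
  linguoclination, open bite) as a deterministic, fully configurable rule
  engine with a per-criterion trace.
- **Treatment evaluation** — paired pre/post comparison within a template
  group (mean templates, per-landmark displacement field, paired Student
  t-tests per measurement) and two-sample contrasts between treatment arms.
- **Synthetic cohorts** — because clinical cephalogram databases are rarely
  shareable, a first-class generator produces schema-complete synthetic
  cohorts from 21 deformation-based archetypes with known ground truth,
  used by every recovery test.

## Worked example

Simulate a cohort drawn from three archetypes (skeletal I straight profile;
skeletal II high-angle deep overjet; skeletal III retruded maxilla /
protruded mandible), run the full pipeline, and label the recovered
templates:

```r
library(cephmorph)

cfg <- synthetic_config(seed = 1,
                        designs = cmt_prototype_designs(scale = 2)[c(1, 10, 18)],
                        n_per_cluster = 30)
sim    <- generate_cohort(cfg)
cohort <- ingest_cohort(sim$landmarks, sim$meta)   # calibrate + register
cohort
#> <ceph_cohort> 90 cases, 60 landmarks, registered (S-origin/SN-axis) frame
#>   recalibration flags set for 3505 landmark digitizations
#>   timepoints: pre=90

meas <- evaluate_cohort(cohort)
round(meas[1, c("SNA", "SNB", "ANB", "MP/SN", "overjet", "UL-EP", "LL-EP")], 2)
#>     SNA   SNB  ANB MP/SN overjet UL-EP LL-EP
#> 1 83.84 81.02 2.83  32.3    5.44 -1.49  -0.5

diagnose(meas[1, ], case_id = meas$case_id[1])
#> <ceph_diagnosis> case_0001: skeletal I, average angle -> CMT 1 (matched: 1)

fm <- build_features(cohort)        # 90 x 117 coordinate variables
cl <- cluster_cases(fm, k = "auto", k_max = 10, seed = 1)
cl
#> <ceph_clusters> ward, k_raw = 3 -> 3 CMTs (min size 5), 0 unclassed

label_templates(make_templates(cl, cohort))
#>                                                                   1
#>                          "skeletal I, mean angle, straight profile"
#>                                                                   2
#>                             "skeletal II, high angle, deep overjet"
#>                                                                   3
#> "skeletal III, mean angle, retruded maxilla and protruded mandible"

cmt_distribution(cl, cohort)[, c("cmt", "n", "percent")]
#>         cmt  n percent
#> 1     CMT_1 30    33.3
#> 2     CMT_2 30    33.3
#> 3     CMT_3 30    33.3
#> 4 unclassed  0     0.0
#> 5     total 90   100.0
```

The first case's measurements (ANB 2.8°, MP/SN 32.3°, lips behind the
esthetic line) place it in the skeletal I / average-angle / straight-profile
template; the silhouette-selected clustering recovers the three generating
archetypes exactly, and each mean template diagnoses back to its generating
archetype's clinical label.

Templates render as deterministic SVG wireframes
(`render_template(tpl[[1]], file = "cmt1.svg")`), and pre/post overlays with
per-landmark displacement arrows via `render_overlay()`. A thin command-line
wrapper for simulation, ingest, measurement and diagnosis ships in
`inst/cli/ceph.R`.

## Scope notes

- Coordinates arrive already digitized (CSV or TPS); there is no image
  processing or automatic landmark detection, and no 3-D/CBCT support.
- The skeletal-class ANB interval ([0, 4.7]°) and MP/SN vertical bands
  (27°/37°) are configurable population-norm defaults, printed with every
  diagnosis; the template criteria themselves (8 mm overjet, lip and
  crossbite thresholds) follow the 21-template criterion table.
- Measurement names without a standard two-to-four-landmark construction
  are registered but marked not computable — deliberately partial scope.
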