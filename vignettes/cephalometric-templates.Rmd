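---
title: "Cephalometric morphology templates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cephalometric morphology templates: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
models and procedures, the tunable parameters with their defaults and units,
what the synthetic generator does and does not emulate, and the numerical
and design choices made where the methodology was genuinely open.

## The pipeline in one paragraph

A lateral-cephalogram case enters as up to three digitization replicates per
landmark on a 60-landmark schema (46 hard-tissue, 14 soft-tissue points).
Calibration averages the replicates and flags unreliable landmarks;
magnification is divided out; a rigid transform places sella at the origin
with the sella–nasion line as x-axis. From the registered coordinates the
package computes classical cephalometric measurements, clusters the
coordinate vectors into morphology groups whose mean configurations are the
cephalometric morphology templates (CMTs), fits per-class linear
discriminant score functions for assigning new cases to templates, labels
templates clinically through a deterministic rule engine, and compares
paired pre/post cohorts within a template.

## Calibration: the triple-digitization rule

With three replicates of a landmark, let $d_{max}$ and $d_{min}$ be the
largest and smallest of the three pairwise distances. The landmark is
flagged for recalibration when $d_{max} > 2\,d_{min}$ (strict inequality,
exactly as worded clinically). Degenerate inputs need explicit rules: if all
three replicates coincide (distances below $\varepsilon = 10^{-9}$ image
units) nothing is flagged; if only $d_{min} < \varepsilon$ the ratio is
treated as infinite and the flag fires. Cases with one or two replicates are
accepted (mean of what exists, never flagged) so that external single-pass
digitizations still load — the triple protocol is a study convention, not a
file-format requirement. The flag statistic $d_{max}/d_{min}$ is scale-free
for isotropic Gaussian replicate noise, so the expected flag rate is a
universal constant (about 0.66, estimated by `expected_flag_rate()` with
$n \ge 10^5$ Monte-Carlo triples); the generated cohorts' observed rates are
tested against that estimate.

## Registration frame and axis convention

Input files use image convention: y grows downward. Registration applies
translation and a pure rotation (determinant $+1$, never a reflection or
scaling) taking S to $(0,0)$ and N to $(+|SN|, 0)$. After registration $+x$
is anterior and $+y$ inferior, matching how clinicians read a cephalogram
facing right. No convention is universal for the image y-orientation; the one here is a
documented package choice, and every sign convention in the
measurement catalog (anterior-positive signed distances, inferior-positive
overbite) is defined relative to it. Registration is an exact isometry;
property tests require all $\binom{60}{2}$ pairwise distances preserved to
$10^{-9}$ mm and idempotence of re-registration.

## Measurement catalog

Measurements are declarative: name → primitive + ordered landmark codes.
Seven primitives cover the catalog: three-point angle (`angle3`, vertex
angle in $[0,180]°$), undirected line/line angle ($[0,90]°$), **directed
ray/ray angle** ($[0,180]°$), point–point distance, signed point-to-line
distance, signed projection onto an axis, and signed projection onto an
axis normal. Two derived forms (difference, percent ratio) give
ANB = SNA − SNB and the S-Go/N-Me facial-height ratio.

Incisor inclinations (U1/SN, L1/MP, U1/L1, U1/NA, L1/NB) use the *directed*
ray angle between the reference ray (e.g. S→N) and the incisor long axis
oriented edge→apex: an upright incisor reads 90°, proclination reads above
90°, retroclination below. An undirected angle (capped at 90°) would make
the clinical linguoclination rule "U1/SN < 90°" vacuous, which is why the
directed form is used for axes while plane/plane angles stay undirected.

Reference-plane choices are configurable defaults, since analysis schools name
planes without agreeing on constructions: mandibular plane Go–Me, Frankfort
horizontal P–Or, functional occlusal plane Interdental-M→Interdental-I (used
by Wits), esthetic line Prn→Pos oriented superior→inferior so the anterior
side is positive, overjet/overbite projected along/normal to the Frankfort
horizontal. The full printed inventory of 135 measurement names is
registered; the roughly 60 entries with a standard construction compute,
and the rest return the `NA` not-computable marker rather than an invented
definition. Angles are degrees, distances mm; file output rounds to two
decimals; internal values are never rounded.

## Clustering and templates

Features are the concatenated registered coordinates in mm. The three
frame-fixed coordinates (S_x, S_y, N_y) are constant by construction and are
dropped, leaving $p = 117$ variables for the full schema; any other column
with variance below $10^{-12}$ is dropped and recorded. No standardization
is applied — all coordinates share the mm scale, and standardizing would
distort anatomy.

The default clustering is agglomerative with Ward's criterion on Euclidean
distances (deterministic given input order); restarted k-means is available.
`k = "auto"` maximizes the mean silhouette width over $k \in [2, k_{max}]$
($k_{max}$ default 40, spanning well beyond the ~21 groups such template systems produce).
Groups smaller than `min_size = 5` are pruned, their members reported as
"unclassed" (never reassigned), and survivors are renumbered by descending
size. Templates are the coordinate-wise arithmetic means of their members —
which stay exactly in the registered frame — with the catalog evaluated on
the mean geometry. Degenerate input (all cases identical) yields one
cluster without pruning.

## Discriminant classification functions

For class $g$ with mean $\mu_g$ and pooled within-class covariance $S$, the
score of a case $x$ is
$Y_g = a_{0g} + a_g^\top x$ with $a_g = S^{-1}\mu_g$ and
$a_{0g} = -\tfrac12 \mu_g^\top S^{-1}\mu_g + \log \pi_g$;
the case is assigned to the largest $Y_g$, ties to the lower class id. The
linear score form has no intercept in its classical presentation; the
intercept is included here because an argmax over intercept-free scores
cannot express priors or centroid offsets, and exported equations print it
explicitly. Priors default to class proportions. Because $p = 117$ can
approach class sizes, $S$ is ridge-regularized as
$S + \lambda\,\overline{\mathrm{diag}(S)}\,I$ with $\lambda = 10^{-6}$ by
default; $\lambda = 0$ demands a nonsingular $S$ and fails with advice
otherwise.

Stepwise variable selection follows the classical Wilks'-Λ procedure:
greedily enter the variable minimizing Λ while its partial F-to-enter is at
least 3.84, then remove variables whose F-to-remove falls below 2.71 (both
configurable). Leave-one-out cross-validation keeps the full-fit variable
set frozen inside the loop by default — optimistic, but the common practice
the method mirrors — with `nested = TRUE` re-running selection per fold.
LOO folds that leave a class unfittable (singletons) assign the largest
remaining class, which makes the two-case example (one case per class)
correctly score zero accuracy.

## The 21-template rule engine

Skeletal class comes from ANB — Class I inside the closed interval
$[0, 4.7]°$, II above, III below — and vertical type from MP/SN — average
inside $[27, 37]°$, low below, high above. These cutoffs are **not** part of
the template criterion table; they are configurable defaults following
widely used Chinese-population norms and are printed with every report.
The criteria themselves follow the 21-template criterion table: lip distances to the
esthetic line with the 1 mm / 2 mm (Class I) and 2.5 mm / 4 mm (Class II)
thresholds, deep overjet $\ge 8$ mm, Class III anterior-crossbite ranges
$(-3, 0)$ mild / $< -3$ severe (low-angle variant $(-2,0)$ / $< -2$), upper
incisor linguoclination U1/SN $< 90°$ (cutoff a documented default), and
open bite as overbite $< 0$.

Two table rows overlap at the lip boundaries; the split is made exhaustive
and exclusive by defining protrusion = (both lips beyond the threshold) OR
(sum beyond the sum threshold), straight otherwise — the raw per-criterion
truth values remain visible in the diagnosis `trace`. When several
templates match, the primary diagnosis applies a fixed precedence within the
skeletal class: open bite, then deep overjet / severe Class III overjet,
then linguoclination, then the lip split and mild Class III overjet. An
overjet of exactly −3 mm matches neither the mild (strictly greater) nor the
severe (strictly less) Class III rows and is reported unclassed — the table
wording is followed literally rather than patched.

## Treatment evaluation

Pre and post cohorts are paired by case id. The comparison reports the two
mean templates, the per-landmark displacement field (post − pre), and a
two-sided **paired** Student t-test per measurement on within-patient
differences (the cohorts are the same patients, so an unpaired test would be wrong). No
multiple-testing correction is applied by default, matching descriptive
practice; Holm adjustment is available and recorded. Arm contrasts use the
pooled-variance two-sample t on per-patient differences. Zero-variance
degenerate data follow a documented convention (all differences zero →
t = 0, p = 1) instead of erroring. Growth is neither modeled nor
subtracted; the module is descriptive.

## The synthetic generator

The generator exists because clinical cephalogram cohorts are rarely
shareable; it produces data with the statistical structure the analysis
assumes, plus stored ground truth for recovery testing. Its base wireframe
is a hand-constructed, schema-complete 60-landmark geometry (S–N = 70 mm,
adult scale) whose measurements sit in unremarkable clinical ranges; it is
internally consistent but **not** a population norm. Twenty-one archetypes
derive from it by local rigid moves along exactly the axes the rule engine
reads: sagittal maxilla/mandible shifts (ANB), mandibular-plane rotation
about gonion with the dentition left in place, emulating dental
compensation (MP/SN), incisor block shifts and tilts about the apices
(overjet, overbite, inclination), and lip offsets (E-line distances). Each
archetype's noiseless geometry diagnoses back to its own template — a
property the tests assert for all 21.

Defaults define the emulated study conditions: within-cluster anatomical SD
1.5 mm per coordinate (isotropic Gaussian), digitization replicate SD
0.3 mm with three replicates, magnification factor 1.1, sex ~
Bernoulli(0.663 female), age ~ truncated normal (mean 14.35, SD 4.99,
range 7–62 years). Optional treatment effects add a fixed per-landmark
displacement field to each patient's true geometry for a "post" copy, per
arm. What the generator does **not** emulate: inter-observer digitization
bias, age–shape covariance, growth, and correlated (non-isotropic)
anatomical variation — so passing recovery tests demonstrate pipeline
correctness under the stated noise model, not robustness to every property
of clinical data.

## Recovery experiments and problem sizes

One consequence of registering before clustering is worth stating: iid
landmark noise on S and N perturbs each case's frame by a small rotation
whose displacement grows with a landmark's distance from sella, so the
effective within-cluster SD per coordinate is up to about twice
$\sigma_{within}$, concentrated in a common rotation mode. Two design
choices in the cluster-recovery experiments follow from this. First,
recovery subsets (`recovery_prototype_ids()`) pick K archetypes with
near-uniform pairwise separations, because strongly nested separations make
the mean silhouette prefer super-groups over the generating partition — a
known behaviour of silhouette-based k selection, not a clustering failure.
Second, the experiments use deformation scale 3, placing minimum prototype
separations at 88–190 mm against the default 1.5 mm noise (separation/noise
well beyond the factor-10 regime the recovery guarantee targets). Template
accuracy is asserted as RMS deviation within 3 standard errors, with the SE
estimated from the realized member variance — the correct error model given
the rotation-mode inflation.

Problem sizes were chosen to keep the full suite and the acceptance script
comfortably within a desk-scale run: 20 seeded replicates per K for
recovery, 15–40 cases per cluster, an 840-case end-to-end analogue
(21 archetypes × 40 cases) for the cluster → discriminant → leave-one-out
loop, 1000 random cases for isometry/invariance properties, $2\times10^5$
Monte-Carlo triples for the flag rate, and about 700 simulated
measurement-tests for the null false-positive check. At the default noise
the 840-case analogue typically resolves into a small number of
super-groups (several archetypes differ by a few mm on a few landmarks,
well inside the within-cluster spread); the leave-one-out guarantee
($\ge 0.85$) applies to the data-driven labels.

## Known limitations

- The rule engine and the data-driven clustering are two independent
  labeling layers; no attempt is made to force case-by-case agreement.
- Stepwise Wilks selection recomputes Λ from scratch per candidate — fine at
  these sizes, quadratic in the variable count.
- TPS input is read in the file's own axis convention; files digitized
  y-up must be flipped by the caller.
- The measurement catalog's non-computable entries are a deliberate
  registry, not a to-do list: definitions vary across analysis schools, and
  inventing one silently would be worse than `NA`.
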