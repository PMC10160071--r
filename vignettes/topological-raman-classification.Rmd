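---
title: "Topological classification of Raman spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological classification of Raman spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramantda)
```

## The problem

Chondrogenic bone tumours span a benign form (enchondroma, EC, coded 0) and
three chondrosarcoma malignancy grades (CS G1–G3, coded 1–3). Distinguishing
EC from CS G1 under the microscope is a recognised source of false positives
and negatives, and Raman spectroscopy — which reads out the biochemical
composition of a tissue spot as an intensity curve over wavenumber — is a
promising adjunct. The cohorts this package is built around are small and
patient-structured: a training cohort of 400 spectra from ten patients
(per-patient counts 32, 31, 37, 24, 38, 38, 50, 50, 49, 51; patient-level
grades 0, 0, 0, 1, 1, 1, 2, 2, 3, 3) and a held-out cohort of ten new
patients with one spectrum each, acquired later on different hardware.

`ramantda` implements the full analysis pipeline: spectra are restricted to
the 400–1800 cm⁻¹ fingerprint region, embedded as planar point clouds,
summarised by Vietoris–Rips persistent homology in dimensions 0 and 1,
vectorized four ways, and classified by a grid of standard classifiers under
patient-aware validation, with a six-fold augmentation recipe, a
no-topology ablation and an unsupervised clustering evaluation alongside.

## From a spectrum to a persistence diagram

Each spectral sample $(w_i, y_i)$ is treated as a point of $\mathbb{R}^2$
(`embed_spectrum()`; by default raw coordinates — a `normalize` flag
min–max scales each axis to $[0,1]$, since axis scaling changes Euclidean
distances and therefore the filtration, and the package exposes the choice
rather than hiding it). The Vietoris–Rips
filtration adds a simplex when all its pairwise distances fall below the
scale parameter. `vietoris_rips_diagram()` records:

* **H0** (components): every interval has birth 0; the finite deaths are
  exactly the edge lengths of a Euclidean minimum spanning tree (computed by
  Kruskal's algorithm), plus one essential interval for the surviving
  component.
* **H1** (loops): (birth, death) pairs computed by persistent-cohomology
  reduction of the edge coboundary columns over GF(2), with triangle
  cofacets enumerated lazily.

A lower-star filtration was deliberately not used: for one-dimensional
signals it produces no H1 classes at all, whereas loops in the planar
embedding (created by close peak doublets, valleys and noise) are exactly
the extra information the second homology dimension contributes.

Two exactness devices keep the computation honest and fast:

* the filtration is truncated at the *enclosing radius*
  $\min_i \max_j d(i,j)$ — beyond it the complex is a cone, hence has
  trivial H1, so nothing is lost;
* positive-persistence H1 classes can only be born at *lens-empty* edges
  (edges with no third point strictly closer to both endpoints; any other
  edge is filled by a triangle at its own filtration value — by induction on
  edge length every cycle is homologous to one through strictly shorter
  edges). The reduction therefore starts from a threshold just above the
  largest lens-empty edge and doubles it until no class is left alive,
  with the enclosing radius as a certified ceiling.

Conventions: zero-persistence H0 intervals (coincident points) are retained
as (0, 0); zero-persistence H1 edge–triangle pairs are dropped in both the
main implementation and the brute-force oracle, since a (b, b) pair
corresponds to no homology class at any scale and at cohort scale they
dominate memory without carrying information. Essential intervals are kept
in the diagram but never vectorized — all four vector representations
consume finite intervals only (the alternative of capping deaths at the
diameter is not offered because no downstream consumer needs it).

`brute_force_diagram()` is an independent oracle for clouds of ≤ 12 points:
it enumerates every vertex, edge and triangle, orders them by (filtration
value, dimension, lexicographic index) and reduces the full boundary matrix
with the textbook column algorithm. It shares no code with the main path
(no union-find, no MST, no truncation) and the test suite asserts multiset
equality on hundreds of random clouds.

## Vectorization

Four representations, each producing a fixed-length vector from the finite
intervals (`vec_config()` bundles method, parameters and fusion strategy):

* **Betti curve** (BC): $\beta(t) = \#\{(b,d) : b \le t < d\}$ at $n$
  equally spaced points (both endpoints included).
* **Persistence landscape** (PL): the $j$-th largest tent value
  $\max(0, \min(t-b, d-t))$, levels $\lambda_1 \ge \dots \ge \lambda_k$,
  concatenated. Default $k = 5$: enough levels to see multiplicity in these
  diagrams while keeping the vector short.
* **Persistence silhouette** (PS): the $(d-b)^p$-weighted average of the
  tents; default $p = 1$, the standard first choice that weights features
  proportionally to persistence.
* **Persistence image** (PI): intervals mapped to (birth, persistence),
  smoothed by a unit-mass isotropic Gaussian of bandwidth $\sigma$, weighted
  linearly in persistence (zero at zero, one at the fitted training
  maximum — the weighting originally recommended for the method), and
  integrated over an $n \times n$ pixel grid by midpoint evaluation times
  pixel area. The unit-mass property (total image mass ≈ interval weight
  when the grid extends ≥ 4σ past the point) is tested at tolerance 1e-3,
  which the midpoint rule comfortably meets at the tested pixel/σ ratio.

Homology fusion follows four strategies: H0 only, H1 only, all intervals
pooled regardless of dimension ("fused"), and H0/H1 vectorized separately
then concatenated ("concat").

Sampling ranges are *fitted on training diagrams only* —
`fit_value_range()` freezes [min birth, max death] (separate birth and
persistence ranges for PI) before any validation or test diagram is
transformed; out-of-range test intervals are clipped to the boundary. This
is the no-leakage discipline that patient-aware validation requires, and the
test suite asserts it with an instrumented fit log. A fusion block with no
training intervals anywhere (e.g. H1 of a loop-free cohort) gets a
degenerate unit range and vectorizes to zeros; only a completely empty
training collection is an error.

## Classifiers and the grid

The default grid crosses PI ($\sigma \in \{0.1, 1, 10\}$,
$n \in \{5, 10, 25\}$), PL/PS/BC ($n \in \{25, 50, 75, 100\}$), the four
fusion strategies, and three classifier families: an RBF support vector
classifier with cost $C \in \{1, 2, 3, 5, 10, 20\}$ (one-vs-one for
multiclass, unscaled features, bandwidth $1/(p \cdot \mathrm{var}(X))$), a
100-tree random forest, and ridge regression used as a classifier with
penalty $\alpha = 1$. The ridge construction is the standard one — classes
one-hot coded to ±1, closed-form L2 solve with an unpenalised intercept,
prediction by argmax — written out in full because "ridge regression as a
classifier" admits no other canonical reading.

Validation schemes: leave-one-patient-out (`lopo_splits()`, one run per
patient in order of first appearance), shuffled unstratified ten-fold
cross-validation (`kfold_splits()`, which deliberately lets one patient's
spectra straddle train and test — that contrast is the point of the
comparison), and a static patient-level split (`static_split()`, train =
patients 1, 3, 5, 6, 8, 10). Reporting mirrors the two table shapes used in
this literature: per-run best accuracy with the achieving method
(`best_per_run()`, mean ± *population* SD across runs) and best single
method by mean accuracy (`best_single_method()`), both grouped by fusion
strategy. Ties anywhere resolve to the first method in canonical order
(vectorization, then parameters, then fusion, then classifier). Methods that
fail on a split are recorded as `NA` with a warning and excluded from the
argmax rather than counted as zero.

## The synthetic cohort generator

The clinical spectra are not redistributable, so `generate_cohort()` exists
as a first-class module to make every downstream stage testable. What it
emulates:

* **Class structure.** Four profiles share the cartilage bands
  (856/872 proline–hydroxyproline doublet, 1003 phenylalanine, 1245/1262
  amide III, 1302, 1440/1458 CH₂, 1660 amide I) and differ in the bands that
  track grade: DNA at 785 and the glycosaminoglycan doublet 1063/1081 grow
  with malignancy while the collagen band at 938 shrinks — biochemically
  plausible, visually similar profiles, which is the premise of the grading
  task. Lines are Lorentzian by default (the natural Raman line shape),
  Gaussian optionally.
* **Patient effects.** Each patient draws once: log-normal per-peak
  amplitude jitter (SD 0.10), a global intensity scale (SD 0.05) and a small
  calibration shift (SD 1 cm⁻¹); spectra then add i.i.d. Gaussian noise
  (SD 0.3 against peak amplitudes of 4–30). Within-patient variability is
  therefore low relative to between-patient variability — the property that
  makes spectrum-level cross-validation optimistic and patient-level
  validation hard, especially for grades G2/G3 which have only two patients
  each in the reference composition.
* **Sampling.** The default grid is 400–1800 cm⁻¹ in steps of 4 cm⁻¹
  (351 points), a desk-scale choice consistent with the ~5 cm⁻¹ spectral
  resolution of dispersive Raman microscopes used for tissue work. The
  close doublets produce genuine H1 loops in the planar embedding, as real
  spectra do.

What it does not emulate: instrument response, fluorescence background
(assumed already removed), shot-noise statistics, cosmic rays, or any
within-patient heterogeneity of tumour tissue. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline machinery is correct and
that it recovers planted class structure under patient confounding — not
that any particular accuracy carries over to clinical spectra.

`synthetic_dataset1()` and `synthetic_dataset2()` fix the two reference
compositions (400 spectra / 10 patients, and 10 new patients × 1 spectrum
with truth 1, 2, 2, 1, 1, 2, 0, 3, 3, 0); the held-out generator uses a
seed stream disjoint from the training cohort so the patient populations
never coincide.

## Augmentation

`augment_sixfold()` applies the five-transform recipe: small Gaussian noise
(SD = per-spectrum max / 1000), unit Gaussian noise, a wavenumber shift
drawn uniformly from ±5 cm⁻¹, and the two noise+shift combinations — six
times the data including the originals. The shift is interpreted as a
horizontal (calibration) shift, implemented continuously with linear
interpolation and boundary-value fill — the continuous reading is the more
physical model of a wavelength-calibration error than a whole-sample shift. Each (spectrum, variant) pair draws from its own
seed-derived stream, so augmentation is reproducible and order-independent.

## Clustering evaluation

`cluster_eval()` scores unsupervised structure in the feature vectors:
k-means, mini-batch k-means, Ward agglomerative clustering, a spherical
Gaussian mixture, spectral clustering, affinity propagation, DBSCAN and
mean shift (the last four parameter-free methods choose their own cluster
count; DBSCAN's radius defaults to the median 5th-neighbour distance and
mean shift's bandwidth to the 0.3 distance quantile). Accuracy is computed
under the *optimal one-to-one assignment* of clusters to true labels — an
exact dynamic programme over label subsets, equivalent to the Hungarian
matching for these sizes, with unmatched clusters contributing zero; a
degenerate single-cluster result scores the majority-class frequency and is
flagged. BIRCH and OPTICS are recognised names but intentionally not
implemented; requesting them is an informative error.

## Numerical choices and degenerate inputs

* Range restriction uses the closed interval [lo, hi]: a wavenumber window
  quoted as "400–1800" reads most naturally with both endpoints included.
* Grid points for BC/PL/PS include both endpoints; a fitted range that
  collapses to a point is padded by ±0.5.
* Coincident points merge at filtration value 0 and stay in the diagram.
* A cohort whose spectra share no common wavenumber support cannot be fed to
  the no-topology ablation; differing grids are linearly interpolated onto
  the first spectrum's grid restricted to the common support, or rejected if
  interpolation is disabled.
* Constant-label training data yields a constant classifier rather than an
  error, so degenerate folds score the test frequency of that label.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  with per-(run, method) and per-(spectrum, variant) derived streams, so
  grid results and augmentations are bit-reproducible.

## Problem sizes used by the tests

The unit tests run cohorts on coarse grids (25–50 cm⁻¹ steps) to keep
round-trips fast; the end-to-end acceptance checks use the full reference
composition (400 spectra, 351-point spectra) with a reduced method grid
(BC and PS at resolution 50, H0 and fused fusion, SVC C = 1 and the random
forest) over three seeds, and mild patient effects (amplitude jitter SD
0.05, scale SD 0.02) as the "strong class separation" condition for signal
recovery. The oracle-equivalence property is checked on 200 random clouds
of 4–10 points per run.

## Known limitations

* Homology stops at dimension 1 and the metric is Euclidean only.
* The persistence backend is exact but specialised to planar clouds; it is
  not a general-dimension VR engine.
* Synthetic cohorts cannot validate clinical accuracy claims; they validate
  machinery and qualitative behaviour (patient confounding, augmentation
  effects, leakage discipline).
* Mclust's spherical covariance restriction (EII/VII) keeps the Gaussian
  mixture tractable in high feature dimensions but limits its expressiveness.
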