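---
title: "Methods: gluten network morphometry, dough rheology and their link"
author: "doughnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gluten network morphometry, dough rheology and their link}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doughnet)
```

## The problem

The mechanical behaviour of wheat dough — how it flows, springs back and
resists deformation — is dominated by the spatial arrangement of its
gluten protein network. Confocal micrographs of protein-stained dough
show that arrangement directly, and small-strain rheometry measures the
mechanics, but the two are usually reported side by side rather than
connected. `doughnet` implements a quantitative bridge: it reduces a
micrograph to five morphometric attributes, reduces two standard
rheometer tests to eight viscoelastic attributes, links the two sets with
partial least squares regression, and classifies samples into six
archetypal network types whose rheological character is known.

## Protein network analysis (PNA)

A binary micrograph (protein = foreground) is reduced to five attributes:

* **protein width, `pw` (µm)** — protein area divided by total skeleton
  length, i.e. the mean thread thickness;
* **branching rate, `br` (µm⁻²)** — skeleton branch points per unit
  protein area: network connectivity;
* **average protein length, `apl` (µm)** — mean skeleton length of a
  connected protein particle;
* **end-point rate, `epr` (µm⁻²)** — skeleton endpoints per unit protein
  area: loose ends, i.e. network weakness;
* **lacunarity, `ly` (–)** — a gliding-box measure of the amount and
  size of gaps.

Grayscale images are thresholded with Otsu's method (a fixed threshold is
available); the protein phase is thinned to a one-pixel, 8-connected
skeleton with the Zhang–Suen algorithm. Branch points are pixels where at
least three skeleton branches meet, judged by the *crossing number*
(0→1 transitions around the pixel) rather than the raw neighbour count,
which staircase pixels would inflate; adjacent branch-point pixels are
merged into a single junction so a thick crossing counts once. Skeleton
length is edge-based (1 px per orthogonal step, √2 px per diagonal
step); an isolated single-pixel component is given a length of one pixel
so that point-like particles retain their pixel extent and `pw` stays
finite on particulate images.

Lacunarity is the variance-to-squared-mean ratio of foreground mass under
a gliding box, averaged over box sizes (default 8, 16, 32, 64, 128 px).
Boxes lie fully inside the image; the scan is exhaustive (stride 1) for
boxes up to 32 px and strided at box/4 above, which changes the estimate
negligibly (tested) while keeping large boxes tractable. This convention
makes `ly = 0` for a completely filled image, matching a 0–0.5 working
scale rather than the `Λ = 1 + σ²/µ²` convention. The default image
calibration is 215/1024 ≈ 0.21 µm/px (a 1024 px confocal frame covering
215 µm); every attribute except `ly` scales with that calibration, so
absolute comparisons require matching optics.

Numerical caveat: Zhang–Suen thinning removes pixels in two directional
subiterations, so skeleton-derived quantities are only approximately
invariant under 90° rotation (below 2% for lengths and 6% for counts on
mesh images in the test suite); area and lacunarity are exactly
invariant.

## Rheological models

Two standard tests are modelled:

**Oscillatory frequency sweep** (0.1–50 Hz, 0.1% strain, within the
linear viscoelastic region). The complex modulus follows the power law
`G*(ω) = A_f · ω^(1/z)`, with `A_f` the network strength and `z` the
network connectivity. The fit is ordinary least squares of `log G*` on
`log ω` — the standard linearization under multiplicative error; a
natural-scale nonlinear fit serves as an independent oracle in the tests.
A nonpositive slope is rejected as non-physical. `G*` and
`tanδ = G″/G′` are reported at 1 Hz, by log-log interpolation if 1 Hz is
not a grid point; `tanδ` is evaluated at the same single frequency as
`G*` (one-value convention).

**Creep–recovery** (250 Pa for 180 s, recovery for 360 s). The creep
compliance follows the four-parameter Burgers model
`J(t) = J₀ + J₁(1 − e^(−t/λ)) + t/η₀`, and the *recovered* compliance
`R(τ) = J(180 s) − J(180 s + τ)` follows the five-parameter
two-Kelvin-element form
`R(τ) = J₀ᵣ + J₁ᵣ(1 − e^(−τ/λ₁)) + J₂ᵣ(1 − e^(−τ/λ₂))`, `λ₁ < λ₂` by
convention. Modelling recovered rather than residual compliance is
deliberate: it keeps the relative elastic part `J_el = J_r/J_max × 100`
equal to 100% for a fully elastic sample, which the alternative reading
("minimal compliance at the end of recovery") would not.

Fits use Levenberg–Marquardt on *log-parameters*: every Burgers
parameter is positive by definition, the decades-spanning magnitudes
(10⁻⁴ Pa⁻¹ compliances against 10⁵ Pa·s viscosities) become comparably
scaled, and boundary sticking at λ → 0 cannot occur. Initialization is
deterministic (J₀ from the first sample, η₀ from the terminal slope of
the last 20% of the creep phase, λ = t_end/5; recovery analogues), so
identical inputs give identical fits. Parameters are bounded to
(10⁻¹², 10¹²); convergence uses relative tolerances of 10⁻¹⁵ with at
most 10,000 function evaluations.

Derived attributes: `j_max` (compliance at the end of creep), `j_r`
(recovered compliance at the end of recovery, read from the data),
`j_el`, `eta0`, `g_star`, `tan_delta`, `a_f`, `z`.

## Linking microstructure to rheology

Responses are linearized before regression: `log10` for `J_max`, `J_r`,
`η₀`; reciprocal for `G*`, `A_f`; identity for `J_el`, `tanδ`, `z`.
Each response is fitted separately (PLS1) against the five attributes by
NIPALS with X-deflation: predictors are autoscaled, the response
centred. Per-response models are the only reading consistent with
per-response factor counts; with a single response the NIPALS weight
update is its own fixed point, so each factor is closed-form. The factor
count is chosen at the minimum leave-one-out Root Mean PRESS
(`sqrt(PRESS/n)`, model refit on every size-(n−1) subset; ties within
10⁻¹² go to the smaller count). Coefficients are returned on the
original predictor scales with an explicit intercept. VIP scores use
`VIP_j = sqrt(p · Σ_a SSY_a w_ja² / Σ_a SSY_a)`; their mean square is 1
by construction and predictors with VIP > 0.8 are flagged important. At
full rank PLS1 reproduces ordinary least squares, which the tests verify,
and predictions and VIP match the independent `mixOmics` implementation
to 10⁻¹⁰.

Whether the source models also scaled the response internally cannot be
determined from coefficients printed on original predictor scales; for
PLS1 the choice only rescales intermediate quantities and leaves
back-transformed coefficients, R²Y and VIP unchanged, so the package
centres the response without scaling it.

Eight **frozen prediction equations** (one per response, on the
transformed scales) ship both in code and as a versioned JSON resource;
a checksum test asserts they agree digit for digit. `predict_rheology()`
evaluates them and back-transforms; a reciprocal prediction ≤ 0 is
flagged non-physical rather than raised, since linear models admit such
outputs for extreme inputs. These equations are tied to the
magnification and resolution of the micrographs behind them — batch
predictions therefore carry the pixel size as provenance, and absolute
predictions from other optics should not be trusted.

The exploratory layer — `correlation_matrix()` (per pair, an OLS line
and an exponential trend `y = a + b·e^(cx)`, the better R² selected;
exponential initialization from a log-linearized fit at offsets placed
just outside the data range on either side) and `pca_attributes()`
(autoscaled PCA with deterministic sign orientation) — reports
descriptive R² values with no multiplicity control, mirroring standard
practice for these matrices.

## Network types and classification

Six archetypes are defined by a lacunarity range plus the direction of
each attribute relative to a standard (additive-free) dough:

| type | lacunarity | br | pw | apl | epr | rheology |
|---|---|---|---|---|---|---|
| cleaved | ≤ 0.16 | −− | + | − | ++ | low viscous |
| rigid | (0.16, 0.26] | ++ | − | ++ | −− | highly viscous |
| spread | (0.16, 0.26] | ++ | − | + | − | viscoelastic |
| strengthened | (0.16, 0.26] | − | + | − | + | viscoelastic |
| particulate, dense | (0.26, 0.5] | − | + | −− | ++ | highly viscous |
| particulate, loose | > 0.5 | −− | ++ | −− | ++ | low viscous |

(with ly itself moving −, −, 0, +, +, ++ across the columns.)

Classification is three-step: the lacunarity bin selects candidates; the
five attributes are compared with the standard and collapsed to signs
with a ±10% dead band (the source scheme gives only ordinal arrows, so
the dead band is configurable); each candidate's pattern is scored +1
per matching sign, 0 when either side is neutral, −1 per contradiction,
and the best score wins. Ties are flagged ambiguous; a standard-like
sample in the middle bin resolves to *spread*, consistent with standard
doughs mapping to spread/strengthened networks. Double arrows are not
weighted more by default (an optional flag enables 2× weighting).
Printed ranges 0–0.16 / 0.17–0.26 / 0.27–0.5 / >0.5 leave
sub-resolution gaps; bins are treated as half-open with the boundary in
the lower bin. The ranges are indicative, not sharp — they shift if
another phase (e.g. gas bubbles from yeast) adds gaps — so the
classifier keeps them as crisp, configurable thresholds and the
consistency check below provides a second opinion.
`rheology_consistency()` places a sample's η₀ in cohort terciles and
reports whether the tercile matches the assigned type's viscosity
character; it never overrides the microstructural assignment.

## Synthetic data: what it emulates and what it does not

The generator exists so that every stage is testable without measured
data; its defaults are the study conditions the analysis assumes.

* **Attribute tables**: each archetype multiplies a standard-dough
  attribute vector by direction factors (−−: 0.5, −: 0.8, 0: 1.0,
  +: 1.3, ++: 2.0 — an invented, configurable quantification of ordinal
  arrows) and by unit-mean lognormal noise (multiplicative, because all
  attributes are positive). Lacunarity is clamped into the archetype's
  range afterwards so labels stay consistent with the classifier. The
  shipped standard (`pw` 3.5 µm, `br` 0.010 µm⁻², `apl` 30 µm, `ly`
  0.21, `epr` 0.005 µm⁻²) is synthetic configuration — no reference
  attribute values are published — chosen so the frozen equations return
  physically plausible rheology (`G*` ≈ 10⁴ Pa, `tanδ` ≈ 0.5–0.7,
  `J_max` ≈ 10⁻³–10⁻² Pa⁻¹) and every reciprocal-transformed response
  stays strictly positive across all six archetypes.
* **Micrographs**: idealized geometry per archetype — wavy meshes
  (spread; finer and thinner for rigid; wider, thicker, cut and patched
  for strengthened), scattered short segments (cleaved), packed disks
  (particulate dense), sparse elongated agglomerates (particulate
  loose). Drawing parameters were calibrated against the package's own
  quantifier so each archetype lands in its lacunarity bin and moves at
  least four of five attributes in the published direction relative to
  the spread mesh, which doubles as the image-domain standard dough.
  Sample jitter perturbs waviness, cut/patch counts and blob sizes, not
  the mesh spacing, whose lacunarity bins are narrow. The images are
  *not* photorealistic confocal simulations: no point-spread function,
  no staining photophysics, no partial-volume gray levels. Passing the
  end-to-end benchmark therefore shows the quantification-classification
  chain is internally consistent, not that it is robust to confocal
  imaging artefacts.
* **Rheometer curves**: closed-form model values on the default protocol
  grids (creep sampled every 2 s, 25 log-spaced frequencies with 1 Hz
  included) times lognormal noise; one noise factor per frequency scales
  G′, G″ and |G*| together so their consistency is preserved. The sweep
  uses the constant phase angle δ = π/(2z) a power-law relaxation
  implies.
* **Linked datasets**: responses are generated *through the frozen
  equations* on the transformed scale (Gaussian noise proportional to
  each response's across-sample SD), then back-transformed. Refitting
  PLS on noiseless output must therefore reproduce the shipped
  coefficients exactly — the package's strongest self-consistency check.
  Natural-scale consistency (`j_r ≤ j_max`) is *not* enforced between
  independently generated responses; violations are reported as
  warnings.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 512 px synthetic fields
(120 images for the end-to-end benchmark), 50-seed noise ensembles for
the Burgers recovery study, and linked datasets of 24–60 samples; these
sizes give stable medians while keeping a full run in a few minutes.
Fixed choices collected in one place: Otsu default threshold; crossing
number ≥ 3 for junctions; gliding boxes {8, 16, 32, 64, 128} px with
stride box/4 above 32 px; log-parameter Levenberg–Marquardt with
deterministic starts and (10⁻¹², 10¹²) bounds; LOO Root Mean PRESS with
smallest-count tie-breaking at 10⁻¹²; ±10% direction dead band;
half-open lacunarity bins.

## Known limitations

* Attribute absolute scales depend on magnification and resolution; the
  frozen equations and the default standard are only meaningful at the
  shipped 0.21 µm/px calibration.
* The classifier is a codified qualitative scheme: the ±10% dead band,
  the ordinal-to-factor mapping and the crisp bin edges are this
  package's operationalization, not measured constants.
* Skeleton metrics depend on the thinning algorithm; other thinning
  choices shift `br` and `epr` by a few percent (see the rotation
  caveat), so cross-software comparisons should re-baseline the
  standard dough.
* Yeast-leavened or gas-containing systems inflate lacunarity and are
  out of scope.

## A worked example

```{r example}
set.seed(1)
img <- generate_network_image("strengthened", size_px = 256, seed = 42)
at <- quantify_micrograph(img)
round(unclass(at), 4)

std <- standard_dough_attributes()
res <- classify_network(at, quantify_micrograph(
  generate_network_image("spread", size_px = 256, seed = 1)))
res$assigned

pred <- predict_all_rheology(std)
signif(vapply(pred, `[[`, numeric(1), "natural"), 4)
```
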