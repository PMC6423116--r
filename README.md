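# doughnet

Structure–function analysis of wheat dough in R: quantify the gluten
protein network in confocal micrographs, fit viscoelastic models to
rheometer data, link the two with partial least squares, and classify
samples into six gluten network types.

The mechanical behaviour of wheat dough is dominated by its gluten
network. `doughnet` is for cereal scientists and food rheologists who
have micrographs of protein-stained dough and/or oscillatory and
creep-recovery rheometer curves and want the quantitative bridge between
them.

## What it computes

**Protein network analysis (PNA).** A binary micrograph is reduced to
five attributes: protein width *pw* = area / skeleton length (µm),
branching rate *br* = junctions / area (µm⁻²), average protein length
*apl* = mean skeleton length per connected particle (µm), end-point rate
*epr* = endpoints / area (µm⁻²), and lacunarity *ly* = mean gliding-box
σ²/µ² of foreground mass (–; 0 for a filled image). Skeletons come from
Zhang–Suen thinning; junctions use the crossing-number criterion with
8-connected cluster merging.

**Rheology.** Frequency sweeps are fitted with the power law
*G\*(ω) = A_f·ω^(1/z)* (network strength *A_f*, connectivity *z*);
creep–recovery curves with the 4-parameter Burgers model
*J(t) = J₀ + J₁(1 − e^(−t/λ)) + t/η₀* and a 5-parameter two-Kelvin
model of the recovered compliance. Derived attributes: *J_max*, *J_r*,
*J_el = J_r/J_max·100*, *η₀*, *G\** and *tanδ* at 1 Hz, *A_f*, *z*.

**Linking.** NIPALS PLS1 per response on the five attributes
(responses linearized: log₁₀ for *J_max*, *J_r*, *η₀*; reciprocal for
*G\**, *A_f*), leave-one-out Root-Mean-PRESS factor selection, VIP
scores (VIP > 0.8 flags important predictors). Eight frozen published
prediction equations ship as code and JSON, e.g.

    log10(J_max) = 1.598·pw − 48.694·br + 0.016·apl − 9.188·ly + 52.705·epr − 4.874

**Classification.** Six network types — cleaved, rigid, spread,
strengthened, particulate-dense, particulate-loose — identified by
lacunarity range (≤0.16, three types in (0.16, 0.26], (0.26, 0.5],
>0.5) plus the direction of each attribute relative to a standard dough.

**Synthetic data.** Generators for archetype micrographs, rheometer
curves and linked attribute tables make every stage testable without
measured data.

## Worked example

Simulate a rheometer measurement at 0.5% noise and fit it:

```r
library(doughnet)
crv <- generate_rheology_curves(list(a_f = 12000, z = 4),
  list(j0 = 1e-4, j1 = 2e-4, lambda = 10, eta0 = 1e5),
  list(j0 = 1e-4, j1 = 1.2e-4, j2 = 6e-5, lambda1 = 5, lambda2 = 60),
  noise_cv = 0.005, seed = 3)
fit_rheology(crv$sweep, crv$curve)
#> power law: A_f = 1.199e+04 Pa s^(1/z), z = 4.005 (R2 = 0.9999)
#> Burgers creep: J0 = 0.0001005, J1 = 0.0001999 1/Pa, lambda = 9.985 s, eta0 = 9.999e+04 Pa s (R2 = 0.99991)
#> Burgers recovery: J0 = 9.853e-05, J1 = 0.0001279, J2 = 5.311e-05 1/Pa, lambda = 5.273 / 66.19 s (R2 = 0.78742)
#> attributes: J_max = 0.0021, J_r = 0.0002846 1/Pa, J_el = 13.55%, G* = 1.912e+04 Pa, tan(delta) = 0.414
```

The fitted parameters sit on the generating values: *η₀* within 0.01%,
*z* within 0.2%; *J_el* = 13.6% says this synthetic dough recovers about
an eighth of its deformation elastically, and *tanδ* = 0.414 = tan(π/8)
is exactly the loss factor a *z* = 4 power-law network implies.

Quantify a synthetic micrograph and classify it against a spread-mesh
standard:

```r
img <- generate_network_image("strengthened", size_px = 512, seed = 42)
at <- quantify_micrograph(img)
round(unclass(at), 4)
#>       pw       br      apl       ly      epr
#>   0.7024   0.1052 749.1692   0.2417   0.0272
std <- quantify_micrograph(generate_network_image("spread", size_px = 512, seed = 1))
classify_network(at, std)
#> assigned: strengthened  [lacunarity bin (0.16, 0.26]]
#> directions: pw +, br -, apl -, ly +, epr +
#> scores: rigid -5, spread -4, strengthened 5
```

Thicker strands (*pw* up), fewer branch points (*br* down), shorter
particles, more loose ends and larger gaps than the standard mesh —
every sign matches the strengthened archetype, and its score separates
cleanly from the alternatives.

Predict rheology from microstructure with the frozen equations:

```r
pred <- predict_all_rheology(standard_dough_attributes())
signif(vapply(pred, `[[`, numeric(1), "natural"), 4)
#>     j_max       j_r      j_el      eta0    g_star tan_delta       a_f         z
#> 1.112e-01 7.743e-02 2.069e+01 1.864e+03 6.201e+03 6.838e-01 6.353e+03 5.802e+00
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/doughnet.R simulate --type cleaved --n 5 --seed 1 --noise 0.1 --images --out imgs/
Rscript inst/cli/doughnet.R quantify --in imgs/ --pixel-size 0.2100 --out pna.csv
Rscript inst/cli/doughnet.R classify --in pna.csv --tol 0.10 --out types.csv
Rscript inst/cli/doughnet.R run --stages simulate,quantify,classify --n 5 --seed 1 --out run/
```

## Documentation

The methods vignette (`vignettes/gluten-network-analysis.Rmd`) describes
the models, their assumptions, the tunable parameters with units and
defaults, what the synthetic generators emulate and what they do not,
and the package's numerical choices and known limitations.
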