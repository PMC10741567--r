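# shadowcyte

Label-free identification and enumeration of CD34+ hematopoietic
stem/progenitor cells from **lens-free shadow images** — the in-line
holograms a cell casts directly onto a CMOS sensor when illuminated by a
semi-coherent LED, with no lenses and no fluorescent staining.

CD34+ fractions guide leukemia diagnosis and the timing of hematopoietic
stem-cell harvests, but the reference method (flow cytometry) needs
staining, trained operators and bulky instruments. `shadowcyte` implements
the full alternative analysis chain for an R audience:

1. **Simulation** (`opticalConfig`, `renderCellPattern`, `renderFrame`,
   `generateCohort`) — scalar angular-spectrum propagation of circular
   phase/amplitude objects under plane-wave illumination, rendered onto a
   full 2592 × 1944 px, 8-bit sensor frame with Gaussian read noise, plus
   ground-truth manifests. Two class-conditional parameter regimes emulate
   CD34+ cells versus residual mononuclear cells.
2. **Detection** (`detectCells` = `removeBackground` → `segmentShadows` →
   `extractObjects` → `cropCells`) — global-mean background removal,
   |deviation| > kσ binarization with one pass of 3 × 3 closing,
   8-connected components filtered to bounding boxes of 8–40 px, and
   30 × 30 crops around each centre.
3. **Shadow statistics** (`radialProfile`, `computeShadowParams`,
   `ppdGate`, `boxplotSummary`) — the four classical shadow parameters:

   - **CMV**, central maxima value: the intensity at the pattern centre;
   - **MMD**, maxima-to-minima distance: the radius of the first dark
     concentric ring;
   - **PPD**, peak-to-peak distance: `CMV − I(MMD)`, the intensity drop
     from the centre to the first dark ring;
   - **SMD**: the angular dispersion of MMD over eight sectors.

   CD34+ cells concentrate in the PPD gate **40–60 counts**; the gate
   screens the positive training class.
4. **Dataset assembly** (`buildManifest`, `assignSplits`,
   `preprocessCrop`) — PPD-gated labelling, the 8:1:1
   train/validation/test split, and bilinear 30 → 50 px resizing on the
   [0, 1] intensity scale.
5. **Classifier** (`architectureSpec`, `buildModel`, `trainModel`,
   `evaluateModel`, `gradCAM`) — an AlexNet-style network of eight 3 × 3
   convolutions with max pooling after layers 1, 2, 4, 6 and 8, three
   fully connected layers, and the SELU activation

   `selu(x) = λx` for `x ≥ 0`, `λα(eˣ − 1)` for `x < 0`,
   with λ = 1.0507, α = 1.6732,

   trained with Adam (batch 16, learning rate 5 × 10⁻⁴) on softmax
   cross-entropy. The numerical core is compiled (RcppArmadillo,
   im2col + GEMM). Grad-CAM exposes which image regions drive the class
   score.
6. **Quantification** (`classifySample`, `compareToReference`) —
   per-sample CD34+ percentages and Bland–Altman agreement against a
   reference method: bias = mean(measured − reference), 95% limits of
   agreement bias ± 1.96 SD, plus the OLS coefficient of determination.

## Worked example

Simulate a labelled cohort on a quarter-scale sensor, detect and crop the
cells of the first frame, and inspect their shadow statistics:

```r
library(shadowcyte)

cfg    <- opticalConfig(frame_shape = c(486L, 648L))
cohort <- generateCohort(cfg, n_per_class = 40, seed = 7)

det    <- detectCells(cohort$frames[[1]])
params <- do.call(rbind, lapply(det$crops, computeShadowParams))
head(params, 3)
#>   cmv   ppd mmd    smd valid
#> 1 126 44.74   9 0.4330  TRUE
#> 2 133 55.82   9 0.4841  TRUE
#> 3 154 96.58   8 0.0000  TRUE

nrow(ppdGate(params))      # crops inside the 40-60 PPD gate
#> [1] 3
```

Rows 1–2 are CD34+-like patterns (shallow first ring, PPD in the gate);
row 3 is a residual-cell pattern (PPD ≈ 97, far outside it). Agreement of
per-sample percentages against a reference method:

```r
compareToReference(c(22.4, 38.0, 55.1, 70.2, 85.2),
                   c(25.0, 35.2, 58.3, 66.9, 80.8))
#> AgreementReport on 5 pairs
#>   R^2 = 0.985, mean |diff| = 3.26
#>   bias = -0.94, 95% limits of agreement [-7.92, 6.04]
```

A thin command-line front end over the same functions lives at
`inst/cli/shadowcyte.R` (subcommands `simulate`, `detect`, `stats`,
`build`, `train`, `evaluate`, `compare`).

The methods vignette (`vignettes/shadowcyte-methods.Rmd`) documents the
propagation model, the parameter conventions, the synthetic study design
and its limitations.

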