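# fibrestorm

Single-fibre STORM analysis of molecular exchange in supramolecular
nanofibres.

Peptide-amphiphile (PA) nanofibres — stiff, ~7-nm-wide, micrometre-long
supramolecular polymers — exchange monomers with each other. Two-colour
single-molecule localization microscopy (STORM) can resolve *where* along
an individual fibre foreign monomers insert, and therefore *how* exchange
happens: random insertion along the whole contour, polymerization–
depolymerization at the ends, or fragmentation–recombination. This package
implements the full quantitative chain for such experiments, for
microscopists and soft-matter chemists working with localization data of
filamentous assemblies:

* **segmentation** of localization tables into fibres with density-based
  clustering and background removal;
* **backbone tracing** (raster → skeleton → longest geodesic → smoothing →
  data recentring) and arc-length parameterization;
* **density profiles** in 25-nm arc-length bins, apparent-width
  (resolution) estimation, linear densities, persistence length;
* **spatial correlation**: per-fibre autocorrelation with unbiased
  normalization, `g(r) = C(r)/mu^2`, two-channel cross-correlation,
  ensemble averages with 95% CIs, and a brute-force pair-distance oracle;
* **model fitting**: the overcounting model
  `g(r) = A exp(-r^2/(4 sigma^2))` (blinking artefact; `sigma` estimates
  the resolution) and the micro-emulsion microdomain model
  `g(r) = A exp(-r^2/(4 sigma^2)) + B exp(-r/alpha) cos(pi r/(2 r0))`
  (`r0` = mean microdomain size, `alpha` = coherence length), compared by
  a chi-squared ratio;
* **exchange kinetics**: foreign-channel linear-density time courses,
  exchange-state classification, positional insertion profiles, bundling
  detection and mechanism discrimination;
* a **forward simulator** of two-colour localization tables — worm-like
  chain fibres, microdomain-modulated labelling, blinking overcounting,
  background, bundling, and explicit exchange mechanisms — with full
  ground truth, so every stage is testable without experimental data.

## Worked example

Simulate a 25-fibre Cy3-like sample (5-µm fibres, labelling modulated by
300-nm microdomains with 500-nm coherence), run the full pipeline, and fit
both correlation models:

```r
library(fibrestorm)

sim <- simulateFibreField(25,
  list(cy3 = LabelField(0.15, m = 0.8, r0 = 300, alpha = 500)),
  ImagingModel(sigmaLoc = 20, muLoc = 3, backgroundDensity = 0.5),
  contourLength = 5000, persistenceLength = 10000, seed = 11)
sim$table
#> LocalizationTable with 60996 localizations, channels: cy3
#>   per channel: cy3=60996

res  <- analyzeFibreTable(sim$table, eps = 500)
keep <- Filter(function(f) backboneLength(f$backbone) >= 4000, res$fibres)
ens  <- ensembleCorrelation(keep, "cy3")

f1 <- fitOvercounting(ens, fitRange = c(50, 1500))
f2 <- fitMicroemulsion(ens, fitRange = c(50, 1500))
f2
#> Micro-emulsion model fit: A = 0, sigma = 72.23 nm, B = 0.5568, r0 = 313.5 nm, alpha = 409 nm
#>   (chi2 = 69.23, df = 54, converged)
compareFits(f1, f2)
#> Model comparison: chi2 ratio = 7.37 (threshold 2) -> microemulsion model
```

The fitted microdomain size (313 nm) and coherence length (409 nm) recover
the generative 300/500 nm; the chi-squared ratio far exceeds the selection
threshold, so the microdomain model is adopted — for a homogeneously
labelled (Cy5-like) sample the same comparison keeps the simpler
overcounting-only model. The ensemble curve is anti-correlated at
intermediate distances (`g(500 nm) = -0.151` here): a microdomain is
flanked by label-depleted regions.

The clustering radius of 500 nm (rather than the 100-nm default used for
homogeneous fibres) keeps a domain-bearing fibre one object across its
genuinely unlabelled stretches; see the methods vignette
(`vignettes/fibrestorm-methods.Rmd`) for this and every other parameter
choice.

A command-line front end over the same functions ships in
`inst/scripts/fibrestorm-cli.R` with verbs `simulate`, `segment`,
`backbone`, `profile`, `correlate`, `fit`, `kinetics`, `run-all`, a YAML
run configuration, and `--seed` / `--out` flags.

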