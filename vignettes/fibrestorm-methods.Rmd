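---
title: "Methods: single-fibre STORM analysis of molecular exchange in supramolecular nanofibres"
author: "fibrestorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-fibre STORM analysis of molecular exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrestorm)
```

# The problem

Peptide-amphiphile (PA) molecules self-assemble into stiff nanofibres about
7 nm wide and micrometres long. Whether and how monomers migrate between
such fibres — randomly along the whole contour, preferentially at the fibre
ends, or by fibre scission and recombination — determines the material's
dynamic and adaptive behaviour, but ensemble techniques such as FRET only
report a mixing timescale, not a mechanism. Two-colour single-molecule
localization microscopy (STORM) resolves the distribution of dye-labelled
monomers along individual fibre backbones, and correlation analysis of
those distributions discriminates the mechanisms.

`fibrestorm` implements the complete analysis chain for such experiments —
fibre segmentation, backbone tracing, arc-length density profiles,
spatial auto-/cross-correlation, correlation-model fitting and
exchange-kinetics summaries — together with a forward simulator that
generates two-colour localization tables under explicit, controllable
exchange mechanisms. Every analysis stage is therefore testable against a
known ground truth without any experimental download.

# The analysis model

## From localizations to profiles

A STORM experiment yields a table of localizations: fitted emitter
positions $(x, y)$ in nm with a frame index and a colour channel. The
pipeline:

1. **Segmentation** (`clusterAndFilter`): density-based clustering (DBSCAN
   semantics; a core point has at least `minPts` neighbours, itself
   included, within `eps`) pooled over both channels, followed by a
   minimum-size filter and a principal-axis elongation filter that rejects
   adsorbed aggregates. Everything else is background (`clusterId = -1`).
2. **Backbone tracing** (`traceBackbone`): localizations are rasterized on
   a 25-nm grid; the occupancy mask is dilated once (bridging single-cell
   sampling gaps) and thinned to a skeleton (Zhang–Suen); skeleton
   fragments closer than `gapBridge` (600 nm) are reconnected with straight
   chords — a fibre is physically continuous even where labelling happens
   to be absent; the longest geodesic through the skeleton graph is
   smoothed with a 5-vertex moving average, extended at both ends to the
   extremal projected localizations, and finally recentred on the locally
   averaged transverse offset of the data (a 7-vertex window), which
   removes the fraction-of-a-cell raster wobble that would otherwise
   inflate the apparent fibre width.
3. **Projection** (`projectToBackbone`): each localization maps to its
   nearest backbone point, giving an arc-length coordinate $s$ and a signed
   transverse offset $d$ (positive to the left of increasing $s$; ties
   toward smaller $s$; offsets beyond 100 nm are dropped and counted).
4. **Profiles** (`densityProfile`): counts of $s$ in half-open 25-nm bins
   covering the whole backbone, per channel.

The **apparent width** — $2\sqrt{2\ln 2}\,\hat\sigma_d$, the FWHM of a
Gaussian fitted to the $d$ distribution — estimates the experimental
resolution, because the physical fibre is far narrower than the
localization precision. With $\sigma_{loc} = 21.2$ nm the expected width is
$\approx 50$ nm.

## Correlation analysis

Localization-count fluctuations along a fibre mix two sources: genuine
monomer inhomogeneity and the stochastic imaging process (fluorophore
blinking produces several localizations of one dye — *overcounting*).
Spatial autocorrelation separates them. With bin counts $x_1..x_N$ and mean
$\mu$, `autocorrelate` computes the unbiased autocovariance

$$C(k\Delta) = \frac{1}{N-k}\sum_{i=1}^{N-k}(x_i-\mu)(x_{i+k}-\mu),
\qquad g(k\Delta) = C(k\Delta)/\mu^2 ,$$

so that a homogeneous random profile gives $g \approx 0$ at positive lags.
The $\mu^2$ normalization is our choice of the (unstated) constant that
makes $g$ dimensionless with a zero random baseline. Two-channel
cross-correlation is computed the same way and symmetrized over $\pm k$.
Ensembles average fibres with equal weight; 95% confidence half-widths are
$t_{0.975,\,n-1}\,\mathrm{SE}$ across fibres with the per-lag fibre count
$n(r)$ recorded.

Two models are fitted to ensemble curves by weighted least squares
(weights $1/\mathrm{se}(r)^2$; lag 0 always excluded; lags with fewer than
5 contributing fibres excluded; deterministic multi-start grids;
`minpack.lm` under bounds):

* **overcounting only**: $g(r) = A e^{-r^2/(4\sigma^2)}$ — the pair
  separation of two localizations of one dye is Gaussian with variance
  $2\sigma_{loc}^2$, so $\sigma$ estimates the resolution;
* **micro-emulsion (microdomains)**:
  $g(r) = A e^{-r^2/(4\sigma^2)} + B e^{-r/\alpha}\cos(\pi r / (2 r_0))$,
  where $r_0$ is the mean size of fibre regions enriched in the labelled
  monomer and $\alpha$ their coherence length. The damped cosine is
  negative around $r \approx 2 r_0$ (anti-correlation: a domain is flanked
  by depleted regions). The exact printed forms of the source models are
  not restated here; this family reproduces the documented parameter
  semantics and the negative lobe, and the generator (below) uses the same
  family, so recovery is exactly posed.

Both amplitudes are constrained non-negative: they are physical excess
probabilities, and allowing $A < 0$ lets a broad negative Gaussian absorb
intermediate-lag domain structure and destabilize $\alpha$. Model choice
follows a $\chi^2$ ratio: the micro-emulsion model is adopted only if
$\chi^2_{overcounting} / \chi^2_{micro}$ reaches a threshold (default 2;
the parsimony rule keeps the simpler model otherwise).

## Exchange kinetics

The linear density of foreign-channel localizations (count per µm of arc)
on initially single-colour fibres tracks the incorporation of monomers
from the other population. `densityTimecourse` summarizes per-fibre
densities per time point (n, mean, SD, median, quartiles, 5-µm⁻¹
histograms). The equilibrium reference is the density of original
single-colour foreign-channel fibres scaled by the mixing fraction
(default 0.5 for a 1:1 mix — at full mixing each fibre carries half the
single-colour dye density; the factor is exposed because the convention is
a design choice). `classifyExchangeState` splits fibres into
`unexchanged` (< 0.2 of the reference), `fully_mixed` (> 0.7) and
`partial`; the thresholds are ours and config-exposed — the subpopulations
are only described qualitatively in the literature.

Three signatures discriminate the mechanisms (`classifyMechanism`):

* a **flat positional insertion profile** (foreign counts folded about the
  fibre midpoint into 20 relative-position bins) with no end enrichment,
  plus an autocorrelation explained by overcounting alone → random
  insertion;
* a pooled **end/centre ratio above 3** → end exchange
  (polymerization–depolymerization); the decision uses counts pooled over
  fibres before folding because per-fibre-normalized profiles are extremely
  heavy-tailed under block-structured labelling, and end exchange leaves
  the fibre centre essentially empty so its pooled ratio is far above the
  threshold while the other mechanisms stay near 1 (observed spread
  roughly 0.8–2.2);
* a **block signature**: the fraction of fibres whose mean foreign
  autocorrelation over lags 100–600 nm is positive. Recombined fragments
  make almost every mixed fibre positive there (observed ≥ 0.85), while
  random insertion centres slightly below one half (the mean-subtracted
  estimator is biased slightly negative), observed ≤ 0.55; the threshold
  0.7 sits in the gap. A per-fibre sign statistic is used instead of the
  ensemble mean ± SE because fragmentation makes per-fibre foreign means —
  and hence normalized amplitudes — vary over orders of magnitude.

`bundleOverlap` flags bundles at $t \approx 0$: the fraction of profile
bins occupied in *both* channels among bins occupied in either; above 0.5
the object is two differently coloured fibres adsorbed together, not a
mixed fibre.

# The forward simulator

`simulateFibreField` / `simulateExchangeExperiment` generate what the
analysis consumes, plus the ground truth used as a recovery oracle.

* **Geometry**: discretized 2-D worm-like chains (`sampleBackbone`); the
  heading increment over a step $h$ is $\mathcal N(0, h/P)$, so the
  tangent correlation decays as $e^{-\Delta s/(2P)}$ and
  $\langle R^2\rangle = 2\lambda L(1 - (\lambda/L)(1-e^{-L/\lambda}))$
  with $\lambda = 2P$ (`wlcMeanSquaredR`, used as the closed-form test
  oracle). The 2-D convention is used consistently by the generator and
  by the `persistenceLength` estimator.
* **Labelling** (`placeLabels`): an inhomogeneous Poisson process with
  intensity $\lambda(s) = \lambda_0 (1 + m F(s))$ clipped at zero. $F$ is
  synthesized spectrally (`domainField`): a superposition of 256 cosines
  with random phases whose frequencies are Cauchy-distributed around
  $\pm\pi/(2 r_0)$ with scale $1/\alpha$, which yields exactly the
  autocorrelation $e^{-\Delta/\alpha}\cos(\pi\Delta/(2 r_0))$ — the same
  functional family the fitter assumes, making parameter recovery
  well-posed. The generative process behind real microdomains is unknown;
  only the correlation signature is matched.
* **Imaging** (`simulateLocalizations`): each label emits a geometric
  (default; heavier tail, matching blinking statistics), Poisson or
  deterministic number of localizations with mean `muLoc`, displaced by
  isotropic Gaussian noise `sigmaLoc`; background is uniform over the
  field of view; frames are uniform and carry no kinetic meaning.
* **Exchange** (`applyExchange`): per-label memoryless kinetics with one
  rate $k$ — a label has exchanged by time $t$ with probability
  $1-e^{-kt}$, drawing its new identity from the 50/50 mixed pool
  (simplest law consistent with monomer expulsion/reinclusion; no rate law
  is documented for the real system). End exchange restricts eligibility
  to within `endWindow` of either end. Fragmentation–recombination cuts
  each fibre at Poisson($kt$) uniform positions and rebuilds fibres of the
  original lengths from the randomly permuted fragment pool. Contiguous
  inert segments (mean length 500 nm) never change identity, emulating
  locally cohesive regions that resist exchange.

## Default study conditions

The generator defaults are the package's reference conditions: contour
5 µm; persistence length 10 µm (stiff fibres, consistent with the rigid
appearance of PA nanofibres); labelled-channel density 0.15 labels/nm (at
5% labelling a PA fibre carries ~10 labelled monomers per nm, so 0.15
*visible* labels/nm is conservative and gives the ~2000–3000 localizations
per fibre of a well-reconstructed image); modulation $m = 0.8$ with
$r_0 = 300$ nm and $\alpha = 500$ nm for the Cy3-like channel;
$\sigma_{loc} = 20$ nm; mean 3 localizations per label; background
0.5 µm⁻². Simulated fibres are laid out on a grid with pitch 2.2× the
contour length so distinct fibres can never approach within a clustering
radius.

# Numerical and design choices

* **Clustering radius for microdomain fibres.** With $m = 0.8$ the clipped
  intensity is exactly zero over stretches up to about $2 r_0$, so a
  single-colour Cy3-like fibre contains genuinely unlabelled gaps of
  several hundred nm. The default `eps = 100` nm (≈ 2× resolution) is
  appropriate for background removal on homogeneous fibres, but splits
  domain-bearing fibres at their gaps; the ensemble analyses therefore run
  segmentation at `eps = 500` nm for such samples — above the largest
  unlabelled stretch, far below the fibre spacing, and far too small for
  the sparse background (0.5 µm⁻²) to percolate. All parameters are
  config-exposed.
* **Well-reconstructed fibres.** Profiles enter ensembles only for fibres
  traced to at least 300 localizations, and the microdomain ensembles
  additionally require a traced length of ≥ 4 µm (80% of the nominal
  contour) so that every kept fibre spans many domain periods. Short
  fragments systematically under-represent empty domains and bias
  $\alpha$ low.
* **Fit ranges.** Lag 0 is always excluded (shot noise). Domain-model fits
  use lags 50–1500 nm: lag 25 is dominated by the overcounting spike and
  its binning distortion, and beyond ~3 coherence lengths the model is
  indistinguishable from zero, so longer lags only add noise.
  Overcounting-σ estimation on homogeneous fibres keeps lag 25 — for
  $\sigma \approx 20$ nm virtually all the Gaussian signal lies below
  60 nm.
* **Unbiased normalization bias.** Estimating $\mu$ per fibre biases
  $g$ slightly negative ($O(1/N)$); the effect is visible as a null
  coverage slightly below nominal and a suppressed positive tail beyond
  ~1 µm. It is the standard estimator's behaviour and is shared by the
  brute-force pair-distance oracle comparison.
* **Degenerate inputs.** Empty tables cluster to an empty candidate list;
  two-point clusters raise a tracing error; profiles of an absent channel
  are all-zero (autocorrelation of an empty channel is a contract error);
  a single-curve ensemble returns its CI as undefined; a zero curve fits
  with $A \approx 0$.
* **Reproducibility.** All generators take explicit seeds and are
  bit-reproducible; fitting uses deterministic multi-start grids, no
  random restarts.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to keep each stage to seconds while leaving
comfortable statistical margins: 30-fibre ensembles for microdomain
recovery (≈ 75 000 localizations through the full pipeline), 20 fibres for
the homogeneous control, 15 two-colour fibres for the cross-correlation
null, 10 replicates of 15 fibres per exchange mechanism for the
discrimination triad, and 500–600 worm-like-chain replicates for the
closed-form geometry oracles.

# What passing tests do and do not show

The simulator reproduces the *statistical structure* of the real
experiment — worm-like fibre geometry, microdomain-modulated labelling
with the fitted correlation family, blinking overcounting, uniform
background, and the candidate exchange mechanisms. It deliberately omits
photophysical realism (per-frame on/off kinetics, activation light),
stage drift, 3-D astigmatism, pixelation, and crossing-fibre
disentanglement. Recovery of generative parameters therefore validates
the analysis chain's correctness and calibration, not its robustness to
every instrumental artefact of a physical microscope. Real microdomains
need not arise from the spectral process used here; only their
correlation signature is matched, and any alternative closed form can be
swapped behind the same fit interface.

# Known limitations

* Backbones are planar and unbranched; loops and crossings are not
  disentangled.
* The $\chi^2$ ratio rule is the only model-selection criterion (no
  F-test or information criteria).
* Fragmentation–recombination rebuilds fibre geometry afresh (the 1-D
  label pattern is what matters downstream); spatial correlations between
  pre- and post-scission geometry are not preserved.
* The per-label exponential exchange law is an assumption; rate constants
  are inputs, not estimates fitted to ensemble kinetics.
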