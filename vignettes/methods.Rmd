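---
title: "Methods: multimodal nonlinear-microscopy tissue typing with carsdelin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal nonlinear-microscopy tissue typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During breast-conserving surgery the surgeon needs to know, within minutes,
whether the margin of an excised specimen contains tumor. Label-free
nonlinear microscopy offers a route: hyperspectral coherent anti-Stokes
Raman scattering (CARS) images report chemical-bond densities across the
high-wavenumber window (2700--3200 cm^-1), second harmonic generation (SHG)
highlights collagen (connective tissue), and two-photon fluorescence (TPF)
highlights cells and elastin. `carsdelin` implements the full analysis
chain that turns such raw multimodal mosaics into per-block tissue classes
(fat, cancer cells, cancer connective tissue, healthy cells, healthy
connective tissue) and a per-sample cancer/healthy call.

No imaging data accompanied the study this pipeline models, so the package
ships a synthetic phantom generator that reproduces the statistical
structure the analysis assumes. Every stage is exercised and verified
against that stated world.

## The measurement model

A raw frame intensity at pixel $(x,y)$ and wavenumber $\nu$ is modeled as

$$ I_{\text{raw}}(x,y,\nu) = S(x,y)\; P_p(\nu)^2 P_s\;
   \gamma(x,y)\, T_c(\nu) + o + \varepsilon $$

where $S$ is the multiplicative frame shading (vignetting), $P_p$ and
$P_s$ are pump and Stokes beam powers (CARS intensity scales as pump
squared times Stokes, which fixes the calibration exponents), $T_c$ is the
spectral template of tissue class $c$, $\gamma$ is a tissue-heterogeneity
scale, $o \approx 50$ mV is the constant ADC offset, and $\varepsilon$ is
detector noise. SHG and TPF channels are per-pixel log-normal draws from
class-conditional distributions, excited at the reference wavenumber's
pump power.

The correction chain inverts this model stage by stage:

1. **Offset subtraction** removes $o$; negative values are retained so
   noise statistics survive (clipping happens only at rendering).
2. **Power calibration** divides the channel at $\nu$ by
   $P_p(\nu)^2 P_s$ (SHG/TPF by $P_p(\nu_{\text{ref}})^2$), making the
   spectrum independent of input power.
3. **Flat-field correction** fits a fourth-order bivariate polynomial to
   the per-pixel mean over all frames (CARS channels only: SHG/TPF have
   structurally different spatial statistics) and divides frames by the
   unit-mean fitted field. The field is floored at 5% of its maximum
   before division because fitted polynomials can approach zero at frame
   corners. Flat-fielding has an inherent global-gain gauge freedom; all
   recovery checks compare up to one scale factor.
4. **Stitching** abuts frames on their grid with no blending: residual
   seams are diagnostic of imperfect shading correction, and one test
   asserts they appear and then shrink after correction.
5. **Block averaging** reduces noise by averaging 4x4-pixel blocks
   (3.7 x 3.7 um) into one spectrum. A block is kept iff >= 75% of its
   pixels are annotated and >= 75% of the annotated pixels agree on one
   label (the source study does not state its mixed-block rule; this is
   the package's choice, exposed as parameters).

## Feature selection

Two schemes are implemented.

**Multiclass SVM-RFE.** All pairwise linear SVMs are trained on the
remaining z-scored wavenumbers; each wavenumber is scored by the sum over
binary classifiers of its squared weight, and the lowest-scoring one is
eliminated per round ("adding the weights" of the binary subproblems is
ambiguous between signed, absolute and squared aggregation; the squared
sum is chosen for sign-invariance). Selected sets are read off the ranking
greedily under a 40 cm^-1 minimum pairwise distance — the width of Raman
peaks in this window — applied at read-out rather than during elimination,
which gives a well-defined greedy rule.

**Occurrence-voted SFS.** Each repeat grows a set greedily by
cross-validated classifier accuracy (stratified 5-fold; for more than two
classes the criterion is the accuracy of the pairwise majority-vote
ensemble, so feature selection and classification share one notion of
accuracy) up to 30 features; 20 repeats with different fold shuffles are
tallied and wavenumbers are ordered by occurrence count, ties broken by
mean selection step.

A noteworthy reproduction: in the five-class phantom world, RFE's top
wavenumbers are protein- and water-band points, *not* the 2850 cm^-1 lipid
peak — fat differs from soft tissue across the whole CH-stretch region, so
the famous peak is informative but redundant. The published wavenumber
list shows the same pattern. When the problem is reduced to fat-vs-cells,
the nearest-2850 point ranks in the top 3.

## Classification

Ten linear SVMs, one per unordered pair of the five classes, vote on every
block; the class with most votes wins, ties broken by summed signed
decision values (margin information already computed, deterministic). Each
pair sees the selected CARS wavenumbers plus exactly one morphology
channel — TPF for {cancer cells, fat}, {cancer cells, healthy cells},
{fat, healthy cells}; SHG for the other seven — because giving every SVM
all channels was reported detrimental. Scarce classes (fat, healthy cells)
are never subsampled; abundant classes are capped at 30,000 spectra.

The per-sample call sums blocks predicted cancerous (cancer cells +
cancer connective) against healthy (healthy cells + healthy connective);
fat is excluded as it is neither margin state. An exact tie is called
cancer: the clinical cost of a missed positive margin is asymmetric.

Evaluation is group-aware: cross-validation folds are assigned at the
sample level so blocks from one specimen never span train and test.

### The linear SVM

No SVM implementation is available in the dependency set, so the package
implements an L2-regularized squared-hinge linear SVM by dual coordinate
descent in C++ (the standard dual CD scheme; the bias enters as an
augmented, hence regularized, constant feature). The squared hinge keeps
the primal smooth and differentiable, so the test suite verifies the
solver against an independent oracle that minimizes the primal directly
with L-BFGS-B. Fits use a private seeded permutation and never touch R's
RNG stream.

## The synthetic phantom: what it emulates, and what not

Templates are sums of Gaussian bands (true CARS lineshapes are dispersive,
but the analysis uses intensities only, so symmetric analytic bands
suffice): fat is dominated by the CH2 stretch at 2850 cm^-1; the other
classes combine the protein CH3 band near 2930 cm^-1 with a broad water
band near 3150 cm^-1, scaled so each cancer class has a strictly lower
water/fat ratio (I(3150)/I(2845)) than its healthy counterpart. SHG/TPF
intensities are log-normal per class: connective tissue dominates SHG,
healthy cells peak at low TPF while cancer cells carry a heavier
high-intensity TPF tail, fat emits only background in both. Class regions
are smoothed random blobs on the stitched canvas with one dominant anchor
bump per class (so every configured class is guaranteed present); ~8% of
pixels are left unannotated.

Stochastic instrument terms, each a stated default chosen once:

* detector noise, additive Gaussian, sigma 5 mV (vs signals of 0.05--1 V);
* ADC offset 50 mV;
* per-wavenumber pump-power fluctuation, uniform +/-5% (the study reports
  fluctuations exist but not their scale);
* frame vignetting, a radially symmetric order-4 polynomial falling to
  0.65 at corners (bright center, dim edges);
* tissue heterogeneity `biological_cv = 0.10`: a patchy (4-px cells)
  multiplicative log-normal scale on the CARS spectrum. Without it every
  wavenumber separates classes by hundreds of sigma and weight-based
  feature ranking is meaningless; real class-mean spectra show substantial
  within-class spread.

A `separation` dial blends all class templates and channel distributions
toward their common mean: 1 is the stated world, 0 makes the classes
statistically identical, which is how the chance-level degradation
property is exercised.

The phantom does **not** model: non-resonant background interference or
any coherent CARS field effects, point-spread functions, stitching
registration error, or spatial correlation between morphology channels and
the CARS texture. A green end-to-end test therefore establishes that the
pipeline recovers the statistical structure it assumes — not that the
classifier would reach the published clinical numbers on patient tissue,
which were computed on undeposited data and are out of desk-scale reach.

## Numerical choices and degenerate inputs

* z-scoring uses training-fold statistics inside every CV fold;
  zero-variance features scale by 1 (z-scores stay 0).
* Majority-vote ties break by summed signed decision values; sample-call
  ties break toward cancer.
* The water/fat ratio is flagged undefined (NA) for non-positive
  denominators; all-zero mean images abort the illumination fit; empty
  classes are omitted from histograms with a flag; single-record classes
  report sd 0 with a flag.
* Sub-seeds derive from the global seed plus a stage-name hash, so adding
  or disabling a stage never shifts another stage's random stream; all
  derived seeds stay below 2^31.
* Multiclass MCC uses the k-class covariance form on a double-precision
  confusion matrix (integer products overflow beyond ~46k blocks).

## Scale of the test world

The acceptance study runs 6 samples of 2x2-frame mosaics (256-px frames,
10 cm^-1 axis step, ~16k blocks per sample) with per-class training caps
(800 for ranking, 30,000 for classification) so the whole suite fits a
single-CPU desk budget; these are compute-scale choices, not model
parameters. Unit tests run the same code on smaller phantoms.

## Known limitations

* The per-frame shading is identical across frames of one stack; the
  estimate is therefore per stack (the study's per-session vs per-sample
  fitting is unstated).
* RFE eliminates exactly one feature per round (batch size unstated in the
  source; one is the conservative choice).
* The published 10 RFE wavenumbers are data-dependent and are not treated
  as targets.
* Probability calibration, kernelized classifiers and spatial
  regularization of the class map are out of scope by design.
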