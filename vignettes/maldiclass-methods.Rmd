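---
title: "Methods: classifying MALDI imaging peptide profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying MALDI imaging peptide profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiclass)
```

## The problem

MALDI imaging mass spectrometry acquires a tryptic-peptide profile spectrum
at each raster position of a tissue section. After a pathologist annotates
tumor regions, the spectra from those regions can be used to classify
tissues by molecular subtype — here, by oncogene mutation status
(BRAF-mutated, NRAS-mutated, or wildtype melanoma). `maldiclass` implements
the full statistical workflow for this setting: spectral preprocessing,
univariate and wrapper feature selection, and linear classification
evaluated under cross-validation designs that respect the grouping of
spectra within patients.

Because clinical imaging cohorts of this kind are rarely deposited, the
package ships a synthetic cohort generator with known ground truth, so that
every stage — and the pipeline end to end — can be validated by
parameter-recovery experiments rather than by eyeballing.

## Preprocessing

A raw profile spectrum is a pair of aligned vectors over the acquisition
range (default m/z 600–3200 Da). The canonical processing order, recorded
per spectrum in a provenance field, is:

1. **TopHat baseline subtraction.** The morphological opening of the
   intensity profile — erosion (running minimum) followed by dilation
   (running maximum) with a flat structuring element — is subtracted from
   the profile. Any baseline component broader than the structuring element
   is removed exactly; peaks narrower than the element survive at full
   height, and the output is non-negative and idempotent under a second
   pass. The element width (`window_points`) defaults to the odd number of
   samples spanning about 10 Da: wider than any singly-charged tryptic
   peptide peak, narrower than chemical-noise baseline undulation. Edges are
   replicate-padded, which avoids the artificial troughs that infinite
   padding would create. The erosion/dilation kernels are compiled code; a
   naive sliding-extrema implementation serves as the test oracle.
2. **TIC normalization.** Each spectrum is rescaled so its total ion count
   equals a common target (default 1); the original TIC is retained. This
   removes per-pixel ionization-efficiency differences; it assumes the
   overall signal mass is comparable across tissue classes.
3. **Mass-shift alignment.** Residual calibration error is modeled as a
   single global shift per spectrum, estimated by maximizing the
   cross-correlation between the spectrum and a comb of reference peak
   positions over a ±1 Da window on the spectrum's native sampling grid.
   The resolution of the estimate is therefore one grid step; sub-grid
   jitter is absorbed by the binning tolerance.
4. **Apex binning.** Each feature value is the maximum intensity inside the
   half-open window `[mz − tol, mz + tol)` around a representative feature
   mass — apex rather than area, matching the "average peak intensity"
   semantics of published discriminator tables. Features dead in every
   spectrum are dropped. Windows come either from an explicit peak list
   (e.g. known peptide masses, or the generator's ground truth) or from a
   uniform partition of the range.

Spectra are optionally subsampled to around 17 per tumor region before
statistics, reflecting the smallest annotated tumor areas in the motivating
study; this keeps each patient's contribution comparable.

## Feature selection

Two selectors are provided.

**AUROC thresholding.** For each feature the area under the ROC curve is
computed by the Mann–Whitney rank identity `U/(n1·n0)` with midrank tie
handling, so it equals the probability that a random member of one class
exceeds a random member of the other. Because a feature may be higher in
either class, thresholds are applied to the folded score
`max(AUC, 1 − AUC)`; published workflows use cutoffs between 0.7 and 0.84.
No multiplicity correction is applied (none is used in the motivating
workflow); the selection is descriptive, not inferential.

**Forward feature selection (FFS).** A greedy wrapper: at each step every
remaining feature is tentatively added, the cross-validated accuracy of the
classifier on the enlarged set is computed, and the best addition is kept,
with ties broken toward the lowest m/z for platform-independent
reproducibility. Selection stops when the improvement falls below
`min_improvement` (default 0.001) or at `max_features` (default 30, the
upper end of published trace sizes). The internal criterion deliberately
uses the same cross-validation design as the final evaluation: scoring
candidates by resubstitution would bias selection toward overfit sets.
Note that the reported CV accuracy of an FFS-selected set is still an
optimistic estimate (the selection itself consumed the folds); an unbiased
estimate would require nested CV, which the motivating workflow does not
use and which is out of scope here.

## Classifiers

Both classifiers are linear, appropriate for profiles where features can
vastly outnumber samples.

**Shrinkage LDA.** The two-class linear discriminant
`w = Σ⁻¹(μ₁ − μ₀)` uses a pooled within-class covariance with the
maximum-likelihood denominator `n`, shrunk toward the scaled identity
`μI`: `Σ_λ = (1−λ)S + λμI`. With `shrinkage = "auto"` the intensity λ is
the Ledoit–Wolf estimate; a fixed value in `[0, 1]` is also accepted. Plain
LDA is singular when features outnumber samples; shrinkage keeps the
discriminant well-defined there. Class priors are uniform, not empirical:
under leave-one-out the held-out unit's class is always underrepresented in
training, and empirical priors would push every prediction toward the other
class, biasing null-data accuracy below chance. The ML denominator makes
the estimator exactly invariant under duplication of the training set.

**Linear SVM.** A soft-margin maximum-margin classifier
(`e1071`/libsvm) with cost 1. Features are standardized using
training-fold statistics only, so no scale information leaks from test
folds; whether the motivating workflow standardized is unstated, so this is
exposed as a switch (default on).

## Cross-validation designs

- **Leave-one-out**: one unit out per fold.
- **k-fold** (k = 4 or 10): a seeded random partition into k groups whose
  sizes differ by at most one; unstratified by default, faithful to a plain
  "randomly divided into equisized groups" protocol, with stratification
  available as an option.
- **Holdout**: a single stratified split without cross-validation, the
  control used to probe overfitting.

The evaluation **unit** is either the spectrum or the patient. At patient
level, spectra are first collapsed to per-patient mean profiles
(feature-wise arithmetic means), so all of a patient's spectra always
travel together and no patient can appear on both sides of a split — the
central anti-leakage contract of per-patient designs. Accuracy is reported
from the confusion table pooled over folds, not as a mean of fold
accuracies. AUROC selection is recomputed at each analysis level rather
than assumed transferable between spectra and mean profiles, since
published feature counts differ between levels at the same threshold.

## The synthetic cohort generator

The generator emulates the study conditions of a three-genotype melanoma
cohort: 22 patients per class, 17 spectra per patient tumor region,
acquisition range 600–3200 Da. Each spectrum is a sum of Gaussian peaks
(constant σ = 0.35 Da, centers snapped to a 0.1 Da grid), a smooth
exponential baseline `a·exp(−(mz − mz_min)/τ)` with a = 15 and τ = 400 Da
standing in for the matrix-cluster background that TopHat must remove,
additive point noise, and a per-spectrum global mass shift
~ Normal(0, 0.15 Da).

Intensities are hierarchical and log-normal throughout, reflecting the
positive, heteroscedastic character of MALDI intensities: base peak
intensities are drawn log-normally spanning roughly 2–50 arbitrary units
(the magnitude range of published average discriminator intensities); each
discriminative peak's class means differ by exactly `2^|effect_log2fc|`
(default effect 1.0, within the published 0.3–2.5 range), with effects
cycling over the classes; each patient draws a per-peak expected intensity
around its class mean (CV 0.3); each spectrum draws apex amplitudes around
the patient mean (CV 0.2). All log-normal draws are mean-corrected, so
arithmetic class means equal the declared ground truth — which is what
makes exact parameter-recovery tests possible. The patient level of the
hierarchy is essential: it creates the within-patient correlation that
makes spectrum-level cross-validation optimistically biased and
patient-level designs necessary, the methodological point the package
exists to support.

What the generator does **not** emulate: 2-D spatial structure (spectra are
region-grouped profiles, not images), isotope patterns and charge states,
detector saturation, peak-width dependence on m/z, correlated (e.g.
same-protein) peptide peaks, or batch effects between slides. Passing
parameter-recovery tests on this generator therefore demonstrates
correctness of the statistical machinery under a plausible noise model, not
performance on real tissue data.

## Numerical and validation choices

- Binning windows are half-open `[lo, hi)` so adjacent windows partition
  the axis without double counting; explicit windows must not overlap.
- Shift estimation searches the native grid; ties are broken toward the
  smallest absolute shift.
- FFS ties break toward the lowest m/z; k-fold partitions, holdout splits
  and per-region subsampling are all seeded and restore the caller's RNG
  state.
- Accuracies in report tables are rounded half-up to integer percent,
  matching the convention of published accuracy tables.
- Degenerate inputs fail loudly and by name: all-zero spectra at TIC
  normalization, single-class training sets, folds whose training data lose
  a class (named with fold and seed), constant matrices at PCA, non-positive
  means at fold changes.

Validation experiments are sized to finish quickly while keeping the study
geometry: parameter recovery runs ten replicate cohorts of 3 × 22 patients
× 17 spectra on a reduced window (600–1400 Da, 30 peaks, 9 discriminative,
effect 1.5, spectrum CV 0.2); with those conditions the planted features
are recovered by the 0.8 AUROC filter and leave-one-patient-out LDA/SVM
accuracy is essentially perfect. Null cohorts (effect 0, 22 patients/class)
are evaluated at patient level for all six model × design combinations;
accuracies pooled over the ten replicates must stay within three binomial
standard deviations of chance. The pooled check is used because individual
cross-validation accuracies have super-binomial variance (fold predictions
share training data), and because at spectrum level the generator's
patient hierarchy makes null accuracy genuinely exceed chance — that excess
is the leakage the patient-level designs exist to avoid, and is exercised
separately by the overfitting control (post-selection resubstitution must
exceed cross-validated accuracy on null data).

## Known limitations

- Binary comparisons only; a three-class problem is run as pairwise
  contrasts, as in the motivating workflow.
- One global mass shift per spectrum; no non-linear m/z warping.
- No peak picking: features come from explicit masses or uniform bins, so
  vendor-software peak tables must be supplied, not inferred.
- The LDA/SVM hyperparameters are deliberately plain (no nested tuning);
  reported accuracies compare designs, they do not chase a maximum.
- imzML input is not supported; spectra are exchanged as two-column text
  with a CSV manifest.
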