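Package: maldiclass
Title: Classification of MALDI Imaging Mass Spectrometry Peptide Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for tissue classification from MALDI imaging mass
    spectrometry peptide profiles: morphological TopHat baseline
    subtraction, total-ion-count normalization, mass-shift alignment and
    peak binning; AUROC-based and wrapper forward feature selection;
    shrinkage linear discriminant analysis and linear support vector
    machine classifiers evaluated under leave-one-out, k-fold and holdout
    cross-validation at the spectrum and the patient level, with strict
    patient-grouped fold assignment. Includes a hierarchical synthetic
    cohort generator with known ground-truth discriminative peaks for
    validation of every stage, and reporting of group fold-change tables
    and accuracy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
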