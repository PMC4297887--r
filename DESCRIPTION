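Package: cisconvert
Title: Predicting Conversion from Clinically Isolated Syndrome to Multiple
    Sclerosis from Lesion and Clinical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Single-patient prediction of conversion from a clinically
    isolated syndrome (CIS) to clinically definite multiple sclerosis from
    baseline MRI lesion masks and clinical records. Implements extraction of
    eight lesion-mask features (18-connected component counting, lesion load,
    mean PD/T2 lesion intensity, distance-to-centre statistics in template
    space, and a three-bin lesion size profile), encoding of four
    clinical/demographic features, balanced-bootstrap leave-one-out
    cross-validation of a polynomial-kernel support vector machine trained by
    sequential minimal optimisation, and forward as well as exhaustive
    wrapper feature-combination search.  A synthetic cohort generator
    (NIfTI volumes, masks in native and template space, clinical CSV) with
    plantable class effects makes the whole pipeline testable end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
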