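Package: dirqa
Title: Patient-Specific Quality Assurance for Deformable Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for patient-specific quality assurance (QA) of deformable
    image registration (DIR) in abdominal radiotherapy. Generates a synthetic
    abdominal CT phantom with organ masks and an analytic multi-level dose
    model, constructs ground-truth displacement vector fields combining
    smooth superior-inferior respiratory motion with uniform digestive organ
    shifts, runs a multi-resolution demons registration (or imports an
    external DVF), and quantifies both the voxelwise geometric error of the
    candidate registration and the dosimetric error it would introduce into
    dose accumulation, including DVH-metric errors and binned correlation
    analyses between displacement magnitude, registration error, and dose
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
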