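Package: voxar
Title: Voxelwise Atlas Rating for Atlas-Based Computer-Aided Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided diagnosis of morphology-altering conditions from
    3D volumes using multiple unlabelled atlas databases. Implements the
    voxelwise atlas rating (VoxAR) method: a Gaussian-windowed local
    normalised correlation coefficient (LNCC) between the target and every
    mapped atlas, pooled cross-database ranking of the per-voxel
    similarities, a rating map assigning each voxel the condition holding an
    absolute majority among the T most similar atlases, and a rating
    histogram whose mode is the diagnosis. Also provides the predecessor
    image-synthesis approach (ISA; rank-weighted intensity fusion per
    database, diagnosed by global NCC), rough organ-mask extraction and
    majority-vote mask fusion, a two-stage registration adapter with a
    built-in affine backend, a synthetic multi-condition phantom generator,
    and experiment harnesses (leave-one-out comparison, database-size sweep,
    unbalanced-database study, missing-pathology probe).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
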