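Package: spicafuse
Title: Sparse Parallel ICA Fusion of Gray Matter Volume and SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint sparse factorization of a gray-matter-volume (voxel) block
    and a SNP-dosage block into loadings and components, with Infomax ICA per
    modality, a Hoyer sparsity constraint on the genomic components, adaptive
    enhancement of cross-modal loading correlations, ICASSO run-stability
    selection, and order estimation by run-to-run consistency. Includes the
    surrounding analysis machinery: voxel masking and subject quality control,
    voxel-wise covariate residualization, region-of-interest reconstruction
    from prior spatial maps, p-value-informed LD clumping, family
    random-intercept association models, permutation and subsampling stability
    checks, projection-based replication in an independent cohort, and a
    synthetic-data generator with planted cross-modal links for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
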