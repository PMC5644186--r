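Package: aips
Title: Ancestry Inference Using Principal Components and Spatial Interpolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based inference of genetic ancestry among closely related
    populations. Fits a P-mode principal component analysis over a panel of
    ancestry informative markers (AIMs), yielding portable per-SNP weights that
    project new samples into a shared score space. Ancestry membership
    proportions are then assigned by inverse-distance-weighted interpolation
    against centroids of labelled reference populations, using power-distance,
    exponential-distance, or eigenvalue-weighted distance kernels, with an
    explicit geometric rule selecting each individual's admixture set.
    Includes Hotelling's T-squared tests of centroid separation with
    permutation p-values, accuracy evaluation against known labels, PLINK
    binary and text genotype input/output, and a Balding-Nichols simulator of
    structured and admixed genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
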