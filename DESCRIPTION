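Package: tomojoint
Title: Joint Iterative Reconstruction and Reprojection Alignment for
    Parallel-Beam Nanotomography
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-acquisition alignment of jittered parallel-beam
    tomographic projection stacks by joint estimation of per-projection
    translation errors and the 3D object. Provides voxel-driven forward
    and back projection operators with a matched transpose, SIRT, MLEM
    and ramp-filtered backprojection reconstruction kernels, sub-pixel
    phase-correlation registration, a sequential (reconstruct-then-align)
    baseline driver and the joint driver that interleaves one registration
    pass after every reconstruction update, a three-sphere simulation
    benchmark with uniform jitter and Gaussian noise, convergence metrics,
    and TIFF/CSV dataset input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
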