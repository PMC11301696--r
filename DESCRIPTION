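Package: petsim
Title: Analytical PET Simulation and Image-Quality Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analytical simulation of positron emission tomography (PET)
    acquisitions for a cylindrical time-of-flight scanner. Given 3D activity
    (Bq/ml) and attenuation (1/cm) maps, the package produces realistic noisy
    sinograms via a counts-preserving Joseph-method forward projector,
    attenuation factors, uniform randoms, a 2D single-scatter estimate expanded
    axially by inverse single-slice rebinning, and element-wise Poisson noise;
    images are reconstructed with ordinary-Poisson ordered-subset
    expectation maximization (OP-OSEM). An evaluation stack covers NEMA
    image-quality analysis (recovery coefficients, background variability,
    voxelwise mean/STD maps, Freedman-Diaconis histograms), intensity and
    grey-level co-occurrence texture features, and segmentation concordance
    (STAPLE consensus, overlap/volume metrics, shape features, Lin's
    concordance correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
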