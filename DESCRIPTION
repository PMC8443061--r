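Package: gprnorm
Title: Gaussian Process Regression and Uncertainty Decomposition for Normative Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact Gaussian process regression (GPR) with linear, radial basis
    function (RBF), Matern, rational-quadratic, white-noise and weighted-sum
    kernels, built for studying what the GPR predictive variance does and does
    not measure in normative modeling. The predictive variance of exact GPR
    depends only on the kernel and the training inputs, so it quantifies
    epistemic (sampling) uncertainty, not the conditional outcome variability
    Var(y|x) that a normative model must estimate. The package provides the
    posterior mean and variance in closed form, an equivalent singular-value
    decomposition quadratic form over explicit kernel feature maps, an
    epistemic plus aleatoric variance decomposition with a sliding-window
    aleatoric estimator, z-scores under both the naive and the decomposed
    variance, marginal-likelihood hyperparameter optimization for a hybrid
    linear + RBF + white kernel, and seeded generators for the homoskedastic
    and heteroskedastic synthetic benchmark datasets used to demonstrate the
    distinction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), kernlab, optparse, jsonlite, withr
Config/testthat/edition: 3
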