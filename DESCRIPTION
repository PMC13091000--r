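Package: dtialps
Title: Diffusion-Tensor ALPS Index Computation and Longitudinal Modelling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the diffusion along the perivascular space (DTI-ALPS)
    index from diffusion-tensor volumes, with automated placement of the
    periventricular projection- and association-fiber regions of interest
    and a corpus-callosum Dxx negative control.  Provides a log-linear
    tensor fit for diffusion-weighted volumes, group-wise IQR outlier
    filtering with a bilateral-validity rule, linear mixed-effects
    trajectory models with participant-level random slopes (and an
    optional family-level intercept), an ALPS versus Glx/GABA regression,
    Benjamini-Hochberg FDR correction, and 2x2 contingency tests.
    Synthetic tensor phantoms with known ground-truth ALPS and simulated
    longitudinal cohorts make every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
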