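Package: vaxpolicy
Title: Synthetic Control and Difference-in-Differences Evaluation of School
    Vaccination Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-experimental evaluation of state school-entry vaccination
    policies (such as California's 2016 elimination of nonmedical exemptions)
    from kindergarten vaccination panels. Provides a state-level synthetic
    control estimator with nested donor-weight/predictor-weight optimization,
    cross-validated stepwise predictor selection and placebo (permutation)
    inference; a county-level difference-in-differences estimator with
    cluster-robust (CR1) standard errors and parallel-trends diagnostics;
    the paper-style cleaning rules for vaccination panels (population
    filters, MMR-as-proxy substitution, impute-or-exclude missingness); a
    robustness suite (leave-one-out, covariate sweeps, proxy-free
    subanalysis); and a synthetic panel generator with known ground truth so
    every stage is testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
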