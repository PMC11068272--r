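Package: coalsky
Title: Bayesian Coalescent Skyline Plot Models for Demographic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference of demographic histories (effective population size
    through time) from fixed or sampled genealogies under the heterochronous
    coalescent. Provides the coalescent probability density over piecewise
    constant or piecewise linear population-size trajectories with analytic
    per-segment integrals, nine interchangeable prior models on the
    trajectory (Constant, Skyline, BSP, EBSP, Skyride, Skygrid, GMRF, HSMRF
    and the Poisson-change-point Skyfish model), Metropolis-Hastings and
    reversible-jump MCMC samplers, stepping-stone marginal-likelihood
    estimation for Bayes-factor model selection, an exact inversion-sampling
    coalescent simulator with a Jukes-Cantor sequence simulator for
    validation, trajectory summarization on time grids, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
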