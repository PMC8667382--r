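Package: zibayes
Title: Bayesian Inference for Zero-Inflated Bernoulli Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits zero-inflated Bernoulli (ZIB) models that separate
    structural zeros (units never at risk) from sample zeros (at-risk units
    without the event) in a Bayesian framework.  Without covariates the
    marginal outcome is Bernoulli with success probability omega * p, so the
    exposure probability omega and the occurrence probability p are not
    identifiable by likelihood alone; identification comes from informative
    uniform priors, and the exact posterior marginals are available in closed
    form through the beta distribution function.  With covariates, both model
    parts get logit links and normal priors on the coefficients, and the
    posterior is sampled with a built-in Hamiltonian Monte Carlo sampler (a
    random-walk Metropolis fallback is included).  The package also provides
    the matching synthetic-data generator, a replicated parameter-recovery
    harness, and pooled / exposed-only logistic-regression comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
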