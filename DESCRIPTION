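Package: synsampler
Title: Synaptic Sampling: Stochastic Plasticity as Posterior Sampling over Network Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models network plasticity as Langevin sampling from a posterior
    distribution over synaptic parameters instead of convergence to a maximum
    likelihood point estimate. Provides the stochastic parameter-sampling
    engine (batch, online and discrete-time rules with temperature and
    state-dependent sampling speed), Gaussian/mixture/uniform structural
    priors, reference stationary-density oracles based on the Fokker-Planck
    equation, a restricted Boltzmann machine trained by contrastive divergence
    with weight priors and exact test log-likelihood, a spiking winner-take-all
    generative circuit with stochastic STDP and structural plasticity
    (exponential parameter-to-weight mapping, synapse retraction and regrowth),
    spine formation/survival statistics with power-law and two-term
    exponential fits, synthetic sensory environments (tuning-curve populations
    over mixture-of-Gaussians worlds, digit-like binary images, bimodal
    audio/visual pattern pairs), and reproducible experiment drivers for
    generalization, environment-enrichment and lesion-compensation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
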