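Package: bayesdend
Title: Bayesian Cue Integration in Conductance-Based Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single neurons whose dendritic compartments act as
    Gaussian opinions about the somatic membrane potential: each compartment's
    effective reversal potential is the opinion and its membrane conductance
    the reliability. The soma pools these opinions into a Gaussian posterior
    by conductance-weighted (precision-weighted) averaging, samples from it
    via Langevin (Ornstein-Uhlenbeck) membrane dynamics, and learns target
    potential distributions with a gradient rule on excitatory and inhibitory
    synaptic weights. Includes Gaussian-tuned feature-detector populations,
    training and evaluation pipelines for multimodal discrimination,
    cross-modal suppression sweeps, stimulus-evoked response statistics, and
    psychometric-curve fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    deSolve,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
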