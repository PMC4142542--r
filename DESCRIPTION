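Package: critnet
Title: Criticality and Attention in Recurrent Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a stimulus-driven recurrent network of excitatory and
    inhibitory integrate-and-fire neurons in which attention, modelled as a
    global change of coupling efficacy, controls the emergence of gamma-band
    synchrony. Provides the full quantification chain used to characterise
    such networks: synthetic local field potentials by exponential-kernel
    filtering of spiking activity, complex Morlet wavelet power spectra,
    single-trial stimulus decoding by linear support vector machines and a
    closed-form discriminability index, neuronal-avalanche statistics with
    discrete maximum-likelihood power-law fits, Kolmogorov-Smirnov
    goodness-of-fit and a supercriticality indicator, coarse-grained
    spike-pattern entropy, and drivers that sweep the excitatory/inhibitory
    coupling plane to locate the transition region between subcritical and
    supercritical dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr,
    yaml,
    readr
Config/testthat/edition: 3
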