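# Random valid parameter sets spanning a generous physiological range;
# used by property-style tests and the acceptance checks.
random_params <- function() {
  spina_parameters(
    alphaG = stats::runif(1, 0.05, 0.3),
    betaG  = stats::runif(1, 2e-4, 2e-3),
    Gbeta  = exp(stats::runif(1, log(0.5e-12), log(10e-12))),
    Dbeta  = stats::runif(1, 3e-3, 12e-3),
    alphaI = stats::runif(1, 0.1, 0.4),
    betaI  = stats::runif(1, 1e-3, 8e-3),
    GR     = exp(stats::runif(1, log(0.5), log(10))),
    DR     = stats::runif(1, 0.5e-9, 4e-9),
    GE     = stats::runif(1, 20, 100),
    P      = stats::runif(1, 50e-6, 300e-6))
}

# the healthy reference equifinal pair, used across many tests
ref_steady <- function() equifinal_state(spina_parameters())
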