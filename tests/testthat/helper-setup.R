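# Shared fixtures for the suite. table1_params() is the reference parameter
# table (simulation-2 myosin twisting constant); frag_setup() the
# small-adhesion regime used for all coupled-fragment analyses.

table1_params <- function(...) default_parameters("simulation2", ...)

frag_setup <- function(...) fragment_defaults(...)

# reference torque-balance zeroes under table1_params(), frozen from the
# closed-form quadratic/linear branch roots
W10 <- (pi - 70 * pi / 180) / 2         # 0.95993108...
W20 <- 0.639739741038407
W30 <- 0.175058626425991
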