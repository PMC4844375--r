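# Shared fixture builders: everything is generated in code at test time.

net_vars <- function() default_network()$variables$name

# replicate table with an equicorrelated target over the network variables
equicorr_table <- function(n, rho, seed, species = "syn", treatment = "syn") {
  simulate_correlated(n, equicorr(10, rho), variables = net_vars(),
                      means = 10, sds = 2, species = species,
                      treatment = treatment, seed = seed)
}

# reference values shipped with the package
reported_connectance <- function() {
  read_replicate_table(system.file("extdata", "reported_connectance.csv",
                                   package = "photonet"))
}

reported_drymass <- function() {
  read_replicate_table(system.file("extdata", "reported_drymass.csv",
                                   package = "photonet"))
}

# direct-formula Pearson correlation oracle, independent of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y) * (n - 1))
}
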