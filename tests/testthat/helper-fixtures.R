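# shared fixtures and reduced-size model configurations for the test suite

collagen_fixture <- function() {
  read_collagen(weanmix_example("canimar_collagen.tsv"))
}

sources_fixture <- function() {
  read_sources(weanmix_example("weaning_sources.tsv"))
}

juveniles_of <- function(samples) samples[samples$cohort == "juvenile", ]
females_of <- function(samples) samples[samples$cohort == "adult_female", ]

# grouped isotope values (G1..G4 + Female), as used for the comparisons
grouped_values <- function(samples, col) {
  juv <- juveniles_of(samples)
  grp <- assign_age_group(juv$age_low_years, juv$age_high_years)
  g <- split(juv[[col]], grp)
  g$Female <- females_of(samples)[[col]]
  g
}

# short sampler runs for unit tests (inference-scale runs live in the
# acceptance tests)
test_mixing_config <- function(seed = 42, ...) {
  mixing_config(n_iterations = 6000, n_burn = 2000, thin = 4,
                n_chains = 2, rng_seed = seed, ...)
}

test_abc_config <- function(seed = 42, n_sims = 2e4, ...) {
  abc_config(n_sims = n_sims, accept_fraction = 0.02, rng_seed = seed,
              ode_step = 0.05, ...)
}

# two-source table with simple round numbers, for closed-form checks
toy_sources <- function(sd_N = 1, sd_C = 1, conc_N = c(2, 2),
                        conc_C = c(40, 40)) {
  data.frame(name = c("A", "B"),
             mu_N = c(5, 15), sd_N = sd_N, mu_C = c(-20, -10), sd_C = sd_C,
             conc_N = conc_N, sd_conc_N = 0, conc_C = conc_C, sd_conc_C = 0,
             frac_N = 0, sd_frac_N = 0, frac_C = 0, sd_frac_C = 0)
}
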