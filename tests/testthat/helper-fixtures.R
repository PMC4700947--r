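# Small cohort configurations used across test files.

small_cohort_config <- function(seed = 1, n = 60, h2prime = 0.15,
                                h2d = 0.15, n_sites = 60, tag_error = 0,
                                within_family_theta = 0.002) {
  cohort_config(
    groups = c(test = as.integer(n)),
    subtype_freqs = data.frame(group = "test", H2prime = h2prime,
                               H2D = h2d),
    n_sites = n_sites, tag_error = tag_error,
    within_family_theta = within_family_theta, seed = seed)
}

two_group_cohort_config <- function(seed = 1, n = c(a = 30L, b = 30L)) {
  cohort_config(
    groups = n,
    subtype_freqs = data.frame(group = names(n),
                               H2prime = c(0.2, 0.1), H2D = c(0.2, 0.3)),
    n_sites = 60, seed = seed)
}

# small simulator configuration for fast stochastic tests
fast_sim_config <- function(...) {
  sim_config(Ne = 100L, region_length = 20000L, n_inverted = 20L,
             n_standard = 40L, ...)
}
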