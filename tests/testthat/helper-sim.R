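# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# compact configuration for unit tests: 2 groups, small genome
small_cfg <- function(seed = 1, ...) {
  sim_config(n_groups = 2, n_source = 6, n_counterpart = 6, n_neo = 6,
             n_chromosomes = 2, chromosome_length_bp = 2e6,
             n_sites_per_chromosome = 500, seed = seed, ...)
}

small_pop <- function() {
  cache_get("small_pop", function() simulate_bantam_population(small_cfg()))
}

# default-condition population reused across modules
study_pop <- function() {
  cache_get("study_pop",
            function() simulate_bantam_population(sim_config(seed = 11)))
}

# the full 20-seed simulation study (shared by the localization,
# heterogeneity and introgression acceptance tests)
study_results <- function() {
  cache_get("study", function()
    bantam_replicate_study(n_seeds = 20, base_seed = 2000))
}

# structured founder panel: breeds x samples dosage matrix without any
# cross, for calibration tests
founder_panel <- function(n_breeds = 4, n_per = 25, n_sites = 10000,
                          F = 0.1, seed = 5) {
  cfg <- sim_config(n_groups = n_breeds / 2,
                    n_source = n_per, n_counterpart = n_per,
                    n_chromosomes = 1,
                    chromosome_length_bp = n_sites * 500,
                    n_sites_per_chromosome = n_sites,
                    breed_divergence_F = F, seed = seed)
  f <- generate_founders(cfg)
  dosage <- do.call(cbind, lapply(f$haplotypes, function(H)
    H[, seq(1, ncol(H), 2), drop = FALSE] +
      H[, seq(2, ncol(H), 2), drop = FALSE]))
  breed <- rep(names(f$haplotypes),
               each = ncol(dosage) / length(f$haplotypes))
  list(dosage = dosage, breed = breed, sites = f$sites)
}
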