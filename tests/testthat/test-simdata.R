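test_that("founder frequencies follow the Balding-Nichols construction", {
  cfg <- sim_config(n_groups = 1, n_source = 30, n_counterpart = 30,
                    n_chromosomes = 1, chromosome_length_bp = 5e6,
                    n_sites_per_chromosome = 5000,
                    breed_divergence_F = 0.2, seed = 3)
  f <- generate_founders(cfg)
  # drift F = 0.2 between two breeds: windowed W&C F_ST over 5000 sites
  # estimates the coancestry within Monte-Carlo tolerance
  d1 <- f$haplotypes$source_g1
  d2 <- f$haplotypes$counterpart_g1
  G1 <- d1[, seq(1, ncol(d1), 2)] + d1[, seq(2, ncol(d1), 2)]
  G2 <- d2[, seq(1, ncol(d2), 2)] + d2[, seq(2, ncol(d2), 2)]
  comp <- wc_fst_site(G1, G2)
  fst <- sum(comp$a[comp$informative]) /
    sum((comp$a + comp$b + comp$c)[comp$informative])
  expect_gt(fst, 0.17)
  expect_lt(fst, 0.23)
  # theoretical moment check: Var(p_b) = F p (1 - p)
  ok <- f$sites$ancestral_p > 0.2 & f$sites$ancestral_p < 0.8
  vr <- (f$breed_freq[ok, 1] - f$sites$ancestral_p[ok])^2 /
    (f$sites$ancestral_p[ok] * (1 - f$sites$ancestral_p[ok]))
  expect_equal(mean(vr), 0.2, tolerance = 0.05)
})

test_that("F = 0 collapses every breed onto the ancestral frequency", {
  cfg <- sim_config(n_groups = 1, n_chromosomes = 1,
                    n_sites_per_chromosome = 300,
                    breed_divergence_F = 0, seed = 4)
  f <- generate_founders(cfg)
  expect_equal(unname(f$breed_freq[, 1]), f$sites$ancestral_p)
  expect_equal(unname(f$breed_freq[, 2]), f$sites$ancestral_p)
})

test_that("seeded founder generation is bit-reproducible", {
  cfg <- sim_config(n_groups = 1, n_chromosomes = 1,
                    n_sites_per_chromosome = 100, seed = 99)
  expect_identical(generate_founders(cfg), generate_founders(cfg))
  expect_identical(simulate_bantam_population(small_cfg(seed = 7)),
                   simulate_bantam_population(small_cfg(seed = 7)))
})

test_that("planting the causal locus fixes the allele difference", {
  cfg <- small_cfg(seed = 5)
  f <- plant_causal_loci(generate_founders(cfg), cfg)
  cl <- cfg$causal_loci[1, ]
  idx <- which(f$sites$chrom == cl$chrom & f$sites$pos == cl$pos)
  for (g in 1:2) {
    expect_true(all(f$haplotypes[[paste0("source_g", g)]][idx, ] == 1))
    expect_true(all(f$haplotypes[[paste0("counterpart_g", g)]][idx, ] == 0))
  }
  # sweep: source haplotypes identical within the radius
  region <- which(f$sites$chrom == cl$chrom &
                    abs(f$sites$pos - cl$pos) <= cfg$sweep_radius_bp)
  H <- f$haplotypes$source_g1[region, ]
  expect_true(all(H == H[, 1]))
})

test_that("intermediate planting frequencies follow the binomial", {
  cfg <- sim_config(n_groups = 1, n_source = 200, n_counterpart = 20,
                    n_chromosomes = 1, n_sites_per_chromosome = 200,
                    source_freq = 0.9, seed = 8)
  f <- plant_causal_loci(generate_founders(cfg), cfg)
  cl <- cfg$causal_loci[1, ]
  idx <- which(f$sites$chrom == cl$chrom & f$sites$pos == cl$pos)
  phat <- mean(f$haplotypes$source_g1[idx, ])
  se <- sqrt(0.9 * 0.1 / 400)
  expect_lt(abs(phat - 0.9), 3 * se + 1e-9)
})

test_that("recombination follows the Haldane model", {
  sites <- data.frame(chrom = "chr1", pos = seq(1000, 999000, 1000))
  # 1 Morgan chromosome
  map <- constant_rate_map("chr1", 1e6, cM_per_Mb = 100)
  set.seed(10)
  n_gam <- 10000
  counts <- vapply(seq_len(n_gam), function(i)
    length(recombine(rep(0L, nrow(sites)), rep(1L, nrow(sites)), sites,
                     map, keep_breaks = TRUE)$breaks$chr1$bp_break),
    numeric(1))
  expect_lt(abs(mean(counts) - 1), 3 / sqrt(n_gam))

  # (near-)zero map length: gamete equals one parental haplotype intact
  map0 <- bantamize:::validate_genetic_map(data.frame(
    chrom = "chr1", pos_bp = c(0, 1e6), pos_cM = c(0, 1e-9)))
  h1 <- rep(0L, nrow(sites)); h2 <- rep(1L, nrow(sites))
  g <- recombine(h1, h2, sites, map0)$alleles
  expect_true(identical(g, h1) || identical(g, h2))
})

test_that("ancestry tracks tile chromosomes exactly", {
  pop <- small_pop()
  anc <- pop$ancestry
  for (key in unique(paste(anc$sample, anc$hap))[1:8]) {
    a <- anc[paste(anc$sample, anc$hap) == key, ]
    for (ch in unique(a$chrom)) {
      seg <- a[a$chrom == ch, ]
      seg <- seg[order(seg$start), ]
      expect_equal(seg$start[1], 0)
      expect_equal(seg$end[nrow(seg)], pop$config$chromosome_length_bp)
      if (nrow(seg) > 1)
        expect_equal(seg$start[-1], seg$end[-nrow(seg)])
      expect_equal(sum(seg$end - seg$start),
                   pop$config$chromosome_length_bp)
    }
  }
})

test_that("an F1-only cross gives exactly half source ancestry", {
  cfg <- small_cfg(seed = 12, n_backcross_generations = 0,
                   n_intercross_generations = 0)
  pop <- simulate_bantam_population(cfg)
  fr <- source_ancestry_fraction(pop, exclude_cM = 0)
  by_sample <- tapply(fr$fraction, fr$sample, mean)
  expect_true(all(abs(by_sample - 0.5) < 1e-12))
})

test_that("backcrossing dilutes source ancestry as (1/2)^(g+1) off the causal chromosome", {
  # selection drags a long hitchhiking flank on the causal chromosome
  # (chromosomes here span only ~6-15 cM), so the neutral expectation is
  # checked on the non-causal chromosome over replicates
  reps <- 20
  fr <- vapply(seq_len(reps), function(k) {
    cfg <- sim_config(n_groups = 1, n_source = 6, n_counterpart = 6,
                      n_neo = 8, n_chromosomes = 2,
                      chromosome_length_bp = 2e6,
                      n_sites_per_chromosome = 200, seed = 100 + k)
    pop <- simulate_bantam_population(cfg)
    anc <- pop$ancestry
    neutral <- anc[anc$chrom != pop$causal$chrom[1], ]
    len <- neutral$end - neutral$start
    sum(len[neutral$origin == "source"]) / sum(len)
  }, numeric(1))
  expected <- 0.5^(4 + 1)
  se <- stats::sd(fr) / sqrt(reps)
  expect_lt(abs(mean(fr) - expected), 3 * se)
})

test_that("phenotypes follow the causal-carrier model", {
  pop <- small_pop()
  expect_true(all(pop$samples$phenotype[pop$samples$role != "counterpart"]
                  == 1))
  expect_true(all(pop$samples$phenotype[pop$samples$role == "counterpart"]
                  == 0))
  expect_equal(table(pop$samples$role)[["neo_bantam"]],
               2 * pop$config$n_neo)
})

test_that("configuration validation rejects invalid settings", {
  expect_error(sim_config(breed_divergence_F = 1), "\\[0, 1\\)")
  expect_error(sim_config(n_source = 0), "positive")
  expect_error(sim_config(source_freq = 1.2), "frequencies")
  expect_error(sim_config(causal_loci = data.frame(
    chrom = "chr1", pos = 9e9, groups = "1")), "bounds")
})
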