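test_that("fixed-effects combination matches closed forms and oracles", {
  # single study: identity
  cf <- combine_fixed_effects(1.5, 0.4)
  expect_equal(cf$beta, 1.5)
  expect_equal(cf$se, 0.4)
  # two equal-weight studies
  cf <- combine_fixed_effects(c(1, 3), c(1, 1))
  expect_equal(cf$beta, 2)
  expect_equal(cf$se, 1 / sqrt(2))
  het <- heterogeneity(c(1, 3), c(1, 1), cf$beta)
  expect_equal(het$Q, 2)
  expect_equal(het$df, 1)
  # arbitrary weights vs the WLS oracle
  set.seed(61)
  for (i in 1:20) {
    beta <- rnorm(3); se <- runif(3, 0.2, 2)
    cf <- combine_fixed_effects(beta, se)
    o <- oracle_wls_meta(beta, se)
    expect_equal(cf$beta, o$beta, tolerance = 1e-12)
    expect_equal(cf$se, o$se, tolerance = 1e-12)
  }
})

test_that("combination agrees with metafor's fixed-effects model", {
  skip_if_not_installed("metafor")
  set.seed(62)
  beta <- rnorm(4); se <- runif(4, 0.3, 1.5)
  cf <- combine_fixed_effects(beta, se)
  het <- heterogeneity(beta, se, cf$beta)
  rma <- metafor::rma(yi = beta, sei = se, method = "FE")
  expect_equal(cf$beta, unname(coef(rma)), tolerance = 1e-10)
  expect_equal(cf$se, unname(rma$se), tolerance = 1e-10)
  expect_equal(cf$p, unname(rma$pval), tolerance = 1e-10)
  expect_equal(het$Q, unname(rma$QE), tolerance = 1e-10)
  expect_equal(het$p_het, unname(rma$QEp), tolerance = 1e-10)
})

test_that("k identical studies scale z by sqrt(k)", {
  z1 <- combine_fixed_effects(0.8, 0.3)$z
  for (k in 2:4)
    expect_equal(combine_fixed_effects(rep(0.8, k), rep(0.3, k))$z,
                 sqrt(k) * z1, tolerance = 1e-12)
})

test_that("combination invariants hold on random inputs", {
  set.seed(63)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    beta <- rnorm(k); se <- runif(k, 0.1, 2)
    cf <- combine_fixed_effects(beta, se)
    expect_lte(cf$se, min(se))
    expect_gte(cf$beta, min(beta))
    expect_lte(cf$beta, max(beta))
    q1 <- heterogeneity(beta, se, cf$beta)$Q
    q2 <- heterogeneity(-beta, se, -cf$beta)$Q
    expect_equal(q1, q2, tolerance = 1e-12)
  }
})

test_that("genomic control inflates standard errors only when lambda > 1", {
  st <- data.frame(beta = c(0.5, -0.2), se = c(0.1, 0.3))
  st$p <- pchisq((st$beta / st$se)^2, 1, lower.tail = FALSE)
  expect_identical(genomic_control_correct(st, 1), st)
  expect_identical(genomic_control_correct(st, 0.8), st)
  adj <- genomic_control_correct(st, 2)
  expect_equal(adj$se, st$se * sqrt(2))
  expect_equal(qchisq(adj$p, 1, lower.tail = FALSE),
               qchisq(st$p, 1, lower.tail = FALSE) / 2,
               tolerance = 1e-10)
  expect_equal(sign(adj$beta), sign(st$beta))
  expect_error(genomic_control_correct(st, 0), "positive")
})

test_that("heterogeneity handles identical, single and missing studies", {
  het <- heterogeneity(c(1, 1, 1), c(0.5, 0.5, 0.5), 1)
  expect_equal(het$Q, 0)
  expect_equal(het$I2, 0)
  expect_equal(het$direction, "+++")
  het1 <- heterogeneity(1, 0.5, 1)
  expect_true(is.na(het1$Q))
  hetm <- heterogeneity(c(1, NA, -2), c(0.5, NA, 0.5), -0.5)
  expect_equal(hetm$direction, "+?-")
  expect_equal(hetm$df, 1L)
})

test_that("meta tables align alleles and inherit single-study results", {
  s1 <- data.frame(chrom = "chr1", pos = c(100, 200), ref = c("A", "A"),
                   alt = c("C", "C"), beta = c(0.5, 1), se = c(0.2, 0.4),
                   p = 0.01)
  # second study has ref/alt swapped at pos 100 and a private variant
  s2 <- data.frame(chrom = "chr1", pos = c(100, 300), ref = c("C", "G"),
                   alt = c("A", "T"), beta = c(-0.5, 0.7),
                   se = c(0.2, 0.3), p = 0.01)
  res <- run_meta(list(a = s1, b = s2), gc_correct = FALSE)
  r100 <- res$stats[res$stats$pos == 100, ]
  expect_equal(r100$k, 2)
  expect_equal(r100$beta, 0.5, tolerance = 1e-12)  # flip reconciles
  expect_equal(r100$Q, 0, tolerance = 1e-12)
  r200 <- res$stats[res$stats$pos == 200, ]
  expect_equal(r200$beta, 1)
  expect_equal(r200$se, 0.4)
  expect_equal(r200$k, 1)
  expect_equal(r200$direction, "+?")
})

test_that("grouped meta-analysis outperforms the pooled scan", {
  pop <- study_pop()
  dos <- population_dosage(pop)
  scans <- lapply(1:3, function(g)
    run_group_scan(dos, pop$sites, pop$samples, g))
  names(scans) <- paste0("group", 1:3)
  pooled <- run_group_scan(dos, pop$sites, pop$samples, NULL)
  meta <- run_meta(scans)
  thr <- 5e-8
  key <- function(st) paste(st$chrom, st$pos)
  sig_meta <- key(meta$stats)[!is.na(meta$stats$p) & meta$stats$p <= thr]
  sig_pool <- key(pooled$stats)[!is.na(pooled$stats$p) &
                                  pooled$stats$p <= thr]
  expect_true(all(sig_pool %in% sig_meta))
  expect_gt(length(sig_meta), length(sig_pool))
  # the group-3 private locus is found by the meta but lost by pooling
  ci <- pop$causal[pop$causal$group == 3, ][1, ]
  expect_true(paste(ci$chrom, ci$pos) %in% sig_meta)
  expect_false(paste(ci$chrom, ci$pos) %in% sig_pool)
})
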