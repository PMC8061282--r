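# Independent oracles, written directly from the published formulas and
# kept deliberately scalar/naive so they share no code with the package's
# vectorized implementations.

# Weir & Cockerham (1984) variance components for ONE bi-allelic site and
# two populations, from genotype vectors (0/1/2, NA allowed).
oracle_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  r <- 2
  n_i <- c(length(g1), length(g2))
  p_i <- c(sum(g1) / (2 * n_i[1]), sum(g2) / (2 * n_i[2]))
  h_i <- c(mean(g1 == 1), mean(g2 == 1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# windowed ratio-of-sums F_ST via the scalar oracle
oracle_wc_window <- function(G1, G2) {
  comp <- lapply(seq_len(nrow(G1)), function(i)
    oracle_wc_site(G1[i, ], G2[i, ]))
  num <- 0; den <- 0
  for (x in comp) {
    informative <- abs(x$a) > 0 || abs(x$b) > 0 || abs(x$c) > 0
    if (informative) { num <- num + x$a; den <- den + x$a + x$b + x$c }
  }
  if (den == 0) NA_real_ else num / den
}

# random two-population genotype tables with mild structure
random_geno_table <- function(n_sites, n1, n2) {
  p0 <- rbeta(n_sites, 0.8, 0.8)
  p1 <- pmin(pmax(p0 + rnorm(n_sites, 0, 0.1), 0), 1)
  p2 <- pmin(pmax(p0 + rnorm(n_sites, 0, 0.1), 0), 1)
  G1 <- matrix(rbinom(n_sites * n1, 2, rep(p1, n1)), n_sites, n1)
  G2 <- matrix(rbinom(n_sites * n2, 2, rep(p2, n2)), n_sites, n2)
  list(G1 = G1, G2 = G2)
}

# weighted-least-squares oracle for the fixed-effects combination: the
# intercept of a weights-only regression, with its sampling variance
# taken at unit residual scale
oracle_wls_meta <- function(beta, se) {
  w <- 1 / se^2
  fit <- stats::lm(beta ~ 1, weights = w)
  sigma2 <- summary(fit)$sigma^2
  list(beta = unname(coef(fit)[1]),
       se = sqrt(unname(vcov(fit)[1, 1]) / sigma2))
}

# OLS Wald chi-square p-values through lm(), for the identity-kinship
# equivalence check
oracle_ols_wald <- function(y, x) {
  fit <- stats::lm(y ~ x)
  ct <- summary(fit)$coefficients
  if (nrow(ct) < 2) return(c(beta = NA, se = NA, p = NA))
  c(beta = ct[2, 1], se = ct[2, 2],
    p = stats::pchisq(ct[2, 3]^2, 1, lower.tail = FALSE))
}

# Hand-built 6-record VCF, 10 samples, exercising each QC rule exactly
# once; the sole survivor sits exactly on the MAF = 0.05 boundary:
#   s1 pos 100: one het of 10 -> MAF exactly 0.05, clean     -> survives
#   s2 pos 200: quality 5 (<= 10)                            -> quality
#   s3 pos 300: 3 of 10 genotypes missing (call rate 0.7)    -> call_rate
#   s4 pos 400: one depth-1100 genotype (masked; call rate stays 0.9)
#               pulls the site mean depth to 200 (> 100)     -> mean_depth
#   s5 pos 500: every genotype depth 1 -> all masked         -> genotype_depth
#   s6 pos 600: monomorphic reference (MAF 0 < 0.05)         -> maf
write_qc_fixture <- function(path) {
  n <- 10
  gt_common <- c(rep("0/1", 5), rep("0/0", 5))         # af 0.25
  gt_boundary <- c("0/1", rep("0/0", n - 1))           # MAF 0.05 exactly
  gt_call <- c(rep("./.", 3), rep("0/1", 4), rep("0/0", 3))
  gt_maf <- rep("0/0", n)
  dp_ok <- rep(10, n)
  rows <- list(
    list(pos = 100, qual = 50, gt = gt_boundary, dp = dp_ok),
    list(pos = 200, qual = 5, gt = gt_common, dp = dp_ok),
    list(pos = 300, qual = 50, gt = gt_call, dp = dp_ok),
    list(pos = 400, qual = 50, gt = gt_common, dp = c(rep(100, 9), 1100)),
    list(pos = 500, qual = 50, gt = gt_common, dp = rep(1, n)),
    list(pos = 600, qual = 50, gt = gt_maf, dp = dp_ok))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("S", seq_len(n))),
                 collapse = "\t"))
  body <- vapply(rows, function(r)
    paste(c("chr1", r$pos, ".", "A", "C", r$qual, "PASS", ".", "GT:DP",
            paste0(r$gt, ":", r$dp)), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}
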