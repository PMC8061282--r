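ibd_fixture <- function(n_sites = 300, chrom_len = 3e6, cM_per_Mb = 3) {
  sites <- data.frame(chrom = "chr1",
                      pos = round(seq(1e4, chrom_len - 1e4,
                                      length.out = n_sites)))
  map <- constant_rate_map("chr1", chrom_len, cM_per_Mb)
  list(sites = sites, map = map)
}

test_that("identical haplotypes yield one chromosome-spanning segment", {
  fx <- ibd_fixture()
  h <- matrix(rbinom(300, 1, 0.5), ncol = 1,
              dimnames = list(NULL, "s1_h1"))
  h2 <- h; colnames(h2) <- "s2_h1"
  segs <- detect_ibd(h, h2, fx$sites, fx$map, min_length_cM = 0.03)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, fx$sites$pos[1])
  expect_equal(segs$end_bp, fx$sites$pos[300])
})

test_that("runs below the genetic length threshold are not reported", {
  fx <- ibd_fixture()
  h1 <- matrix(0L, 300, 1, dimnames = list(NULL, "a_h1"))
  h2 <- h1; colnames(h2) <- "b_h1"
  # mismatches every 3 sites: max run ~ 2 sites << 0.5 cM
  h2[seq(1, 300, 3), 1] <- 1L
  segs <- detect_ibd(h1, h2, fx$sites, fx$map, min_length_cM = 0.5,
                     max_mismatches = 0)
  expect_equal(nrow(segs), 0)
})

test_that("the detector is symmetric and tolerates allowed mismatches", {
  fx <- ibd_fixture()
  set.seed(81)
  h1 <- matrix(rbinom(300, 1, 0.5), ncol = 1,
               dimnames = list(NULL, "a_h1"))
  h2 <- h1; colnames(h2) <- "b_h2"
  h2[150, 1] <- 1L - h2[150, 1]  # one interior mismatch
  s12 <- detect_ibd(h1, h2, fx$sites, fx$map, min_length_cM = 0.03)
  s21 <- detect_ibd(h2, h1, fx$sites, fx$map, min_length_cM = 0.03)
  expect_equal(nrow(s12), 1)  # single mismatch absorbed (max_mismatches 1)
  expect_equal(s12$start_bp, s21$start_bp)
  expect_equal(s12$end_bp, s21$end_bp)
  expect_equal(s12$length_cM, s21$length_cM)
  s0 <- detect_ibd(h1, h2, fx$sites, fx$map, min_length_cM = 0.03,
                   max_mismatches = 0)
  expect_equal(nrow(s0), 2)   # split at the mismatch
})

test_that("F1 hybrids share about half their genome with the source cohort", {
  fracs <- vapply(1:6, function(k) {
    cfg <- sim_config(n_groups = 1, n_source = 8, n_counterpart = 8,
                      n_neo = 8, n_backcross_generations = 0,
                      n_intercross_generations = 0,
                      n_chromosomes = 2, chromosome_length_bp = 2e6,
                      n_sites_per_chromosome = 600, seed = 300 + k)
    pop <- simulate_bantam_population(cfg)
    sel <- which(pop$samples$group == 1)
    role <- pop$samples$role[sel]
    hap_cols <- function(rows) sort(c(2 * rows - 1, 2 * rows))
    h_src <- pop$haplotypes[, hap_cols(sel[role == "source"])]
    h_f1 <- pop$haplotypes[, hap_cols(sel[role == "neo_bantam"])]
    segs <- detect_ibd(h_src, h_f1, pop$sites, pop$map,
                       min_length_cM = 0.5)
    # fraction of the F1 diploid genome covered by IBD with the source
    tot <- 2 * cfg$n_neo * cfg$n_chromosomes * cfg$chromosome_length_bp
    cov <- 0
    for (id in unique(paste(segs$sample2, segs$hap2, segs$chrom))) {
      s <- segs[paste(segs$sample2, segs$hap2, segs$chrom) == id, ]
      ir <- IRanges::reduce(IRanges::IRanges(s$start_bp, s$end_bp))
      cov <- cov + sum(IRanges::width(ir))
    }
    cov / tot
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.5), max(3 * se, 0.05))
})

test_that("IBD segment files round-trip with scores preserved", {
  segs <- data.frame(sample1 = c("a", "b"), hap1 = c(1L, 2L),
                     sample2 = c("c", "c"), hap2 = c(2L, 1L),
                     chrom = "chr1", start_bp = c(100L, 5000L),
                     end_bp = c(4000L, 9000L), length_cM = NA_real_,
                     score = c(3.5, 12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ibd_file(segs, path)
  back <- read_ibd_file(path)
  expect_equal(back$sample1, segs$sample1)
  expect_equal(back$start_bp, segs$start_bp)
  expect_equal(back$score, segs$score)
  # empty file -> empty list
  writeLines(character(0), path)
  expect_equal(nrow(read_ibd_file(path)), 0)
  # malformed line reported with its number
  writeLines(c("a\t1\tb", "x"), path)
  expect_error(read_ibd_file(path), "malformed")
})

test_that("rIBD respects its bounds and degenerate cases", {
  samples <- data.frame(id = c("s1", "n1", "c1"),
                        role = c("source", "neo_bantam", "counterpart"),
                        group = 1)
  lens <- c(chr1 = 3e4)
  full <- data.frame(sample1 = "s1", hap1 = c(1, 1, 2, 2),
                     sample2 = "n1", hap2 = c(1, 2, 1, 2),
                     chrom = "chr1", start_bp = 1, end_bp = 3e4,
                     length_cM = 1, score = 10)
  empty <- full[0, ]
  tr <- ribd_scan(full, empty, samples, 1, window_bp = 1e4,
                  chrom_lengths = lens)
  expect_equal(tr$nIBD_source, rep(1, 3))
  expect_equal(tr$ribd, rep(1, 3))
  tr0 <- ribd_scan(empty, empty, samples, 1, window_bp = 1e4,
                   chrom_lengths = lens)
  expect_equal(tr0$ribd, rep(0, 3))
  expect_true(all(tr$cIBD_source <= tr$tIBD_source))
})

test_that("the introgressed causal region carries positive rIBD", {
  pop <- study_pop()
  g <- 1
  sel <- which(pop$samples$group == g)
  role <- pop$samples$role[sel]
  hap_cols <- function(rows) sort(c(2 * rows - 1, 2 * rows))
  segs_sn <- detect_ibd(pop$haplotypes[, hap_cols(sel[role == "source"])],
                        pop$haplotypes[, hap_cols(sel[role == "neo_bantam"])],
                        pop$sites, pop$map, min_length_cM = 0.15)
  segs_cn <- detect_ibd(pop$haplotypes[, hap_cols(sel[role == "counterpart"])],
                        pop$haplotypes[, hap_cols(sel[role == "neo_bantam"])],
                        pop$sites, pop$map, min_length_cM = 0.15)
  lens <- setNames(rep(pop$config$chromosome_length_bp,
                       pop$config$n_chromosomes),
                   paste0("chr", 1:pop$config$n_chromosomes))
  tr <- ribd_scan(segs_sn, segs_cn, pop$samples, g, chrom_lengths = lens)
  expect_true(all(tr$ribd >= -1 & tr$ribd <= 1))
  ci <- pop$causal[pop$causal$group == g, ][1, ]
  reg <- tr$chrom == ci$chrom & tr$start < ci$pos + 5e4 &
    tr$end > ci$pos - 5e4
  expect_gt(mean(tr$ribd[reg]), 0)
  expect_gte(mean(tr$ribd[reg]), quantile(tr$ribd, 0.99))
})
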