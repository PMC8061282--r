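test_that("haplotype blocks span the lead variant plus its flanks", {
  pop <- small_pop()
  ci <- pop$causal[1, ]
  block <- extract_block(pop$haplotypes, pop$sites, ci$chrom, ci$pos,
                         flank_bp = 1000, samples = pop$samples)
  in_int <- pop$sites$chrom == ci$chrom &
    abs(pop$sites$pos - ci$pos) <= 1000
  expect_equal(nrow(block$sites), sum(in_int))
  expect_equal(ncol(block$haplotypes), 2 * nrow(pop$samples))
  expect_true(all(grepl("\\|g[12]\\|(bantam|normal)$", block$labels)))
  # flank 0: the lead site only
  b0 <- extract_block(pop$haplotypes, pop$sites, ci$chrom, ci$pos, 0)
  expect_equal(nrow(b0$sites), 1)
  expect_error(extract_block(pop$haplotypes, pop$sites, "chr1", 123),
               "lead variant")
})

test_that("haplotype r2 follows the frequency formula", {
  mk <- function(nAB, nAb, naB, nab) {
    h1 <- c(rep(1, nAB + nAb), rep(0, naB + nab))
    h2 <- c(rep(1, nAB), rep(0, nAb), rep(1, naB), rep(0, nab))
    list(h1 = h1, h2 = h2)
  }
  h <- mk(40, 10, 10, 40)
  expect_equal(ld_r2(h$h1, h$h2), 0.36, tolerance = 1e-12)
  h <- mk(25, 25, 25, 25)
  expect_equal(ld_r2(h$h1, h$h2), 0, tolerance = 1e-12)
  expect_equal(ld_r2(h$h1, h$h1), 1)
  # symmetry and allele-relabeling invariance
  h <- mk(40, 10, 10, 40)
  expect_equal(ld_r2(h$h1, h$h2), ld_r2(h$h2, h$h1))
  expect_equal(ld_r2(1 - h$h1, h$h2), ld_r2(h$h1, h$h2),
               tolerance = 1e-12)
  expect_true(is.na(ld_r2(rep(1, 10), h$h2[1:10])))
})

test_that("the LD profile peaks at the lead variant", {
  pop <- small_pop()
  ci <- pop$causal[1, ]
  block <- extract_block(pop$haplotypes, pop$sites, ci$chrom, ci$pos,
                         flank_bp = 25000)
  prof <- ld_profile(block)
  expect_equal(prof$r2[prof$pos == ci$pos], 1)
  expect_true(all(prof$r2 >= 0 & prof$r2 <= 1, na.rm = TRUE))
})

test_that("block trees separate case and control haplotypes", {
  # synthetic block: identical case haplotypes, diverse controls
  sites <- data.frame(chrom = "chr1", pos = seq(100, 2000, 100))
  n_sites <- nrow(sites)
  case_h <- matrix(rep(c(0L, 1L), length.out = n_sites), n_sites, 6)
  set.seed(91)
  ctrl_h <- matrix(rbinom(n_sites * 6, 1, 0.5), n_sites, 6)
  h <- cbind(case_h, ctrl_h)
  colnames(h) <- paste0(rep(paste0(rep(c("case", "ctrl"), each = 3),
                                   rep(1:3, 2)), each = 2), "_h", 1:2)
  block <- structure(list(region = list(chrom = "chr1", start = 100,
                                        end = 2000, lead_pos = 100),
                          sites = sites, haplotypes = h,
                          labels = colnames(h)),
                     class = "haplotype_block")
  tr <- block_tree(block)
  expect_equal(ape::Ntip(tr), ncol(h))
  cd <- ape::cophenetic.phylo(tr)
  cases <- grep("^case", tr$tip.label, value = TRUE)
  expect_true(all(cd[cases, cases] < 1e-10))
})

test_that("introgressed neo-bantam haplotypes cluster with the source at the causal block", {
  pop <- study_pop()
  ci <- pop$causal[pop$causal$group == 1, ][1, ]
  block <- extract_block(pop$haplotypes, pop$sites, ci$chrom, ci$pos,
                         flank_bp = 30000, samples = pop$samples)
  g1 <- grepl("\\|g1\\|", block$labels)
  keep <- which(g1)
  sub <- block
  sub$haplotypes <- block$haplotypes[, keep]
  sub$labels <- block$labels[keep]
  D <- ibs_matrix(`colnames<-`(sub$haplotypes, sub$labels),
                  level = "haplotype")$distance
  lab <- sub$labels
  is_src <- grepl("^g1_src", lab)
  is_cpt <- grepl("^g1_cpt", lab)
  # causal-allele-carrying neo haplotypes sit nearer the source breed
  anc <- pop$ancestry
  carrier_hap <- paste0(anc$sample[anc$origin == "source" &
                                     anc$chrom == ci$chrom &
                                     anc$start <= ci$pos &
                                     anc$end > ci$pos], "_h",
                        anc$hap[anc$origin == "source" &
                                  anc$chrom == ci$chrom &
                                  anc$start <= ci$pos &
                                  anc$end > ci$pos])
  is_neo_carrier <- sub("\\|.*$", "", lab) %in% carrier_hap
  for (j in which(is_neo_carrier)) {
    expect_lt(mean(D[j, is_src]), mean(D[j, is_cpt]))
  }
})

test_that("significant-variant views separate phenotypes more than random sets", {
  pop <- study_pop()
  dos <- population_dosage(pop)
  scans <- lapply(1:3, function(g)
    run_group_scan(dos, pop$sites, pop$samples, g))
  names(scans) <- paste0("group", 1:3)
  meta <- run_meta(scans)
  sig <- which(!is.na(meta$stats$p) & meta$stats$p <= 5e-8)
  rows <- match(paste(meta$stats$chrom[sig], meta$stats$pos[sig]),
                paste(pop$sites$chrom, pop$sites$pos))
  view <- significant_variant_view(dos, rows)
  expect_equal(nrow(view$pca$coordinates), nrow(pop$samples))
  expect_setequal(view$tree$tip.label, pop$samples$id)
  ph <- pop$samples$phenotype == 1
  between <- function(D) mean(D[ph, !ph])
  set.seed(92)
  rand_rows <- sample(setdiff(seq_len(nrow(dos)), rows), length(rows))
  D_rand <- ibs_matrix(dos[rand_rows, , drop = FALSE])$distance
  expect_gt(between(view$distance), between(D_rand))
})

test_that("a single-variant view degenerates to one informative dimension", {
  pop <- small_pop()
  dos <- population_dosage(pop)
  ci <- pop$causal[1, ]
  row <- which(pop$sites$chrom == ci$chrom & pop$sites$pos == ci$pos)
  view <- significant_variant_view(dos, row, n_components = 2)
  expect_gt(view$pca$explained[1], 0.999)
  expect_error(significant_variant_view(dos, integer(0)), "empty")
})
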