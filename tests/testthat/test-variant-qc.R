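test_that("simulator VCF round-trips through the reader exactly", {
  pop <- small_pop()
  dir <- withr::local_tempdir()
  paths <- write_outputs(pop, dir)
  gm <- read_vcf(paths$vcf)
  expect_true(gm$phased)
  expect_identical(unname(gm$haplotypes), unname(pop$haplotypes))
  expect_identical(unname(gm$dosage), unname(population_dosage(pop)))
  expect_equal(gm$samples, pop$samples$id)
  expect_equal(gm$sites$pos, pop$sites$pos)
  # format contracts: VCF positions 1-based, ancestry BED 0-based
  expect_true(all(gm$sites$pos >= 1))
  bed <- read.table(paths$ancestry, sep = "\t")
  expect_equal(min(bed$V2), 0)
  meta <- read_sample_metadata(paths$metadata)
  expect_equal(nrow(meta), nrow(pop$samples))
})

test_that("GT parsing handles phase, missingness and depth", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "chr1\t10\t.\tA\tC\t30\tPASS\t.\tGT:DP\t0|1:12\t./.:3",
    "chr1\t20\t.\tG\tT\t30\tPASS\t.\tGT:DP\t1|1:9\t0|0:7"), path)
  gm <- read_vcf(path)
  expect_equal(gm$dosage[, "A"], c(1L, 2L))
  expect_true(is.na(gm$dosage[1, "B"]))
  expect_true(gm$phased)
  expect_equal(gm$depth[1, "A"], 12)
})

test_that("multi-allelic records split into per-alt bi-allelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "chr1\t10\t.\tA\tC,G\t30\tPASS\t.\tGT\t1/2\t0/1\t2/2",
    "chr1\t20\t.\tG\tT\t30\tPASS\t.\tGT\t0/1\t./.\t1/1"), path)
  gm <- read_vcf(path)
  sp <- split_multiallelic(gm)
  expect_equal(nrow(sp$sites), 3)
  expect_equal(sp$sites$alt[1:2], c("C", "G"))
  # GT 1/2: one copy of each alt
  expect_equal(unname(sp$dosage[1, ]), c(1L, 1L, 0L))
  expect_equal(unname(sp$dosage[2, ]), c(1L, 0L, 2L))
  # distinct allele identifiers
  expect_equal(length(unique(sp$sites$id[1:2])), 2)
  # splitting then summing per-alt dosages never exceeds ploidy
  expect_true(all(colSums(sp$dosage[1:2, ]) <= 2))
  # bi-allelic input unchanged and idempotent
  expect_equal(sp$dosage[3, ], gm$dosage[2, ])
  expect_identical(split_multiallelic(sp)$dosage, sp$dosage)
})

test_that("the QC cascade removes exactly one site per rule on the toy panel", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_qc_fixture(path)
  res <- apply_qc(split_multiallelic(read_vcf(path)))
  expect_equal(res$report$n_input, 6)
  expect_equal(res$report$n_survivors, 1)
  expect_equal(unname(res$report$removed),
               c(1L, 1L, 1L, 1L, 1L))
  # survivor is the MAF = 0.05 boundary site (strictly-below rule)
  expect_equal(res$matrix$sites$pos, 100)
})

test_that("QC is idempotent and monotone in threshold strictness", {
  pop <- small_pop()
  dir <- withr::local_tempdir()
  paths <- write_outputs(pop, dir)
  gm <- split_multiallelic(read_vcf(paths$vcf))
  r1 <- apply_qc(gm)
  r2 <- apply_qc(r1$matrix)
  expect_identical(r2$matrix$dosage, r1$matrix$dosage)
  expect_equal(r2$report$n_survivors, r1$report$n_survivors)
  strict <- apply_qc(gm, qc_thresholds(min_maf = 0.2))
  expect_lte(strict$report$n_survivors, r1$report$n_survivors)
})

test_that("all-masked sites are dropped with call rate zero", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "chr1\t10\t.\tA\tC\t30\tPASS\t.\tGT:DP\t0/1:1\t0/0:2"), path)
  res <- NULL
  expect_warning(res <- apply_qc(split_multiallelic(read_vcf(path))),
                 "all sites removed")
  expect_equal(res$report$n_survivors, 0)
  expect_equal(unname(res$report$removed["genotype_depth"]), 1L)
})

test_that("sex is inferred from the W/Z coverage ratio", {
  expect_equal(infer_sex(c(30, 28, 25), c(0, 28, 25 * 0.3)),
               c("ZZ_male", "ZW_female", "ZW_female"))
  expect_error(infer_sex(0, 1), "Z coverage")
})
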