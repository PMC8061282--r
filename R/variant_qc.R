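#' Quality-control thresholds
#'
#' Defaults follow the standard short-read filtering cascade for this kind
#' of whole-genome panel: site quality strictly above 10, call rate
#' strictly above 0.8 (computed after depth masking), site mean depth and
#' per-genotype depth inside [3, 100] (inclusive), and minor allele
#' frequency of at least 0.05 (strictly smaller is removed).
#'
#' @param min_site_quality sites with quality <= this are dropped
#' @param min_call_rate sites with call rate <= this are dropped
#' @param site_mean_depth_range inclusive bounds on the site mean depth
#' @param genotype_depth_range inclusive bounds on per-genotype depth;
#'   genotypes outside are masked to missing before the site filters
#' @param min_maf sites with minor allele frequency < this are dropped
#' @export
qc_thresholds <- function(min_site_quality = 10, min_call_rate = 0.8,
                          site_mean_depth_range = c(3, 100),
                          genotype_depth_range = c(3, 100),
                          min_maf = 0.05) {
  structure(list(min_site_quality = min_site_quality,
                 min_call_rate = min_call_rate,
                 site_mean_depth_range = site_mean_depth_range,
                 genotype_depth_range = genotype_depth_range,
                 min_maf = min_maf),
            class = "qc_thresholds")
}

#' Split multi-allelic records into bi-allelic ones
#'
#' Each record with several alternative alleles becomes one record per alt
#' allele; genotypes are recoded against that alt, with every other alt
#' counted as reference-class. Each output row carries a distinct allele
#' identifier (`src_id` plus an `_altK` suffix) so no information is lost
#' to ambiguity. Bi-allelic input passes through unchanged.
#'
#' @param gm a `genotype_matrix` from [read_vcf()]
#' @return a `genotype_matrix` with exactly one alt allele per row
#' @export
split_multiallelic <- function(gm) {
  multi <- grepl(",", gm$sites$alt, fixed = TRUE)
  if (!any(multi)) {
    if (anyNA(gm$sites$src_id)) gm$sites$src_id <-
        paste0(gm$sites$chrom, ":", gm$sites$pos)
    return(gm)
  }
  al <- gt_alleles(gm$gt)
  rows <- list(); gts <- list(); depths <- list()
  for (i in seq_len(nrow(gm$sites))) {
    alts <- strsplit(gm$sites$alt[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      s <- gm$sites[i, , drop = FALSE]
      s$alt <- alts[k]
      s$id <- if (length(alts) > 1)
        paste0(ifelse(s$id %in% c(".", NA), s$src_id, s$id), "_alt", k)
      else s$id
      rows[[length(rows) + 1L]] <- s
      a1 <- al$a1[i, ]; a2 <- al$a2[i, ]
      sep <- ifelse(grepl("|", gm$gt[i, ], fixed = TRUE), "|", "/")
      g <- paste0(as.integer(a1 == k), sep, as.integer(a2 == k))
      g[is.na(a1) | is.na(a2)] <- "./."
      gts[[length(gts) + 1L]] <- g
      if (!is.null(gm$depth))
        depths[[length(depths) + 1L]] <- gm$depth[i, ]
    }
  }
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  gt <- do.call(rbind, gts)
  colnames(gt) <- gm$samples
  depth <- if (is.null(gm$depth)) NULL else {
    d <- do.call(rbind, depths); colnames(d) <- gm$samples; d
  }
  build_genotype_matrix(sites, gt, depth)
}

# subset a genotype_matrix to a set of site rows
gm_subset <- function(gm, rows) {
  gm$sites <- gm$sites[rows, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm$dosage <- gm$dosage[rows, , drop = FALSE]
  gm$gt <- gm$gt[rows, , drop = FALSE]
  if (!is.null(gm$depth)) gm$depth <- gm$depth[rows, , drop = FALSE]
  if (!is.null(gm$haplotypes))
    gm$haplotypes <- gm$haplotypes[rows, , drop = FALSE]
  gm
}

#' Apply the quality-control cascade
#'
#' Order of operations: (1) genotypes whose depth falls outside the
#' genotype-depth bounds are masked to missing; (2) sites are dropped when
#' their quality is not strictly above the quality threshold, their call
#' rate (computed after masking) is not strictly above the call-rate
#' threshold, or their mean depth falls outside the site bounds; (3) sites
#' with minor allele frequency strictly below the MAF threshold (computed
#' on non-missing alleles) are dropped. The report attributes each removed
#' site to the first rule it violates in the order quality, call rate,
#' mean depth, MAF; a site that fails call rate only because of the depth
#' masking is attributed to the genotype-depth rule.
#'
#' @param gm a bi-allelic `genotype_matrix`
#' @param thresholds a [qc_thresholds()]
#' @return list with `matrix` (the filtered `genotype_matrix`) and
#'   `report` (per-rule removal counts, masked-genotype count, survivors)
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds()) {
  if (any(grepl(",", gm$sites$alt, fixed = TRUE)))
    stop("run split_multiallelic() before apply_qc()")
  th <- thresholds
  n_sites <- nrow(gm$sites)
  n_samp <- length(gm$samples)
  callrate_pre <- rowMeans(!is.na(gm$dosage))
  masked <- 0L
  if (!is.null(gm$depth)) {
    bad <- !is.na(gm$depth) &
      (gm$depth < th$genotype_depth_range[1] |
       gm$depth > th$genotype_depth_range[2])
    masked <- sum(bad & !is.na(gm$dosage))
    gm$dosage[bad] <- NA_integer_
    gm$gt[bad] <- "./."
    if (!is.null(gm$haplotypes)) {
      hb <- matrix(FALSE, n_sites, 2 * n_samp)
      hb[, seq(1, 2 * n_samp, 2)] <- bad
      hb[, seq(2, 2 * n_samp, 2)] <- bad
      gm$haplotypes[hb] <- NA_integer_
    }
  }
  callrate <- rowMeans(!is.na(gm$dosage))
  qual <- gm$sites$qual
  fail_qual <- !is.na(qual) & qual <= th$min_site_quality
  fail_cr <- callrate <= th$min_call_rate
  cr_from_mask <- fail_cr & callrate_pre > th$min_call_rate
  mean_depth <- if (is.null(gm$depth)) rep(NA_real_, n_sites) else
    rowMeans(gm$depth, na.rm = TRUE)
  fail_md <- !is.na(mean_depth) &
    (mean_depth < th$site_mean_depth_range[1] |
     mean_depth > th$site_mean_depth_range[2])
  af <- rowMeans(gm$dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- !is.na(maf) & maf < th$min_maf
  fail_maf[is.nan(af)] <- TRUE  # all-missing sites carry no allele info

  # first-violation attribution
  reason <- rep(NA_character_, n_sites)
  reason[fail_maf] <- "maf"
  reason[fail_md] <- "mean_depth"
  reason[fail_cr] <- "call_rate"
  reason[cr_from_mask] <- "genotype_depth"
  reason[fail_qual] <- "quality"
  keep <- is.na(reason)
  if (!any(keep))
    warning("all sites removed by QC")
  report <- list(
    n_input = n_sites,
    genotypes_masked = masked,
    removed = c(quality = sum(reason == "quality", na.rm = TRUE),
                genotype_depth = sum(reason == "genotype_depth",
                                     na.rm = TRUE),
                call_rate = sum(reason == "call_rate", na.rm = TRUE),
                mean_depth = sum(reason == "mean_depth", na.rm = TRUE),
                maf = sum(reason == "maf", na.rm = TRUE)),
    n_survivors = sum(keep))
  list(matrix = gm_subset(gm, which(keep)), report = report)
}

#' Write the QC report as a two-column TSV
#' @param report the `report` element of [apply_qc()]'s result
#' @param path file path
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("n_input", "genotypes_masked",
               paste0("removed_", names(report$removed)), "n_survivors"),
    value = c(report$n_input, report$genotypes_masked,
              unname(report$removed), report$n_survivors))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Infer sex from W/Z sequence-coverage ratios
#'
#' Chickens are ZZ (male) / ZW (female); a sample whose mean W coverage is
#' at least `threshold` times its mean Z coverage is called female.
#'
#' @param depth_z,depth_w per-sample mean depth on the Z and W chromosome
#' @param threshold W/Z ratio at or above which a sample is called female
#' @return character vector, "ZZ_male" or "ZW_female"
#' @export
infer_sex <- function(depth_z, depth_w, threshold = 0.3) {
  if (any(depth_z <= 0)) stop("zero or negative Z coverage")
  ratio <- depth_w / depth_z
  ifelse(ratio >= threshold, "ZW_female", "ZZ_male")
}
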