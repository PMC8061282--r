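#' Extract the phased haplotype block around a lead variant
#'
#' All sites within `flank_bp` of the lead position are included; every
#' individual contributes its two phased haplotypes. Haplotype labels
#' carry group and phenotype as suffixes when a sample table is given.
#'
#' @param haplotypes sites x 2N phased 0/1 matrix with `sample_hK`
#'   column names
#' @param sites site table (chrom, pos)
#' @param lead_chrom,lead_pos lead variant coordinates (must be a site)
#' @param flank_bp flanking width on each side (default 1000)
#' @param samples optional sample metadata for label annotation
#' @return a `haplotype_block`: list(region, sites, haplotypes, labels)
#' @export
extract_block <- function(haplotypes, sites, lead_chrom, lead_pos,
                          flank_bp = 1000, samples = NULL) {
  lead <- site_index(sites, lead_chrom, lead_pos)
  if (is.na(lead)) stop("lead variant not present among sites")
  rows <- which(sites$chrom == lead_chrom &
                abs(sites$pos - lead_pos) <= flank_bp)
  block_h <- haplotypes[rows, , drop = FALSE]
  labels <- colnames(block_h)
  if (!is.null(samples)) {
    sample_of <- sub("_h[12]$", "", labels)
    m <- match(sample_of, samples$id)
    pheno <- if ("phenotype" %in% names(samples))
      ifelse(samples$phenotype[m] == 1, "bantam", "normal")
    else samples$size_class[m]
    labels <- paste0(labels, "|g", samples$group[m], "|", pheno)
  }
  structure(list(region = list(chrom = lead_chrom,
                               start = max(1, lead_pos - flank_bp),
                               end = lead_pos + flank_bp,
                               lead_pos = lead_pos),
                 sites = sites[rows, , drop = FALSE],
                 haplotypes = block_h, labels = labels),
            class = "haplotype_block")
}

#' Haplotype-frequency linkage disequilibrium r^2
#'
#' r^2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B)) from phased
#' haplotype counts; NA when either site is monomorphic.
#'
#' @param h1,h2 0/1 allele vectors of the two sites over the same
#'   haplotypes
#' @export
ld_r2 <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  h1 <- h1[ok]; h2 <- h2[ok]
  pA <- mean(h1); pB <- mean(h2)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(h1 == 1 & h2 == 1)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' LD profile of a haplotype block against its lead variant
#'
#' @param block a `haplotype_block`
#' @return data.frame pos, r2 (r^2 of each marker against the lead; 1 at
#'   the lead itself)
#' @export
ld_profile <- function(block) {
  lead <- which(block$sites$pos == block$region$lead_pos)
  hl <- block$haplotypes[lead, ]
  r2 <- vapply(seq_len(nrow(block$sites)), function(i)
    ld_r2(block$haplotypes[i, ], hl), numeric(1))
  r2[lead] <- if (length(unique(hl)) > 1) 1 else NA_real_
  data.frame(pos = block$sites$pos, r2 = r2)
}

#' Neighbor-joining tree of the haplotypes in a block
#'
#' Haplotype-level 1-IBS distances converted to an NJ tree; leaves are
#' the annotated haplotype labels.
#'
#' @param block a `haplotype_block`
#' @return a `phylo` tree
#' @export
block_tree <- function(block) {
  if (ncol(block$haplotypes) < 3) stop("need at least 3 haplotypes")
  h <- block$haplotypes
  colnames(h) <- block$labels
  D <- ibs_matrix(h, level = "haplotype")$distance
  nj_tree(D)
}

#' PCA and NJ view of the significant-variant subset
#'
#' Subsets the genotype matrix to the significant variants and delegates
#' to [genotype_pca()] and [nj_tree()] on sample-level 1-IBS distances:
#' the "PhyloGWAS" topology check that associated variants group samples
#' by phenotype rather than overall relatedness.
#'
#' @param dosage sites x samples dosage matrix
#' @param sig_rows indices (or logical) of significant sites
#' @param n_components principal components to return
#' @return list with `pca`, `tree`, `distance`
#' @export
significant_variant_view <- function(dosage, sig_rows, n_components = 2) {
  sub <- dosage[sig_rows, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty significant set")
  ibs <- ibs_matrix(sub, level = "sample")
  list(pca = genotype_pca(sub, n_components),
       tree = nj_tree(ibs$distance),
       distance = ibs$distance)
}
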