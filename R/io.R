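#' Write a phased (or unphased) VCF 4.2 file
#'
#' @param sites site table with columns chrom, pos, ref, alt (and optional
#'   id, qual)
#' @param haplotypes sites x 2N matrix of 0/1 alleles (phased) or `NULL`
#' @param dosage sites x N matrix of 0/1/2/NA dosages, used when
#'   `haplotypes` is `NULL` (written unphased)
#' @param sample_ids character vector of N sample ids
#' @param path output path
#' @param contig_lengths named vector of contig lengths for the header
#' @param depth optional sites x N integer matrix written as the DP field
#' @return `path`, invisibly
#' @export
write_vcf <- function(sites, haplotypes = NULL, dosage = NULL, sample_ids,
                      path, contig_lengths = NULL, depth = NULL) {
  n <- length(sample_ids)
  if (!is.null(haplotypes)) {
    a1 <- haplotypes[, seq(1, 2 * n, 2), drop = FALSE]
    a2 <- haplotypes[, seq(2, 2 * n, 2), drop = FALSE]
    gt <- matrix(paste0(a1, "|", a2), nrow = nrow(sites))
    gt[is.na(a1) | is.na(a2)] <- ".|."
  } else {
    stopifnot(!is.null(dosage))
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix(code[dosage + 1L], nrow = nrow(sites))
    gt[is.na(dosage)] <- "./."
  }
  fmt <- "GT"
  if (!is.null(depth)) {
    gt <- matrix(paste0(gt, ":", ifelse(is.na(depth), ".", depth)),
                 nrow = nrow(sites))
    fmt <- "GT:DP"
  }
  qual <- if (is.null(sites$qual)) rep(".", nrow(sites)) else sites$qual
  id <- if (is.null(sites$id)) rep(".", nrow(sites)) else sites$id
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bantamize",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(depth))
    hdr <- c(hdr, paste0('##FORMAT=<ID=DP,Number=1,Type=Integer,',
                         'Description="Read Depth">'))
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_ids),
                      collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, id, sites$ref, sites$alt, qual,
                "PASS", ".", fmt,
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' GT is parsed to alt-allele dosage ("./." becomes missing); phase is
#' preserved when every non-missing genotype is phased; per-genotype DP is
#' captured when present. Multi-allelic records are kept as read -- run
#' [split_multiallelic()] to obtain one alt allele per row (a no-op on
#' bi-allelic input).
#'
#' @param path VCF file (plain or gzipped)
#' @return a `genotype_matrix`: list with `sites` (chrom, pos, id, ref,
#'   alt, qual, src_id), `samples`, `dosage`, `gt` (raw GT strings),
#'   `depth` (or NULL), `phased`, and `haplotypes` (sites x 2N, phased
#'   input only)
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      stringsAsFactors = FALSE)
  sites$src_id <- paste0(sites$chrom, ":", sites$pos)
  gt <- vcfR::extract.gt(v, element = "GT")
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID)
    depth <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  build_genotype_matrix(sites, gt, depth)
}

# Shared assembly from site table + raw GT strings (+ optional DP).
build_genotype_matrix <- function(sites, gt, depth = NULL) {
  samples <- colnames(gt)
  gt[is.na(gt)] <- "./."
  sep_phased <- grepl("|", gt, fixed = TRUE)
  non_missing <- !grepl("^\\.([/|]\\.)?$", gt)
  ploidy <- nchar(gsub("[^/|]", "", gt)) + 1L
  if (any(ploidy[non_missing] != 2L))
    stop("mixed or non-diploid ploidy in GT records: ",
         paste(utils::head(which(rowSums(
           matrix(ploidy != 2L & non_missing, nrow = nrow(gt))) > 0)),
           collapse = ", "))
  phased <- all(sep_phased[non_missing])
  al <- gt_alleles(gt)
  multi <- grepl(",", sites$alt, fixed = TRUE)
  dosage <- (al$a1 == 1L) + (al$a2 == 1L)
  dosage[multi, ] <- NA_integer_  # defined only after splitting
  dimnames(dosage) <- list(NULL, samples)
  haplotypes <- NULL
  if (phased && !any(multi)) {
    haplotypes <- matrix(NA_integer_, nrow(sites), 2 * length(samples))
    haplotypes[, seq(1, ncol(haplotypes), 2)] <- al$a1
    haplotypes[, seq(2, ncol(haplotypes), 2)] <- al$a2
    colnames(haplotypes) <- paste0(rep(samples, each = 2), "_h", 1:2)
  }
  structure(list(sites = sites, samples = samples, dosage = dosage,
                 gt = gt, depth = depth, phased = phased,
                 haplotypes = haplotypes),
            class = "genotype_matrix")
}

# split GT strings into two integer allele matrices (NA for '.')
gt_alleles <- function(gt) {
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^[^/|]*[/|]", "", gt)
  conv <- function(x) {
    out <- suppressWarnings(matrix(as.integer(x), nrow = nrow(gt)))
    out
  }
  list(a1 = conv(a1), a2 = conv(a2))
}

#' Write / read the sample metadata table
#'
#' Tab-separated columns: id, breed, size_class, role, group (and any
#' extras present, e.g. phenotype).
#' @param samples data.frame as in `bantam_population$samples`
#' @param path file path
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#' @param genes data.frame chrom, start, end (1-based inclusive), strand,
#'   gene_id, gene_name, biotype
#' @param path file path
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tbantamize\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$gene_name, genes$biotype))
  writeLines(lines, path)
  invisible(path)
}

#' Write ancestry intervals as BED (0-based half-open)
#' @param ancestry data.frame sample, hap, chrom, start, end, origin
#' @param path file path
#' @export
write_ancestry_bed <- function(ancestry, path) {
  lines <- sprintf("%s\t%d\t%d\t%s_h%d:%s", ancestry$chrom,
                   as.integer(ancestry$start), as.integer(ancestry$end),
                   ancestry$sample, ancestry$hap, ancestry$origin)
  writeLines(lines, path)
  invisible(path)
}

#' Emit all simulator artifacts to a directory
#'
#' Writes the phased VCF (with contig headers), sample metadata TSV,
#' genetic map, toy GFF3 gene models centered on the causal loci, and the
#' neo-bantam ancestry truth track as BED.
#'
#' @param pop a `bantam_population`
#' @param dir output directory, created if needed
#' @return named list of file paths
#' @export
write_outputs <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- stats::setNames(
    rep(pop$config$chromosome_length_bp, pop$config$n_chromosomes),
    paste0("chr", seq_len(pop$config$n_chromosomes)))
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    metadata = file.path(dir, "samples.tsv"),
    map = file.path(dir, "genetic_map.tsv"),
    genes = file.path(dir, "genes.gff3"),
    ancestry = file.path(dir, "ancestry_truth.bed"))
  write_vcf(pop$sites, haplotypes = pop$haplotypes,
            sample_ids = pop$samples$id, path = paths$vcf,
            contig_lengths = contigs)
  write_sample_metadata(pop$samples, paths$metadata)
  write_genetic_map(pop$map, paths$map)
  loci <- unique(pop$causal[, c("chrom", "pos")])
  genes <- data.frame(
    chrom = loci$chrom,
    start = pmax(1, loci$pos - 20000), end = loci$pos + 20000,
    strand = "+",
    gene_id = sprintf("GENE%04d", seq_len(nrow(loci))),
    gene_name = sprintf("CAUSAL_%s_%d", loci$chrom, loci$pos),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  write_gff3(genes, paths$genes)
  write_ancestry_bed(pop$ancestry, paths$ancestry)
  paths
}
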