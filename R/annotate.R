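#' Read gene models from GFF3 or BED
#'
#' GFF3 is parsed with \pkg{rtracklayer}; rows of type `gene` (or all
#' rows when none are typed `gene`) become the gene set. BED input (0-based
#' half-open) is converted to 1-based inclusive coordinates.
#'
#' @param path GFF3 (.gff/.gff3) or BED (.bed) file
#' @return data.frame chrom, start, end (1-based inclusive), strand,
#'   gene_id, gene_name, biotype
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    md <- S4Vectors::mcols(gr)
    pick <- function(nm, default) if (nm %in% names(md))
      as.character(md[[nm]]) else default
    genes <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = pick("ID", paste0("gene", seq_along(gr))),
      gene_name = pick("Name", NA_character_),
      biotype = pick("biotype", NA_character_),
      stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    genes <- data.frame(
      chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
      strand = if (ncol(bed) >= 6) bed[[6]] else ".",
      gene_id = if (ncol(bed) >= 4) bed[[4]] else
        paste0("gene", seq_len(nrow(bed))),
      gene_name = if (ncol(bed) >= 4) bed[[4]] else NA_character_,
      biotype = NA_character_, stringsAsFactors = FALSE)
  } else stop("unrecognized gene-model format: ", path)
  genes$strand[is.na(genes$strand) | genes$strand == "*"] <- "."
  if (any(genes$start > genes$end)) stop("gene with start > end")
  genes
}

#' Assign variants to genes by position with flanking regions
#'
#' A variant is assigned to every gene whose interval, extended by
#' `flank_bp` on both sides (strand-symmetric, covering promoter
#' regions), contains its position; variants falling in several
#' (overlapping) genes yield one row per gene, and variants hitting no
#' gene are flagged intergenic.
#'
#' @param variants data.frame with chrom, pos (1-based)
#' @param genes gene models from [read_gene_models()]
#' @param flank_bp flank width (default 1000)
#' @return data.frame chrom, pos, gene_id, gene_name, intergenic
#' @export
assign_variants <- function(variants, genes, flank_bp = 1000) {
  if (length(intersect(unique(variants$chrom), unique(genes$chrom))) == 0)
    stop("no shared chromosome names between variants (",
         paste(unique(variants$chrom), collapse = ","), ") and genes (",
         paste(unique(genes$chrom), collapse = ","), ")")
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos,
                                               variants$pos))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(
                                pmax(1L, genes$start - flank_bp),
                                genes$end + flank_bp))
  ov <- GenomicRanges::findOverlaps(v, g)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  assigned <- data.frame(chrom = variants$chrom[qh],
                         pos = variants$pos[qh],
                         gene_id = genes$gene_id[sh],
                         gene_name = genes$gene_name[sh],
                         intergenic = FALSE, stringsAsFactors = FALSE)
  orphan <- setdiff(seq_len(nrow(variants)), unique(qh))
  if (length(orphan))
    assigned <- rbind(assigned, data.frame(
      chrom = variants$chrom[orphan], pos = variants$pos[orphan],
      gene_id = NA_character_, gene_name = NA_character_,
      intergenic = TRUE, stringsAsFactors = FALSE))
  assigned[order(assigned$chrom, assigned$pos), , drop = FALSE]
}

#' Shared and unique elements across analyses (Venn summary)
#'
#' @param sets named list of character vectors (e.g. significant variant
#'   keys per analysis, or gene ids derived from [assign_variants()])
#' @return list with `membership` (elements x analyses logical matrix),
#'   `shared_by_at_least` and `shared_by_exactly` (counts indexed by k),
#'   `unique_per_set`
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least two analyses")
  elements <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1)
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(elements, names(sets)))
  rownames(membership) <- elements
  counts <- rowSums(membership)
  ks <- seq_along(sets)
  list(membership = membership,
       shared_by_at_least = stats::setNames(
         vapply(ks, function(k) sum(counts >= k), integer(1)),
         paste0("k", ks)),
       shared_by_exactly = stats::setNames(
         vapply(ks, function(k) sum(counts == k), integer(1)),
         paste0("k", ks)),
       unique_per_set = vapply(seq_along(sets), function(j)
         sum(membership[, j] & counts == 1), integer(1)))
}

#' Genes hit by at least one significant variant
#'
#' @param assignments output of [assign_variants()] restricted to the
#'   significant variants
#' @return character vector of gene ids
#' @export
genes_hit <- function(assignments) {
  sort(unique(assignments$gene_id[!assignments$intergenic]))
}
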