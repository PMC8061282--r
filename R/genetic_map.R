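#' Genetic maps: bp <-> cM interpolation
#'
#' A genetic map is a data.frame with columns `chrom`, `pos_bp`, `pos_cM`,
#' holding, per chromosome, a strictly increasing list of knots. Positions
#' between knots are linearly interpolated; the inverse mapping (cM -> bp)
#' uses the same knots.
#'
#' @param chromosomes character vector of chromosome names
#' @param lengths_bp integer vector of chromosome lengths (bp), recycled
#' @param cM_per_Mb constant recombination rate (default 3 cM/Mb, a typical
#'   genome-wide average for chicken macrochromosomes)
#' @return a `genetic_map` data.frame
#' @export
constant_rate_map <- function(chromosomes, lengths_bp, cM_per_Mb = 3) {
  lengths_bp <- rep_len(as.numeric(lengths_bp), length(chromosomes))
  map <- do.call(rbind, lapply(seq_along(chromosomes), function(i) {
    data.frame(chrom = chromosomes[i],
               pos_bp = c(0, lengths_bp[i]),
               pos_cM = c(0, lengths_bp[i] * cM_per_Mb / 1e6),
               stringsAsFactors = FALSE)
  }))
  validate_genetic_map(map)
}

validate_genetic_map <- function(map) {
  stopifnot(all(c("chrom", "pos_bp", "pos_cM") %in% names(map)))
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    if (nrow(m) < 2 || any(diff(m$pos_bp) <= 0) || any(diff(m$pos_cM) <= 0))
      stop("genetic map for chromosome ", ch,
           " must be strictly increasing in bp and cM with >= 2 knots")
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

map_chrom <- function(map, chrom) {
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) stop("no genetic map entries for chromosome ", chrom)
  m
}

#' Interpolate physical positions to genetic positions
#'
#' @param map a `genetic_map`
#' @param chrom chromosome name (scalar)
#' @param bp numeric vector of physical positions
#' @return numeric vector of cM positions
#' @export
bp_to_cM <- function(map, chrom, bp) {
  m <- map_chrom(map, chrom)
  stats::approx(m$pos_bp, m$pos_cM, xout = bp, rule = 2)$y
}

#' @rdname bp_to_cM
#' @param cM numeric vector of genetic positions
#' @export
cM_to_bp <- function(map, chrom, cM) {
  m <- map_chrom(map, chrom)
  stats::approx(m$pos_cM, m$pos_bp, xout = cM, rule = 2)$y
}

#' Chromosome genetic length in cM
#' @inheritParams bp_to_cM
#' @export
map_length_cM <- function(map, chrom) {
  m <- map_chrom(map, chrom)
  max(m$pos_cM) - min(m$pos_cM)
}

#' Read / write a two-column-per-chromosome genetic map text file
#'
#' Format: tab-separated `chrom  pos_bp  pos_cM`, one knot per line.
#' @param path file path
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_genetic_map(map)
}

#' @rdname read_genetic_map
#' @param map a `genetic_map`
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("chrom", "pos_bp", "pos_cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
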