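#' Detect identity-by-descent segments between two haplotype cohorts
#'
#' A deterministic identity-run detector: for every inter-cohort
#' haplotype pair and chromosome, the maximal left-to-right runs of
#' allele identity containing at most `max_mismatches` mismatching sites
#' are reported as segments whenever their genetic length reaches
#' `min_length_cM`. The detector is symmetric in its two cohorts; the
#' segment score is the number of matching sites. Segments come from the
#' same population rather than a single co-ancestor, so the length
#' threshold, not a probabilistic model, is the detection criterion.
#'
#' @param hapA,hapB sites x haplotypes 0/1 matrices (phased), with column
#'   names used as haplotype labels `sample_hK`
#' @param sites site table (chrom, pos)
#' @param map a `genetic_map`
#' @param min_length_cM minimum segment genetic length (default 0.03 cM;
#'   appropriate for sequence-dense data -- raise it at sparser site
#'   spacing so chance identity runs cannot qualify)
#' @param max_mismatches mismatching sites tolerated inside one segment
#' @return data.frame sample1, hap1, sample2, hap2, chrom, start_bp,
#'   end_bp, length_cM, score
#' @export
detect_ibd <- function(hapA, hapB, sites, map, min_length_cM = 0.03,
                       max_mismatches = 1) {
  if (anyNA(hapA) || anyNA(hapB)) stop("phased input without missing alleles required")
  labA <- colnames(hapA); labB <- colnames(hapB)
  if (is.null(labA)) labA <- paste0("A", seq_len(ncol(hapA)), "_h1")
  if (is.null(labB)) labB <- paste0("B", seq_len(ncol(hapB)), "_h1")
  acc_i <- list(); acc_j <- list(); acc_ch <- list()
  acc_from <- list(); acc_to <- list(); acc_len <- list()
  acc_score <- list(); k <- 0L
  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom == ch)
    pos <- sites$pos[rows]
    cm <- bp_to_cM(map, ch, pos)
    A <- hapA[rows, , drop = FALSE]; B <- hapB[rows, , drop = FALSE]
    for (i in seq_len(ncol(A))) {
      ai <- A[, i]
      for (j in seq_len(ncol(B))) {
        segs <- maximal_match_runs(which(ai != B[, j]), length(rows),
                                   max_mismatches)
        if (length(segs$from) == 0) next
        len <- cm[segs$to] - cm[segs$from]
        keep <- len >= min_length_cM
        if (!any(keep)) next
        k <- k + 1L
        acc_i[[k]] <- rep(i, sum(keep)); acc_j[[k]] <- rep(j, sum(keep))
        acc_ch[[k]] <- rep(ch, sum(keep))
        acc_from[[k]] <- pos[segs$from[keep]]
        acc_to[[k]] <- pos[segs$to[keep]]
        acc_len[[k]] <- len[keep]
        acc_score[[k]] <- segs$to[keep] - segs$from[keep] + 1L -
          segs$n_mism[keep]
      }
    }
  }
  segs <- data.frame(
    hap_label1 = labA[unlist(acc_i)], hap_label2 = labB[unlist(acc_j)],
    chrom = as.character(unlist(acc_ch)),
    start_bp = as.integer(unlist(acc_from)),
    end_bp = as.integer(unlist(acc_to)),
    length_cM = as.numeric(unlist(acc_len)),
    score = as.integer(unlist(acc_score)), stringsAsFactors = FALSE)
  if (nrow(segs) == 0)
    return(data.frame(sample1 = character(), hap1 = integer(),
                      sample2 = character(), hap2 = integer(),
                      chrom = character(), start_bp = integer(),
                      end_bp = integer(), length_cM = numeric(),
                      score = integer(), stringsAsFactors = FALSE))
  split_hap_labels(segs)
}

# maximal windows of sites [from, to] containing <= m mismatches, given
# sorted mismatch site indices within 1..L; returns parallel vectors
maximal_match_runs <- function(mism, L, m) {
  k <- length(mism)
  if (L == 0) return(list(from = integer(), to = integer(),
                          n_mism = integer()))
  if (k <= m) return(list(from = 1L, to = L, n_mism = k))
  bnd <- c(0L, mism, L + 1L)
  # window j spans (bnd[j], bnd[j + m + 1]) exclusive: sites strictly
  # between the two bounding mismatches, containing the m mismatches
  # bnd[j+1..j+m]
  j <- seq_len(k - m + 1)
  from <- bnd[j] + 1L
  to <- bnd[j + m + 1L] - 1L
  ok <- from <= to & !duplicated(paste(from, to))
  list(from = from[ok], to = to[ok], n_mism = rep(m, sum(ok)))
}

# hap labels "sample_hK" -> sample / hap columns
split_hap_labels <- function(segs) {
  parse <- function(lab) {
    hap <- as.integer(sub("^.*_h([12])$", "\\1", lab))
    sample <- sub("_h[12]$", "", lab)
    list(sample = sample, hap = hap)
  }
  p1 <- parse(segs$hap_label1); p2 <- parse(segs$hap_label2)
  data.frame(sample1 = p1$sample, hap1 = p1$hap,
             sample2 = p2$sample, hap2 = p2$hap,
             chrom = segs$chrom, start_bp = segs$start_bp,
             end_bp = segs$end_bp, length_cM = segs$length_cM,
             score = segs$score, stringsAsFactors = FALSE)
}

#' Read / write tab-delimited IBD segment files
#'
#' Column layout follows Refined-IBD-style output: sample1, hap1,
#' sample2, hap2, chrom, start, end (1-based inclusive), LOD/score.
#'
#' @param path file path
#' @param map optional `genetic_map` used to recompute segment cM lengths
#' @return IBD segment data.frame as in [detect_ibd()]
#' @export
read_ibd_file <- function(path, map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(sample1 = character(), hap1 = integer(),
                      sample2 = character(), hap2 = integer(),
                      chrom = character(), start_bp = integer(),
                      end_bp = integer(), length_cM = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8))
    stop("malformed IBD lines (expected 8 tab-separated fields): ",
         paste(which(nf != 8), collapse = ", "))
  m <- do.call(rbind, fields)
  segs <- data.frame(sample1 = m[, 1], hap1 = as.integer(m[, 2]),
                     sample2 = m[, 3], hap2 = as.integer(m[, 4]),
                     chrom = m[, 5], start_bp = as.integer(m[, 6]),
                     end_bp = as.integer(m[, 7]),
                     length_cM = NA_real_,
                     score = as.numeric(m[, 8]),
                     stringsAsFactors = FALSE)
  if (any(is.na(segs$start_bp) | is.na(segs$end_bp)))
    stop("malformed coordinates in IBD file")
  if (!is.null(map))
    segs$length_cM <- vapply(seq_len(nrow(segs)), function(i)
      diff(bp_to_cM(map, segs$chrom[i],
                    c(segs$start_bp[i], segs$end_bp[i]))), numeric(1))
  segs
}

#' @rdname read_ibd_file
#' @param segments IBD segment data.frame
#' @export
write_ibd_file <- function(segments, path) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%d\t%d\t%g",
                   segments$sample1, segments$hap1, segments$sample2,
                   segments$hap2, segments$chrom,
                   as.integer(segments$start_bp),
                   as.integer(segments$end_bp), segments$score)
  writeLines(lines, path)
  invisible(path)
}

#' Relative IBD (rIBD) introgression scan for one group
#'
#' Per 10-kb window, cIBD counts the haplotype pairs (one haplotype from
#' the comparison cohort, one from the neo-bantams) sharing at least one
#' IBD segment overlapping the window; tIBD = 2 n_X x 2 n_N is the total
#' possible pairings, nIBD their ratio, and
#' rIBD = nIBD(source, neo) - nIBD(counterpart, neo). Positive rIBD
#' marks regions where neo-bantam haplotypes resemble the bantam source
#' more than the normal-sized counterpart -- the signature of
#' bantamization introgression. Any window overlap counts.
#'
#' @param segments_source_neo,segments_counterpart_neo IBD segments from
#'   [detect_ibd()] (or [read_ibd_file()]) for the two comparisons
#' @param samples sample metadata of the group
#' @param group_id group to resolve cohort sizes from `samples`
#' @param window_bp window width (default 10 kb)
#' @param chrom_lengths named vector of chromosome lengths
#' @return data.frame chrom, start, end, cIBD_source, nIBD_source,
#'   cIBD_counterpart, nIBD_counterpart, tIBD_source, tIBD_counterpart,
#'   ribd
#' @export
ribd_scan <- function(segments_source_neo, segments_counterpart_neo,
                      samples, group_id, window_bp = 1e4,
                      chrom_lengths) {
  sam <- samples[samples$group == group_id, , drop = FALSE]
  n_src <- sum(sam$role == "source")
  n_cpt <- sum(sam$role == "counterpart")
  n_neo <- sum(sam$role == "neo_bantam")
  if (n_src == 0 || n_cpt == 0 || n_neo == 0)
    stop("group ", group_id, " is missing a cohort")
  t_src <- 4 * n_src * n_neo
  t_cpt <- 4 * n_cpt * n_neo
  win <- NULL
  for (ch in names(chrom_lengths)) {
    ids <- 0:((chrom_lengths[[ch]] - 1) %/% window_bp)
    win <- rbind(win, data.frame(chrom = ch, start = ids * window_bp,
                                 end = (ids + 1) * window_bp,
                                 stringsAsFactors = FALSE))
  }
  count_pairs <- function(segs) {
    cnt <- integer(nrow(win))
    if (nrow(segs) == 0) return(cnt)
    pair <- paste(segs$sample1, segs$hap1, segs$sample2, segs$hap2)
    for (ch in unique(segs$chrom)) {
      wrows <- which(win$chrom == ch)
      srows <- which(segs$chrom == ch)
      # windows overlapped by each segment (any overlap counts)
      w_from <- pmax(segs$start_bp[srows] - 1, 0) %/% window_bp
      w_to <- (segs$end_bp[srows] - 1) %/% window_bp
      w_to <- pmin(w_to, length(wrows) - 1)
      # pair-distinct window hits
      hits <- unique(data.frame(
        pair = rep(pair[srows], w_to - w_from + 1),
        w = unlist(mapply(seq, w_from, w_to, SIMPLIFY = FALSE))))
      tab <- table(hits$w)
      cnt[wrows[as.integer(names(tab)) + 1]] <- as.integer(tab)
    }
    cnt
  }
  c_src <- count_pairs(segments_source_neo)
  c_cpt <- count_pairs(segments_counterpart_neo)
  win$cIBD_source <- c_src
  win$tIBD_source <- t_src
  win$nIBD_source <- c_src / t_src
  win$cIBD_counterpart <- c_cpt
  win$tIBD_counterpart <- t_cpt
  win$nIBD_counterpart <- c_cpt / t_cpt
  win$ribd <- win$nIBD_source - win$nIBD_counterpart
  win
}
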