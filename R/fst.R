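#' Weir & Cockerham (1984) per-site variance components
#'
#' For each bi-allelic site the among-population (a), among-individual
#' (b), and within-individual (c) variance components are computed from
#' the per-population sample sizes, allele frequencies, and observed
#' heterozygote proportions, including the unequal-sample-size
#' corrections (n-bar, n_c, p-bar, s^2, h-bar). Sites monomorphic across
#' both populations are flagged uninformative with components (0, 0, 0).
#'
#' @param dosage1,dosage2 sites x samples dosage matrices of the two
#'   populations (0/1/2, NA = missing)
#' @return data.frame with per-site a, b, c, fst (a/(a+b+c), NA when
#'   uninformative), n1, n2, informative
#' @export
wc_fst_site <- function(dosage1, dosage2) {
  if (is.null(dim(dosage1))) dosage1 <- matrix(dosage1, nrow = 1)
  if (is.null(dim(dosage2))) dosage2 <- matrix(dosage2, nrow = 1)
  stopifnot(nrow(dosage1) == nrow(dosage2))
  r <- 2
  n1 <- rowSums(!is.na(dosage1)); n2 <- rowSums(!is.na(dosage2))
  if (any(n1 < 2 | n2 < 2))
    stop("need >= 2 non-missing genotypes per population at every site")
  p1 <- rowSums(dosage1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(dosage2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(dosage1 == 1, na.rm = TRUE) / n1
  h2 <- rowSums(dosage2 == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) *
       hbar)
  c <- hbar / 2
  informative <- !(pbar %in% c(0, 1)) | hbar > 0
  a[!informative] <- 0; b[!informative] <- 0; c[!informative] <- 0
  denom <- a + b + c
  fst <- ifelse(informative & denom != 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = c, fst = fst, n1 = n1, n2 = n2,
             informative = informative)
}

#' Windowed F_ST by the ratio-of-sums (weighted) estimator
#'
#' Per fixed-width window (0-based half-open tiling anchored at 0):
#' sum(a) / sum(a + b + c) over informative sites, NA when a window holds
#' no informative site. This is the weighted windowed estimator VCFtools
#' reports.
#'
#' @param components output of [wc_fst_site()]
#' @param sites site table (chrom, pos, 1-based)
#' @param window_bp window width (default 10 kb)
#' @param chrom_lengths optional named vector; windows then tile each
#'   full chromosome instead of stopping at the last site
#' @return data.frame chrom, start, end (0-based half-open), n_sites,
#'   fst
#' @export
fst_windows <- function(components, sites, window_bp = 1e4,
                        chrom_lengths = NULL) {
  stopifnot(nrow(components) == nrow(sites))
  out <- NULL
  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom == ch)
    w <- (sites$pos[rows] - 1) %/% window_bp   # 1-based pos -> window id
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      max(sites$pos[rows])
    ids <- 0:((len - 1) %/% window_bp)
    inf <- components$informative[rows]
    num <- tapply(components$a[rows][inf], w[inf], sum)
    den <- tapply((components$a + components$b + components$c)[rows][inf],
                  w[inf], sum)
    nsite <- tapply(rep(1, sum(inf)), w[inf], sum)
    fst <- rep(NA_real_, length(ids))
    ns <- rep(0L, length(ids))
    m <- match(as.integer(names(num)), ids)
    fst[m] <- ifelse(den == 0, NA_real_, num / den)
    ns[m] <- nsite
    out <- rbind(out, data.frame(chrom = ch, start = ids * window_bp,
                                 end = (ids + 1) * window_bp,
                                 n_sites = ns, fst = fst,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Genome-wide and regional summaries of a window track
#'
#' @param track a window track with a value column (`fst`, `ribd`, ...)
#' @param value name of the value column
#' @param regions optional data.frame (chrom, start, end; 0-based
#'   half-open) of regions to summarize separately
#' @return list with `mean`, `median` (NA windows excluded) and, when
#'   regions are given, `region_means`
#' @export
mean_fst_summary <- function(track, value = "fst", regions = NULL) {
  v <- track[[value]]
  if (all(is.na(v))) stop("track has no informative windows")
  out <- list(mean = mean(v, na.rm = TRUE),
              median = stats::median(v, na.rm = TRUE))
  if (!is.null(regions)) {
    out$region_means <- vapply(seq_len(nrow(regions)), function(i) {
      sel <- track$chrom == regions$chrom[i] &
        track$start < regions$end[i] & track$end > regions$start[i]
      mean(v[sel], na.rm = TRUE)
    }, numeric(1))
  }
  out
}

#' Write a BED-like window track as TSV
#' @param track data.frame with chrom, start, end and value columns
#' @param path file path
#' @export
write_window_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
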