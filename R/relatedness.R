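#' Identity-by-state similarity and distance matrices
#'
#' Sample level: for each pair the mean, over loci non-missing in both, of
#' (2 - |g_i - g_j|)/2 with g the alt-allele dosage. Haplotype level: the
#' fraction of identical alleles over loci non-missing in both. Distance
#' is 1 - similarity. The IBS similarity matrix doubles as the kinship
#' matrix of the mixed-model scan.
#'
#' @param x a `genotype_matrix`, a dosage matrix (sites x samples), or --
#'   for `level = "haplotype"` -- a 0/1 haplotype matrix (sites x
#'   haplotypes)
#' @param level `"sample"` (dosage IBS) or `"haplotype"` (allele IBS)
#' @return list with `similarity` and `distance` matrices
#' @export
ibs_matrix <- function(x, level = c("sample", "haplotype")) {
  level <- match.arg(level)
  if (inherits(x, "genotype_matrix")) {
    x <- if (level == "haplotype") {
      if (is.null(x$haplotypes)) stop("haplotype-level IBS needs phased input")
      x$haplotypes
    } else x$dosage
  }
  n <- ncol(x)
  if (n < 2) stop("need at least two columns")
  M <- !is.na(x)
  X0 <- x; X0[!M] <- 0
  n_both <- crossprod(M)
  if (level == "sample") {
    XX <- crossprod(X0)
    sq <- crossprod(X0^2, M)           # sum g_i^2 over shared loci
    d2 <- sq + t(sq) - 2 * XX          # sum (g_i - g_j)^2
    I0 <- (x == 0) & M; I2 <- (x == 2) & M
    opp <- crossprod(I0, I2)
    sum_abs <- d2 - 2 * (opp + t(opp)) # |g_i - g_j| per locus summed
    sim <- 1 - sum_abs / (2 * n_both)
  } else {
    XX <- crossprod(X0)
    sq <- crossprod(X0, M)             # alleles are 0/1: x^2 = x
    mism <- sq + t(sq) - 2 * XX
    sim <- 1 - mism / n_both
  }
  if (any(n_both == 0)) {
    warning("pairs with zero overlapping loci reported as NA")
    sim[n_both == 0] <- NA_real_
  }
  diag(sim)[!is.na(diag(sim))] <- 1
  labs <- colnames(x)
  dimnames(sim) <- list(labs, labs)
  list(similarity = sim, distance = 1 - sim)
}

#' Principal components of a genotype matrix
#'
#' Dosages are imputed to the per-variant mean, mean-centered, and scaled
#' by sqrt(2p(1-p)) with p the alt-allele frequency; principal components
#' are the eigenvectors of the resulting sample covariance, ordered by
#' eigenvalue. Monomorphic variants carry no information and are dropped.
#'
#' @param x a `genotype_matrix` or dosage matrix (sites x samples)
#' @param n_components number of components to return
#' @return list with `coordinates` (samples x components, eigenvector
#'   scaled by sqrt(eigenvalue)), `explained` (proportion of variance) and
#'   `values` (eigenvalues)
#' @export
genotype_pca <- function(x, n_components = 2) {
  if (inherits(x, "genotype_matrix")) x <- x$dosage
  n <- ncol(x)
  if (n_components > n) stop("more components requested than samples")
  mu <- rowMeans(x, na.rm = TRUE)
  imp <- x
  idx <- which(is.na(imp))
  if (length(idx)) imp[idx] <- mu[(idx - 1) %% nrow(imp) + 1]
  p <- mu / 2
  sd <- sqrt(2 * p * (1 - p))
  keep <- sd > 0 & !is.na(sd)
  Z <- (imp[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  C <- crossprod(Z) / sum(keep)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_components)]), n_components)
  rownames(coords) <- colnames(x)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coordinates = coords,
       explained = vals / sum(vals),
       values = vals)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch lengths
#' arising from non-additive noise are clamped to zero.
#'
#' @param D symmetric distance matrix with labels, n >= 3, no missing
#'   entries
#' @return an [ape::nj()] `phylo` tree
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(D)) stop("distance matrix has missing entries")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Serialize a tree to Newick text
#' @param tree a `phylo` object
#' @param path optional file; when NULL the Newick string is returned
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#' @param D matrix
#' @param path file path
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(as.matrix(D), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
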