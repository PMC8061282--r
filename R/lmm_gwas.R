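#' Fit the null linear mixed model y = Wa + u + e, u ~ N(0, sg^2 K)
#'
#' The binary bantam phenotype (0 = normal, 1 = bantam) is analysed as a
#' quantitative trait. K is eigendecomposed once (eigenvalues clamped at
#' zero with a warning if needed) and the restricted likelihood is
#' maximized over the variance ratio lambda = sg^2/se^2 by a log-spaced
#' grid on [1e-5, 1e5] followed by golden-section refinement; exact ties
#' resolve toward the smaller lambda.
#'
#' @param y numeric phenotype vector
#' @param K symmetric relatedness matrix (IBS similarity)
#' @param W covariate matrix; an intercept column is always prepended
#' @return an `lmm_fit` list: `lambda_vr`, `loglik`, eigenvalues `d`,
#'   eigenvectors `U`, rotated phenotype `ys` and covariates `Ws`, `n`
#' @export
fit_null <- function(y, K, W = NULL) {
  n <- length(y)
  if (stats::var(y) == 0) stop("constant phenotype")
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  W <- cbind(`(Intercept)` = rep(1, n), W)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    warning("K is not PSD; negative eigenvalues clamped to 0")
  d <- pmax(e$values, 0)
  U <- e$vectors
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  grid <- 10^seq(-5, 5, length.out = 81)
  ll <- vapply(grid, reml_loglik, numeric(1), ys = ys, Xs = Ws, d = d)
  i <- which(ll == max(ll))[1]               # ties -> smaller lambda
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(l) reml_loglik(10^l, ys, Ws, d),
                         interval = log10(c(lo, hi)),
                         maximum = TRUE,
                         tol = .Machine$double.eps^0.35)
  cand_l <- c(grid[i], 10^opt$maximum)
  cand_ll <- c(ll[i], opt$objective)
  best <- order(-cand_ll, cand_l)[1]
  structure(list(lambda_vr = cand_l[best], loglik = cand_ll[best],
                 d = d, U = U, ys = ys, Ws = Ws, n = n),
            class = "lmm_fit")
}

# restricted profile log-likelihood over the variance ratio (natural
# scale), up to an additive constant
reml_loglik <- function(lambda, ys, Xs, d) {
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  n <- length(ys); q <- ncol(Xs)
  -0.5 * ((n - q) * log(rss) + sum(log(v)) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

#' Wald association tests for a panel of variants
#'
#' Generalized least squares in the eigenrotated space. Mode `"null"`
#' (default) reuses the null-model variance ratio for every variant;
#' `"exact"` re-maximizes the restricted likelihood per variant with the
#' variant in the design. Missing dosages are imputed to the variant
#' mean. The Wald statistic (beta/se)^2 is referred to chi-square with
#' 1 df. Variants monomorphic after imputation are reported as NA.
#'
#' @param fit an `lmm_fit`
#' @param X dosage matrix, sites x samples (sample order matching `fit`)
#' @param mode `"null"` or `"exact"`
#' @return data.frame with beta, se, p, n per variant
#' @export
score_variants <- function(fit, X, mode = c("null", "exact")) {
  mode <- match.arg(mode)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == fit$n)
  mu <- rowMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- mu[(idx - 1) %% nrow(X) + 1]
  mono <- apply(X, 1, function(r) max(r) == min(r))
  Xr <- crossprod(fit$U, t(X))           # n x m rotated variants
  m <- nrow(X)
  beta <- se <- pval <- rep(NA_real_, m)
  q <- ncol(fit$Ws)
  if (mode == "null") {
    w <- 1 / (fit$lambda_vr * fit$d + 1)
    WtW <- crossprod(fit$Ws, fit$Ws * w)
    proj <- function(z) z - fit$Ws %*% solve(WtW, crossprod(fit$Ws, z * w))
    yt <- drop(proj(fit$ys))
    Xt <- proj(Xr)
    sxx <- colSums(w * Xt^2)
    sxy <- colSums(w * Xt * yt)
    syy <- sum(w * yt^2)
    ok <- !mono & sxx > 1e-12
    b <- sxy[ok] / sxx[ok]
    dfree <- fit$n - q - 1
    # floor the residual variance: an exactly collinear variant otherwise
    # yields se = 0/NaN instead of a finite, extreme Wald statistic
    s2 <- pmax((syy - b^2 * sxx[ok]) / dfree, 1e-12 * syy / dfree)
    beta[ok] <- b
    se[ok] <- sqrt(s2 / sxx[ok])
    pval[ok] <- stats::pchisq((b / se[ok])^2, 1, lower.tail = FALSE)
  } else {
    for (j in which(!mono)) {
      Xj <- cbind(fit$Ws, Xr[, j])
      gr <- 10^seq(-5, 5, length.out = 41)
      ll <- vapply(gr, reml_loglik, numeric(1), ys = fit$ys, Xs = Xj,
                   d = fit$d)
      i <- which(ll == max(ll))[1]
      opt <- stats::optimize(function(l) reml_loglik(10^l, fit$ys, Xj,
                                                     fit$d),
                             interval = log10(c(gr[max(i - 1, 1)],
                                                gr[min(i + 1,
                                                       length(gr))])),
                             maximum = TRUE)
      lam <- if (opt$objective > ll[i]) 10^opt$maximum else gr[i]
      w <- 1 / (lam * fit$d + 1)
      XtWX <- crossprod(Xj, Xj * w)
      bfull <- solve(XtWX, crossprod(Xj, fit$ys * w))
      r <- fit$ys - Xj %*% bfull
      s2 <- max(sum(w * r^2), 1e-12 * sum(w * fit$ys^2)) /
        (fit$n - q - 1)
      vb <- s2 * solve(XtWX)[q + 1, q + 1]
      beta[j] <- bfull[q + 1]
      se[j] <- sqrt(vb)
      pval[j] <- stats::pchisq(beta[j]^2 / vb, 1, lower.tail = FALSE)
    }
  }
  data.frame(beta = beta, se = se, p = pval, n = fit$n,
             reason = ifelse(mono, "monomorphic", NA_character_),
             stringsAsFactors = FALSE)
}

#' Genomic-control inflation factor
#'
#' lambda_GC = median of the observed Wald chi-square statistics divided
#' by the median of the chi-square(1) distribution (0.4549364).
#'
#' @param pvals vector of p-values (NAs dropped)
#' @export
genomic_lambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) stop("no p-values")
  chi <- stats::qchisq(pvals, 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, 1)
}

#' Case/control association scan for one bantamization group
#'
#' Cases are the bantam-sized samples of the group (neo-bantams plus the
#' true-bantam source), controls the normal-sized counterparts; the
#' phenotype column of the sample table is used when present. With
#' `group_id = NULL` the scan pools every sample (the "pooled" GWAS
#' comparison). The kinship defaults to the IBS similarity matrix of the
#' scanned samples; `kinship = FALSE` omits the random effect entirely
#' (fixed-effects regression), which is the stratification-sensitivity
#' comparator.
#'
#' @param dosage sites x samples dosage matrix
#' @param sites site table (chrom, pos, ref, alt, ...)
#' @param samples sample metadata (id, role, group, size_class, and
#'   optionally phenotype)
#' @param group_id group to scan, or NULL for all samples pooled
#' @param kinship kinship matrix, NULL (IBS of scanned samples), or FALSE
#' @param mode passed to [score_variants()]
#' @param threshold significance threshold (default 5e-8)
#' @param covariates optional covariate matrix (rows = all samples)
#' @return list with `stats` (per-variant association table), `summary`
#'   (`lambda_gc`, `n_significant`, `threshold`, `n_cases`,
#'   `n_controls`), and the null `fit`
#' @export
run_group_scan <- function(dosage, sites, samples, group_id = NULL,
                           kinship = NULL, mode = "null",
                           threshold = 5e-8, covariates = NULL) {
  sel <- if (is.null(group_id)) seq_len(nrow(samples)) else
    which(samples$group == group_id)
  if (length(sel) == 0) stop("no samples in group ", group_id)
  sam <- samples[sel, , drop = FALSE]
  y <- if ("phenotype" %in% names(sam)) sam$phenotype else
    as.integer(sam$size_class == "bantam")
  if (all(y == 0) || all(y == 1))
    stop("group needs both cases and controls")
  X <- dosage[, sel, drop = FALSE]
  K <- kinship
  omit_k <- identical(kinship, FALSE)
  if (is.null(K)) K <- ibs_matrix(X, level = "sample")$similarity
  if (omit_k) K <- diag(length(y))
  W <- if (is.null(covariates)) NULL else covariates[sel, , drop = FALSE]
  fit <- fit_null(y, K, W)
  st <- score_variants(fit, X, mode = mode)
  af <- function(rows) rowMeans(X[, rows, drop = FALSE], na.rm = TRUE) / 2
  stats_out <- cbind(sites[, intersect(c("chrom", "pos", "ref", "alt", "id"),
                                       names(sites)), drop = FALSE],
                     af_case = af(y == 1), af_ctrl = af(y == 0), st)
  lam <- genomic_lambda(stats_out$p)
  list(stats = stats_out,
       summary = list(lambda_gc = lam,
                      n_significant = sum(stats_out$p <= threshold,
                                          na.rm = TRUE),
                      threshold = threshold,
                      n_cases = sum(y == 1), n_controls = sum(y == 0)),
       fit = fit)
}

#' Write an association table as TSV
#' @param stats the `stats` element of [run_group_scan()]
#' @param path file path
#' @export
write_assoc_table <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
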