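#' Fixed-effects inverse-variance combination of per-study effects
#'
#' Classical (METAL-style) scheme: weights w_i = 1/se_i^2, combined
#' effect sum(w b)/sum(w), combined se 1/sqrt(sum(w)), z = beta/se and a
#' two-sided normal p-value. Studies with missing or non-positive se are
#' dropped from the combination.
#'
#' @param beta,se numeric vectors of per-study effects and standard errors
#' @return list beta, se, z, p, k (studies contributing)
#' @export
combine_fixed_effects <- function(beta, se) {
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (!any(ok)) return(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                            p = NA_real_, k = 0L))
  w <- 1 / se[ok]^2
  b <- sum(w * beta[ok]) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(beta = b, se = s, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       k = sum(ok))
}

#' Per-study genomic-control correction
#'
#' When a study's lambda_GC exceeds 1, its standard errors are inflated
#' by sqrt(lambda_GC) before combining (equivalently, each Wald
#' chi-square is divided by lambda_GC); lambda_GC <= 1 leaves the study
#' unchanged. Effect signs are never altered.
#'
#' @param stats an association table with `se` and `p` columns
#' @param lambda_gc the study's genomic-control inflation factor
#' @return the corrected table
#' @export
genomic_control_correct <- function(stats, lambda_gc) {
  if (!is.finite(lambda_gc) || lambda_gc <= 0)
    stop("lambda_GC must be positive")
  if (lambda_gc <= 1) return(stats)
  stats$se <- stats$se * sqrt(lambda_gc)
  chi <- (stats$beta / stats$se)^2
  stats$p <- stats::pchisq(chi, 1, lower.tail = FALSE)
  stats
}

#' Cochran heterogeneity of per-study effects
#'
#' Q = sum over studies of w_i (beta_i - beta_hat)^2 against chi-square
#' with k - 1 df; I^2 = max(0, (Q - (k-1))/Q). The direction string shows
#' the per-study effect sign ("+", "-", or "?" for a missing study).
#'
#' @param beta,se per-study effects and standard errors (NA = missing)
#' @param beta_hat the combined fixed-effect estimate
#' @return list Q, df, p_het, I2, direction
#' @export
heterogeneity <- function(beta, se, beta_hat) {
  ok <- is.finite(beta) & is.finite(se) & se > 0
  k <- sum(ok)
  direction <- paste(ifelse(!ok, "?", ifelse(beta >= 0, "+", "-")),
                     collapse = "")
  if (k <= 1)
    return(list(Q = NA_real_, df = NA_integer_, p_het = NA_real_,
                I2 = NA_real_, direction = direction))
  w <- 1 / se[ok]^2
  Q <- sum(w * (beta[ok] - beta_hat)^2)
  df <- k - 1L
  list(Q = Q, df = df,
       p_het = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = max(0, (Q - df) / Q), direction = direction)
}

# align study effects to the reference (ref, alt) orientation; returns
# beta (possibly sign-flipped) or NA when alleles cannot be reconciled
align_effect <- function(ref0, alt0, ref, alt, beta) {
  same <- ref == ref0 & alt == alt0
  flip <- ref == alt0 & alt == ref0
  out <- ifelse(same, beta, ifelse(flip, -beta, NA_real_))
  attr(out, "n_dropped") <- sum(!same & !flip & !is.na(beta))
  out
}

#' Meta-analysis across group scans
#'
#' Applies per-study genomic control, matches variants on (chrom, pos)
#' with allele alignment (effects flipped when ref/alt are swapped,
#' irreconcilable alleles excluded), combines by fixed-effects
#' inverse-variance weighting, and tests between-study heterogeneity.
#'
#' @param scans named list of [run_group_scan()] results (or of their
#'   `stats` tables plus a `lambda_gc` attribute)
#' @param threshold significance threshold for the summary
#' @param gc_correct apply per-study genomic control (default TRUE)
#' @return list with `stats` (combined table incl. Q, p_het, I2,
#'   direction, k) and `summary` (n_significant, heterogeneous fraction
#'   among significant variants with k >= 2)
#' @export
run_meta <- function(scans, threshold = 5e-8, gc_correct = TRUE) {
  tabs <- lapply(scans, function(s) {
    if (!is.null(s$stats)) {
      tab <- s$stats
      lam <- s$summary$lambda_gc
    } else {
      tab <- s
      lam <- attr(s, "lambda_gc")
    }
    if (gc_correct && !is.null(lam)) tab <- genomic_control_correct(tab, lam)
    tab
  })
  keys <- lapply(tabs, function(t) paste(t$chrom, t$pos))
  all_keys <- Reduce(union, keys)
  if (length(all_keys) == 0) stop("no variants to combine")
  ref_tab <- tabs[[1]][match(all_keys, keys[[1]]), c("chrom", "pos",
                                                     "ref", "alt")]
  # reference alleles from the first study carrying the variant
  for (j in seq_along(tabs)[-1]) {
    miss <- is.na(ref_tab$ref)
    if (!any(miss)) break
    m <- match(all_keys[miss], keys[[j]])
    ref_tab[miss, ] <- tabs[[j]][m, c("chrom", "pos", "ref", "alt")]
  }
  k_stud <- length(tabs)
  B <- S <- matrix(NA_real_, length(all_keys), k_stud)
  for (j in seq_len(k_stud)) {
    m <- match(all_keys, keys[[j]])
    t_j <- tabs[[j]][m, ]
    B[, j] <- align_effect(ref_tab$ref, ref_tab$alt, t_j$ref, t_j$alt,
                           t_j$beta)
    S[, j] <- t_j$se
  }
  res <- vector("list", length(all_keys))
  for (i in seq_along(all_keys)) {
    cf <- combine_fixed_effects(B[i, ], S[i, ])
    het <- heterogeneity(B[i, ], S[i, ], cf$beta)
    res[[i]] <- data.frame(beta = cf$beta, se = cf$se, z = cf$z,
                           p = cf$p, k = cf$k, Q = het$Q,
                           p_het = het$p_het, I2 = het$I2,
                           direction = het$direction,
                           stringsAsFactors = FALSE)
  }
  stats <- cbind(ref_tab, do.call(rbind, res))
  o <- order(stats$chrom, stats$pos)
  stats <- stats[o, ]
  rownames(stats) <- NULL
  sig <- !is.na(stats$p) & stats$p <= threshold
  shared_sig <- sig & stats$k >= 2
  summary <- list(
    n_significant = sum(sig),
    n_shared_significant = sum(shared_sig),
    het_fraction_significant = if (any(shared_sig))
      mean(stats$p_het[shared_sig] < 0.05, na.rm = TRUE) else NA_real_,
    threshold = threshold)
  list(stats = stats, summary = summary)
}
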