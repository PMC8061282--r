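#' Run the full bantamization inference chain on one simulated cohort
#'
#' Simulates the crossbreeding design with the study defaults, runs the
#' per-group mixed-model scans, the fixed-effects meta-analysis with
#' heterogeneity, the windowed F_ST contrasts, and the rIBD introgression
#' scan, and collects the recovery metrics the simulation study is scored
#' on. One call is one replicate; [bantam_replicate_study()] aggregates
#' over seeds.
#'
#' @param seed integer seed for this replicate
#' @param config a [sim_config()]; its `seed` is overridden by `seed`
#' @param min_ibd_cM IBD detection length used at the study's site
#'   density (0.15 cM; see the methods vignette)
#' @param window_bp F_ST / rIBD window width
#' @param causal_region_bp width of the causal region used for the
#'   regional summaries (default 100 kb, centered on the causal locus)
#' @return list of per-group and meta-level metrics
#' @export
bantam_experiment <- function(seed, config = NULL, min_ibd_cM = 0.15,
                              window_bp = 1e4, causal_region_bp = 1e5) {
  if (is.null(config)) config <- sim_config(seed = seed)
  else config$seed <- as.integer(seed)
  pop <- simulate_bantam_population(config)
  dosage <- population_dosage(pop)
  chrom_lengths <- stats::setNames(
    rep(config$chromosome_length_bp, config$n_chromosomes),
    paste0("chr", seq_len(config$n_chromosomes)))

  scans <- list(); groups <- sort(unique(pop$samples$group))
  group_metrics <- list()
  for (g in groups) {
    scan <- run_group_scan(dosage, pop$sites, pop$samples, group_id = g)
    scans[[paste0("group", g)]] <- scan
    ci <- pop$causal[pop$causal$group == g, ][1, ]
    st <- scan$stats
    imin <- which.min(st$p)
    dist <- if (st$chrom[imin] == ci$chrom)
      abs(st$pos[imin] - ci$pos) else Inf
    cidx <- which(st$chrom == ci$chrom & st$pos == ci$pos)

    sel <- which(pop$samples$group == g)
    role <- pop$samples$role[sel]
    hap_cols <- function(rows) sort(c(2 * rows - 1, 2 * rows))
    h_src <- pop$haplotypes[, hap_cols(sel[role == "source"]),
                            drop = FALSE]
    h_cpt <- pop$haplotypes[, hap_cols(sel[role == "counterpart"]),
                            drop = FALSE]
    h_neo <- pop$haplotypes[, hap_cols(sel[role == "neo_bantam"]),
                            drop = FALSE]
    seg_sn <- detect_ibd(h_src, h_neo, pop$sites, pop$map,
                         min_length_cM = min_ibd_cM)
    seg_cn <- detect_ibd(h_cpt, h_neo, pop$sites, pop$map,
                         min_length_cM = min_ibd_cM)
    ribd <- ribd_scan(seg_sn, seg_cn, pop$samples, g,
                      window_bp = window_bp,
                      chrom_lengths = chrom_lengths)
    region <- data.frame(chrom = ci$chrom,
                         start = ci$pos - causal_region_bp / 2,
                         end = ci$pos + causal_region_bp / 2)
    in_region <- ribd$chrom == region$chrom &
      ribd$start < region$end & ribd$end > region$start
    ribd_causal <- mean(ribd$ribd[in_region])
    ribd_q99 <- stats::quantile(ribd$ribd, 0.99, names = FALSE)

    d_neo <- dosage[, sel[role == "neo_bantam"], drop = FALSE]
    d_cpt <- dosage[, sel[role == "counterpart"], drop = FALSE]
    d_src <- dosage[, sel[role == "source"], drop = FALSE]
    fst_cpt <- fst_windows(wc_fst_site(d_neo, d_cpt), pop$sites,
                           window_bp, chrom_lengths)
    fst_src <- fst_windows(wc_fst_site(d_neo, d_src), pop$sites,
                           window_bp, chrom_lengths)
    sum_cpt <- mean_fst_summary(fst_cpt, regions = region)
    sum_src <- mean_fst_summary(fst_src, regions = region)
    # a causal region with no informative site between neo-bantams and the
    # source is completely introgressed and identical: differentiation 0
    if (is.nan(sum_src$region_means[1])) sum_src$region_means[1] <- 0

    group_metrics[[as.character(g)]] <- list(
      lambda_gc = scan$summary$lambda_gc,
      n_significant = scan$summary$n_significant,
      minp = st$p[imin], minp_dist_bp = dist,
      p_at_causal = if (length(cidx)) st$p[cidx[1]] else NA_real_,
      ribd_causal_mean = ribd_causal, ribd_q99 = ribd_q99,
      fst_mean_neo_counterpart = sum_cpt$mean,
      fst_mean_neo_source = sum_src$mean,
      fst_causal_neo_counterpart = sum_cpt$region_means[1],
      fst_causal_neo_source = sum_src$region_means[1])
  }

  meta <- run_meta(scans)
  shared <- pop$causal[duplicated(pop$causal[c("chrom", "pos")]) |
                         duplicated(pop$causal[c("chrom", "pos")],
                                    fromLast = TRUE), ]
  shared_groups <- shared$group
  sl <- shared[1, ]
  mrow <- which(meta$stats$chrom == sl$chrom & meta$stats$pos == sl$pos)
  group_p_shared <- vapply(groups, function(g) {
    st <- scans[[paste0("group", g)]]$stats
    i <- which(st$chrom == sl$chrom & st$pos == sl$pos)
    if (length(i)) st$p[i[1]] else NA_real_
  }, numeric(1))
  # the group-private locus (smallest group id owning an unshared locus)
  priv <- pop$causal[!pop$causal$group %in% shared_groups, ]
  p_het_private <- NA_real_
  if (nrow(priv)) {
    prow <- which(meta$stats$chrom == priv$chrom[1] &
                    meta$stats$pos == priv$pos[1])
    if (length(prow)) p_het_private <- meta$stats$p_het[prow[1]]
  }
  list(groups = group_metrics,
       meta_p_shared = if (length(mrow)) meta$stats$p[mrow[1]] else
         NA_real_,
       min_group_p_shared = min(group_p_shared, na.rm = TRUE),
       p_het_private = p_het_private,
       het_fraction_significant = meta$summary$het_fraction_significant,
       n_meta_significant = meta$summary$n_significant)
}

#' Replicate the simulation study over seeds and aggregate recovery rates
#'
#' @param n_seeds number of replicates (default 20)
#' @param base_seed seeds are `base_seed + 0:(n_seeds-1)`
#' @param localization_bp window around the causal locus within which the
#'   minimal-p variant counts as localized (default 50 kb)
#' @param ... passed to [bantam_experiment()]
#' @return list with per-replicate metrics and aggregate rates
#' @export
bantam_replicate_study <- function(n_seeds = 20, base_seed = 1000,
                                   localization_bp = 5e4, ...) {
  reps <- lapply(seq_len(n_seeds) - 1L,
                 function(k) bantam_experiment(base_seed + k, ...))
  per_group <- function(field)
    t(vapply(reps, function(r)
      vapply(r$groups, function(g) g[[field]], numeric(1)),
      numeric(length(reps[[1]]$groups))))
  dist <- per_group("minp_dist_bp")
  ribd_mean <- per_group("ribd_causal_mean")
  ribd_q99 <- per_group("ribd_q99")
  fst_gw_cpt <- per_group("fst_mean_neo_counterpart")
  fst_gw_src <- per_group("fst_mean_neo_source")
  fst_ca_cpt <- per_group("fst_causal_neo_counterpart")
  fst_ca_src <- per_group("fst_causal_neo_source")
  lam <- per_group("lambda_gc")
  meta_le <- vapply(reps, function(r)
    r$meta_p_shared <= r$min_group_p_shared, logical(1))
  het <- vapply(reps, function(r) r$p_het_private, numeric(1))
  list(
    replicates = reps,
    localization_rate = mean(rowMeans(dist <= localization_bp) == 1),
    localization_rate_per_scan = mean(dist <= localization_bp),
    meta_le_min_group_rate = mean(meta_le),
    heterogeneity_rate = mean(het < 0.05, na.rm = TRUE),
    ribd_positive_rate = mean(rowMeans(ribd_mean > 0) == 1),
    ribd_top1_rate = mean(rowMeans(ribd_mean >= ribd_q99) == 1),
    fst_ordering_rate = mean(rowMeans(fst_gw_cpt < fst_gw_src) == 1),
    fst_reversal_rate = mean(rowMeans(fst_ca_src < fst_ca_cpt) == 1),
    lambda_gc_range = range(lam),
    mean_fst_neo_counterpart = mean(fst_gw_cpt),
    mean_fst_neo_source = mean(fst_gw_src))
}
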