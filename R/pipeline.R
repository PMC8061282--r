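#' Pipeline configuration
#'
#' A single flat configuration for the end-to-end workflow. When `vcf` is
#' NULL the simulate stage generates all inputs from `sim`; otherwise the
#' given VCF / metadata / map / gene files are used as-is.
#'
#' @param out_dir artifact directory
#' @param sim a [sim_config()] (used when no input files are given)
#' @param vcf,metadata,map,genes optional input file paths
#' @param qc a [qc_thresholds()]
#' @param gwas_mode `"null"` or `"exact"`
#' @param threshold GWAS/meta significance threshold in (0, 1)
#' @param window_bp F_ST / rIBD window width
#' @param flank_bp haplotype-block flank
#' @param min_ibd_cM IBD segment length threshold
#' @param seed integer seed
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), vcf = NULL,
                            metadata = NULL, map = NULL, genes = NULL,
                            qc = qc_thresholds(), gwas_mode = "null",
                            threshold = 5e-8, window_bp = 1e4,
                            flank_bp = 1000, min_ibd_cM = 0.15,
                            seed = 1L) {
  if (!is.null(vcf) && (is.null(metadata) || is.null(map)))
    stop("external input needs vcf, metadata and map together")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(out_dir = out_dir, sim = sim, vcf = vcf,
                 metadata = metadata, map = map, genes = genes,
                 qc = qc, gwas_mode = gwas_mode, threshold = threshold,
                 window_bp = window_bp, flank_bp = flank_bp,
                 min_ibd_cM = min_ibd_cM, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
        collapse = "\n")
}

pipeline_log <- function(manifest, msg) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", msg)
  message(line)
  cat(line, "\n", file = manifest$log, append = TRUE)
}

#' Run the end-to-end workflow
#'
#' Stage order: simulate (when no input VCF is given), qc, structure,
#' per-group gwas, meta, fst + ribd per group, haplotype block around the
#' top meta variant, annotation. Every stage logs its parameters, writes
#' its outputs under `out_dir/<stage>/`, and records file checksums in
#' `manifest.json`; re-running with an unchanged configuration skips
#' completed stages whose outputs still exist.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) the manifest list
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(out, "manifest.json")
  hash <- config_hash(config)
  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("bantamize")),
                   stages = list(), files = list(),
                   log = file.path(out, "run.log"))
  prev <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else NULL
  resume <- !is.null(prev) && identical(prev$config_hash, hash)

  done <- function(stage, files) {
    files <- unlist(files)
    manifest$stages[[stage]] <<- TRUE
    manifest$files[[stage]] <<-
      as.list(tools::md5sum(files[file.exists(files)]))
    jsonlite::write_json(manifest[setdiff(names(manifest), "log")],
                         man_path, auto_unbox = TRUE, pretty = TRUE)
  }
  skip <- function(stage) {
    ok <- resume && isTRUE(prev$stages[[stage]]) &&
      all(file.exists(names(prev$files[[stage]])))
    if (ok) {
      manifest$stages[[stage]] <<- TRUE
      manifest$files[[stage]] <<- prev$files[[stage]]
      pipeline_log(manifest, paste0("[", stage, "] up to date, skipped"))
    }
    ok
  }
  run_stage <- function(stage, fn) {
    if (skip(stage)) return(invisible())
    pipeline_log(manifest, paste0("[", stage, "] running"))
    files <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    done(stage, files)
  }

  set.seed(config$seed)
  sim_dir <- file.path(out, "simulate")
  if (is.null(config$vcf)) {
    run_stage("simulate", function() {
      cfg <- config$sim; cfg$seed <- config$seed
      pop <- simulate_bantam_population(cfg)
      write_outputs(pop, sim_dir)
    })
    config$vcf <- file.path(sim_dir, "genotypes.vcf")
    config$metadata <- file.path(sim_dir, "samples.tsv")
    config$map <- file.path(sim_dir, "genetic_map.tsv")
    config$genes <- file.path(sim_dir, "genes.gff3")
  }
  for (f in c("vcf", "metadata", "map"))
    if (!file.exists(config[[f]]))
      stop("input for the qc/group stage missing: ", config[[f]])

  qc_dir <- file.path(out, "qc")
  run_stage("qc", function() {
    dir.create(qc_dir, showWarnings = FALSE)
    gm <- split_multiallelic(read_vcf(config$vcf))
    res <- apply_qc(gm, config$qc)
    saveRDS(res$matrix, file.path(qc_dir, "filtered.rds"))
    write_qc_report(res$report, file.path(qc_dir, "qc_report.tsv"))
    write_vcf(res$matrix$sites, haplotypes = res$matrix$haplotypes,
              dosage = res$matrix$dosage,
              sample_ids = res$matrix$samples,
              path = file.path(qc_dir, "filtered.vcf"))
    c(file.path(qc_dir, "qc_report.tsv"),
      file.path(qc_dir, "filtered.vcf"))
  })
  gm <- readRDS(file.path(qc_dir, "filtered.rds"))
  samples <- read_sample_metadata(config$metadata)
  map <- read_genetic_map(config$map)
  chrom_lengths <- stats::setNames(
    vapply(unique(map$chrom), function(ch)
      max(map_chrom(map, ch)$pos_bp), numeric(1)), unique(map$chrom))
  gm$dosage <- gm$dosage[, samples$id, drop = FALSE]

  st_dir <- file.path(out, "structure")
  run_stage("structure", function() {
    dir.create(st_dir, showWarnings = FALSE)
    ibs <- ibs_matrix(gm$dosage)
    write_distance_matrix(ibs$distance,
                          file.path(st_dir, "ibs_distance.tsv"))
    pca <- genotype_pca(gm$dosage)
    utils::write.table(pca$coordinates,
                       file.path(st_dir, "pca.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    write_newick(nj_tree(ibs$distance), file.path(st_dir, "nj.nwk"))
    file.path(st_dir, c("ibs_distance.tsv", "pca.tsv", "nj.nwk"))
  })

  gwas_dir <- file.path(out, "gwas")
  groups <- sort(unique(samples$group))
  scans <- list()
  run_stage("gwas", function() {
    dir.create(gwas_dir, showWarnings = FALSE)
    files <- character()
    for (g in groups) {
      scan <- run_group_scan(gm$dosage, gm$sites, samples, group_id = g,
                             mode = config$gwas_mode,
                             threshold = config$threshold)
      f <- file.path(gwas_dir, sprintf("group%d.tsv", g))
      write_assoc_table(scan$stats, f)
      saveRDS(scan, file.path(gwas_dir, sprintf("group%d.rds", g)))
      files <- c(files, f)
    }
    files
  })
  scans <- lapply(groups, function(g)
    readRDS(file.path(gwas_dir, sprintf("group%d.rds", g))))
  names(scans) <- paste0("group", groups)

  meta_dir <- file.path(out, "meta")
  run_stage("meta", function() {
    dir.create(meta_dir, showWarnings = FALSE)
    meta <- run_meta(scans, threshold = config$threshold)
    f <- file.path(meta_dir, "meta.tsv")
    write_assoc_table(meta$stats, f)
    saveRDS(meta, file.path(meta_dir, "meta.rds"))
    f
  })
  meta <- readRDS(file.path(meta_dir, "meta.rds"))

  intro_dir <- file.path(out, "introgression")
  run_stage("introgression", function() {
    dir.create(intro_dir, showWarnings = FALSE)
    files <- character()
    hap_cols <- function(rows) sort(c(2 * rows - 1, 2 * rows))
    sample_idx <- match(samples$id, gm$samples)
    for (g in groups) {
      sel <- which(samples$group == g)
      role <- samples$role[sel]
      pick <- function(r)
        gm$haplotypes[, hap_cols(sample_idx[sel[role == r]]),
                      drop = FALSE]
      seg_sn <- detect_ibd(pick("source"), pick("neo_bantam"),
                           gm$sites, map, config$min_ibd_cM)
      seg_cn <- detect_ibd(pick("counterpart"), pick("neo_bantam"),
                           gm$sites, map, config$min_ibd_cM)
      ribd <- ribd_scan(seg_sn, seg_cn, samples, g, config$window_bp,
                        chrom_lengths)
      f1 <- file.path(intro_dir, sprintf("ribd_group%d.tsv", g))
      write_window_track(ribd, f1)
      sel_d <- function(r) gm$dosage[, sel[role == r], drop = FALSE]
      fst_cpt <- fst_windows(wc_fst_site(sel_d("neo_bantam"),
                                         sel_d("counterpart")),
                             gm$sites, config$window_bp, chrom_lengths)
      f2 <- file.path(intro_dir, sprintf("fst_group%d.tsv", g))
      write_window_track(fst_cpt, f2)
      files <- c(files, f1, f2,
                 write_ibd_file(seg_sn, file.path(
                   intro_dir, sprintf("ibd_source_neo_group%d.tsv", g))))
    }
    files
  })

  haplo_dir <- file.path(out, "haplotypes")
  run_stage("haplotypes", function() {
    dir.create(haplo_dir, showWarnings = FALSE)
    lead <- meta$stats[which.min(meta$stats$p), ]
    block <- extract_block(gm$haplotypes, gm$sites, lead$chrom,
                           lead$pos, config$flank_bp, samples)
    write_newick(block_tree(block), file.path(haplo_dir, "block.nwk"))
    ld <- ld_profile(block)
    utils::write.table(ld, file.path(haplo_dir, "ld_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- which(!is.na(meta$stats$p) & meta$stats$p <= config$threshold)
    files <- file.path(haplo_dir, c("block.nwk", "ld_profile.tsv"))
    if (length(sig) >= 1) {
      rows <- match(paste(meta$stats$chrom[sig], meta$stats$pos[sig]),
                    paste(gm$sites$chrom, gm$sites$pos))
      view <- significant_variant_view(gm$dosage, rows[!is.na(rows)])
      write_newick(view$tree, file.path(haplo_dir, "sig_variants.nwk"))
      files <- c(files, file.path(haplo_dir, "sig_variants.nwk"))
    }
    files
  })

  if (!is.null(config$genes)) {
    ann_dir <- file.path(out, "annotate")
    run_stage("annotate", function() {
      dir.create(ann_dir, showWarnings = FALSE)
      genes <- read_gene_models(config$genes)
      sig_meta <- meta$stats[!is.na(meta$stats$p) &
                               meta$stats$p <= config$threshold, ]
      assign <- assign_variants(sig_meta, genes, config$flank_bp)
      f <- file.path(ann_dir, "significant_assignments.tsv")
      utils::write.table(assign, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      sets <- lapply(scans, function(s) {
        st <- s$stats
        paste(st$chrom, st$pos)[!is.na(st$p) & st$p <= config$threshold]
      })
      sets$meta <- paste(sig_meta$chrom, sig_meta$pos)
      ov <- overlap_sets(sets)
      f2 <- file.path(ann_dir, "overlap_membership.tsv")
      utils::write.table(data.frame(element = rownames(ov$membership),
                                    ov$membership), f2, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      c(f, f2)
    })
  }
  pipeline_log(manifest, "pipeline complete")
  invisible(manifest)
}
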