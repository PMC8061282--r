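#' Configuration for the bantamization forward simulator
#'
#' The simulator emulates the crossbreeding design that created the Dutch
#' neo-bantam breeds: per group, a true-bantam *source* breed and a
#' normal-sized *counterpart* breed are crossed (F1), followed by repeated
#' backcrossing of causal-allele carriers to counterpart individuals with
#' selection at a group-specific causal locus; the final carriers form the
#' *neo-bantam* cohort. Founder breeds drift apart under the
#' Balding-Nichols model. By default three groups are simulated, with
#' groups 1 and 2 sharing one causal locus and group 3 carrying a private
#' one, mirroring the historical structure of the bantamization groups.
#'
#' @param n_groups number of (source, counterpart, neo) triads
#' @param n_source,n_counterpart,n_neo diploid sample counts per breed
#' @param n_backcross_generations number of backcross generations g; the
#'   expected source-genome fraction outside the causal region is
#'   (1/2)^(g+1)
#' @param n_intercross_generations generations of carrier-by-carrier
#'   intercrossing after the backcrosses, emulating the within-breed
#'   matings that consolidated the neo-bantam breeds: the cohort becomes
#'   a homozygote/heterozygote mixture at the causal locus (causal-allele
#'   frequency above 1/2) instead of uniformly heterozygous, while the
#'   expected neutral source-genome fraction stays at (1/2)^(g+1). Set 0
#'   to stop at the last backcross
#' @param n_chromosomes,chromosome_length_bp,n_sites_per_chromosome genome
#'   dimensions
#' @param ancestral_freq_beta length-2 shape parameters of the Beta
#'   distribution of ancestral allele frequencies
#' @param breed_divergence_F Balding-Nichols drift parameter in [0, 1),
#'   scalar or one value per breed
#' @param recombination_rate constant recombination rate, cM per Mb
#' @param causal_loci data.frame with columns `chrom`, `pos`, `groups`
#'   (comma-separated group ids sharing the locus); `NULL` for the default
#'   layout (chr1 midpoint shared by groups 1 and 2, chr2 midpoint private
#'   to group 3, remaining groups get private loci on successive
#'   chromosomes)
#' @param source_freq,counterpart_freq causal-allele frequency planted in
#'   the source and counterpart founder breeds
#' @param sweep_radius_bp radius of the selective sweep around each causal
#'   locus in the source breed: within it all source haplotypes are copies
#'   of one founder haplotype, emulating the consensus haplotype that
#'   historical selection left around the bantam allele
#' @param selection_mode `"carrier"` keeps any causal-allele carrier at
#'   each backcross; `"homozygote_preferred"` ranks homozygotes first when
#'   drawing the final cohort
#' @param phenotype_model `"causal_carrier"` (bantam iff carrying the
#'   causal allele) or `"liability"` (carrier effect plus standard normal
#'   noise, thresholded)
#' @param seed integer seed; every simulator draw derives from it
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_groups = 3,
                       n_source = 10, n_counterpart = 10, n_neo = 10,
                       n_backcross_generations = 4,
                       n_intercross_generations = 2,
                       n_chromosomes = 3,
                       chromosome_length_bp = 5e6,
                       n_sites_per_chromosome = 2400,
                       ancestral_freq_beta = c(0.5, 0.5),
                       breed_divergence_F = 0.2,
                       recombination_rate = 3,
                       causal_loci = NULL,
                       source_freq = 1, counterpart_freq = 0,
                       sweep_radius_bp = 5e4,
                       selection_mode = c("homozygote_preferred", "carrier"),
                       phenotype_model = c("causal_carrier", "liability"),
                       seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  phenotype_model <- match.arg(phenotype_model)
  counts <- c(n_groups, n_source, n_counterpart, n_neo, n_chromosomes,
              chromosome_length_bp, n_sites_per_chromosome)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_backcross_generations < 0) stop("n_backcross_generations must be >= 0")
  if (n_intercross_generations < 0)
    stop("n_intercross_generations must be >= 0")
  if (any(breed_divergence_F < 0) || any(breed_divergence_F >= 1))
    stop("breed_divergence_F must lie in [0, 1)")
  if (any(c(source_freq, counterpart_freq) < 0) ||
      any(c(source_freq, counterpart_freq) > 1))
    stop("causal allele frequencies must lie in [0, 1]")
  if (is.null(causal_loci)) causal_loci <- default_causal_loci(
    n_groups, n_chromosomes, chromosome_length_bp)
  if (any(causal_loci$pos < 1 | causal_loci$pos > chromosome_length_bp))
    stop("causal positions must lie inside chromosome bounds")
  cfg <- list(
    n_groups = n_groups, n_source = n_source,
    n_counterpart = n_counterpart, n_neo = n_neo,
    n_backcross_generations = n_backcross_generations,
    n_intercross_generations = n_intercross_generations,
    n_chromosomes = n_chromosomes,
    chromosome_length_bp = chromosome_length_bp,
    n_sites_per_chromosome = n_sites_per_chromosome,
    ancestral_freq_beta = ancestral_freq_beta,
    breed_divergence_F = breed_divergence_F,
    recombination_rate = recombination_rate,
    causal_loci = causal_loci,
    source_freq = source_freq, counterpart_freq = counterpart_freq,
    sweep_radius_bp = sweep_radius_bp,
    selection_mode = selection_mode,
    phenotype_model = phenotype_model,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Default causal layout: one locus at the chr1 midpoint shared by groups 1
# and 2, a private locus for group 3 on chr2, further groups on successive
# chromosomes (recycled).
default_causal_loci <- function(n_groups, n_chromosomes, chrom_len) {
  mid <- floor(chrom_len / 2)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (n_groups == 1)
    return(data.frame(chrom = chroms[1], pos = mid, groups = "1",
                      stringsAsFactors = FALSE))
  loci <- data.frame(chrom = chroms[1], pos = mid, groups = "1,2",
                     stringsAsFactors = FALSE)
  if (n_groups >= 3) {
    extra <- 3:n_groups
    chr_idx <- 1 + ((seq_along(extra) - 1) %% max(n_chromosomes - 1, 1)) + 1
    chr_idx <- pmin(chr_idx, n_chromosomes)
    loci <- rbind(loci, data.frame(
      chrom = chroms[chr_idx],
      pos = mid + (seq_along(extra) - 1) * 0,  # midpoints; distinct chroms
      groups = as.character(extra), stringsAsFactors = FALSE))
  }
  loci
}

breed_names <- function(config) {
  g <- seq_len(config$n_groups)
  list(source = paste0("source_g", g),
       counterpart = paste0("counterpart_g", g),
       neo = paste0("neo_g", g))
}

#' Draw founder breed haplotypes under the Balding-Nichols model
#'
#' For each site an ancestral frequency p is drawn from the configured Beta
#' distribution; each breed's frequency is then drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with that breed's drift parameter F (F = 0
#' degenerates to all breeds sharing p). Founder haplotype alleles are
#' independent Bernoulli draws at the breed frequency; all founders are
#' phased by construction.
#'
#' @param config a [sim_config()]
#' @return a `founders` list: `sites` (chrom, pos, ref, alt, ancestral_p),
#'   `haplotypes` (named list of sites x 2n 0/1 matrices per breed),
#'   `breed_freq` (sites x breeds matrix), `map` (the genetic map)
#' @export
generate_founders <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chromosome_length_bp,
                           config$n_sites_per_chromosome))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  # make sure causal positions exist as sites
  for (i in seq_len(nrow(config$causal_loci))) {
    cl <- config$causal_loci[i, ]
    hit <- sites$chrom == cl$chrom & sites$pos == cl$pos
    if (!any(hit)) {
      sites <- rbind(sites, data.frame(chrom = cl$chrom, pos = cl$pos,
                                       stringsAsFactors = FALSE))
    }
  }
  sites <- sites[order(match(sites$chrom, chroms), sites$pos), ]
  sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
  rownames(sites) <- NULL
  n_sites <- nrow(sites)
  sites$ref <- "A"
  sites$alt <- "C"
  ab <- config$ancestral_freq_beta
  p_anc <- stats::rbeta(n_sites, ab[1], ab[2])
  # pin causal-site ancestral frequency at 1/2 so breeds outside the target
  # group remain polymorphic there
  causal_idx <- site_index(sites, config$causal_loci$chrom,
                           config$causal_loci$pos)
  p_anc[causal_idx] <- 0.5
  sites$ancestral_p <- p_anc

  nm <- breed_names(config)
  breeds <- c(nm$source, nm$counterpart)
  Fv <- rep_len(config$breed_divergence_F, length(breeds))
  n_per <- rep(c(config$n_source, config$n_counterpart),
               each = config$n_groups)
  freq <- matrix(NA_real_, n_sites, length(breeds),
                 dimnames = list(NULL, breeds))
  haplotypes <- vector("list", length(breeds))
  names(haplotypes) <- breeds
  for (b in seq_along(breeds)) {
    F <- Fv[b]
    if (F == 0) {
      pb <- p_anc
    } else {
      k <- (1 - F) / F
      pb <- stats::rbeta(n_sites, p_anc * k, (1 - p_anc) * k)
    }
    freq[, b] <- pb
    nh <- 2L * n_per[b]
    haplotypes[[b]] <- matrix(
      stats::rbinom(n_sites * nh, 1L, rep(pb, nh)),
      nrow = n_sites, ncol = nh)
  }
  structure(list(sites = sites, haplotypes = haplotypes,
                 breed_freq = freq,
                 map = constant_rate_map(chroms,
                                         config$chromosome_length_bp,
                                         config$recombination_rate)),
            class = "founders")
}

site_index <- function(sites, chrom, pos) {
  match(paste(chrom, pos), paste(sites$chrom, sites$pos))
}

#' Plant a causal locus (and its source-breed sweep) into founder breeds
#'
#' Source haplotypes of the targeted groups receive the causal allele at
#' `source_freq` (default 1), counterpart haplotypes at `counterpart_freq`
#' (default 0). Within `sweep_radius_bp` of the locus all source
#' haplotypes are replaced by copies of the breed's first founder
#' haplotype, carrying the causal allele: the local monomorphism that
#' historical selection for the bantam allele leaves in the source breed.
#' A locus shared by several groups uses the same position and allele in
#' each group's breeds.
#'
#' @param founders output of [generate_founders()]
#' @param config the [sim_config()]
#' @return modified `founders`
#' @export
plant_causal_loci <- function(founders, config) {
  sites <- founders$sites
  for (i in seq_len(nrow(config$causal_loci))) {
    cl <- config$causal_loci[i, ]
    idx <- site_index(sites, cl$chrom, cl$pos)
    if (is.na(idx)) stop("causal locus not present among sites")
    groups <- as.integer(strsplit(cl$groups, ",")[[1]])
    region <- which(sites$chrom == cl$chrom &
                    abs(sites$pos - cl$pos) <= config$sweep_radius_bp)
    for (g in groups) {
      src <- paste0("source_g", g)
      cpt <- paste0("counterpart_g", g)
      Hs <- founders$haplotypes[[src]]
      nh <- ncol(Hs)
      # sweep: clone haplotype 1 across the region, then set the causal allele
      Hs[region, ] <- Hs[region, 1]
      Hs[idx, ] <- stats::rbinom(nh, 1L, config$source_freq)
      if (config$source_freq == 1) Hs[idx, ] <- 1L
      # keep the sweep consistent: every swept haplotype is identical, so the
      # causal allele must be constant across them when freq is 0 or 1; for
      # intermediate freq the locus site itself is exempt from the clone
      founders$haplotypes[[src]] <- Hs
      Hc <- founders$haplotypes[[cpt]]
      Hc[idx, ] <- stats::rbinom(ncol(Hc), 1L, config$counterpart_freq)
      if (config$counterpart_freq == 0) Hc[idx, ] <- 0L
      founders$haplotypes[[cpt]] <- Hc
    }
  }
  founders$causal <- causal_table(config)
  founders
}

# one row per group: its causal locus
causal_table <- function(config) {
  out <- do.call(rbind, lapply(seq_len(nrow(config$causal_loci)), function(i) {
    cl <- config$causal_loci[i, ]
    data.frame(group = as.integer(strsplit(cl$groups, ",")[[1]]),
               chrom = cl$chrom, pos = cl$pos, stringsAsFactors = FALSE)
  }))
  out[order(out$group), ]
}

#' Meiosis: recombine a haplotype pair into one gamete
#'
#' Haldane model (no interference): the crossover count per chromosome is
#' Poisson with mean the map length in Morgans, crossover positions are
#' uniform in cM and mapped back to bp by inverse linear interpolation; the
#' gamete copies alternate parental haplotypes between breakpoints with a
#' random starting haplotype.
#'
#' @param h1,h2 parental haplotype allele vectors over `sites`
#' @param sites site table (chrom, pos)
#' @param map a `genetic_map`
#' @param origin1,origin2 optional ancestry interval data.frames
#'   (chrom, start, end, origin) carried through the same breakpoints
#' @param keep_breaks also return the breakpoints per chromosome, so the
#'   ancestry splice can be applied later (used by the cross simulator to
#'   track ancestry only for retained offspring)
#' @return list with `alleles`; `origin` intervals tiling each chromosome
#'   when origins were supplied; `breaks` when requested
#' @export
recombine <- function(h1, h2, sites, map, origin1 = NULL, origin2 = NULL,
                      keep_breaks = FALSE) {
  alleles <- integer(length(h1))
  origin <- NULL
  track <- !is.null(origin1)
  chroms <- unique(sites$chrom)
  breaks <- if (keep_breaks) vector("list", length(chroms)) else NULL
  if (keep_breaks) names(breaks) <- chroms
  for (ch in chroms) {
    sidx <- which(sites$chrom == ch)
    L_cM <- map_length_cM(map, ch)
    n_xo <- stats::rpois(1, L_cM / 100)
    bp_break <- sort(cM_to_bp(map, ch, stats::runif(n_xo, 0, L_cM)))
    start_first <- sample.int(2L, 1L) == 1L
    # segment index for each site: 0 breakpoints before it -> first parent
    seg <- findInterval(sites$pos[sidx], bp_break)
    use1 <- (seg %% 2 == 0) == start_first
    alleles[sidx] <- ifelse(use1, h1[sidx], h2[sidx])
    if (track) {
      chrom_len <- max(map_chrom(map, ch)$pos_bp)
      origin <- rbind(origin,
                      splice_origin(origin1, origin2, ch, bp_break,
                                    start_first, chrom_len))
    }
    if (keep_breaks)
      breaks[[ch]] <- list(bp_break = bp_break,
                           start_first = start_first)
  }
  out <- list(alleles = alleles)
  if (track) out$origin <- origin
  if (keep_breaks) out$breaks <- breaks
  out
}

# apply recorded breakpoints to the parent's ancestry intervals
origin_from_breaks <- function(origin1, origin2, breaks, map) {
  do.call(rbind, lapply(names(breaks), function(ch) {
    chrom_len <- max(map_chrom(map, ch)$pos_bp)
    splice_origin(origin1, origin2, ch, breaks[[ch]]$bp_break,
                  breaks[[ch]]$start_first, chrom_len)
  }))
}

# Compose ancestry intervals of the gamete from the two parents' interval
# sets, alternating at crossover breakpoints. Intervals are 0-based
# half-open and tile [0, chrom_len).
splice_origin <- function(origin1, origin2, chrom, bp_break, start_first,
                          chrom_len) {
  bnd <- c(0, floor(bp_break), chrom_len)
  bnd <- bnd[!duplicated(bnd)]
  pieces <- vector("list", length(bnd) - 1)
  for (k in seq_len(length(bnd) - 1)) {
    use1 <- ((k - 1) %% 2 == 0) == start_first
    src <- if (use1) origin1 else origin2
    src <- src[src$chrom == chrom, , drop = FALSE]
    lo <- bnd[k]; hi <- bnd[k + 1]
    keep <- src$end > lo & src$start < hi
    seg <- src[keep, , drop = FALSE]
    seg$start <- pmax(seg$start, lo)
    seg$end <- pmin(seg$end, hi)
    pieces[[k]] <- seg
  }
  out <- do.call(rbind, pieces)
  # merge adjacent intervals with identical origin
  out <- out[order(out$start), , drop = FALSE]
  if (nrow(out) > 1) {
    keep <- c(TRUE, out$origin[-1] != out$origin[-nrow(out)])
    grp <- cumsum(keep)
    out <- data.frame(chrom = chrom,
                      start = tapply(out$start, grp, min),
                      end = tapply(out$end, grp, max),
                      origin = out$origin[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

founder_origin <- function(config, origin_label) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  data.frame(chrom = chroms, start = 0,
             end = config$chromosome_length_bp,
             origin = origin_label, stringsAsFactors = FALSE)
}

#' Simulate the full bantamization cross
#'
#' Per group: the F1 is a cross of one source founder with one counterpart
#' founder; each backcross generation mates causal-allele carriers of the
#' previous generation to counterpart founder individuals, retaining only
#' offspring that satisfy the selection mode at the group's causal locus;
#' the final neo-bantam cohort is drawn without replacement from the last
#' generation. The sampled source and counterpart cohorts are the founder
#' individuals themselves (breed pools are small and the birds used for
#' crossing are birds of the breed), which is what makes the neo-bantam
#' haplotype mosaic traceable by IBD against the sampled cohorts.
#'
#' @param config a [sim_config()]
#' @param founders output of [plant_causal_loci()]
#' @return a `bantam_population` list: `haplotypes` (sites x 2N matrix),
#'   `samples` (id, breed, size_class, role, group, phenotype),
#'   `sites`, `map`, `causal`, `ancestry` (per neo haplotype, 0-based
#'   half-open intervals with origin source/counterpart), `config`
#' @export
simulate_cross <- function(config, founders) {
  if (is.null(founders$causal)) stop("plant_causal_loci() must be run first")
  sites <- founders$sites
  map <- founders$map
  n_off_per_gen <- max(4L * config$n_neo, 24L)
  max_rounds <- 40L

  all_h <- list(); all_samples <- list(); ancestry <- list()
  for (g in seq_len(config$n_groups)) {
    src <- paste0("source_g", g); cpt <- paste0("counterpart_g", g)
    Hs <- founders$haplotypes[[src]]; Hc <- founders$haplotypes[[cpt]]
    ci <- founders$causal[founders$causal$group == g, ]
    cidx <- site_index(sites, ci$chrom, ci$pos)
    o_src <- founder_origin(config, "source")
    o_cpt <- founder_origin(config, "counterpart")

    # breeding population: list of individuals, each
    # list(h1, h2, o1, o2) where h2/o2 is always the counterpart-derived side
    # a gamete from a counterpart founder is pure counterpart ancestry and
    # needs no splice; the hybrid-side gamete records its breakpoints so
    # the ancestry splice is applied only to offspring kept by selection
    make_offspring <- function(parent) {
      cpick <- sample.int(ncol(Hc) / 2, 1)
      gam_c <- recombine(Hc[, 2 * cpick - 1], Hc[, 2 * cpick], sites, map)
      gam_p <- recombine(parent$h1, parent$h2, sites, map,
                         keep_breaks = TRUE)
      list(h1 = gam_p$alleles, h2 = gam_c$alleles,
           breaks = gam_p$breaks, parent = parent)
    }
    resolve_origin <- function(ind) {
      if (is.null(ind$breaks)) return(ind)
      ind$o1 <- origin_from_breaks(ind$parent$o1, ind$parent$o2,
                                   ind$breaks, map)
      ind$o2 <- o_cpt
      ind$breaks <- NULL; ind$parent <- NULL
      ind
    }
    carrier <- function(ind) ind$h1[cidx] + ind$h2[cidx] >= 1L

    # F1 generation: source x counterpart (gametes are pure-breed, so the
    # ancestry of each F1 haplotype is a single full-length interval)
    gen <- lapply(seq_len(n_off_per_gen), function(i) {
      spick <- sample.int(ncol(Hs) / 2, 1)
      cpick <- sample.int(ncol(Hc) / 2, 1)
      gs <- recombine(Hs[, 2 * spick - 1], Hs[, 2 * spick], sites, map)
      gc <- recombine(Hc[, 2 * cpick - 1], Hc[, 2 * cpick], sites, map)
      list(h1 = gs$alleles, h2 = gc$alleles, o1 = o_src, o2 = o_cpt)
    })
    gen <- Filter(carrier, gen)
    if (length(gen) == 0) stop("selection extinguished all carriers at F1")

    if (config$n_backcross_generations > 0) {
      for (bc in seq_len(config$n_backcross_generations)) {
        nxt <- list(); rounds <- 0L
        while (length(nxt) < n_off_per_gen && rounds < max_rounds) {
          rounds <- rounds + 1L
          batch <- lapply(seq_len(n_off_per_gen), function(i)
            make_offspring(gen[[sample.int(length(gen), 1)]]))
          nxt <- c(nxt, lapply(Filter(carrier, batch), resolve_origin))
        }
        if (length(nxt) == 0)
          stop("selection extinguished all carriers at backcross ", bc,
               " in group ", g)
        gen <- nxt
      }
    }
    # fixation stage: carriers mated inter se, causal homozygotes kept,
    # yielding a true-breeding neo-bantam cohort
    if (config$n_intercross_generations > 0) {
      if (length(gen) < 2)
        stop("need >= 2 carriers to intercross in group ", g)
      for (ic in seq_len(config$n_intercross_generations)) {
        keep_rule <- carrier
        nxt <- list(); rounds <- 0L
        while (length(nxt) < n_off_per_gen && rounds < max_rounds) {
          rounds <- rounds + 1L
          batch <- lapply(seq_len(n_off_per_gen), function(i) {
            par <- sample.int(length(gen), 2)
            ga <- recombine(gen[[par[1]]]$h1, gen[[par[1]]]$h2, sites,
                            map, keep_breaks = TRUE)
            gb <- recombine(gen[[par[2]]]$h1, gen[[par[2]]]$h2, sites,
                            map, keep_breaks = TRUE)
            list(h1 = ga$alleles, h2 = gb$alleles, breaks = ga$breaks,
                 breaks2 = gb$breaks, parent = gen[[par[1]]],
                 parent2 = gen[[par[2]]])
          })
          kept <- Filter(keep_rule, batch)
          nxt <- c(nxt, lapply(kept, function(ind) {
            ind$o1 <- origin_from_breaks(ind$parent$o1, ind$parent$o2,
                                         ind$breaks, map)
            ind$o2 <- origin_from_breaks(ind$parent2$o1, ind$parent2$o2,
                                         ind$breaks2, map)
            ind[c("h1", "h2", "o1", "o2")]
          }))
        }
        if (length(nxt) == 0)
          stop("selection extinguished all carriers at intercross ", ic,
               " in group ", g)
        gen <- nxt
      }
    }
    if (length(gen) < config$n_neo)
      stop("not enough carriers to draw the neo-bantam cohort in group ", g)
    if (config$selection_mode == "homozygote_preferred") {
      hom <- vapply(gen, function(ind) ind$h1[cidx] + ind$h2[cidx] == 2L,
                    logical(1))
      ord <- order(!hom)  # homozygotes first, original order within class
      pick <- ord[seq_len(config$n_neo)]
    } else {
      pick <- sample.int(length(gen), config$n_neo)
    }
    neo <- gen[pick]

    # assemble haplotype columns: source, counterpart founders, then neo
    ids_src <- sprintf("g%d_src_%02d", g, seq_len(config$n_source))
    ids_cpt <- sprintf("g%d_cpt_%02d", g, seq_len(config$n_counterpart))
    ids_neo <- sprintf("g%d_neo_%02d", g, seq_len(config$n_neo))
    Hn <- do.call(cbind, lapply(neo, function(ind) cbind(ind$h1, ind$h2)))
    all_h[[g]] <- cbind(Hs, Hc, Hn)
    all_samples[[g]] <- data.frame(
      id = c(ids_src, ids_cpt, ids_neo),
      breed = c(rep(src, config$n_source), rep(cpt, config$n_counterpart),
                rep(paste0("neo_g", g), config$n_neo)),
      size_class = c(rep("bantam", config$n_source),
                     rep("normal", config$n_counterpart),
                     rep("bantam", config$n_neo)),
      role = c(rep("source", config$n_source),
               rep("counterpart", config$n_counterpart),
               rep("neo_bantam", config$n_neo)),
      group = g, stringsAsFactors = FALSE)
    ancestry[[g]] <- do.call(rbind, lapply(seq_along(neo), function(i) {
      rbind(cbind(sample = ids_neo[i], hap = 1L, neo[[i]]$o1),
            cbind(sample = ids_neo[i], hap = 2L, neo[[i]]$o2))
    }))
  }

  H <- do.call(cbind, all_h)
  samples <- do.call(rbind, all_samples)
  rownames(samples) <- NULL
  colnames(H) <- paste0(rep(samples$id, each = 2), "_h", 1:2)

  pop <- structure(list(haplotypes = H, samples = samples, sites = sites,
                        map = map, causal = founders$causal,
                        ancestry = do.call(rbind, ancestry),
                        config = config),
                   class = "bantam_population")
  pop$samples$phenotype <- assign_phenotype(pop)
  pop
}

# 0/1 bantam phenotype per sample
assign_phenotype <- function(pop) {
  cfg <- pop$config
  dos <- causal_dosage(pop)
  if (cfg$phenotype_model == "causal_carrier") {
    as.integer(dos >= 1L)
  } else {
    # liability: carrier effect 3 on a standard normal background,
    # threshold 1.5 -- a major locus with high but imperfect penetrance
    as.integer(3 * (dos >= 1L) + stats::rnorm(nrow(pop$samples)) > 1.5)
  }
}

# dosage at the own group's causal locus (source/neo/counterpart breeds);
# for samples in groups without a causal locus, 0
causal_dosage <- function(pop) {
  dos <- integer(nrow(pop$samples))
  for (g in unique(pop$samples$group)) {
    ci <- pop$causal[pop$causal$group == g, ]
    if (nrow(ci) == 0) next
    idx <- site_index(pop$sites, ci$chrom[1], ci$pos[1])
    sel <- which(pop$samples$group == g)
    cols <- rep(2 * (sel - 1), each = 2) + 1:2
    hm <- matrix(pop$haplotypes[idx, cols], nrow = 2)
    dos[sel] <- colSums(hm)
  }
  dos
}

#' Convenience wrapper: founders -> planted loci -> cross
#' @param config a [sim_config()]
#' @return a `bantam_population`
#' @export
simulate_bantam_population <- function(config = sim_config()) {
  founders <- generate_founders(config)
  founders <- plant_causal_loci(founders, config)
  simulate_cross(config, founders)
}

#' Genotype dosages of a population
#'
#' @param pop a `bantam_population`
#' @return integer matrix sites x samples with values 0/1/2
#' @export
population_dosage <- function(pop) {
  n <- nrow(pop$samples)
  d <- pop$haplotypes[, seq(1, 2 * n, 2), drop = FALSE] +
    pop$haplotypes[, seq(2, 2 * n, 2), drop = FALSE]
  colnames(d) <- pop$samples$id
  d
}

#' Realized source-ancestry fraction of each neo-bantam haplotype
#'
#' @param pop a `bantam_population`
#' @param exclude_cM half-width (cM) of a window around the group's causal
#'   locus to exclude (the selected region is enriched for source ancestry
#'   by construction); 0 disables the exclusion
#' @return data.frame sample, hap, group, fraction
#' @export
source_ancestry_fraction <- function(pop, exclude_cM = 2) {
  anc <- pop$ancestry
  grp <- pop$samples$group[match(anc$sample, pop$samples$id)]
  out <- NULL
  for (g in unique(grp)) {
    ci <- pop$causal[pop$causal$group == g, ][1, ]
    a <- anc[grp == g, , drop = FALSE]
    if (exclude_cM > 0) {
      c_cM <- bp_to_cM(pop$map, ci$chrom, ci$pos)
      lo <- cM_to_bp(pop$map, ci$chrom, c_cM - exclude_cM)
      hi <- cM_to_bp(pop$map, ci$chrom, c_cM + exclude_cM)
      excl <- a$chrom == ci$chrom
      # interval length minus its overlap with the exclusion window
      ov <- pmax(0, pmin(a$end, hi) - pmax(a$start, lo))
      len <- (a$end - a$start) - ifelse(excl, ov, 0)
    } else {
      len <- a$end - a$start
    }
    key <- paste(a$sample, a$hap)
    tot <- tapply(len, key, sum)
    srcl <- tapply(len * (a$origin == "source"), key, sum)
    out <- rbind(out, data.frame(
      sample = sub(" .*", "", names(tot)),
      hap = as.integer(sub(".* ", "", names(tot))),
      group = g, fraction = as.numeric(srcl / tot),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
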