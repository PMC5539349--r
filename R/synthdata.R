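#' Simulation configuration
#'
#' Bundles every tunable of the synthetic single-cell NOMe-seq world and
#' validates it. Defaults describe a sparse single-cell regime: ~10% of
#' sites recovered per cell, read depth 1 + Poisson(2) at covered sites,
#' GCH methylation probability 0.8 in accessible chromatin (NDRs and
#' linkers) and 0.05 inside nucleosome cores, and symmetric bisulfite
#' error of 0.5% in both directions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param chrom_names optional names (default chr1..chrN).
#' @param gc_fraction genome GC content.
#' @param nucleosome_core core width (bp).
#' @param nucleosome_repeat core-to-core repeat length (bp).
#' @param n_genes genes per genome.
#' @param ndr_fraction_of_promoters fraction of promoters given a planted
#'   NDR containing the TSS.
#' @param ndr_width_range planted NDR width range (bp).
#' @param n_distal_ndrs planted NDRs far (>2 kb) from every TSS.
#' @param p_gch_open,p_gch_closed GCH methylation probability in
#'   accessible chromatin / nucleosome cores.
#' @param wcg_level_by_stage_and_allele nested list: stage -> element
#'   class (intragenic/intergenic/CGI) -> c(maternal, paternal) level.
#' @param bisulfite_failure_rate P(unmethylated C read as C).
#' @param inappropriate_conversion_rate P(methylated C read as T).
#' @param site_detection_prob per-cell probability a site is covered.
#' @param depth_mean mean of the Poisson part of depth (depth = 1 +
#'   Poisson(depth_mean)).
#' @param snp_density heterozygous SNPs per bp.
#' @param cells_per_stage named integer vector.
#' @param ploidy_by_cell optional named vector cell -> true ploidy
#'   (default 2 everywhere).
#' @param chrom_copy_by_cell optional named list cell -> named numeric
#'   vector of per-chromosome copy multipliers (for CNV simulation).
#' @param lambda_spike_reads expected lambda spike-in reads per cell.
#' @param genomic_reads_2n expected genomic reads for a diploid cell.
#' @param n_allele_reads simplified read records per cell (for allele
#'   partitioning).
#' @param read_length length of simplified reads (bp).
#' @param denovo_events optional list(from_stage, to_stage, n_sites,
#'   level_from, level_to) planting stage-transition methylation gains.
#' @param seed RNG seed.
#' @return validated config list of class "cool_config".
#' @export
simulation_config <- function(n_chromosomes = 1L,
                              chrom_length = 200000L,
                              chrom_names = NULL,
                              gc_fraction = 0.42,
                              nucleosome_core = 147L,
                              nucleosome_repeat = 180L,
                              n_genes = 20L,
                              ndr_fraction_of_promoters = 0.5,
                              ndr_width_range = c(200L, 400L),
                              n_distal_ndrs = 10L,
                              p_gch_open = 0.8,
                              p_gch_closed = 0.05,
                              wcg_level_by_stage_and_allele = list(
                                ES = list(intragenic = c(0.75, 0.75),
                                          intergenic = c(0.70, 0.70),
                                          CGI = c(0.10, 0.10))),
                              bisulfite_failure_rate = 0.005,
                              inappropriate_conversion_rate = 0.005,
                              site_detection_prob = 0.10,
                              depth_mean = 2,
                              snp_density = 0.002,
                              cells_per_stage = c(ES = 8L),
                              ploidy_by_cell = NULL,
                              chrom_copy_by_cell = NULL,
                              lambda_spike_reads = 5000,
                              genomic_reads_2n = 20000,
                              n_allele_reads = 2000L,
                              read_length = 100L,
                              denovo_events = NULL,
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(gc_fraction, p_gch_open, p_gch_closed, bisulfite_failure_rate,
             inappropriate_conversion_rate, site_detection_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
  if (nucleosome_core >= nucleosome_repeat)
    stop("nucleosome_core must be < nucleosome_repeat")
  if (ndr_width_range[1] > ndr_width_range[2])
    stop("ndr_width_range must be non-decreasing")
  for (st in names(wcg_level_by_stage_and_allele))
    for (cls in names(wcg_level_by_stage_and_allele[[st]])) {
      lv <- wcg_level_by_stage_and_allele[[st]][[cls]]
      if (length(lv) != 2L || any(lv < 0 | lv > 1))
        stop("WCG levels must be (maternal, paternal) pairs in [0,1]")
    }
  if (is.null(cfg$chrom_names))
    cfg$chrom_names <- paste0("chr", seq_len(n_chromosomes))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cool_config"
  cfg
}

#' Simulate a genome with planted regulatory ground truth
#'
#' Generates random chromosome sequences at the requested GC fraction,
#' places genes (TSS + body), CpG islands at half the promoters, planted
#' NDRs at the configured fraction of promoters plus random distal NDRs,
#' tiles all remaining chromatin with nucleosome cores at the repeat
#' length, and scatters heterozygous SNPs (maternal allele = reference).
#' Everything is deterministic given the seed.
#'
#' @param config a \code{simulation_config}.
#' @return "cool_truth" list: genome, chrom_lengths, tss_table, genes,
#'   cgis, planted_ndrs, nucleosome_cores, snp_table, element class maps,
#'   accessibility maps, per-gene true promoter state, de novo event
#'   sites.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$chrom_length
  if (config$n_genes > 0L && L < 25000L)
    stop("chromosome too short to host the requested genes")
  chroms <- config$chrom_names
  gc <- config$gc_fraction
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- stats::setNames(vapply(chroms, function(ch) {
    paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
          collapse = "")
  }, character(1)), chroms)
  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)

  # genes: TSS on a spaced grid, random strand, body 2-8 kb
  genes_per_chrom <- diff(round(seq(0, config$n_genes,
                                    length.out = length(chroms) + 1)))
  genes <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    ng <- genes_per_chrom[ci]
    if (ng == 0L) next
    slots <- floor(seq(10000, L - 10000, length.out = max(ng, 2L)))[seq_len(ng)]
    tss <- as.integer(slots + sample(-1000:1000, ng, replace = TRUE))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    blen <- sample(2000:8000, ng, replace = TRUE)
    gstart <- ifelse(strand == "+", tss, pmax(0L, tss - blen + 1L))
    gend <- ifelse(strand == "+", pmin(L, tss + blen), tss + 1L)
    genes[[ci]] <- data.table::data.table(
      gene = paste0("g", gid + seq_len(ng)), chrom = chroms[ci],
      tss = tss, strand = strand, start = as.integer(gstart),
      end = as.integer(gend))
    gid <- gid + ng
  }
  genes <- data.table::rbindlist(genes)
  if (nrow(genes) == 0L)
    genes <- data.table::data.table(gene = character(), chrom = character(),
                                    tss = integer(), strand = character(),
                                    start = integer(), end = integer())
  tss_table <- genes[, .(gene, chrom, tss, strand)]

  # CpG islands at a random half of promoters
  cgi_genes <- genes[sample(.N, floor(.N / 2))]
  cgis <- if (nrow(cgi_genes)) intervals(cgi_genes$chrom,
                                         pmax(0L, cgi_genes$tss - 300L),
                                         pmin(L, cgi_genes$tss + 300L))
          else intervals(character(), integer(), integer())[0]

  # planted promoter NDRs (contain the TSS) and distal NDRs
  n_prom_ndr <- round(nrow(genes) * config$ndr_fraction_of_promoters)
  prom_idx <- if (n_prom_ndr > 0) sample(nrow(genes), n_prom_ndr) else integer()
  wr <- config$ndr_width_range
  ndrs <- list()
  if (length(prom_idx)) {
    w <- sample(wr[1]:wr[2], length(prom_idx), replace = TRUE)
    off <- floor(w * stats::runif(length(prom_idx), 0.2, 0.8))
    s <- pmax(0L, genes$tss[prom_idx] - off)
    ndrs[[1]] <- data.table::data.table(chrom = genes$chrom[prom_idx],
                                        start = as.integer(s),
                                        end = as.integer(pmin(L, s + w)),
                                        class = "promoter")
  }
  if (config$n_distal_ndrs > 0) {
    placed <- 0L; tries <- 0L; acc <- list()
    while (placed < config$n_distal_ndrs && tries < 50L * config$n_distal_ndrs) {
      tries <- tries + 1L
      ch <- sample(chroms, 1)
      w <- sample(wr[1]:wr[2], 1)
      s <- sample.int(L - w, 1)
      tssd <- tss_table[chrom == ch, tss]
      if (length(tssd) && min(abs(c(tssd - s, tssd - (s + w)))) < 2500L) next
      prev <- data.table::rbindlist(c(ndrs, acc), fill = TRUE)
      if (nrow(prev) &&
          any(prev$chrom == ch & prev$start < s + w & s < prev$end)) next
      acc[[length(acc) + 1L]] <- data.table::data.table(
        chrom = ch, start = as.integer(s), end = as.integer(s + w),
        class = "distal")
      placed <- placed + 1L
    }
    ndrs <- c(ndrs, acc)
  }
  planted_ndrs <- if (length(ndrs)) data.table::rbindlist(ndrs, fill = TRUE)
    else data.table::data.table(chrom = character(), start = integer(),
                                end = integer(), class = character())
  data.table::setorder(planted_ndrs, chrom, start)

  # nucleosome cores tile everything outside NDRs at the repeat length
  # nucleosome cores: each segment between NDRs is tiled with evenly
  # spaced cores flush at both segment edges, so the -1/+1 nucleosomes
  # abut planted NDRs exactly (well-positioned flanking nucleosomes) and
  # internal linkers stay near repeat - core. Closed promoters get a
  # dense, linker-free block of cores centered on the TSS so the planted
  # promoter state is unambiguous at the accessibility level.
  core <- config$nucleosome_core; rep_len <- config$nucleosome_repeat
  closed_idx <- setdiff(seq_len(nrow(genes)), prom_idx)
  zones <- NULL
  if (length(closed_idx)) {
    half <- core + core %/% 2L   # zone spans 3 cores centered on the TSS
    z <- intervals(genes$chrom[closed_idx],
                   pmax(0L, genes$tss[closed_idx] - half),
                   pmin(L, genes$tss[closed_idx] + half + 1L))
    z <- merge_intervals(z)
    # stretch each zone to a whole number of flush cores
    z[, end := pmin(L, start + as.integer(ceiling((end - start) / core)) *
                         core)]
    # drop zones colliding with a planted NDR (cannot happen for spaced
    # genes; defensive)
    keep <- vapply(seq_len(nrow(z)), function(i)
      !nrow(planted_ndrs[chrom == z$chrom[i] & start < z$end[i] &
                         z$start[i] < end]), logical(1))
    zones <- z[keep]
  }
  blocked <- merge_intervals(rbind(
    planted_ndrs[, .(chrom, start, end)],
    if (!is.null(zones)) zones[, .(chrom, start, end)]))
  cores <- list()
  for (ch in chroms) {
    nd <- blocked[chrom == ch]
    bounds <- c(0L, as.vector(rbind(nd$start, nd$end)), L)
    s_list <- integer()
    for (si in seq_len(length(bounds) / 2)) {
      seg_start <- bounds[2 * si - 1]; seg_end <- bounds[2 * si]
      seg_len <- seg_end - seg_start
      if (seg_len < core) next
      n <- max(1L, round(seg_len / rep_len))
      while (n * core > seg_len) n <- n - 1L
      if (n >= 2L && (seg_len - n * core) / (n - 1) >= 140 &&
          (n + 1L) * core <= seg_len) n <- n + 1L
      if (n == 1L) {
        s <- if (si == 1L) seg_end - core else seg_start
        s_list <- c(s_list, s)
      } else {
        gap_total <- seg_len - n * core
        i <- seq_len(n) - 1L
        s_list <- c(s_list,
                    seg_start + as.integer(round(i * gap_total / (n - 1))) +
                      i * core)
      }
    }
    # dense zone cores, packed back-to-back
    zc <- if (!is.null(zones)) zones[chrom == ch] else NULL
    if (!is.null(zc) && nrow(zc)) {
      for (i in seq_len(nrow(zc))) {
        n <- (zc$end[i] - zc$start[i]) %/% core
        if (n > 0)
          s_list <- c(s_list, zc$start[i] + (seq_len(n) - 1L) * core)
      }
    }
    s_list <- sort(unique(s_list))
    if (length(s_list))
      cores[[ch]] <- data.table::data.table(chrom = ch, start = s_list,
                                            end = s_list + core)
  }
  nucleosome_cores <- data.table::rbindlist(cores)

  # heterozygous SNPs; maternal allele is the reference base
  snps <- list()
  for (ch in chroms) {
    n_snp <- stats::rbinom(1, L, config$snp_density)
    if (n_snp == 0L) next
    pos <- sort(sample.int(L, n_snp) - 1L)
    ref <- substring(genome[[ch]], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
      USE.NAMES = FALSE)
    snps[[ch]] <- data.table::data.table(chrom = ch, pos = pos,
                                         maternal_allele = ref,
                                         paternal_allele = alt)
  }
  snp_table <- data.table::rbindlist(snps)
  if (nrow(snp_table) == 0L)
    snp_table <- data.table::data.table(chrom = character(),
                                        pos = integer(),
                                        maternal_allele = character(),
                                        paternal_allele = character())

  # per-position lookups: accessibility (TRUE = inside a nucleosome core)
  # and element class (0 intergenic, 1 intragenic, 2 CGI; CGI wins)
  in_core <- lapply(chroms, function(ch) {
    v <- logical(L)
    cc <- nucleosome_cores[chrom == ch]
    for (i in seq_len(nrow(cc))) v[(cc$start[i] + 1L):cc$end[i]] <- TRUE
    v
  })
  names(in_core) <- chroms
  element_map <- lapply(chroms, function(ch) {
    v <- integer(L)
    gb <- genes[chrom == ch]
    for (i in seq_len(nrow(gb))) v[(gb$start[i] + 1L):gb$end[i]] <- 1L
    cg <- cgis[chrom == ch]
    for (i in seq_len(nrow(cg))) v[(cg$start[i] + 1L):cg$end[i]] <- 2L
    v
  })
  names(element_map) <- chroms

  true_promoter_state <- genes[, .(gene, chrom, tss,
    state = ifelse(seq_len(.N) %in% prom_idx, "open", "closed"))]

  truth <- list(genome = genome, chrom_lengths = chrom_lengths,
                tss_table = tss_table, genes = genes, cgis = cgis,
                planted_ndrs = planted_ndrs,
                nucleosome_cores = nucleosome_cores,
                snp_table = snp_table, in_core = in_core,
                element_map = element_map,
                true_promoter_state = true_promoter_state,
                denovo_sites = NULL, config = config)
  if (!is.null(config$denovo_events)) {
    ev <- config$denovo_events
    ctx <- classify_cytosines(genome)
    wcg <- ctx[context_class == "WCG"]
    pick <- wcg[sample(.N, min(ev$n_sites, .N))]
    truth$denovo_sites <- pick[, .(chrom, pos, strand)][
      , `:=`(from_stage = ev$from_stage, to_stage = ev$to_stage,
             level_from = ev$level_from, level_to = ev$level_to)]
  }
  class(truth) <- "cool_truth"
  truth
}

#' Element class (intergenic/intragenic/CGI) at positions
#' @param truth a \code{cool_truth}.
#' @param chrom,pos vectors of positions (0-based).
#' @return character vector of classes.
#' @export
element_class <- function(truth, chrom, pos) {
  codes <- vapply(seq_along(pos), function(i)
    truth$element_map[[chrom[i]]][pos[i] + 1L], integer(1))
  c("intergenic", "intragenic", "CGI")[codes + 1L]
}

.error_adjust <- function(p, cfg) {
  p * (1 - cfg$inappropriate_conversion_rate) +
    (1 - p) * cfg$bisulfite_failure_rate
}

.wcg_true_level <- function(truth, stage, elements, allele,
                            chrom = NULL, pos = NULL, strand = NULL) {
  cfg <- truth$config
  lv_map <- cfg$wcg_level_by_stage_and_allele[[stage]]
  if (is.null(lv_map)) stop("stage not configured: ", stage)
  ai <- if (allele == "maternal") 1L else 2L
  p <- vapply(elements, function(e) lv_map[[e]][ai], numeric(1),
              USE.NAMES = FALSE)
  dn <- truth$denovo_sites
  if (!is.null(dn) && !is.null(chrom)) {
    stages <- names(cfg$wcg_level_by_stage_and_allele)
    key <- paste(chrom, pos, strand)
    dkey <- paste(dn$chrom, dn$pos, dn$strand)
    hit <- match(key, dkey)
    has <- !is.na(hit)
    if (any(has)) {
      after <- match(stage, stages) >= match(dn$to_stage[hit[has]], stages)
      p[has] <- ifelse(after, dn$level_to[hit[has]],
                       dn$level_from[hit[has]])
    }
  }
  p
}

#' Simulate per-cell call tables, read records and read counts
#'
#' For every cell: each cytosine (any context class, either strand) is
#' covered with probability \code{site_detection_prob}; covered sites
#' draw depth 1 + Poisson(depth_mean); GCH sites are methylated per read
#' with probability p_gch_open in accessible chromatin (planted NDRs and
#' linkers) or p_gch_closed inside nucleosome cores; WCG reads are split
#' evenly between alleles and methylated at the allele's configured true
#' level for the site's element class and the cell's stage; symmetric
#' bisulfite error is applied to both channels. Simplified read records
#' (span + SNP base observations + per-site methylation observations)
#' are emitted for allele partitioning, genomic read positions
#' proportional to ploidy and per-chromosome copy multipliers for CNV,
#' and Poisson lambda spike-in counts for ploidy estimation.
#'
#' @param truth from \code{simulate_genome}.
#' @param config the same \code{simulation_config}.
#' @return "cool_cells" list: cells (summary table), reports (named list
#'   of cytosine-call tables), read_snp_obs, meth_obs, reads (long
#'   tables over all cells), read_pos (named list of genomic read
#'   positions).
#' @export
simulate_cells <- function(truth, config) {
  set.seed(config$seed + 1L)
  ctx <- classify_cytosines(truth$genome)
  chroms <- names(truth$genome)
  # indexed lookups for the per-read loops
  ctx_chan <- ctx[context_class %in% c("WCG", "GCH")]
  chan_idx <- split(seq_len(nrow(ctx_chan)),
                    paste(ctx_chan$chrom, ctx_chan$strand))
  chan_idx <- lapply(chan_idx, function(i) i[order(ctx_chan$pos[i])])
  snp_idx <- split(seq_len(nrow(truth$snp_table)), truth$snp_table$chrom)
  snp_idx <- lapply(snp_idx, function(i) i[order(truth$snp_table$pos[i])])
  range_rows <- function(idx, pos_all, lo, hi) {
    if (is.null(idx)) return(integer())
    p <- pos_all[idx]
    a <- findInterval(lo - 0.5, p) + 1L
    b <- findInterval(hi - 0.5, p)
    if (b < a) integer() else idx[a:b]
  }
  cells <- list(); reports <- list(); read_pos <- list()
  snp_obs_acc <- list(); meth_obs_acc <- list(); reads_acc <- list()
  stages <- rep(names(config$cells_per_stage), config$cells_per_stage)
  cell_ids <- unlist(lapply(names(config$cells_per_stage), function(st)
    sprintf("%s_c%02d", st, seq_len(config$cells_per_stage[[st]]))))
  open_p <- function(chrom, pos) {
    closed <- vapply(seq_along(pos), function(i)
      truth$in_core[[chrom[i]]][pos[i] + 1L], logical(1))
    ifelse(closed, config$p_gch_closed, config$p_gch_open)
  }
  for (k in seq_along(cell_ids)) {
    cell <- cell_ids[k]; stage <- stages[k]
    ploidy <- if (!is.null(config$ploidy_by_cell) &&
                  cell %in% names(config$ploidy_by_cell))
      config$ploidy_by_cell[[cell]] else 2

    covered <- ctx[stats::runif(nrow(ctx)) < config$site_detection_prob]
    d <- 1L + stats::rpois(nrow(covered), config$depth_mean)
    meth <- integer(nrow(covered))
    is_gch <- covered$context_class == "GCH"
    if (any(is_gch)) {
      p <- open_p(covered$chrom[is_gch], covered$pos[is_gch])
      meth[is_gch] <- stats::rbinom(sum(is_gch), d[is_gch],
                                    .error_adjust(p, config))
    }
    is_wcg <- covered$context_class == "WCG"
    if (any(is_wcg)) {
      el <- element_class(truth, covered$chrom[is_wcg],
                          covered$pos[is_wcg])
      pm <- .wcg_true_level(truth, stage, el, "maternal",
                            covered$chrom[is_wcg], covered$pos[is_wcg],
                            covered$strand[is_wcg])
      pp <- .wcg_true_level(truth, stage, el, "paternal",
                            covered$chrom[is_wcg], covered$pos[is_wcg],
                            covered$strand[is_wcg])
      dm <- stats::rbinom(sum(is_wcg), d[is_wcg], 0.5)
      meth[is_wcg] <- stats::rbinom(sum(is_wcg), dm,
                                    .error_adjust(pm, config)) +
        stats::rbinom(sum(is_wcg), d[is_wcg] - dm,
                      .error_adjust(pp, config))
    }
    other <- !is_gch & !is_wcg
    if (any(other))
      meth[other] <- stats::rbinom(sum(other), d[other],
                                   .error_adjust(0.02, config))
    rep_dt <- covered[, .(chrom, pos, strand)]
    rep_dt[, `:=`(meth = meth, unmeth = d - meth,
                  context_class = covered$context_class,
                  trinucleotide = covered$trinucleotide)]
    reports[[cell]] <- rep_dt[]

    # simplified allele reads
    nr <- config$n_allele_reads
    if (nr > 0) {
      rchrom <- sample(chroms, nr, replace = TRUE,
                       prob = truth$chrom_lengths[chroms])
      rstart <- as.integer(floor(stats::runif(nr) *
        (truth$chrom_lengths[rchrom] - config$read_length)))
      rstrand <- sample(c("+", "-"), nr, replace = TRUE)
      rallele <- sample(c("maternal", "paternal"), nr, replace = TRUE)
      rid <- sprintf("%s_r%05d", cell, seq_len(nr))
      reads_acc[[cell]] <- data.table::data.table(
        read_id = rid, cell = cell, chrom = rchrom, start = rstart,
        end = rstart + config$read_length, strand = rstrand,
        true_allele = rallele)
      # vectorized per-read overlap expansion via sorted-position ranges
      expand_hits <- function(keys, pos_sorted_idx, pos_all) {
        lo <- integer(nr); hi <- integer(nr)
        for (key in unique(keys)) {
          r <- which(keys == key)
          idx <- pos_sorted_idx[[key]]
          if (is.null(idx)) { lo[r] <- 1L; hi[r] <- 0L; next }
          p <- pos_all[idx]
          lo[r] <- findInterval(rstart[r] - 0.5, p) + 1L
          hi[r] <- findInterval(rstart[r] + config$read_length - 0.5, p)
        }
        n_hit <- pmax(hi - lo + 1L, 0L)
        read_i <- rep.int(seq_len(nr), n_hit)
        rows <- unlist(lapply(which(n_hit > 0L), function(i)
          pos_sorted_idx[[keys[i]]][lo[i]:hi[i]]), use.names = FALSE)
        list(read_i = read_i, rows = rows)
      }
      # SNP observations with bisulfite conversion of the allele base
      sn <- truth$snp_table
      h <- expand_hits(rchrom, snp_idx, sn$pos)
      if (length(h$rows)) {
        s <- sn[h$rows]
        al <- rallele[h$read_i]; str <- rstrand[h$read_i]
        b <- ifelse(al == "maternal", s$maternal_allele,
                    s$paternal_allele)
        b[str == "+" & b == "C"] <- "T"
        b[str == "-" & b == "G"] <- "A"
        snp_obs_acc[[cell]] <- data.table::data.table(
          read_id = rid[h$read_i], cell = cell, strand = str,
          chrom = s$chrom, pos = s$pos, base = b)
      }
      # methylation observations on the read's strand
      h <- expand_hits(paste(rchrom, rstrand), chan_idx, ctx_chan$pos)
      if (length(h$rows)) {
        s <- ctx_chan[h$rows]
        p <- numeric(nrow(s))
        g <- s$context_class == "GCH"
        if (any(g)) p[g] <- open_p(s$chrom[g], s$pos[g])
        w <- !g
        if (any(w)) {
          el <- element_class(truth, s$chrom[w], s$pos[w])
          p[w] <- .wcg_true_level(truth, stage, el, "maternal",
                                  s$chrom[w], s$pos[w], s$strand[w])
          pp <- .wcg_true_level(truth, stage, el, "paternal",
                                s$chrom[w], s$pos[w], s$strand[w])
          pat <- rallele[h$read_i][w] == "paternal"
          p[w][pat] <- pp[pat]
        }
        meth_obs_acc[[cell]] <- data.table::data.table(
          read_id = rid[h$read_i], cell = cell, chrom = s$chrom,
          pos = s$pos, strand = s$strand, channel = s$context_class,
          methylated = stats::rbinom(nrow(s), 1,
                                     .error_adjust(p, config)))
      }
    }

    # genomic read positions (ploidy- and copy-weighted) + spike-in
    copy <- rep(1, length(chroms)); names(copy) <- chroms
    if (!is.null(config$chrom_copy_by_cell) &&
        cell %in% names(config$chrom_copy_by_cell)) {
      cc <- config$chrom_copy_by_cell[[cell]]
      copy[names(cc)] <- cc
    }
    n_genomic <- stats::rpois(1, config$genomic_reads_2n * ploidy / 2)
    wts <- truth$chrom_lengths[chroms] * copy
    gchrom <- sample(chroms, n_genomic, replace = TRUE,
                     prob = wts / sum(wts))
    gpos <- as.integer(floor(stats::runif(n_genomic) *
                             truth$chrom_lengths[gchrom]))
    read_pos[[cell]] <- data.table::data.table(chrom = gchrom, pos = gpos)
    lambda_reads <- stats::rpois(1, config$lambda_spike_reads)
    cells[[cell]] <- data.table::data.table(
      cell = cell, stage = stage, ploidy = ploidy,
      genomic_reads = n_genomic, lambda_reads = lambda_reads)
  }
  out <- list(cells = data.table::rbindlist(cells), reports = reports,
              reads = data.table::rbindlist(reads_acc),
              read_snp_obs = data.table::rbindlist(snp_obs_acc),
              meth_obs = data.table::rbindlist(meth_obs_acc),
              read_pos = read_pos)
  class(out) <- "cool_cells"
  out
}

#' Write a simulation to disk in the package's on-disk formats
#'
#' Emits genome FASTA, TSS/SNP TSVs, planted-truth BEDs, a ground-truth
#' JSON, per-cell cytosine reports and read-record TSVs.
#'
#' @param truth,sim outputs of \code{simulate_genome} /
#'   \code{simulate_cells}.
#' @param outdir output directory (created).
#' @return outdir, invisibly.
#' @export
write_simulation <- function(truth, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(truth$genome, file.path(outdir, "genome.fa"))
  write_tss_table(truth$tss_table, file.path(outdir, "tss.tsv"))
  write_snp_table(truth$snp_table, file.path(outdir, "snps.tsv"))
  write_bed(truth$planted_ndrs, file.path(outdir, "planted_ndrs.bed"),
            extra_columns = "class")
  write_bed(truth$nucleosome_cores,
            file.path(outdir, "nucleosome_cores.bed"))
  if (nrow(truth$cgis)) write_bed(truth$cgis, file.path(outdir, "cgis.bed"))
  gt <- list(chrom_lengths = as.list(truth$chrom_lengths),
             true_promoter_state = truth$true_promoter_state,
             true_ploidy = as.list(stats::setNames(sim$cells$ploidy,
                                                   sim$cells$cell)))
  jsonlite::write_json(gt, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  celldir <- file.path(outdir, "cells")
  dir.create(celldir, showWarnings = FALSE)
  for (cell in names(sim$reports))
    write_cytosine_report(sim$reports[[cell]],
                          file.path(celldir, paste0(cell, ".tsv")))
  data.table::fwrite(sim$cells, file.path(outdir, "cells.tsv"), sep = "\t")
  if (nrow(sim$reads))
    data.table::fwrite(sim$reads, file.path(outdir, "reads.tsv"),
                       sep = "\t")
  invisible(outdir)
}
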