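# shared fixtures, built once per test run and cached in an environment
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a small deep-coverage world: every site detected in each of 10 cells,
# so merged depth ~30x; used for recovery-style tests
deep_sim <- function() fixture("deep_sim", function() {
  cfg <- simulation_config(seed = 101, chrom_length = 60000L,
                           n_genes = 8L, n_distal_ndrs = 4L,
                           site_detection_prob = 1.0,
                           cells_per_stage = c(ES = 10L),
                           n_allele_reads = 0L)
  truth <- simulate_genome(cfg)
  sim <- simulate_cells(truth, cfg)
  list(cfg = cfg, truth = truth, sim = sim)
})

# the sparse default world (10% detection), with allele reads
sparse_sim <- function() fixture("sparse_sim", function() {
  cfg <- simulation_config(seed = 202, chrom_length = 80000L,
                           n_genes = 8L, n_distal_ndrs = 4L,
                           cells_per_stage = c(ES = 6L),
                           n_allele_reads = 800L)
  truth <- simulate_genome(cfg)
  sim <- simulate_cells(truth, cfg)
  list(cfg = cfg, truth = truth, sim = sim)
})

pooled_gch_counts <- function(sim) {
  data.table::rbindlist(sim$reports)[
    context_class == "GCH",
    .(c_count = sum(meth), t_count = sum(unmeth)), by = .(chrom, pos)]
}

# independent brute-force window scanner: enumerate every window, test,
# keep, merge, filter -- a deliberately naive re-implementation used as
# the oracle for scan_and_call
brute_force_scan <- function(gch_counts, chrom_lengths, params) {
  gc_tot <- sum(gch_counts$c_count)
  gt_tot <- sum(gch_counts$t_count)
  bg <- gc_tot / (gc_tot + gt_tot)
  regions <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    s <- gch_counts[gch_counts$chrom == chr, ]
    kept <- list()
    for (st in seq(0, len - 1, by = params$step_bp)) {
      en <- min(st + params$window_bp, len)
      in_w <- s$pos >= st & s$pos < en
      wc <- sum(s$c_count[in_w]); wt <- sum(s$t_count[in_w])
      tab <- matrix(c(wc, wt, gc_tot - wc, gt_tot - wt), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
      rate <- wc / (wc + wt)
      ok <- if (params$direction == "enriched") rate > bg else rate < bg
      if (p <= params$p_cutoff && ok)
        kept[[length(kept) + 1L]] <- c(st, en)
    }
    if (!length(kept)) next
    km <- do.call(rbind, kept)
    km <- km[order(km[, 1]), , drop = FALSE]
    cur <- km[1, ]
    for (i in seq_len(nrow(km))[-1]) {
      if (km[i, 1] < cur[2]) cur[2] <- max(cur[2], km[i, 2])
      else { regions[[length(regions) + 1L]] <- c(chr, cur); cur <- km[i, ] }
    }
    regions[[length(regions) + 1L]] <- c(chr, cur)
  }
  if (!length(regions)) return(data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer()))
  df <- data.frame(chrom = sapply(regions, `[`, 1),
                   start = as.integer(sapply(regions, `[`, 2)),
                   end = as.integer(sapply(regions, `[`, 3)))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    in_r <- gch_counts$chrom == df$chrom[i] &
      gch_counts$pos >= df$start[i] & gch_counts$pos < df$end[i]
    keep[i] <- (df$end[i] - df$start[i]) >= params$min_region_bp &&
      sum(in_r) >= params$min_gch_sites
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$chrom, df$start), , drop = FALSE]
}

# random pooled GCH count table on one chromosome
random_gch_counts <- function(len, n_sites, level_fun, depth = 30L,
                              chrom = "chr1") {
  pos <- sort(sample.int(len, n_sites) - 1L)
  p <- level_fun(pos)
  d <- stats::rpois(n_sites, depth) + 1L
  cc <- stats::rbinom(n_sites, d, p)
  data.table::data.table(chrom = chrom, pos = pos, c_count = cc,
                         t_count = d - cc)
}
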