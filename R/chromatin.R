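#' Window-test presets
#'
#' The NDR preset scans 120-bp windows at 20-bp spacing, retains windows
#' with chi-square p <= 1e-15 whose GCH methylation rate exceeds the
#' genomic background (enrichment = accessibility), merges overlapping
#' significant windows and keeps merged regions of >= 140 bp covering
#' >= 5 GCH sites. The nucleosome preset scans 40-bp windows at 20-bp
#' spacing with p <= 1e-3 in the depleted direction, keeping regions
#' >= 60 bp with >= 3 GCH sites.
#'
#' @param preset "ndr" or "nucleosome".
#' @return list of scan parameters.
#' @export
window_params <- function(preset = c("ndr", "nucleosome")) {
  preset <- match.arg(preset)
  if (preset == "ndr")
    list(window_bp = 120L, step_bp = 20L, p_cutoff = 1e-15,
         min_region_bp = 140L, min_gch_sites = 5L, direction = "enriched")
  else
    list(window_bp = 40L, step_bp = 20L, p_cutoff = 1e-3,
         min_region_bp = 60L, min_gch_sites = 3L, direction = "depleted")
}

validate_window_params <- function(p) {
  stopifnot(p$step_bp <= p$window_bp, p$p_cutoff > 0, p$p_cutoff < 1,
            p$direction %in% c("enriched", "depleted"))
  p
}

#' Chi-square test of one window against the genomic background
#'
#' 2x2 table [[window_c, window_t], [genome_c - window_c,
#' genome_t - window_t]] with 1 df and no continuity correction; the
#' complement construction keeps the margins independent. Any zero margin
#' makes the table degenerate: statistic 0, p = 1.
#'
#' @param window_c,window_t methylated (C) and unmethylated (T) read
#'   counts in the window; vectors allowed.
#' @param genome_c,genome_t genome-wide totals (scalars).
#' @return list(statistic, p_value), vectorized over windows.
#' @export
window_test <- function(window_c, window_t, genome_c, genome_t) {
  a <- as.numeric(window_c); b <- as.numeric(window_t)
  c2 <- genome_c - a; d <- genome_t - b
  if (any(c2 < 0) || any(d < 0))
    stop("genome totals must be >= window counts")
  n <- a + b + c2 + d
  r1 <- a + b; r2 <- c2 + d; k1 <- a + c2; k2 <- b + d
  degen <- r1 == 0 | r2 == 0 | k1 == 0 | k2 == 0
  stat <- numeric(length(a))
  ok <- !degen
  stat[ok] <- n[ok] * (a[ok] * d[ok] - b[ok] * c2[ok])^2 /
    (r1[ok] * r2[ok] * k1[ok] * k2[ok])
  p <- rep(1, length(a))
  p[ok] <- stats::pchisq(stat[ok], df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p)
}

#' Call NDRs or nucleosome-occupied regions by a windowed scan
#'
#' Pooled (merged-cell) C and T read counts at every covered GCH site are
#' summed in sliding windows tiled from position 0 of each chromosome
#' (the final partial window is tested as-is). Each window is tested
#' against the genome-wide background with \code{window_test}; windows
#' passing the p cutoff in the requested direction (rate strictly above
#' background for "enriched", strictly below for "depleted") are merged
#' when they overlap, and merged regions are retained by minimum width
#' and minimum covered GCH sites. Regions are classified promoter
#' (contains a TSS), proximal (< 2 kb from a TSS) or distal.
#'
#' @param gch_counts data.table chrom, pos (0-based), c_count, t_count:
#'   pooled reads per covered GCH site.
#' @param chrom_lengths named integer vector.
#' @param params from \code{window_params} (or same shape).
#' @param tss_table optional TSS annotation for classification.
#' @return data.table of regions: chrom, start, end, width, n_gch_sites,
#'   c_count, t_count, level, min_p, class.
#' @export
scan_and_call <- function(gch_counts, chrom_lengths, params = window_params("ndr"),
                          tss_table = NULL) {
  params <- validate_window_params(params)
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), width = integer(),
                                  n_gch_sites = integer(), c_count = numeric(),
                                  t_count = numeric(), level = numeric(),
                                  min_p = numeric(), class = character())
  gch_counts <- data.table::as.data.table(gch_counts)
  if (nrow(gch_counts) == 0L) return(empty)
  gc_tot <- sum(gch_counts$c_count)
  gt_tot <- sum(gch_counts$t_count)
  bg_rate <- gc_tot / (gc_tot + gt_tot)
  kept <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    sites <- gch_counts[chrom == chr][order(pos)]
    if (nrow(sites) == 0L) return(NULL)
    starts <- seq.int(0L, max(0L, len - 1L), by = params$step_bp)
    ends <- pmin(starts + params$window_bp, len)
    # prefix sums over sorted site positions
    cum_c <- c(0, cumsum(sites$c_count))
    cum_t <- c(0, cumsum(sites$t_count))
    lo <- findInterval(starts - 0.5, sites$pos) + 1L   # first site >= start
    hi <- findInterval(ends - 0.5, sites$pos)          # last site < end
    wc <- cum_c[hi + 1L] - cum_c[lo]
    wt <- cum_t[hi + 1L] - cum_t[lo]
    tst <- window_test(wc, wt, gc_tot, gt_tot)
    rate <- ifelse(wc + wt > 0, wc / (wc + wt), NA_real_)
    dir_ok <- if (params$direction == "enriched") !is.na(rate) & rate > bg_rate
              else !is.na(rate) & rate < bg_rate
    keep <- tst$p_value <= params$p_cutoff & dir_ok
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = chr, start = starts[keep],
                           end = ends[keep], p = tst$p_value[keep])
  })
  win <- data.table::rbindlist(kept)
  if (is.null(win) || nrow(win) == 0L) return(empty)
  merged <- merge_intervals(win[, .(chrom, start, end)])
  # per-region stats
  merged[, width := end - start]
  stats_dt <- lapply(seq_len(nrow(merged)), function(i) {
    s <- gch_counts[chrom == merged$chrom[i] & pos >= merged$start[i] &
                    pos < merged$end[i]]
    pmin_i <- min(win[chrom == merged$chrom[i] & start >= merged$start[i] &
                      end <= merged$end[i], p])
    data.table::data.table(n_gch_sites = nrow(s), c_count = sum(s$c_count),
                           t_count = sum(s$t_count), min_p = pmin_i)
  })
  merged <- cbind(merged, data.table::rbindlist(stats_dt))
  merged <- merged[width >= params$min_region_bp &
                   n_gch_sites >= params$min_gch_sites]
  if (nrow(merged) == 0L) return(empty)
  merged[, level := c_count / (c_count + t_count)]
  merged[, class := NA_character_]
  if (!is.null(tss_table)) {
    tssp <- data.table::data.table(chrom = tss_table$chrom,
                                   pos = tss_table$tss)
    contains <- vapply(seq_len(nrow(merged)), function(i)
      any(tssp$chrom == merged$chrom[i] & tssp$pos >= merged$start[i] &
          tssp$pos < merged$end[i]), logical(1))
    dist <- interval_nearest_distance(merged, tssp)
    merged[, class := ifelse(contains, "promoter",
                      ifelse(!is.na(dist) & dist < 2000L, "proximal",
                             "distal"))]
  }
  merged[, .(chrom, start, end, width, n_gch_sites, c_count, t_count,
             level, min_p, class)][]
}

#' Fraction of NDRs wider than a threshold
#' @param ndrs NDR table with a width column (or start/end).
#' @param min_width strictly-greater-than width threshold (default 300 bp).
#' @return proportion; NA on an empty set.
#' @export
wide_ndr_fraction <- function(ndrs, min_width = 300L) {
  if (nrow(ndrs) == 0L) return(NA_real_)
  w <- if ("width" %in% names(ndrs)) ndrs$width else ndrs$end - ndrs$start
  mean(w > min_width)
}

#' Differential NDRs between two cell groups
#'
#' For each region, pooled GCH C/T counts of the two groups form a 2x2
#' table tested by chi-square (no correction); Benjamini-Hochberg across
#' all tested regions. A region is differential when q < fdr and the
#' absolute level difference is >= min_delta. Regions uncovered (zero
#' reads) in either group are reported as untested.
#'
#' @param ndrs interval table of regions.
#' @param counts_a,counts_b per-group pooled site count tables
#'   (chrom, pos, c_count, t_count).
#' @param fdr BH threshold (default 0.05).
#' @param min_delta minimum absolute level difference (default 0.2).
#' @return data.table with level_a, level_b, delta, p, q, tested,
#'   differential, direction.
#' @export
differential_ndrs <- function(ndrs, counts_a, counts_b, fdr = 0.05,
                              min_delta = 0.2) {
  pool <- function(counts, i) {
    s <- counts[chrom == ndrs$chrom[i] & pos >= ndrs$start[i] &
                pos < ndrs$end[i]]
    c(sum(s$c_count), sum(s$t_count))
  }
  counts_a <- data.table::as.data.table(counts_a)
  counts_b <- data.table::as.data.table(counts_b)
  n <- nrow(ndrs)
  ca <- ta <- cb <- tb <- numeric(n)
  for (i in seq_len(n)) {
    ab <- pool(counts_a, i); bb <- pool(counts_b, i)
    ca[i] <- ab[1]; ta[i] <- ab[2]; cb[i] <- bb[1]; tb[i] <- bb[2]
  }
  tested <- (ca + ta) > 0 & (cb + tb) > 0
  level_a <- ifelse(ca + ta > 0, ca / (ca + ta), NA_real_)
  level_b <- ifelse(cb + tb > 0, cb / (cb + tb), NA_real_)
  p <- rep(NA_real_, n)
  for (i in which(tested)) {
    tab <- matrix(c(ca[i], ta[i], cb[i], tb[i]), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) { p[i] <- 1; next }
    p[i] <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  q <- rep(NA_real_, n)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  delta <- level_a - level_b
  differential <- tested & !is.na(q) & q < fdr & abs(delta) >= min_delta
  out <- data.table::as.data.table(ndrs)[, .(chrom, start, end)]
  out[, `:=`(level_a = level_a, level_b = level_b, delta = delta, p = p,
             q = q, tested = tested, differential = differential,
             direction = ifelse(differential,
                                ifelse(delta > 0, "A", "B"), NA_character_))]
  out[]
}
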