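#' Spike-in-based ploidy estimation
#'
#' Each cell receives the same quantity of lambda phage DNA, so the ratio
#' of genomic to lambda reads scales with DNA content. Ratios are
#' normalized so that the mean of the reference cells (cells of known
#' diploidy, e.g. MII oocytes) equals 2N. Class boundaries: 1N in
#' [0.75, 1.25], 1N-2N in (1.25, 1.75), 2N in [1.75, 2.25], 2N-4N in
#' (2.25, 3.5), 4N in [3.5, 4.5]; anything else (or zero lambda reads)
#' is an outlier.
#'
#' @param cells data.table: cell, genomic_reads, lambda_reads.
#' @param reference_cells character vector of cell ids assumed diploid.
#' @return data.table cell, genomic_reads, lambda_reads, ratio, ploidy,
#'   class.
#' @export
estimate_ploidy <- function(cells, reference_cells) {
  dt <- data.table::as.data.table(cells)
  if (!any(dt$cell %in% reference_cells))
    stop("no reference cell present")
  dt[, ratio := ifelse(lambda_reads > 0,
                       genomic_reads / lambda_reads, NA_real_)]
  ref <- dt[cell %in% reference_cells & !is.na(ratio), ratio]
  if (length(ref) == 0L) stop("all reference cells have zero lambda reads")
  dt[, ploidy := 2 * ratio / mean(ref)]
  dt[, class := ifelse(is.na(ploidy), "outlier",
               ifelse(ploidy >= 0.75 & ploidy <= 1.25, "1N",
               ifelse(ploidy > 1.25 & ploidy < 1.75, "1N-2N",
               ifelse(ploidy >= 1.75 & ploidy <= 2.25, "2N",
               ifelse(ploidy > 2.25 & ploidy < 3.5, "2N-4N",
               ifelse(ploidy >= 3.5 & ploidy <= 4.5, "4N", "outlier"))))))]
  dt[]
}

#' Bin the genome and normalize read counts for CNV analysis
#'
#' Consecutive fixed-size bins tile each chromosome (final partial bin
#' kept). Raw per-cell counts are optionally GC-corrected by a
#' lowess-style local regression of count on bin GC fraction
#' (median-anchored), then each bin is divided by its across-cell median;
#' log2 ratios are reported and bins with zero median are masked.
#'
#' @param read_pos named list per cell of data.tables (chrom, pos), or
#'   NULL if \code{counts} given.
#' @param chrom_lengths named integer vector.
#' @param bin_size default 1e6.
#' @param counts optional precomputed bins x cells matrix.
#' @param bin_gc optional per-bin GC fraction for correction.
#' @return list(bins = interval table, raw = matrix, norm = linear-scale
#'   normalized matrix, log2 = log2 matrix; masked bins are NA).
#' @export
bin_and_normalize <- function(read_pos = NULL, chrom_lengths,
                              bin_size = 1e6, counts = NULL,
                              bin_gc = NULL) {
  bins <- data.table::rbindlist(lapply(names(chrom_lengths), function(chr) {
    starts <- seq.int(0L, max(0L, chrom_lengths[[chr]] - 1L), by = bin_size)
    data.table::data.table(chrom = chr, start = as.integer(starts),
                           end = as.integer(pmin(starts + bin_size,
                                                 chrom_lengths[[chr]])))
  }))
  if (is.null(counts)) {
    stopifnot(!is.null(read_pos))
    if (length(read_pos) < 3L)
      stop("median normalization requires >= 3 cells")
    counts <- vapply(read_pos, function(rp) {
      rp <- data.table::as.data.table(rp)
      rp[, bin := pos %/% bin_size]
      key <- paste(bins$chrom, bins$start %/% bin_size)
      agg <- rp[, .N, by = .(chrom, bin)]
      n <- agg$N[match(key, paste(agg$chrom, agg$bin))]
      ifelse(is.na(n), 0, n)
    }, numeric(nrow(bins)))
    colnames(counts) <- names(read_pos)
  }
  if (ncol(counts) < 3L) stop("median normalization requires >= 3 cells")
  corrected <- counts
  if (!is.null(bin_gc)) {
    for (j in seq_len(ncol(counts))) {
      ok <- counts[, j] > 0 & !is.na(bin_gc)
      if (sum(ok) >= 10) {
        fit <- stats::lowess(bin_gc[ok], counts[ok, j], f = 0.5)
        pred <- stats::approx(fit$x, fit$y, xout = bin_gc, rule = 2)$y
        pred[pred <= 0] <- NA
        corrected[, j] <- counts[, j] / pred *
          stats::median(counts[ok, j])
      }
    }
  }
  med <- apply(corrected, 1, stats::median)
  norm <- sweep(corrected, 1, med, "/")
  norm[med == 0 | is.na(med), ] <- NA
  l2 <- log2(norm)
  l2[!is.finite(l2)] <- NA
  list(bins = bins, raw = counts, norm = norm, log2 = l2)
}

#' Per-cell coefficient of variation over normalized bins
#'
#' sd/mean of each cell's normalized bin values on the linear scale,
#' skipping masked bins.
#'
#' @param norm linear-scale normalized matrix from
#'   \code{bin_and_normalize}.
#' @return named numeric vector, one CV per cell.
#' @export
per_cell_cv <- function(norm) {
  apply(norm, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x)
  })
}

#' Flag whole-chromosome copy-number gains and losses
#'
#' A chromosome is flagged in a cell when at least
#' \code{min_fraction_of_chrom} of its unmasked bins exceed
#' \code{min_abs_log2} with a consistent sign. Chromosomes with fewer
#' than 3 unmasked bins are untested.
#'
#' @param binres result of \code{bin_and_normalize}.
#' @param min_abs_log2 default 0.4.
#' @param min_fraction_of_chrom default 0.8.
#' @return data.table cell, chrom, n_bins, call
#'   ("gain"/"loss"/"neutral"/"untested").
#' @export
flag_chromosome_cnv <- function(binres, min_abs_log2 = 0.4,
                                min_fraction_of_chrom = 0.8) {
  bins <- binres$bins
  res <- list()
  for (j in seq_len(ncol(binres$log2))) {
    cellname <- colnames(binres$log2)[j]
    for (chr in unique(bins$chrom)) {
      x <- binres$log2[bins$chrom == chr, j]
      x <- x[!is.na(x)]
      call <- if (length(x) < 3L) "untested"
        else if (mean(x > min_abs_log2) >= min_fraction_of_chrom) "gain"
        else if (mean(x < -min_abs_log2) >= min_fraction_of_chrom) "loss"
        else "neutral"
      res[[length(res) + 1L]] <- data.table::data.table(
        cell = cellname, chrom = chr, n_bins = length(x), call = call)
    }
  }
  data.table::rbindlist(res)
}

#' Compare normalized coverage in leading vs lagging replication domains
#'
#' Tiles (typically 100 kb) carry externally supplied domain labels; for
#' one cell, mean normalized counts are computed per label class and a
#' two-tailed Welch t-test compares them. An S-phase cell shows higher
#' coverage in leading domains; a G1 or G2/M cell shows no difference.
#'
#' @param tile_values numeric vector of the cell's normalized tile
#'   counts.
#' @param labels character vector ("leading"/"lagging"/other) aligned
#'   with tiles.
#' @return list(mean_leading, mean_lagging, p_value); NAs when a class
#'   is missing.
#' @export
replication_lead_lag <- function(tile_values, labels) {
  lead <- tile_values[labels == "leading" & !is.na(tile_values)]
  lag <- tile_values[labels == "lagging" & !is.na(tile_values)]
  if (length(lead) < 2L || length(lag) < 2L)
    return(list(mean_leading = NA_real_, mean_lagging = NA_real_,
                p_value = NA_real_))
  tt <- stats::t.test(lead, lag)
  list(mean_leading = mean(lead), mean_lagging = mean(lag),
       p_value = tt$p.value)
}

#' Infer sex from the X-to-autosome read ratio
#'
#' Reads on the X chromosome are compared with reads on a reference
#' autosome, normalizing for chromosome length. An XX cell is expected
#' at ratio (lenX/lenA), an XY cell at half that; the midpoint (0.75 x
#' lenX/lenA) is the decision threshold.
#'
#' @param reads_x,reads_auto read counts.
#' @param len_x,len_auto chromosome lengths.
#' @return "female", "male" or NA when the autosome has no reads.
#' @export
infer_sex <- function(reads_x, reads_auto, len_x, len_auto) {
  if (reads_auto == 0) return(NA_character_)
  ratio <- reads_x / reads_auto
  threshold <- 0.75 * len_x / len_auto
  if (ratio > threshold) "female" else "male"
}
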