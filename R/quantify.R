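#' Depth policy used across the package
#'
#' Single-cell site levels require >= 1 read; bulk samples >= 3; analyses
#' comparing sites across individual cells >= 2.
#' @export
depth_policy <- function() list(single_cell_min = 1L, bulk_min = 3L,
                                cross_cell_min = 2L)

#' Per-site methylation levels under a depth filter
#'
#' level = meth / (meth + unmeth); sites below \code{min_depth} total reads
#' are removed (a depth-0 row can never divide by zero because it is
#' filtered first).
#'
#' @param channel_table WCG or GCH channel table (chrom, pos, strand,
#'   meth, unmeth).
#' @param min_depth minimum total reads at the site.
#' @return data.table chrom, pos, strand, level, depth.
#' @export
site_levels <- function(channel_table, min_depth = 1L) {
  dt <- data.table::as.data.table(channel_table)
  dt[, depth := meth + unmeth]
  dt <- dt[depth >= min_depth]
  dt[, level := meth / depth]
  dt[, .(chrom, pos, strand, level, depth, meth, unmeth)]
}

#' Global methylation / accessibility level of one cell
#'
#' Unweighted mean of qualifying site levels. Returns NA (undefined, not
#' zero) when no site qualifies.
#'
#' @param channel_table channel table for the cell.
#' @param min_depth depth threshold (default single-cell: 1).
#' @return numeric scalar or NA.
#' @export
global_level <- function(channel_table, min_depth = 1L) {
  sl <- site_levels(channel_table, min_depth)
  if (nrow(sl) == 0L) return(NA_real_)
  mean(sl$level)
}

#' Mean level over a region with a minimum-site rule
#'
#' @param region one-row interval (chrom, start, end).
#' @param sites site-level table from \code{site_levels}.
#' @param min_sites minimum covered sites for the region to be defined.
#' @return numeric scalar or NA when fewer than \code{min_sites} sites.
#' @export
region_level <- function(region, sites, min_sites = 5L) {
  s <- sites[chrom == region$chrom[1] & pos >= region$start[1] &
             pos < region$end[1]]
  if (nrow(s) < min_sites) return(NA_real_)
  mean(s$level)
}

#' Mean level for many regions at once
#' @param regions interval table.
#' @inheritParams region_level
#' @return numeric vector aligned with \code{regions} rows (NA = undefined).
#' @export
region_levels <- function(regions, sites, min_sites = 5L) {
  vapply(seq_len(nrow(regions)), function(i)
    region_level(regions[i], sites, min_sites), numeric(1))
}

#' Per-cell levels over consecutive genomic tiles
#'
#' The genome is partitioned into consecutive fixed-size tiles (the final
#' partial tile is kept); each cell contributes a tile level only when it
#' covers at least \code{min_sites} sites there.
#'
#' @param cell_sites named list of site-level tables, one per cell.
#' @param chrom_lengths named integer vector.
#' @param tile_size tile width in bp (default 5000).
#' @param min_sites minimum covered sites per tile per cell (default 5).
#' @return list(tiles = interval table, levels = tiles x cells matrix).
#' @export
tile_levels <- function(cell_sites, chrom_lengths, tile_size = 5000L,
                        min_sites = 5L) {
  tiles <- data.table::rbindlist(lapply(names(chrom_lengths), function(chr) {
    starts <- seq.int(0L, chrom_lengths[[chr]] - 1L, by = tile_size)
    data.table::data.table(chrom = chr, start = starts,
                           end = pmin(starts + tile_size,
                                      chrom_lengths[[chr]]))
  }))
  lv <- vapply(cell_sites, function(s) {
    s <- data.table::as.data.table(s)
    s[, tile := pos %/% tile_size]
    agg <- s[, .(level = mean(level), n = .N), by = .(chrom, tile)]
    key <- paste(tiles$chrom, tiles$start %/% tile_size)
    m <- agg[match(key, paste(agg$chrom, agg$tile))]
    ifelse(!is.na(m$n) & m$n >= min_sites, m$level, NA_real_)
  }, numeric(nrow(tiles)))
  colnames(lv) <- names(cell_sites)
  list(tiles = tiles, levels = lv)
}

#' Strand-aware meta-profile around TSSs or along scaled gene bodies
#'
#' In "tss" mode each gene contributes sites within +/- \code{flank} bp of
#' its TSS, binned by signed distance (minus-strand genes flipped). In
#' "body" mode each site's relative position within the gene body is
#' scaled to [0, 1) and binned; genes shorter than 2 bins are excluded.
#' Each bin reports the unweighted mean of site levels pooled across
#' genes.
#'
#' @param tss_table gene annotation (gene, chrom, tss, strand; plus
#'   start/end for body mode).
#' @param sites site-level table.
#' @param n_bins number of profile bins.
#' @param flank half-window around the TSS in bp.
#' @param mode "tss" or "body".
#' @return data.table bin, mid (bp offset or relative position), level, n.
#' @export
meta_profile <- function(tss_table, sites, n_bins = 40L, flank = 2000L,
                         mode = c("tss", "body")) {
  mode <- match.arg(mode)
  sites <- data.table::as.data.table(sites)
  acc <- vector("list", nrow(tss_table))
  for (i in seq_len(nrow(tss_table))) {
    g <- tss_table[i]
    if (mode == "tss") {
      s <- sites[chrom == g$chrom & pos >= g$tss - flank &
                 pos < g$tss + flank]
      if (nrow(s) == 0L) next
      rel <- s$pos - g$tss
      if (g$strand == "-") rel <- -rel
      bin <- pmin(floor((rel + flank) / (2 * flank) * n_bins), n_bins - 1L)
    } else {
      if ((g$end - g$start) < 2L * n_bins) next
      s <- sites[chrom == g$chrom & pos >= g$start & pos < g$end]
      if (nrow(s) == 0L) next
      rel <- (s$pos - g$start) / (g$end - g$start)
      if (g$strand == "-") rel <- 1 - rel - 1e-9
      bin <- pmin(floor(rel * n_bins), n_bins - 1L)
    }
    acc[[i]] <- data.table::data.table(bin = bin, level = s$level)
  }
  dt <- data.table::rbindlist(acc)
  out <- data.table::data.table(bin = seq_len(n_bins) - 1L)
  if (nrow(dt)) {
    agg <- dt[, .(level = mean(level), n = .N), by = bin]
    out <- agg[out, on = "bin"]
    out[is.na(n), n := 0L]
  } else {
    out[, `:=`(level = NA_real_, n = 0L)]
  }
  width <- if (mode == "tss") 2 * flank else 1
  off <- if (mode == "tss") -flank else 0
  out[, mid := off + (bin + 0.5) / n_bins * width]
  data.table::setorder(out, bin)
  out[, .(bin, mid, level, n)]
}

#' Fraction of a region set covered by a cell
#'
#' A region counts as covered when the cell detects at least
#' \code{min_sites} sites inside it (any depth filtering is done upstream
#' by \code{site_levels}).
#'
#' @param sites the cell's site-level table.
#' @param regions interval table.
#' @param min_sites minimum sites (default 5).
#' @return proportion in [0,1]; NA for an empty region set.
#' @export
region_coverage_fraction <- function(sites, regions, min_sites = 5L) {
  if (nrow(regions) == 0L) return(NA_real_)
  n_cov <- vapply(seq_len(nrow(regions)), function(i) {
    sum(sites$chrom == regions$chrom[i] & sites$pos >= regions$start[i] &
        sites$pos < regions$end[i])
  }, numeric(1))
  mean(n_cov >= min_sites)
}
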