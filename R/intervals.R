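#' Genomic interval tables
#'
#' Intervals are plain \code{data.table}s with columns \code{chrom},
#' \code{start}, \code{end} and optionally \code{strand}; coordinates are
#' 0-based half-open throughout the package. On-disk BED uses the same
#' convention; 1-based formats (cytosine reports, SNP tables) are converted
#' at the I/O boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; \code{start < end}.
#' @param strand optional character vector in \code{c("+", "-")}.
#' @param ... further equal-length columns carried along.
#' @return a \code{data.table} with one row per interval.
#' @export
intervals <- function(chrom, start, end, strand = NULL, ...) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("empty or inverted interval: start >= end")
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = start, end = end)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    dt[, strand := strand]
  }
  extra <- list(...)
  for (nm in names(extra)) dt[[nm]] <- extra[[nm]]
  dt[]
}

#' Merge overlapping intervals into their union spans
#'
#' Overlap is strict (shared bases); book-ended intervals are kept apart.
#' Idempotent and independent of input order.
#'
#' @param x interval table.
#' @return merged interval table sorted by (chrom, start).
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(intervals(character(), integer(), integer())[0])
  x <- data.table::as.data.table(x)[order(chrom, start, end)]
  out <- x[, {
    s <- start; e <- end
    grp <- cumsum(c(1L, as.integer(s[-1] >= cummax(e[-length(e)]))))
    .(start = tapply(s, grp, min), end = tapply(e, grp, max))
  }, by = chrom]
  out[, start := as.integer(start)][, end := as.integer(end)]
  out[]
}

#' Distance from each interval to the nearest point among positions
#'
#' Positions are 0-based single bases. Distance is 0 when a position lies
#' inside the half-open interval.
#'
#' @param x interval table.
#' @param pos_table data.table with columns chrom, pos.
#' @return integer vector of distances (NA when the chromosome has no
#'   position).
#' @export
interval_nearest_distance <- function(x, pos_table) {
  pos_table <- data.table::as.data.table(pos_table)
  vapply(seq_len(nrow(x)), function(i) {
    p <- pos_table[chrom == x$chrom[i], pos]
    if (length(p) == 0L) return(NA_integer_)
    d <- pmax(x$start[i] - p, p - (x$end[i] - 1L), 0L)
    as.integer(min(d))
  }, integer(1))
}

#' Which intervals contain a given position
#' @param x interval table.
#' @param chrom,pos a single 0-based position.
#' @return integer row indices of x containing the position.
#' @export
intervals_containing <- function(x, chrom, pos) {
  which(x$chrom == chrom & x$start <= pos & pos < x$end)
}
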