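#' Promoter assessment region
#'
#' The region used to score a promoter's accessibility in each cell: the
#' merged-cell NDR containing the TSS when one exists, otherwise the
#' strand-aware fallback window of 200 bp upstream to 100 bp downstream
#' of the TSS. If (unexpectedly, post-merge) several NDRs contain the
#' TSS, the widest is chosen with a warning.
#'
#' @param tss_row one-row TSS table (gene, chrom, tss, strand).
#' @param merged_ndrs NDR table from merged cells.
#' @return one-row interval data.table with a source column
#'   ("ndr"/"fallback").
#' @export
assessment_region <- function(tss_row, merged_ndrs = NULL) {
  if (!is.null(merged_ndrs) && nrow(merged_ndrs) > 0L) {
    hit <- intervals_containing(merged_ndrs, tss_row$chrom[1],
                                tss_row$tss[1])
    if (length(hit) > 1L) {
      warning("TSS inside multiple merged NDRs; choosing the widest")
      w <- merged_ndrs$end[hit] - merged_ndrs$start[hit]
      hit <- hit[which.max(w)]
    }
    if (length(hit) == 1L)
      return(data.table::data.table(chrom = merged_ndrs$chrom[hit],
                                    start = merged_ndrs$start[hit],
                                    end = merged_ndrs$end[hit],
                                    source = "ndr"))
  }
  tss <- tss_row$tss[1]
  if (tss_row$strand[1] == "+")
    data.table::data.table(chrom = tss_row$chrom[1], start = tss - 200L,
                           end = tss + 100L, source = "fallback")
  else
    data.table::data.table(chrom = tss_row$chrom[1], start = tss - 100L,
                           end = tss + 200L, source = "fallback")
}

#' Call a promoter open/closed/undefined in one cell
#'
#' Requires >= \code{min_sites} covered GCH sites in the assessment
#' region, else "not_covered". With enough sites the mean level calls
#' open (> 0.5), closed (< 0.3) or undefined (in [0.3, 0.5]; boundary
#' values are undefined because the thresholds are strict).
#'
#' @param region one-row interval.
#' @param sites the cell's GCH site-level table (cross-cell depth policy,
#'   >= 2x, applied upstream).
#' @param min_sites minimum covered GCH sites (default 5).
#' @return list(call, level, n_sites).
#' @export
call_cell_state <- function(region, sites, min_sites = 5L) {
  s <- sites[chrom == region$chrom[1] & pos >= region$start[1] &
             pos < region$end[1]]
  n <- nrow(s)
  if (n < min_sites) return(list(call = "not_covered", level = NA_real_,
                                 n_sites = n))
  lv <- mean(s$level)
  call <- if (lv > 0.5) "open" else if (lv < 0.3) "closed" else "undefined"
  list(call = call, level = lv, n_sites = n)
}

#' Population label of one promoter from its per-cell calls
#'
#' Considered only when covered (call != not_covered) in at least half of
#' all sequenced cells, else "unclassified". Among cells with a
#' definitive call, f = open / (open + closed): homogeneously_open when
#' f > 0.7, homogeneously_closed when f < 0.3, divergent for f in
#' [0.3, 0.7] (bounds inclusive). No definitive call at all ->
#' unclassified.
#'
#' @param calls character vector of per-cell calls for one promoter.
#' @param n_total_cells total sequenced cells.
#' @return label string.
#' @export
classify_population <- function(calls, n_total_cells) {
  covered <- sum(calls != "not_covered")
  if (covered < n_total_cells / 2) return("unclassified")
  n_open <- sum(calls == "open")
  n_closed <- sum(calls == "closed")
  if (n_open + n_closed == 0L) return("unclassified")
  f <- n_open / (n_open + n_closed)
  if (f > 0.7) "homogeneously_open"
  else if (f < 0.3) "homogeneously_closed"
  else "divergent"
}

#' Promoter-state matrix across cells
#'
#' Runs \code{assessment_region}, \code{call_cell_state} and
#' \code{classify_population} over all promoters and cells.
#'
#' @param tss_table TSS annotation.
#' @param cell_sites named list of per-cell GCH site-level tables
#'   (filter to >= 2x depth upstream).
#' @param merged_ndrs merged-cell NDR table (optional).
#' @param min_sites per-cell covered-site minimum (default 5).
#' @return list(calls = promoters x cells character matrix,
#'   levels = numeric matrix, labels = per-promoter labels,
#'   regions = assessment regions).
#' @export
promoter_state_matrix <- function(tss_table, cell_sites, merged_ndrs = NULL,
                                  min_sites = 5L) {
  np <- nrow(tss_table); nc <- length(cell_sites)
  calls <- matrix(NA_character_, np, nc,
                  dimnames = list(tss_table$gene, names(cell_sites)))
  levels <- matrix(NA_real_, np, nc,
                   dimnames = dimnames(calls))
  regions <- vector("list", np)
  for (i in seq_len(np)) {
    reg <- assessment_region(tss_table[i], merged_ndrs)
    regions[[i]] <- reg
    for (j in seq_len(nc)) {
      st <- call_cell_state(reg, cell_sites[[j]], min_sites)
      calls[i, j] <- st$call
      levels[i, j] <- st$level
    }
  }
  labels <- apply(calls, 1, classify_population, n_total_cells = nc)
  list(calls = calls, levels = levels, labels = labels,
       regions = data.table::rbindlist(regions))
}

#' Expected call fractions under partial per-cell detection
#'
#' Analytic form of the sensitivity argument for sparse single-cell
#' chromatin assays: with per-cell detection probability d and a locus
#' truly open in a fraction f of cells, a method that can discriminate
#' closed from undetected calls open in d*f of cells and closed in
#' d*(1-f), leaving 1-d undetermined; a method that cannot discriminate
#' leaves 1-d*f undetermined. The open:closed ratio estimator d*f/(d*(1-f))
#' recovers f/(1-f) exactly.
#'
#' @param detection per-cell detection probability.
#' @param f_open fraction of cells truly open.
#' @return data.table with expected fractions for both method types.
#' @export
sensitivity_expectation <- function(detection = 0.2, f_open = 0.5) {
  data.table::data.table(
    method = c("discriminating", "non_discriminating"),
    open = detection * f_open,
    closed = c(detection * (1 - f_open), 0),
    undetermined = c(1 - detection, 1 - detection * f_open),
    open_closed_ratio = c(f_open / (1 - f_open), NA_real_))
}

#' Simulate the partial-detection sensitivity experiment
#'
#' Each cell is truly open with probability f_open and detected with
#' probability \code{detection}; a discriminating method calls detected
#' cells by their true state, a non-discriminating one can only call
#' open.
#'
#' @inheritParams sensitivity_expectation
#' @param n_cells number of simulated cells.
#' @return data.table of observed fractions, same shape as
#'   \code{sensitivity_expectation}.
#' @export
sensitivity_simulation <- function(n_cells = 1e5, detection = 0.2,
                                   f_open = 0.5) {
  open_true <- stats::runif(n_cells) < f_open
  detected <- stats::runif(n_cells) < detection
  open_call <- mean(detected & open_true)
  closed_call <- mean(detected & !open_true)
  data.table::data.table(
    method = c("discriminating", "non_discriminating"),
    open = open_call,
    closed = c(closed_call, 0),
    undetermined = c(1 - open_call - closed_call, 1 - open_call),
    open_closed_ratio = c(open_call / closed_call, NA_real_))
}
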