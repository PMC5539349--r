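#' Stage-transition de novo / demethylation calling at WCG sites
#'
#' Input is a long per-cell table of WCG calls: site id columns (chrom,
#' pos, strand), cell, stage, meth, unmeth. A site enters a stage only
#' when covered (>= 1 read) in at least \code{min_cells} cells of that
#' stage; its stage mean is the unweighted mean of per-cell levels. The
#' per-site p-value compares stage-pooled (meth, unmeth) counts between
#' the two stages — Fisher's exact test by default (exact at the low
#' counts typical of single cells), chi-square optionally — with
#' Benjamini-Hochberg correction across all sites tested for the
#' transition. A de novo site has from-stage mean < 0.25, an increase of
#' >= 0.3 and q < fdr; a demethylated site has from-stage mean > 0.75, a
#' decrease of >= 0.3 and q < fdr.
#'
#' @param calls long WCG call table (chrom, pos, strand, cell, stage,
#'   meth, unmeth).
#' @param from_stage,to_stage stage labels.
#' @param mode "de_novo" or "demethylated".
#' @param fdr BH threshold (default 0.05).
#' @param min_cells per-stage covered-cell minimum (default 3).
#' @param test "fisher" or "chisq".
#' @return data.table per tested site: stage means, pooled counts, delta,
#'   p, q, called.
#' @export
call_transition_sites <- function(calls, from_stage, to_stage,
                                  mode = c("de_novo", "demethylated"),
                                  fdr = 0.05, min_cells = 3L,
                                  test = c("fisher", "chisq")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  calls <- data.table::as.data.table(calls)
  calls <- calls[stage %in% c(from_stage, to_stage) & meth + unmeth >= 1L]
  if (nrow(calls) == 0L) {
    warning("no qualifying sites for transition ", from_stage, " -> ",
            to_stage)
    return(data.table::data.table())
  }
  per_stage <- calls[, .(
    n_cells = data.table::uniqueN(cell),
    mean_level = mean(meth / (meth + unmeth)),
    meth = sum(meth), unmeth = sum(unmeth)),
    by = .(chrom, pos, strand, stage)]
  wide <- data.table::dcast(per_stage, chrom + pos + strand ~ stage,
                            value.var = c("n_cells", "mean_level", "meth",
                                          "unmeth"))
  cn <- function(pfx, st) paste0(pfx, "_", st)
  need <- c(cn("n_cells", from_stage), cn("n_cells", to_stage))
  if (!all(need %in% names(wide))) {
    warning("a stage has no qualifying sites")
    return(data.table::data.table())
  }
  wide <- wide[wide[[need[1]]] >= min_cells & wide[[need[2]]] >= min_cells]
  if (nrow(wide) == 0L) return(data.table::data.table())
  out <- data.table::data.table(
    chrom = wide$chrom, pos = wide$pos, strand = wide$strand,
    mean_from = wide[[cn("mean_level", from_stage)]],
    mean_to = wide[[cn("mean_level", to_stage)]],
    meth_from = wide[[cn("meth", from_stage)]],
    unmeth_from = wide[[cn("unmeth", from_stage)]],
    meth_to = wide[[cn("meth", to_stage)]],
    unmeth_to = wide[[cn("unmeth", to_stage)]])
  out[, delta := mean_to - mean_from]
  out[, p := vapply(seq_len(.N), function(i) {
    tab <- matrix(c(meth_from[i], unmeth_from[i], meth_to[i], unmeth_to[i]),
                  nrow = 2, byrow = TRUE)
    if (test == "fisher") stats::fisher.test(tab)$p.value
    else {
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }, numeric(1))]
  out[, q := stats::p.adjust(p, method = "BH")]
  if (mode == "de_novo")
    out[, called := mean_from < 0.25 & delta >= 0.3 & q < fdr]
  else
    out[, called := mean_from > 0.75 & -delta >= 0.3 & q < fdr]
  out[]
}

#' De novo methylated CpG islands across consecutive stages
#'
#' A CGI contributes a per-cell level only when the cell detects at least
#' \code{min_sites_per_cell} WCG sites inside it; the CGI is tested for a
#' transition only when both stages have at least \code{min_cells} such
#' cells. Called de novo when the earlier stage mean is < 0.25 and the
#' next stage gains >= 0.3.
#'
#' @param cgis CGI interval table (chrom, start, end and optionally name).
#' @param calls long WCG call table as in \code{call_transition_sites}.
#' @param stage_order character vector giving stage succession.
#' @param min_sites_per_cell default 3.
#' @param min_cells default 3.
#' @return data.table: cgi index, transition, stage means, called.
#' @export
call_de_novo_cgis <- function(cgis, calls, stage_order,
                              min_sites_per_cell = 3L, min_cells = 3L) {
  calls <- data.table::as.data.table(calls)[meth + unmeth >= 1L]
  res <- list()
  for (i in seq_len(nrow(cgis))) {
    s <- calls[chrom == cgis$chrom[i] & pos >= cgis$start[i] &
               pos < cgis$end[i]]
    if (nrow(s) == 0L) next
    per_cell <- s[, .(n_sites = .N, level = mean(meth / (meth + unmeth))),
                  by = .(stage, cell)]
    per_cell <- per_cell[n_sites >= min_sites_per_cell]
    st <- per_cell[, .(n_cells = .N, mean_level = mean(level)), by = stage]
    for (k in seq_len(length(stage_order) - 1L)) {
      a <- st[stage == stage_order[k]]
      b <- st[stage == stage_order[k + 1L]]
      if (nrow(a) == 0L || nrow(b) == 0L) next
      if (a$n_cells < min_cells || b$n_cells < min_cells) next
      res[[length(res) + 1L]] <- data.table::data.table(
        cgi = i, chrom = cgis$chrom[i], start = cgis$start[i],
        end = cgis$end[i],
        transition = paste(stage_order[k], stage_order[k + 1L], sep = "->"),
        mean_from = a$mean_level, mean_to = b$mean_level,
        called = a$mean_level < 0.25 &
                 (b$mean_level - a$mean_level) >= 0.3)
    }
  }
  if (length(res) == 0L) return(data.table::data.table())
  data.table::rbindlist(res)
}

#' Coefficient of variation of per-cell levels for each feature
#'
#' CV = sd/mean over cells within a stage; undefined (NA) when the mean
#' is 0 or fewer than 2 cells have a defined level.
#'
#' @param level_matrix features x cells numeric matrix (NA = undefined).
#' @return numeric vector of CVs per feature.
#' @export
methylation_cv <- function(level_matrix) {
  apply(level_matrix, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    m <- mean(x)
    if (m == 0) return(NA_real_)
    stats::sd(x) / m
  })
}

#' Pairwise correlations among methylation, accessibility and expression
#'
#' Vectors are aligned on shared feature names; each pair drops its own
#' missing values. Spearman by default (robust for bounded, zero-inflated
#' levels); Pearson optionally.
#'
#' @param meth,access,expression named numeric vectors on genes.
#' @param method "spearman" or "pearson".
#' @return data.table pair, r, n; r is NA when fewer than 3 shared genes.
#' @export
correlate_omics <- function(meth, access, expression,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pairs <- list(meth_access = list(meth, access),
                meth_expression = list(meth, expression),
                access_expression = list(access, expression))
  res <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]][[1]]; b <- pairs[[nm]][[2]]
    genes <- intersect(names(a), names(b))
    x <- a[genes]; y <- b[genes]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    r <- if (n < 3L) NA_real_ else
      suppressWarnings(stats::cor(x[ok], y[ok], method = method))
    data.table::data.table(pair = nm, r = r, n = n)
  })
  data.table::rbindlist(res)
}
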