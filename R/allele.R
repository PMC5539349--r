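#' Filter heterozygous SNPs usable under bisulfite conversion
#'
#' Bisulfite chemistry collapses C to T on plus-strand reads and (in
#' reference space) G to A on minus-strand reads. A C/T allele pair is
#' therefore uninformative on plus-strand reads and a G/A pair on
#' minus-strand reads; such SNPs are restricted to the other strand. A
#' SNP unusable on both strands would be dropped (cannot occur for a
#' biallelic pair, but the rule is applied for safety).
#'
#' @param snps SNP table (chrom, pos, maternal_allele, paternal_allele).
#' @return same table with logical columns usable_plus, usable_minus;
#'   rows unusable on both strands removed.
#' @export
filter_informative_snps <- function(snps) {
  snps <- data.table::as.data.table(snps)
  if (any(snps$maternal_allele == snps$paternal_allele))
    stop("homozygous SNP rows at line(s) ",
         paste(utils::head(which(
           snps$maternal_allele == snps$paternal_allele), 5),
           collapse = ", "))
  pair <- paste(pmin(snps$maternal_allele, snps$paternal_allele),
                pmax(snps$maternal_allele, snps$paternal_allele))
  snps[, usable_plus := pair != "C T"]
  snps[, usable_minus := pair != "A G"]
  snps[usable_plus | usable_minus][]
}

# does observed base b (reference space, read on `strand`) match allele a,
# allowing for bisulfite conversion on the read's strand?
.allele_match <- function(b, a, strand) {
  b == a | (strand == "+" & a == "C" & b == "T") |
    (strand == "-" & a == "G" & b == "A")
}

#' Assign reads to parental alleles by SNP majority vote
#'
#' Each read record carries observed bases at the SNP positions it
#' overlaps. Only SNPs usable on the read's strand are counted. A base
#' matches an allele directly or via the strand's bisulfite collapse
#' (plus: C read as T; minus: G read as A). The read is assigned by
#' majority vote over informative SNPs; equal non-zero support is a
#' conflict and no informative SNP leaves the read unassigned.
#'
#' @param read_snp_obs long table: read_id, cell, strand, chrom, pos,
#'   base (observed, reference space).
#' @param snps output of \code{filter_informative_snps}.
#' @param read_ids optional full vector of read ids (so reads without SNP
#'   observations appear as unassigned).
#' @return data.table read_id, cell, n_informative, n_maternal,
#'   n_paternal, assignment.
#' @export
assign_reads <- function(read_snp_obs, snps, read_ids = NULL) {
  obs <- data.table::as.data.table(read_snp_obs)
  m <- snps[obs, on = c("chrom", "pos")]
  m <- m[!is.na(maternal_allele)]
  m <- m[(strand == "+" & usable_plus) | (strand == "-" & usable_minus)]
  m[, mat := .allele_match(base, maternal_allele, strand)]
  m[, pat := .allele_match(base, paternal_allele, strand)]
  m <- m[mat != pat]  # bases matching both or neither are uninformative
  agg <- m[, .(n_informative = .N, n_maternal = sum(mat),
               n_paternal = sum(pat)), by = .(read_id, cell)]
  agg[, assignment := ifelse(n_maternal > n_paternal, "maternal",
                      ifelse(n_paternal > n_maternal, "paternal",
                             "conflict"))]
  if (!is.null(read_ids)) {
    all_reads <- unique(data.table::as.data.table(read_ids))
    agg <- agg[all_reads, on = intersect(names(all_reads), c("read_id",
                                                             "cell"))]
    agg[is.na(assignment), `:=`(assignment = "unassigned",
                                n_informative = 0L, n_maternal = 0L,
                                n_paternal = 0L)]
  }
  agg[]
}

#' Per-allele methylation summaries by genomic element class
#'
#' Methylation observations from assigned reads are summed per site per
#' allele, site levels formed, and per-cell per-class per-allele mean
#' levels reported with the paternal - maternal difference.
#'
#' @param meth_obs long table: read_id, cell, chrom, pos, strand, channel
#'   ("WCG"/"GCH"), methylated (0/1 per read observation).
#' @param assignments from \code{assign_reads}.
#' @param element_of function(chrom, pos) -> class label vector (e.g.
#'   intragenic/intergenic/CGI), or a precomputed label column name in
#'   meth_obs.
#' @return data.table cell, channel, element, allele, level, n_sites,
#'   plus a wide difference table attribute-free via
#'   \code{allelic_differences}.
#' @export
allelic_summary <- function(meth_obs, assignments, element_of) {
  obs <- data.table::as.data.table(meth_obs)
  a <- assignments[, .(read_id, cell, assignment)]
  obs <- a[obs, on = c("read_id", "cell")]
  obs <- obs[assignment %in% c("maternal", "paternal")]
  if (is.function(element_of)) obs[, element := element_of(chrom, pos)]
  else data.table::setnames(obs, element_of, "element")
  per_site <- obs[, .(meth = sum(methylated), tot = .N),
                  by = .(cell, channel, element, assignment, chrom, pos,
                         strand)]
  per_site[, level := meth / tot]
  per_site[, .(level = mean(level), n_sites = .N),
           by = .(cell, channel, element, allele = assignment)]
}

#' Paternal minus maternal level differences per cell/channel/element
#' @param summary output of \code{allelic_summary}.
#' @return data.table cell, channel, element, maternal, paternal,
#'   difference.
#' @export
allelic_differences <- function(summary) {
  wide <- data.table::dcast(summary, cell + channel + element ~ allele,
                            value.var = "level")
  for (col in c("maternal", "paternal"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  wide[, difference := paternal - maternal]
  wide[]
}

#' Per-allele WCG levels over candidate imprinting-control regions
#'
#' @param regions interval table of regions to check.
#' @param meth_obs,assignments as in \code{allelic_summary}.
#' @return data.table region index, chrom, start, end, allele, level,
#'   n_sites; regions covered by no assigned read are absent (undefined).
#' @export
icr_region_check <- function(regions, meth_obs, assignments) {
  obs <- data.table::as.data.table(meth_obs)[channel == "WCG"]
  a <- assignments[, .(read_id, cell, assignment)]
  obs <- a[obs, on = c("read_id", "cell")]
  obs <- obs[assignment %in% c("maternal", "paternal")]
  res <- lapply(seq_len(nrow(regions)), function(i) {
    s <- obs[chrom == regions$chrom[i] & pos >= regions$start[i] &
             pos < regions$end[i]]
    if (nrow(s) == 0L) return(NULL)
    per_site <- s[, .(meth = sum(methylated), tot = .N),
                  by = .(assignment, chrom, pos, strand)]
    per_site[, level := meth / tot]
    agg <- per_site[, .(level = mean(level), n_sites = .N),
                    by = .(allele = assignment)]
    cbind(data.table::data.table(region = i, chrom = regions$chrom[i],
                                 start = regions$start[i],
                                 end = regions$end[i]), agg)
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) return(data.table::data.table())
  out
}
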