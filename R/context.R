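#' Trinucleotide context classification of cytosines
#'
#' Every cytosine on either strand is classified by the trinucleotide read
#' on its own strand: WCG (W = A/T) reports endogenous CpG methylation,
#' GCH (H = A/C/T) reports GpC methyltransferase accessibility, while GCG
#' (ambiguous between channels) and CCG (enzyme off-target) are excluded
#' from both. Anything else, including contexts containing N or truncated
#' at a chromosome end, is OTHER.
#'
#' @param trinuc character vector of 3-mers (middle base C on its strand).
#' @return character vector of context classes.
#' @export
classify_trinucleotide <- function(trinuc) {
  trinuc <- toupper(trinuc)
  out <- rep("OTHER", length(trinuc))
  mid_c <- substr(trinuc, 2, 2) == "C" & nchar(trinuc) == 3L
  up <- substr(trinuc, 1, 1)
  dn <- substr(trinuc, 3, 3)
  out[mid_c & trinuc == "GCG"] <- "GCG"
  out[mid_c & trinuc == "CCG"] <- "CCG"
  out[mid_c & up %in% c("A", "T") & dn == "G"] <- "WCG"
  out[mid_c & up == "G" & dn %in% c("A", "C", "T")] <- "GCH"
  out
}

revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  n <- nchar(comp)
  if (all(n == 3L)) {  # vectorized fast path for trinucleotides
    return(paste0(substr(comp, 3, 3), substr(comp, 2, 2),
                  substr(comp, 1, 1)))
  }
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify every cytosine in a genome
#'
#' Scans both strands of each chromosome. A plus-strand C at 0-based
#' position p has context seq[p-1..p+1]; a minus-strand C sits opposite a
#' plus-strand G and its context is the reverse complement of
#' seq[p-1..p+1]. Cytosines lacking a flanking base are OTHER.
#'
#' @param genome named character vector of chromosome sequences.
#' @return data.table chrom, pos (0-based), strand, trinucleotide,
#'   context_class; one row per cytosine on either strand.
#' @export
classify_cytosines <- function(genome) {
  res <- lapply(names(genome), function(chr) {
    s <- toupper(genome[[chr]])
    n <- nchar(s)
    bases <- strsplit(s, "")[[1]]
    cpos <- which(bases == "C") - 1L   # 0-based
    gpos <- which(bases == "G") - 1L
    tri_at <- function(p) {
      out <- rep(NA_character_, length(p))
      ok <- p >= 1L & p + 1L <= n - 1L    # both flanks inside the sequence
      if (any(ok)) out[ok] <- substring(s, p[ok], p[ok] + 2L)
      out
    }
    plus_tri <- tri_at(cpos)
    minus_tri_fwd <- tri_at(gpos)
    minus_tri <- ifelse(is.na(minus_tri_fwd), NA, revcomp(
      ifelse(is.na(minus_tri_fwd), "NNN", minus_tri_fwd)))
    mk <- function(pos, strand, tri) {
      cls <- ifelse(is.na(tri), "OTHER", classify_trinucleotide(tri))
      data.table::data.table(chrom = chr, pos = pos, strand = strand,
                             trinucleotide = ifelse(is.na(tri), "NNN", tri),
                             context_class = cls)
    }
    rbind(mk(cpos, "+", plus_tri), mk(gpos, "-", minus_tri))
  })
  out <- data.table::rbindlist(res)
  data.table::setkey(out, chrom, pos, strand)
  out[]
}

#' Route cytosine calls into WCG and GCH channel tables
#'
#' Calls are matched to the genome's context map by (chrom, pos, strand);
#' a call at a position with no cytosine on the stated strand is a
#' consistency error. GCG, CCG and OTHER rows are dropped from both
#' channels; read counts on surviving rows are untouched.
#'
#' @param calls cytosine-call table (chrom, pos, strand, meth, unmeth).
#' @param context_map output of \code{classify_cytosines}.
#' @return list(wcg = data.table, gch = data.table) with context columns
#'   from the map.
#' @export
annotate_calls <- function(calls, context_map) {
  calls <- data.table::as.data.table(calls)
  keep <- c("chrom", "pos", "strand", "meth", "unmeth")
  calls <- calls[, ..keep]
  m <- context_map[calls, on = c("chrom", "pos", "strand")]
  if (anyNA(m$context_class))
    stop("call at position with no cytosine on the stated strand: ",
         paste(utils::head(which(is.na(m$context_class)), 3), collapse = ", "))
  list(wcg = m[context_class == "WCG"][],
       gch = m[context_class == "GCH"][])
}
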