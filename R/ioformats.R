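#' @import data.table
#' @importFrom stats p.adjust chisq.test fisher.test lowess median pchisq
#'   rbinom rpois runif sd setNames t.test cor complete.cases approx
#' @importFrom utils read.table write.table
NULL

CONTEXT_CLASSES <- c("WCG", "GCH", "GCG", "CCG", "OTHER")

#' Read a per-cell cytosine report
#'
#' The dialect is a 7-column, headerless, tab-separated file modeled on the
#' Bismark CX report: chrom, 1-based position of the cytosine, strand,
#' methylated (C) read count, unmethylated (T) read count, context class
#' (WCG/GCH/GCG/CCG/OTHER) and the trinucleotide on the cytosine's own
#' strand. Positions are converted to the package-internal 0-based
#' convention on read.
#'
#' @param path file path.
#' @return data.table with columns chrom, pos (0-based), strand, meth,
#'   unmeth, context_class, trinucleotide.
#' @export
read_cytosine_report <- function(path) {
  empty <- data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), meth = integer(),
                                  unmeth = integer(),
                                  context_class = character(),
                                  trinucleotide = character())
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 6, 7)))
  if (ncol(dt) != 7L)
    stop("cytosine report must have 7 tab-separated columns, found ",
         ncol(dt))
  data.table::setnames(dt, c("chrom", "pos1", "strand", "meth", "unmeth",
                             "context_class", "trinucleotide"))
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop("cytosine report parse error (", what, ") at line(s) ",
           paste(utils::head(i, 5), collapse = ", "))
  }
  bad(!dt$strand %in% c("+", "-"), "bad strand")
  bad(dt$pos1 < 1L, "position < 1")
  bad(dt$meth < 0L | dt$unmeth < 0L, "negative count")
  bad(nchar(dt$trinucleotide) != 3L, "non-3-mer context")
  bad(!dt$context_class %in% CONTEXT_CLASSES, "unknown context class")
  dt[, pos := as.integer(pos1) - 1L][, pos1 := NULL]
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "meth", "unmeth",
                                "context_class", "trinucleotide"))
  dt[]
}

#' Write a cytosine report (inverse of \code{read_cytosine_report})
#' @param calls table with the internal columns.
#' @param path output file.
#' @export
write_cytosine_report <- function(calls, path) {
  out <- data.table::data.table(calls$chrom, calls$pos + 1L, calls$strand,
                                calls$meth, calls$unmeth,
                                calls$context_class, calls$trinucleotide)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write BED interval files
#'
#' BED is 0-based half-open, matching internal coordinates, so the
#' round-trip is lossless. Columns beyond chrom/start/end are read into
#' name, score, strand and then kept as extra columns verbatim.
#'
#' @param x interval table (for writing).
#' @param path file path.
#' @param extra_columns character vector of column names of \code{x} to
#'   append after chrom/start/end.
#' @return \code{read_bed}: interval data.table.
#' @export
write_bed <- function(x, path, extra_columns = NULL) {
  if (any(x$start >= x$end)) stop("BED requires start < end")
  out <- data.table::data.table(chrom = x$chrom, start = x$start,
                                end = x$end)
  for (nm in extra_columns) out[[nm]] <- x[[nm]]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names names for columns after the first three (reading).
#' @export
read_bed <- function(path, col_names = NULL) {
  if (file.size(path) == 0L)
    return(intervals(character(), integer(), integer())[0])
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  base <- c("chrom", "start", "end")
  extras <- if (is.null(col_names)) {
    std <- c("name", "score", "strand")
    n <- ncol(dt) - 3L
    if (n > 0) c(utils::head(std, n),
                 if (n > 3) paste0("V", seq_len(n - 3))) else character()
  } else col_names
  data.table::setnames(dt, c(base, extras))
  dt[, start := as.integer(start)][, end := as.integer(end)]
  dt[]
}

#' Read a heterozygous SNP table
#'
#' Tab-separated with header: chrom, pos (1-based), maternal_allele,
#' paternal_allele. Homozygous rows (identical alleles) or non-ACGT bases
#' are rejected with their line numbers.
#'
#' @param path file path.
#' @return data.table chrom, pos (0-based), maternal_allele,
#'   paternal_allele.
#' @export
read_snp_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = c(1, 3, 4)))
  data.table::setnames(dt, c("chrom", "pos1", "maternal_allele",
                             "paternal_allele"))
  bases <- c("A", "C", "G", "T")
  bad <- which(!dt$maternal_allele %in% bases |
               !dt$paternal_allele %in% bases |
               dt$maternal_allele == dt$paternal_allele)
  if (length(bad))
    stop("invalid SNP rows (homozygous or non-ACGT) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  dt[, pos := as.integer(pos1) - 1L][, pos1 := NULL]
  data.table::setcolorder(dt, c("chrom", "pos", "maternal_allele",
                                "paternal_allele"))
  dt[]
}

#' @rdname read_snp_table
#' @param snps SNP table in internal coordinates.
#' @export
write_snp_table <- function(snps, path) {
  out <- data.table::data.table(chrom = snps$chrom, pos = snps$pos + 1L,
                                maternal_allele = snps$maternal_allele,
                                paternal_allele = snps$paternal_allele)
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read / write TSS annotation
#'
#' Accepted as a 4-column TSV with header (gene, chrom, tss, strand;
#' tss 1-based) or as BED6, in which case the TSS is the strand-aware 5'
#' end. Both are normalized to the internal 0-based form.
#'
#' @param path file path.
#' @param format "tsv" or "bed".
#' @return data.table gene, chrom, tss (0-based), strand.
#' @export
read_tss_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    data.table::setnames(dt, c("gene", "chrom", "tss1", "strand"))
    dt[, tss := as.integer(tss1) - 1L][, tss1 := NULL]
  } else {
    bed <- read_bed(path)
    dt <- data.table::data.table(
      gene = bed$name, chrom = bed$chrom,
      tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
      strand = bed$strand)
  }
  if (!all(dt$strand %in% c("+", "-"))) stop("TSS strand must be + or -")
  dt[, .(gene = as.character(gene), chrom = as.character(chrom),
         tss = as.integer(tss), strand)]
}

#' @rdname read_tss_table
#' @param tss TSS table in internal coordinates.
#' @export
write_tss_table <- function(tss, path) {
  out <- data.table::data.table(gene = tss$gene, chrom = tss$chrom,
                                tss = tss$tss + 1L, strand = tss$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings; the genome is handled internally as a
#' named character vector of uppercase sequences.
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a simple key=value config file with section nesting
#'
#' Lines are \code{key = value}; \code{[section]} headers nest keys under
#' the section name. Values are auto-coerced to numeric where possible and
#' comma-split into vectors. '#' starts a comment.
#'
#' @param path config file.
#' @return nested named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    parsed <- if (!anyNA(num)) num else vals
    if (is.null(section)) out[[key]] <- parsed
    else out[[section]][[key]] <- parsed
  }
  out
}
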