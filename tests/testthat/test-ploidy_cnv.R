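test_that("ploidy normalizes to the reference mean and classifies", {
  cells <- data.table::data.table(
    cell = c("ref1", "ref2", "a", "b", "c", "zero"),
    genomic_reads = c(10000, 10000, 5000, 15000, 20000, 100),
    lambda_reads = c(1000, 1000, 1000, 1000, 1000, 0))
  res <- estimate_ploidy(cells, c("ref1", "ref2"))
  expect_equal(res[cell == "ref1", ploidy], 2.0)
  expect_equal(res[cell == "a", ploidy], 1.0)
  expect_equal(res[cell == "a", class], "1N")
  expect_equal(res[cell == "b", ploidy], 3.0)
  expect_equal(res[cell == "b", class], "2N-4N")
  expect_equal(res[cell == "c", ploidy], 4.0)
  expect_equal(res[cell == "c", class], "4N")
  expect_equal(res[cell == "zero", class], "outlier")
  # reference self-consistency: mean normalized reference ploidy is 2
  expect_equal(mean(res[cell %in% c("ref1", "ref2"), ploidy]), 2.0)
})

test_that("simulated 1N/2N/4N cells classify correctly >= 95%", {
  set.seed(50)
  n_per <- 40
  truth_p <- rep(c(1, 2, 4), each = n_per)
  g <- rpois(length(truth_p), 10000 * truth_p / 2)
  l <- rpois(length(truth_p), 500)
  cells <- data.table::data.table(
    cell = paste0("c", seq_along(truth_p)),
    genomic_reads = g, lambda_reads = l)
  refs <- cells$cell[truth_p == 2]
  res <- estimate_ploidy(cells, refs)
  want <- c("1N", "2N", "4N")[match(truth_p, c(1, 2, 4))]
  expect_gte(mean(res$class == want), 0.95)
})

test_that("binning tiles the genome and conserves read counts", {
  lens <- c(chr1 = 10e6)
  set.seed(51)
  rp <- lapply(1:4, function(i) data.table::data.table(
    chrom = "chr1", pos = sample.int(10e6, 5000) - 1L))
  names(rp) <- paste0("c", 1:4)
  br <- bin_and_normalize(rp, lens, bin_size = 1e6)
  expect_equal(nrow(br$bins), 10L)
  expect_equal(colSums(br$raw), rep(5000, 4), ignore_attr = TRUE)
  # identical counts give log2 ratios of exactly 0
  cn <- matrix(100, nrow = 10, ncol = 3,
               dimnames = list(NULL, paste0("c", 1:3)))
  br2 <- bin_and_normalize(chrom_lengths = lens, counts = cn,
                           bin_size = 1e6)
  expect_true(all(br2$log2 == 0))
})

test_that("a 1.5x chromosome sits near log2(1.5) after normalization", {
  set.seed(52)
  lens <- c(chr1 = 5e6, chr2 = 5e6)
  mk <- function(extra_chr2 = 1) {
    n1 <- rpois(1, 5000); n2 <- rpois(1, 5000 * extra_chr2)
    rbind(data.table::data.table(chrom = "chr1",
                                 pos = sample.int(5e6, n1) - 1L),
          data.table::data.table(chrom = "chr2",
                                 pos = sample.int(5e6, n2) - 1L))
  }
  rp <- c(lapply(1:5, function(i) mk(1)), list(mk(1.5)))
  names(rp) <- paste0("c", 1:6)
  br <- bin_and_normalize(rp, lens, bin_size = 1e6)
  gained <- br$log2[br$bins$chrom == "chr2", "c6"]
  expect_lt(abs(mean(gained) - log2(1.5)), 0.15)
  flags <- flag_chromosome_cnv(br)
  expect_equal(flags[cell == "c6" & chrom == "chr2", call], "gain")
  expect_true(all(flags[cell != "c6", call] == "neutral"))
})

test_that("monosomy flags a loss and euploid cells stay clean", {
  set.seed(53)
  lens <- c(chr1 = 5e6, chr2 = 5e6)
  cn <- matrix(rpois(10 * 12, 500), nrow = 10,
               dimnames = list(NULL, paste0("c", 1:12)))
  bins_chr2 <- 6:10
  cn[bins_chr2, 1] <- rpois(5, 250)   # cell 1 loses chr2
  br <- bin_and_normalize(chrom_lengths = lens, counts = cn,
                          bin_size = 1e6)
  flags <- flag_chromosome_cnv(br)
  expect_equal(flags[cell == "c1" & chrom == "chr2", call], "loss")
  expect_equal(nrow(flags[cell != "c1" & call != "neutral"]), 0L)
})

test_that("per-cell CV follows Poisson scaling", {
  set.seed(54)
  lens <- c(chr1 = 50e6)
  cv_at <- function(mu) {
    cn <- matrix(rpois(50 * 6, mu), nrow = 50,
                 dimnames = list(NULL, paste0("c", 1:6)))
    br <- bin_and_normalize(chrom_lengths = lens, counts = cn,
                            bin_size = 1e6)
    mean(per_cell_cv(br$norm))
  }
  expect_equal(cv_at(100), 0.1, tolerance = 0.35)
  cvs <- vapply(c(25, 100, 400), cv_at, numeric(1))
  expect_true(all(diff(cvs) < 0))      # CV decreases with reads per bin
  # constant bins give CV 0
  cn <- matrix(7, nrow = 5, ncol = 3, dimnames = list(NULL, letters[1:3]))
  br <- bin_and_normalize(chrom_lengths = c(chr1 = 5e6), counts = cn,
                          bin_size = 1e6)
  expect_equal(unname(per_cell_cv(br$norm)), rep(0, 3))
})

test_that("GC correction flattens a GC-driven trend", {
  set.seed(55)
  gc <- seq(0.3, 0.6, length.out = 40)
  bias <- 0.5 + gc                      # linear count bias in GC
  cn <- sapply(1:4, function(i) rpois(40, 400 * bias))
  colnames(cn) <- paste0("c", 1:4)
  br <- bin_and_normalize(chrom_lengths = c(chr1 = 40e6), counts = cn,
                          bin_size = 1e6, bin_gc = gc)
  r <- cor(gc, rowMeans(br$raw))
  r_corr <- cor(gc, rowMeans(sweep(br$norm, 1,
                                   apply(br$norm, 1, median), "/")),
                use = "complete.obs")
  expect_gt(r, 0.8)                     # raw counts strongly GC-biased
  expect_lt(abs(r_corr), 0.5)          # corrected much flatter
})

test_that("replication lead/lag separates S-phase from uniform cells", {
  set.seed(56)
  labels <- rep(c("leading", "lagging"), each = 100)
  s_cell <- c(rpois(100, 200), rpois(100, 100))
  g2_cell <- rpois(200, 200)
  rs <- replication_lead_lag(s_cell, labels)
  expect_gt(rs$mean_leading, rs$mean_lagging)
  expect_lt(rs$p_value, 0.01)
  rg <- replication_lead_lag(g2_cell, labels)
  expect_gt(rg$p_value, 0.05)
  # shuffled labels erase the difference
  rsh <- replication_lead_lag(s_cell, sample(labels))
  expect_gt(rsh$p_value, 0.001)
  expect_lt(abs(rsh$mean_leading - rsh$mean_lagging),
            0.35 * rs$mean_lagging)
  # missing class is undefined
  expect_true(is.na(replication_lead_lag(s_cell,
    rep("leading", 200))$p_value))
})

test_that("sex is inferred from the X / autosome read ratio", {
  # equal-length X and autosome: XX ratio ~1, XY ratio ~0.5
  expect_equal(infer_sex(1000, 1000, 1e6, 1e6), "female")
  expect_equal(infer_sex(510, 1000, 1e6, 1e6), "male")
  expect_true(is.na(infer_sex(100, 0, 1e6, 1e6)))
  # simulated XX / XY cells through the generator's copy multipliers
  set.seed(57)
  for (rep_i in 1:5) {
    xx <- c(rpois(1, 2000), rpois(1, 2000))
    xy <- c(rpois(1, 1000), rpois(1, 2000))
    expect_equal(infer_sex(xx[1], xx[2], 1e6, 1e6), "female")
    expect_equal(infer_sex(xy[1], xy[2], 1e6, 1e6), "male")
  }
})
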