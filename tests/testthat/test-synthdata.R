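test_that("config validation catches impossible worlds", {
  expect_error(simulation_config(p_gch_open = 1.2), "probabilities")
  expect_error(simulation_config(nucleosome_core = 200,
                                 nucleosome_repeat = 180), "repeat")
  expect_error(simulation_config(
    wcg_level_by_stage_and_allele = list(E = list(CGI = c(0.1)))),
    "pairs")
  expect_error(simulate_genome(simulation_config(chrom_length = 5000L,
                                                 n_genes = 3L)),
               "too short")
})

test_that("identical seeds give identical worlds and cells", {
  cfg <- simulation_config(seed = 7, chrom_length = 40000L, n_genes = 4L,
                           cells_per_stage = c(ES = 2L),
                           n_allele_reads = 200L)
  t1 <- simulate_genome(cfg); t2 <- simulate_genome(cfg)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$planted_ndrs, t2$planted_ndrs)
  expect_identical(t1$snp_table, t2$snp_table)
  s1 <- simulate_cells(t1, cfg); s2 <- simulate_cells(t2, cfg)
  expect_identical(s1$reports, s2$reports)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$read_snp_obs, s2$read_snp_obs)
})

test_that("realized GC content tracks the configured fraction", {
  cfg <- simulation_config(seed = 8, chrom_length = 1000000L,
                           gc_fraction = 0.42, n_genes = 10L)
  truth <- simulate_genome(cfg)
  gc <- mean(strsplit(truth$genome[[1]], "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.40)   # binomial bound at n = 1e6
  expect_lte(gc, 0.44)
})

test_that("planted structure respects its own invariants", {
  fx <- deep_sim()
  truth <- fx$truth
  # NDRs and cores never overlap
  ov <- merge(truth$nucleosome_cores, truth$planted_ndrs, by = "chrom",
              allow.cartesian = TRUE, suffixes = c("_c", "_n"))
  expect_equal(nrow(ov[start_c < end_n & start_n < end_c]), 0L)
  # every SNP is heterozygous with the reference as maternal allele
  expect_true(all(truth$snp_table$maternal_allele !=
                  truth$snp_table$paternal_allele))
  ref <- substring(truth$genome[truth$snp_table$chrom],
                   truth$snp_table$pos + 1L, truth$snp_table$pos + 1L)
  expect_equal(unname(ref), truth$snp_table$maternal_allele)
  # promoter NDRs contain their gene's TSS
  prom <- truth$planted_ndrs[class == "promoter"]
  open_tss <- truth$true_promoter_state[state == "open"]
  hit <- vapply(seq_len(nrow(open_tss)), function(i)
    any(prom$chrom == open_tss$chrom[i] & prom$start <= open_tss$tss[i] &
        open_tss$tss[i] < prom$end), logical(1))
  expect_true(all(hit))
  # distal NDRs stay >= 2 kb from every TSS
  dist <- truth$planted_ndrs[class == "distal"]
  if (nrow(dist)) {
    d <- interval_nearest_distance(dist, data.table::data.table(
      chrom = truth$tss_table$chrom, pos = truth$tss_table$tss))
    expect_true(all(d >= 2000))
  }
})

test_that("ndr_fraction_of_promoters = 0 plants no promoter NDRs", {
  cfg <- simulation_config(seed = 9, chrom_length = 40000L, n_genes = 4L,
                           ndr_fraction_of_promoters = 0,
                           n_distal_ndrs = 3L)
  truth <- simulate_genome(cfg)
  expect_equal(nrow(truth$planted_ndrs[class == "promoter"]), 0L)
  expect_true(all(truth$true_promoter_state$state == "closed"))
})

test_that("counts conserve depth and calibrate to the planted rates", {
  fx <- deep_sim()
  rep1 <- fx$sim$reports[[1]]
  expect_true(all(rep1$meth >= 0 & rep1$unmeth >= 0))
  expect_true(all(rep1$meth + rep1$unmeth >= 1))
  # pooled GCH level inside planted NDRs ~ p_gch_open (3 binomial SE)
  gch <- pooled_gch_counts(fx$sim)
  nd <- fx$truth$planted_ndrs
  in_ndr <- rep(FALSE, nrow(gch))
  for (i in seq_len(nrow(nd)))
    in_ndr <- in_ndr | (gch$chrom == nd$chrom[i] & gch$pos >= nd$start[i] &
                        gch$pos < nd$end[i])
  n_open <- sum(gch$c_count[in_ndr] + gch$t_count[in_ndr])
  lvl_open <- sum(gch$c_count[in_ndr]) / n_open
  p_eff <- 0.8 * (1 - 0.005) + 0.2 * 0.005
  expect_lt(abs(lvl_open - p_eff), 3 * sqrt(p_eff * (1 - p_eff) / n_open))
  # and inside cores ~ p_gch_closed
  cores <- fx$truth$nucleosome_cores
  in_core <- which(vapply(seq_len(nrow(gch)), function(i)
    any(cores$chrom == gch$chrom[i] & cores$start <= gch$pos[i] &
        gch$pos[i] < cores$end), logical(1)))
  n_cl <- sum(gch$c_count[in_core] + gch$t_count[in_core])
  lvl_cl <- sum(gch$c_count[in_core]) / n_cl
  p_cl <- 0.05 * (1 - 0.005) + 0.95 * 0.005
  expect_lt(abs(lvl_cl - p_cl), 3 * sqrt(p_cl * (1 - p_cl) / n_cl))
})

test_that("full detection at high depth recovers every site", {
  cfg <- simulation_config(seed = 10, chrom_length = 20000L, n_genes = 0L,
                           n_distal_ndrs = 2L, site_detection_prob = 1.0,
                           depth_mean = 999, cells_per_stage = c(ES = 1L),
                           n_allele_reads = 0L, snp_density = 0)
  truth <- simulate_genome(cfg)
  sim <- simulate_cells(truth, cfg)
  ctx <- classify_cytosines(truth$genome)
  expect_equal(nrow(sim$reports[[1]]), nrow(ctx))
  expect_gte(min(sim$reports[[1]]$meth + sim$reports[[1]]$unmeth), 1)
})

test_that("sparsity matches site_detection_prob and WCG obeys stage levels", {
  fx <- sparse_sim()
  ctx <- classify_cytosines(fx$truth$genome)
  frac <- mean(vapply(fx$sim$reports, nrow, numeric(1))) / nrow(ctx)
  expect_lt(abs(frac - 0.10), 0.01)
  # intragenic WCG pooled level tracks the configured 0.75
  wcg <- data.table::rbindlist(fx$sim$reports)[context_class == "WCG"]
  el <- element_class(fx$truth, wcg$chrom, wcg$pos)
  intra <- wcg[el == "intragenic"]
  lvl <- sum(intra$meth) / sum(intra$meth + intra$unmeth)
  expect_lt(abs(lvl - 0.75), 0.03)
})

test_that("ploidy scales genomic reads against a constant spike-in", {
  cfg <- simulation_config(seed = 12, chrom_length = 30000L, n_genes = 0L,
                           n_distal_ndrs = 0L, snp_density = 0,
                           site_detection_prob = 0.01,
                           cells_per_stage = c(ES = 8L),
                           n_allele_reads = 0L,
                           ploidy_by_cell = c(ES_c01 = 4, ES_c02 = 4,
                                              ES_c03 = 2, ES_c04 = 2,
                                              ES_c05 = 2, ES_c06 = 2,
                                              ES_c07 = 1, ES_c08 = 1))
  truth <- simulate_genome(cfg)
  sim <- simulate_cells(truth, cfg)
  cells <- sim$cells
  r <- cells$genomic_reads / cells$lambda_reads
  expect_lt(abs(mean(r[1:2]) / mean(r[3:6]) - 2), 0.15)   # 4N vs 2N
  expect_lt(abs(mean(r[7:8]) / mean(r[3:6]) - 0.5), 0.1)  # 1N vs 2N
})

test_that("maternal and paternal reads are balanced for diploids", {
  fx <- sparse_sim()
  n <- nrow(fx$sim$reads)
  f <- mean(fx$sim$reads$true_allele == "maternal")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
})

test_that("a simulation round-trips through the on-disk formats", {
  cfg <- simulation_config(seed = 13, chrom_length = 30000L, n_genes = 3L,
                           cells_per_stage = c(ES = 2L),
                           n_allele_reads = 50L)
  truth <- simulate_genome(cfg)
  sim <- simulate_cells(truth, cfg)
  out <- file.path(tempdir(), "simout")
  write_simulation(truth, sim, out)
  g <- read_genome_fasta(file.path(out, "genome.fa"))
  expect_equal(g, truth$genome)
  tss <- read_tss_table(file.path(out, "tss.tsv"))
  expect_equal(tss, truth$tss_table)
  snps <- read_snp_table(file.path(out, "snps.tsv"))
  expect_equal(snps, truth$snp_table)
  cell1 <- read_cytosine_report(
    file.path(out, "cells", paste0(names(sim$reports)[1], ".tsv")))
  expect_equal(cell1$meth, sim$reports[[1]]$meth)
  unlink(out, recursive = TRUE)
})
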