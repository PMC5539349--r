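# long-format WCG call table builder: one site x stage x cell row set
mk_calls <- function(site_pos, stage, n_cells, meth_fun, depth = 4L) {
  do.call(rbind, lapply(seq_len(n_cells), function(ci) {
    m <- meth_fun(length(site_pos))
    data.table::data.table(chrom = "chr1", pos = as.integer(site_pos),
                           strand = "+", cell = paste0(stage, "_", ci),
                           stage = stage, meth = m, unmeth = depth - m)
  }))
}

# independent Fisher oracle: two-sided p by full hypergeometric
# enumeration over the 2x2 table with fixed margins
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("de novo sites need low start, +0.3 gain and BH significance", {
  set.seed(40)
  # 30 null sites at level 0.1 in both stages, 1 shifted site
  null_a <- mk_calls(1:30 * 10, "z", 4, function(n) rbinom(n, 4, 0.1))
  null_b <- mk_calls(1:30 * 10, "t", 4, function(n) rbinom(n, 4, 0.1))
  null_b[, stage := "t"]
  site_a <- mk_calls(500, "z", 5, function(n) rbinom(n, 4, 0.10))
  site_b <- mk_calls(500, "t", 5, function(n) rbinom(n, 4, 0.60))
  calls <- rbind(null_a, null_b, site_a, site_b)
  res <- call_transition_sites(calls, "z", "t", "de_novo")
  hit <- res[pos == 500]
  if (hit$mean_from < 0.25 && hit$delta >= 0.3)   # stochastic means
    expect_equal(hit$called, hit$q < 0.05)
  # a 0.25 increase is never enough, however significant
  res2 <- data.table::copy(res)[pos == 500]
  expect_false(res2$mean_from >= 0.25 && res2$called)
})

test_that("fisher p-values match the hypergeometric enumeration oracle", {
  cases <- list(c(2, 18, 10, 10), c(0, 5, 5, 0), c(3, 3, 3, 3),
                c(1, 19, 15, 5), c(8, 2, 2, 8))
  for (cs in cases) {
    got <- stats::fisher.test(matrix(cs, 2, byrow = TRUE))$p.value
    expect_equal(got, fisher_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-8)
  }
  # the caller's p equals fisher.test on the pooled stage counts
  calls <- rbind(
    mk_calls(100, "z", 5, function(n) rep(0L, n), depth = 4L),
    mk_calls(100, "t", 5, function(n) rep(2L, n), depth = 4L))
  res <- call_transition_sites(calls, "z", "t", "de_novo")
  expect_equal(res$p, fisher_oracle(0, 20, 10, 10), tolerance = 1e-8)
})

test_that("thresholds gate the calls exactly as stated", {
  # 0.10 -> 0.35 is an increase of 0.25: not de novo
  calls <- rbind(
    mk_calls(1, "z", 10, function(n) rep(0L, n), depth = 10L),
    mk_calls(1, "t", 10, function(n) rep(4L, n), depth = 10L))
  calls[stage == "z", `:=`(meth = 1L, unmeth = 9L)]
  calls[stage == "t", `:=`(meth = 4L, unmeth = 6L)]  # 0.1 -> 0.4? no: 0.3
  calls[stage == "t" & cell == "t_1", meth := 3L]
  res <- call_transition_sites(calls, "z", "t", "de_novo")
  expect_equal(res$called, res$delta >= 0.3 & res$q < 0.05)
  # demethylation: 0.8 -> 0.4 with strong counts
  dem <- rbind(
    mk_calls(1, "z", 10, function(n) rep(8L, n), depth = 10L),
    mk_calls(1, "t", 10, function(n) rep(4L, n), depth = 10L))
  resd <- call_transition_sites(dem, "z", "t", "demethylated")
  expect_true(resd$called)
  expect_lt(resd$q, 0.05)
})

test_that("the 3-covered-cells rule gates sites and CGIs", {
  two_cells <- rbind(
    mk_calls(100, "z", 2, function(n) rep(0L, n)),
    mk_calls(100, "t", 5, function(n) rep(2L, n)))
  res <- call_transition_sites(two_cells, "z", "t", "de_novo")
  expect_equal(nrow(res), 0L)

  cgi <- intervals("chr1", 0, 1000)
  calls <- rbind(
    mk_calls(c(100, 200, 300), "z", 2, function(n) rep(0L, n)),
    mk_calls(c(100, 200, 300), "t", 5, function(n) rep(2L, n)))
  res_cgi <- call_de_novo_cgis(cgi, calls, c("z", "t"))
  expect_equal(nrow(res_cgi), 0L)   # only 2 qualifying cells in stage z
  calls3 <- rbind(
    mk_calls(c(100, 200, 300), "z", 3, function(n) rbinom(n, 4, 0.05)),
    mk_calls(c(100, 200, 300), "t", 3, function(n) rbinom(n, 4, 0.60)))
  set.seed(41)
  res3 <- call_de_novo_cgis(cgi, calls3, c("z", "t"))
  expect_equal(nrow(res3), 1L)
  expect_equal(res3$called, res3$mean_from < 0.25 &
                 (res3$mean_to - res3$mean_from) >= 0.3)
  # constant CGI never called
  const <- rbind(
    mk_calls(c(100, 200, 300), "z", 4, function(n) rep(0L, n)),
    mk_calls(c(100, 200, 300), "t", 4, function(n) rep(0L, n)))
  resc <- call_de_novo_cgis(cgi, const, c("z", "t"))
  expect_false(any(resc$called))
})

test_that("de novo and demethylated calls are disjoint", {
  set.seed(42)
  calls <- rbind(
    mk_calls(1:50 * 10, "z", 5, function(n) rbinom(n, 6, 0.5), depth = 6L),
    mk_calls(1:50 * 10, "t", 5, function(n) rbinom(n, 6, 0.5), depth = 6L))
  up <- call_transition_sites(calls, "z", "t", "de_novo")
  dn <- call_transition_sites(calls, "z", "t", "demethylated")
  expect_equal(length(intersect(up[called == TRUE, pos],
                                dn[called == TRUE, pos])), 0L)
})

test_that("methylation CV is sd/mean with NA for degenerate input", {
  m <- rbind(a = c(0.2, 0.2, 0.2), b = c(0.1, 0.3, NA),
             c = c(0, 0, 0), d = c(0.5, NA, NA))
  cv <- methylation_cv(m)
  expect_equal(unname(cv["a"]), 0)
  expect_equal(unname(cv["b"]), stats::sd(c(0.1, 0.3)) / 0.2)
  expect_true(is.na(cv["c"]))  # mean zero
  expect_true(is.na(cv["d"]))  # single cell
})

test_that("CV decreases with depth under binomial noise", {
  set.seed(43)
  cv_at <- function(d) {
    m <- t(replicate(50, rbinom(20, d, 0.3) / d))
    mean(methylation_cv(m), na.rm = TRUE)
  }
  cvs <- vapply(c(5, 20, 80), cv_at, numeric(1))
  expect_true(all(diff(cvs) < 0))
})

test_that("omics correlations align genes and drop missing pairs", {
  g <- paste0("g", 1:6)
  acc <- stats::setNames(c(1, 2, 3, 4, 5, 6), g)
  expr <- acc
  meth <- stats::setNames(1 - acc / 6, g)
  res <- correlate_omics(meth, acc, expr)
  expect_equal(res[pair == "access_expression", r], 1)
  expect_equal(res[pair == "meth_access", r], -1)
  # simulated anti-correlation is estimated within sampling error
  set.seed(44)
  n <- 500
  z <- stats::rnorm(n)
  a2 <- stats::setNames(z + stats::rnorm(n, sd = 1), paste0("x", 1:n))
  m2 <- stats::setNames(-z + stats::rnorm(n, sd = 1), paste0("x", 1:n))
  r <- correlate_omics(m2, a2, a2, method = "pearson")[
    pair == "meth_access", r]
  expect_lt(abs(r - (-0.5)), 0.1)
  # fewer than 3 shared genes is undefined
  small <- correlate_omics(meth[1:2], acc[1:2], expr)
  expect_true(is.na(small[pair == "meth_access", r]))
})
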