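# Six-criterion DMR caller: chaining, per-region evaluation, end-to-end
# calls, and the caller's structural invariants.

# Build a pre-flagged sample pair at shared positions with given counts.
flagged_pair <- function(pos, meth_a, tot_a, meth_b, tot_b,
                         flag_a = NULL, flag_b = NULL, context = "CG") {
  a <- cx_records(pos, meth_a, tot_a, context = context,
                  methylated = flag_a %||% (meth_a >= 4))
  b <- cx_records(pos, meth_b, tot_b, context = context,
                  methylated = flag_b %||% (meth_b >= 4))
  list(a = a, b = b)
}

test_that("chaining follows the max-gap rule and the length window", {
  # seeds at 100/250/600: 150 < 200 chains, 350 breaks; the singleton at
  # 600 spans 1 bp and dies by min_len
  s <- flagged_pair(pos = c(100, 250, 600), meth_a = 10, tot_a = 12,
                    meth_b = 2, tot_b = 12, flag_b = FALSE)
  cands <- build_candidate_regions(s$a, s$b, dmr_config(), "CG")
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$start, 100L)
  expect_equal(cands[[1]]$end, 250L)
  expect_equal(nrow(cands[[1]]$sites), 2L)

  # all gaps >= 200: no candidates survive the window
  s2 <- flagged_pair(pos = c(100, 300, 500), meth_a = 10, tot_a = 12,
                     meth_b = 2, tot_b = 12, flag_b = FALSE)
  expect_length(build_candidate_regions(s2$a, s2$b, dmr_config(), "CG"), 0L)

  # a chain spanning more than 10 kb is discarded whole
  pos3 <- seq(1000, 12000, by = 150)
  s3 <- flagged_pair(pos3, meth_a = 10, tot_a = 12, meth_b = 2, tot_b = 12,
                     flag_b = FALSE)
  expect_length(build_candidate_regions(s3$a, s3$b, dmr_config(), "CG"), 0L)
})

test_that("coverage and methylated-read screens gate seed sites", {
  cfg <- dmr_config()
  # second site fails coverage in sample B; third carries < 4 methylated
  # reads despite its flag; neither seeds, so the chain falls apart
  a <- cx_records(c(100, 180, 260), meth = c(10, 10, 3), total = 12,
                  methylated = TRUE)
  b <- cx_records(c(100, 180, 260), meth = 2, total = c(12, 8, 12),
                  methylated = FALSE)
  cands <- build_candidate_regions(a, b, cfg, "CG")
  expect_length(cands, 0L)  # only site 100 seeds; span 1 < min_len
  # disjoint chromosome sets are an input error
  b2 <- b
  b2$chrom <- "chr9"
  expect_error(build_candidate_regions(a, b2, cfg, "CG"), "chromosome")
})

test_that("region evaluation reproduces the chi-square oracle", {
  # pooled 2x2 [[90,10],[20,80]]: chi2 = 200*(90*80-10*20)^2 /
  # (100*100*110*90) = 9800/99 = 98.9898..., p << 0.05, fold 4.5
  s <- flagged_pair(pos = seq(100, 340, by = 60),
                    meth_a = 18, tot_a = 20, meth_b = 4, tot_b = 20)
  cand <- build_candidate_regions(s$a, s$b, dmr_config(), "CG")[[1]]
  ev <- evaluate_region(cand, dmr_config())
  expect_equal(ev$record$level_a, 0.9)
  expect_equal(ev$record$level_b, 0.2)
  expect_equal(ev$record$fold_change, 4.5)
  expect_equal(ev$record$chi2, 9800 / 99, tolerance = 1e-12)
  expect_equal(ev$record$p, pchisq(9800 / 99, 1, lower.tail = FALSE))
  expect_identical(ev$status, "pass")
  expect_identical(ev$record$direction, "hypo")
})

test_that("regions failing individual criteria are rejected with reasons", {
  cfg <- dmr_config()
  # identical pooled counts: fold 1
  s_eq <- flagged_pair(pos = seq(100, 340, by = 60),
                       meth_a = 10, tot_a = 20, meth_b = 10, tot_b = 20)
  ev_eq <- evaluate_region(
    build_candidate_regions(s_eq$a, s_eq$b, cfg, "CG")[[1]], cfg)
  expect_identical(ev_eq$status, "fold_change")
  expect_false(ev_eq$fold_pass)
  # three flagged cytosines per sample: below the site floor regardless of
  # fold
  s_few <- flagged_pair(pos = c(100, 150, 200), meth_a = 18, tot_a = 20,
                        meth_b = 4, tot_b = 20)
  ev_few <- evaluate_region(
    build_candidate_regions(s_few$a, s_few$b, cfg, "CG")[[1]], cfg)
  expect_identical(ev_few$status, "too_few_meth_sites")
  # zero-denominator fold rule: min level 0 with max > 0 passes
  s_zero <- flagged_pair(pos = seq(100, 340, by = 60),
                         meth_a = 12, tot_a = 20, meth_b = 0, tot_b = 20,
                         flag_b = FALSE)
  ev_zero <- evaluate_region(
    build_candidate_regions(s_zero$a, s_zero$b, cfg, "CG")[[1]], cfg)
  expect_identical(ev_zero$record$fold_change, Inf)
  expect_true(ev_zero$fold_pass)
})

test_that("call_dmrs on trivial inputs behaves as the null model requires", {
  cfg <- dmr_config()
  empty <- cx_records(integer(0), integer(0), integer(0))
  expect_equal(nrow(call_dmrs(empty, empty, cfg)), 0L)
  # a sample against itself can never reach fold > 1
  s <- flagged_pair(pos = seq(100, 700, by = 50), meth_a = 15, tot_a = 20,
                    meth_b = 15, tot_b = 20)
  expect_equal(nrow(call_dmrs(s$a, s$a, cfg)), 0L)
})

test_that("swapping samples flips DMR direction but preserves regions", {
  cfg <- tiny_cfg(seed = 37L)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(cfg, genome)
  sim <- simulate_methylomes(cfg, genome, genes)
  ab <- call_dmrs(sim$control, sim$treated, dmr_config())
  ba <- call_dmrs(sim$treated, sim$control, dmr_config())
  expect_gt(nrow(ab), 0L)
  expect_equal(ab[c("chrom", "start", "end", "context", "n_sites")],
               ba[c("chrom", "start", "end", "context", "n_sites")])
  expect_equal(ab$level_a, ba$level_b)
  expect_equal(ab$fold_change, ba$fold_change)
  expect_true(all(ab$direction != ba$direction))
})

test_that("tightening fold or p thresholds never increases the call count", {
  cfg <- tiny_cfg(seed = 41L)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(cfg, genome)
  sim <- simulate_methylomes(cfg, genome, genes)
  n_base <- nrow(call_dmrs(sim$control, sim$treated, dmr_config()))
  for (mf in c(2.5, 3, 4)) {
    expect_lte(nrow(call_dmrs(sim$control, sim$treated,
                              dmr_config(min_fold = mf))), n_base)
  }
  for (mp in c(0.01, 0.001)) {
    expect_lte(nrow(call_dmrs(sim$control, sim$treated,
                              dmr_config(max_p = mp))), n_base)
  }
})

test_that("DMR BED output carries context:direction names and capped scores", {
  dmrs <- data.frame(chrom = "chr1", start = 101L, end = 400L,
                     context = "CG", direction = "hyper", p = c(1e-2000))
  path <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, path)
  f <- read.table(path, sep = "\t")
  expect_equal(f$V2, 100L)  # 0-based start
  expect_identical(f$V4, "CG:hyper")
  expect_lte(f$V5, 1000)
})
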