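# Methylome statistics: context classification, binomial site calling,
# summaries, densities, 9-bp context matrices, metagene geometry.

test_that("context classification matches exhaustive 3-mer enumeration", {
  bases <- c("A", "C", "G", "T")
  trimers <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  genome <- Biostrings::DNAStringSet(trimers)
  names(genome) <- paste0("t", seq_along(trimers))
  for (i in seq_along(trimers)) {
    # plus strand: classify the first base (full lookahead inside trimer)
    expect_identical(classify_context(genome, names(genome)[i], 1, "+"),
                     oracle_context(trimers[i], "+"),
                     label = paste(trimers[i], "+"))
    # minus strand: classify the last base (full lookbehind inside trimer)
    expect_identical(classify_context(genome, names(genome)[i], 3, "-"),
                     oracle_context(trimers[i], "-"),
                     label = paste(trimers[i], "-"))
  }
})

test_that("classification handles boundaries, spot cases and bad input", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT", chr2 = "ACAGT",
                                  chr3 = "ACAAT"))
  expect_identical(classify_context(g, "chr1", 2, "+"), "CG")
  expect_identical(classify_context(g, "chr2", 2, "+"), "CHG")
  expect_identical(classify_context(g, "chr3", 2, "+"), "CHH")
  # insufficient lookahead near the chromosome end
  expect_identical(classify_context(g, "chr1", 4, "+"), NA_character_)
  expect_error(classify_context(g, "chr1", 9, "+"), "outside")
  expect_error(classify_context(g, "chrX", 1, "+"), "chromosome")
})

test_that("enumerated cytosines agree with per-site classification", {
  genome <- generate_genome(sim_config(n_chroms = 1, chrom_length = 6000,
                                       n_genes = 0, seed = 31))
  sites <- inflammeth:::enumerate_cytosines(genome)
  idx <- seq(1, nrow(sites), by = 37)  # spot-check a lattice of sites
  for (i in idx) {
    expect_identical(
      classify_context(genome, sites$chrom[i], sites$pos[i], sites$strand[i]),
      sites$context[i])
  }
})

test_that("binomial site calling flags against non-conversion error", {
  # single-site tails: 10/10 at error 0.005 is 0.005^10; 1/200 leaves an
  # expected false count of 1 and must not be flagged
  rec <- cx_records(pos = c(100, 200, 300),
                    meth = c(10, 1, 0), total = c(10, 200, 50))
  out <- call_methylated_sites(rec, error_rate = 0.005, alpha = 0.05)
  expect_equal(out$p_meth[1], 0.005^10)
  expect_true(out$methylated[1])
  expect_equal(out$p_meth[2], 1 - (1 - 0.005)^200, tolerance = 1e-12)
  expect_false(out$methylated[2])
  expect_false(out$methylated[3])  # zero methylated reads, never flagged
  # uncovered and sub-coverage sites are never tested nor flagged
  rec0 <- cx_records(pos = c(1, 2), meth = c(0, 2), total = c(0, 2))
  out0 <- call_methylated_sites(rec0)
  expect_true(all(is.na(out0$q_meth)))
  expect_false(any(out0$methylated))
})

test_that("summary shares are normalized and counts are per context", {
  rec <- rbind(
    cx_records(pos = 1:80, meth = 10, total = 10, context = "CG",
               methylated = TRUE),
    cx_records(pos = 101:112, meth = 10, total = 10, context = "CHG",
               methylated = TRUE),
    cx_records(pos = 201:208, meth = 10, total = 10, context = "CHH",
               methylated = TRUE))
  s <- summarize_methylome(rec)
  expect_equal(s$contexts$n_mc, c(80L, 12L, 8L))
  expect_equal(s$contexts$share, c(0.80, 0.12, 0.08))
  expect_equal(sum(s$contexts$share), 1)
  # empty input: zero counts, shares fall back to zero
  s0 <- summarize_methylome(call_methylated_sites(empty <- cx_records(
    pos = integer(0), meth = integer(0), total = integer(0))))
  expect_equal(s0$n_mc_total, 0L)
  expect_equal(s0$contexts$share, rep(0, 3))
})

test_that("chromosome density tiles half-open windows and conserves counts", {
  rec <- cx_records(pos = c(150, 250, 1200, 1500), meth = 10, total = 10,
                    methylated = c(TRUE, TRUE, TRUE, FALSE))
  d <- chromosome_density(rec, window = 1000)
  expect_equal(d$n_mc, c(2L, 1L))
  expect_equal(d$window_start, c(0L, 1000L))
  expect_equal(sum(d$n_mc), sum(rec$methylated))
  # a window larger than the chromosome holds everything
  d2 <- chromosome_density(rec, window = 1e6)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$n_mc, 3L)
  expect_error(chromosome_density(rec, window = 0), "window")
})

test_that("9-bp context matrix is one-hot for a single site and CG-locked", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAAACGTTT"))
  rec <- cx_records(pos = 5, meth = 10, total = 10, methylated = TRUE)
  cm <- context_matrix_9bp(g, rec)
  flank <- strsplit("AAAACGTTT", "")[[1]]
  for (j in 1:9) {
    expect_equal(unname(cm$mcg[flank[j], j]), 1, label = paste("offset", j))
    expect_equal(sum(cm$mcg[, j]), 1)
  }
  expect_equal(unname(cm$mcg["C", "0"]), 1)   # center is the site itself
  expect_equal(unname(cm$mcg["G", "1"]), 1)   # +1 is G by CG definition
  # minus-strand site: flank is reverse-complemented before counting
  g2 <- Biostrings::DNAStringSet(c(chr1 = "AAACGTTTT"))
  rec2 <- cx_records(pos = 5, meth = 10, total = 10, strand = "-",
                     methylated = TRUE)
  cm2 <- context_matrix_9bp(g2, rec2)
  rc <- strsplit("AAAACGTTT", "")[[1]]  # revcomp of AAACGTTTT
  for (j in 1:9) expect_equal(unname(cm2$mcg[rc[j], j]), 1)
  # sites too close to an end are skipped and counted
  rec3 <- cx_records(pos = c(5, 2), meth = 10, total = 10,
                     methylated = TRUE)
  cm3 <- suppressWarnings(context_matrix_9bp(g, rec3))
  expect_equal(unname(cm3$skipped["mcg"]), 1L)
})

test_that("metagene geometry: 20 bins per 2-kb flank, flat for uniform input", {
  genes <- gene_table(start = 5000, end = 9000)
  pos <- seq(2600, 11500, by = 25)
  rec <- cx_records(pos = pos, meth = 5, total = 10)
  prof <- metagene_profile(rec, genes, flank = 2000, bin = 100,
                           body_bins = 20)
  cg <- prof[prof$context == "CG", ]
  expect_equal(sum(cg$segment == "upstream"), 20L)
  expect_equal(sum(cg$segment == "downstream"), 20L)
  expect_equal(sum(cg$segment == "body"), 20L)
  filled <- cg$n_genes > 0
  expect_true(any(filled))
  expect_true(all(abs(cg$mean_level[filled] - 0.5) < 1e-12))
  expect_error(metagene_profile(rec, genes, flank = 2000, bin = 300),
               "divisible")
})

test_that("metagene bins are strand-aware in 5'->3' orientation", {
  # minus-strand gene: its TSS is the right coordinate, so upstream lies
  # right of the gene; a site 150 bp beyond the gene end sits 150 bp from
  # the TSS, i.e. in the second-nearest upstream bin (index 18 of 0..19
  # in far->near 5'->3' ordering)
  genes <- gene_table(start = 5000, end = 9000, strand = "-")
  rec <- cx_records(pos = 9150, meth = 8, total = 10)
  prof <- metagene_profile(rec, genes)
  hit <- prof[prof$context == "CG" & prof$n_genes > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$segment, "upstream")
  expect_equal(hit$bin, 18L)
  expect_equal(hit$mean_level, 0.8)
  # mirrored plus-strand gene: a site 150 bp left of the start lands in the
  # same bin
  genes_p <- gene_table(start = 5000, end = 9000, strand = "+")
  rec_p <- cx_records(pos = 4850, meth = 8, total = 10)
  prof_p <- metagene_profile(rec_p, genes_p)
  hit_p <- prof_p[prof_p$context == "CG" & prof_p$n_genes > 0, ]
  expect_equal(hit_p$segment, "upstream")
  expect_equal(hit_p$bin, 18L)
  # genes shorter than body_bins are skipped with a warning
  expect_warning(
    metagene_profile(rec, gene_table(start = 100, end = 110), body_bins = 20),
    "skipped")
})

test_that("cytosine reports round-trip through the TSV dialect", {
  rec <- cx_records(pos = c(10, 20, 30), meth = c(0, 3, 7),
                    total = c(5, 9, 7),
                    context = c("CG", "CHG", "CHH"))
  path <- tempfile(fileext = ".tsv")
  write_cx_report(rec, path)
  back <- read_cx_report(path)
  expect_equal(back[names(rec)], rec)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(hdr, c("chrom", "pos", "strand", "context",
                          "meth_count", "unmeth_count"))
})
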