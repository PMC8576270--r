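# Synthetic-data generator: determinism, construction constraints, and
# convergence of observed methylation to the configured truth.

test_that("genome generation is seed-deterministic and honours GC bounds", {
  cfg <- tiny_cfg(seed = 3L)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  generate_genome(cfg, fasta_path = f1)
  generate_genome(cfg, fasta_path = f2)
  expect_identical(readLines(f1), readLines(f2))

  g0 <- generate_genome(sim_config(n_chroms = 1, chrom_length = 5000,
                                   gc_fraction = 0, n_genes = 0, seed = 2))
  expect_true(all(strsplit(as.character(g0[[1]]), "")[[1]] %in% c("A", "T")))

  # binomial: at p = 0.5 and n = 1e5, 3.16 sd ~ 0.005, so [0.49, 0.51]
  # holds with ~99.8% probability; the seed is fixed
  g5 <- generate_genome(sim_config(n_chroms = 1, chrom_length = 100000,
                                   gc_fraction = 0.5, n_genes = 0, seed = 4))
  gc_obs <- sum(Biostrings::letterFrequency(g5, c("G", "C"))) / 100000
  expect_gt(gc_obs, 0.49)
  expect_lt(gc_obs, 0.51)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(sim_config(dmr_length_range = c(10, 500)), "dmr_length_range")
  expect_error(sim_config(dmr_length_range = c(100, 20000)),
               "dmr_length_range")
  expect_error(sim_config(chrom_length = 5000), "chrom_length")
  expect_error(sim_config(somatic_af_range = c(0.5, 0.1)),
               "somatic_af_range")
})

test_that("gene models are non-overlapping, stranded, and keep 2-kb flanks", {
  cfg <- tiny_cfg(seed = 9L, n_genes = 3L)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(cfg, genome)
  expect_equal(nrow(genes), 3L)
  expect_true(all(genes$start >= 2001L))
  expect_true(all(genes$end <= cfg$chrom_length - 2000L))
  expect_setequal(unique(genes$strand) %in% c("+", "-"), TRUE)
  # brute-force pairwise overlap check
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (i == j) next
      same <- genes$chrom[i] == genes$chrom[j]
      overlap <- genes$start[i] <= genes$end[j] &&
        genes$end[i] >= genes$start[j]
      expect_false(same && overlap)
    }
  }
  # empty case
  cfg0 <- tiny_cfg(n_genes = 0L)
  bed <- tempfile(fileext = ".bed")
  g0 <- generate_gene_models(cfg0, genome, bed_path = bed)
  expect_equal(nrow(g0), 0L)
  expect_equal(file.size(bed), 0)
})

test_that("gene BED round-trips through the rtracklayer-backed reader", {
  cfg <- tiny_cfg(seed = 5L)
  genome <- generate_genome(cfg)
  bed <- tempfile(fileext = ".bed")
  genes <- generate_gene_models(cfg, genome, bed_path = bed)
  back <- read_gene_bed(bed)
  expect_equal(back[c("chrom", "start", "end", "strand", "gene_id")],
               genes[c("chrom", "start", "end", "strand", "gene_id")])
})

test_that("planted DMRs respect the length window, zones and separation", {
  cfg <- sim_config(seed = 21L)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(cfg, genome)
  sim <- simulate_methylomes(cfg, genome, genes)
  truth <- sim$truth
  expect_equal(nrow(truth), 3L * cfg$n_planted_dmrs)
  len <- truth$end - truth$start + 1L
  expect_true(all(len >= 40L & len <= 10000L))
  expect_true(all(len >= cfg$dmr_length_range[1] &
                    len <= cfg$dmr_length_range[2]))
  # fold change of planted truth passes the caller's criterion by design
  expect_true(all(truth$level_treated / truth$level_control > 2))
  # mutual non-overlap
  for (i in seq_len(nrow(truth))) {
    others <- truth[-i, , drop = FALSE]
    expect_false(any(others$chrom == truth$chrom[i] &
                       truth$start[i] <= others$end &
                       truth$end[i] >= others$start))
  }
  # genic DMRs lie entirely inside the recorded zone of their host gene
  genic <- truth[truth$zone != "intergenic", , drop = FALSE]
  for (i in seq_len(nrow(genic))) {
    g <- genes[genes$gene_id == genic$gene_id[i], ]
    zi <- if (genic$zone[i] == "body") {
      c(g$start, g$end)
    } else if ((g$strand == "+") == (genic$zone[i] == "up2k")) {
      c(g$start - 2000L, g$start - 1L)
    } else {
      c(g$end + 1L, g$end + 2000L)
    }
    expect_gte(genic$start[i], zi[1])
    expect_lte(genic$end[i], zi[2])
  }
})

test_that("observed levels converge to configured truth (binomial law)", {
  # all CG background methylated at 0.7: mean observed level ~ 0.7 within
  # binomial error at coverage 30 over ~1e4 sites
  cfg <- sim_config(n_chroms = 1, chrom_length = 120000, n_genes = 0,
                    n_planted_dmrs = 0, baseline_level_cg = 0.7,
                    methylated_fraction_cg = 1, bisulfite_error = 0.001,
                    coverage_dispersion = 0, seed = 8)
  genome <- generate_genome(cfg)
  sim <- simulate_methylomes(cfg, genome, genes = data.frame())
  cgs <- sim$control[sim$control$context == "CG" &
                       sim$control$total_count > 0, ]
  expect_gt(nrow(cgs), 5000)
  m <- mean(cgs$meth_count / cgs$total_count)
  expect_gt(m, 0.69)
  expect_lt(m, 0.71)
})

test_that("a zero delta leaves the two conditions exchangeable", {
  cfg <- tiny_cfg(seed = 13L, dmr_delta = 0)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(cfg, genome)
  sim <- simulate_methylomes(cfg, genome, genes)
  expect_equal(sim$truth$level_control, sim$truth$level_treated)
  # site-level expectations identical: pooled means agree within noise
  lc <- sum(sim$control$meth_count) / sum(sim$control$total_count)
  lt <- sum(sim$treated$meth_count) / sum(sim$treated$total_count)
  expect_lt(abs(lc - lt), 0.005)
})

test_that("variant truth is a disjoint union recoverable by subtraction", {
  cfg <- tiny_cfg(seed = 17L)
  genome <- generate_genome(cfg)
  vars <- simulate_variant_tables(cfg, genome)
  for (m in seq_len(cfg$n_mice)) {
    mouse <- vars$mice[[m]]
    germ <- vars$truth$germline_keys[[m]]
    som <- vars$truth$somatic_keys[[m]]
    expect_length(intersect(germ, som), 0)
    mk <- sort(paste(mouse$mucosa$chrom, mouse$mucosa$pos,
                     mouse$mucosa$ref, mouse$mucosa$alt, sep = ":"))
    expect_identical(mk, sort(c(germ, som)))
    sk <- paste(mouse$muscularis$chrom, mouse$muscularis$pos,
                mouse$muscularis$ref, mouse$muscularis$alt, sep = ":")
    expect_identical(sort(sk), germ)
    # somatic keys absent from the matched muscularis
    expect_length(intersect(som, sk), 0)
  }
  # germline AFs in {0.5, 1}; somatic within the configured range
  mu <- vars$mice[[1]]$mucosa
  germ_af <- mu$allele_fraction[paste(mu$chrom, mu$pos, mu$ref, mu$alt,
                                      sep = ":") %in%
                                  vars$truth$germline_keys[[1]]]
  expect_true(all(germ_af %in% c(0.5, 1)))
  som_af <- mu$allele_fraction[paste(mu$chrom, mu$pos, mu$ref, mu$alt,
                                     sep = ":") %in%
                                 vars$truth$somatic_keys[[1]]]
  expect_true(all(som_af >= cfg$somatic_af_range[1] &
                    som_af <= cfg$somatic_af_range[2]))
})

test_that("zero somatic variants leave mucosa and muscularis identical", {
  cfg <- tiny_cfg(seed = 19L, n_somatic_variants = 0L)
  genome <- generate_genome(cfg)
  vars <- simulate_variant_tables(cfg, genome)
  m1 <- vars$mice[[1]]
  expect_identical(
    sort(paste(m1$mucosa$chrom, m1$mucosa$pos, m1$mucosa$ref,
               m1$mucosa$alt, sep = ":")),
    sort(paste(m1$muscularis$chrom, m1$muscularis$pos, m1$muscularis$ref,
               m1$muscularis$alt, sep = ":")))
})

test_that("pathway map covers every gene and loads back unchanged", {
  cfg <- tiny_cfg(seed = 23L)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(cfg, genome)
  dmr_genes <- genes$gene_id[1:2]
  path <- tempfile(fileext = ".tsv")
  pm <- write_pathway_map(cfg, genes, dmr_gene_ids = dmr_genes, path = path)
  expect_true(all(genes$gene_id %in% pm$map$gene_id))
  # designated pathway holds >= 80% of the DMR-hosting genes by construction
  members <- pm$map$gene_id[pm$map$pathway_id == pm$enriched_pathway_id]
  expect_gte(length(intersect(dmr_genes, members)),
             ceiling(0.8 * length(dmr_genes)))
  back <- read_pathway_map(path)
  expect_equal(back, pm$map)
  # empty gene universe gives an empty map
  pm0 <- write_pathway_map(tiny_cfg(n_genes = 0L), genes[0, ])
  expect_equal(nrow(pm0$map), 0L)
})

test_that("all generator outputs are byte-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 29L)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  simulate_all(cfg, outdir = d1)
  simulate_all(cfg, outdir = d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})
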