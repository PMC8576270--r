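# Synthetic-data generator: seeded genome, gene models, two-condition
# methylomes with planted DMRs, paired mucosa/muscularis variant tables with
# known germline/somatic truth, and a gene->pathway map with one designated
# over-represented pathway. Every downstream stage is testable against the
# returned truth object.

#' Simulation configuration
#'
#' Build and validate the configuration that drives every generator in the
#' synthetic-data module. The defaults define the reference synthetic
#' scenario used throughout the package tests: a small two-chromosome genome,
#' bimodal background methylation, and planted CG/CHG/CHH DMRs whose control
#' level (`baseline_level_*`) and treated level (`baseline + dmr_delta`)
#' satisfy the fold-change criterion (0.2 vs 0.6, fold 3) by construction.
#'
#' @param n_chroms number of chromosomes (named `chr1..chrN`).
#' @param chrom_length length of each chromosome in bp.
#' @param gc_fraction GC content of the random genome, in `[0,1]`.
#' @param n_genes number of non-overlapping gene models to place.
#' @param gene_length_range length-2 vector, min/max gene length (bp).
#' @param n_planted_dmrs planted DMRs per sequence context.
#' @param dmr_host_gene_fraction fraction of genes eligible to host planted
#'   DMRs; concentrating DMRs on a proper subset of the gene universe is
#'   what makes pathway over-representation definable (and is how real
#'   differential methylation behaves).
#' @param dmr_length_range length-2 vector of planted DMR lengths (bp); must
#'   lie within the caller's length window `[40, 10000]`.
#' @param baseline_level_cg,baseline_level_chg,baseline_level_chh true
#'   methylation level of methylated background cytosines (and of planted
#'   DMRs in the control sample), per context.
#' @param methylated_fraction_cg,methylated_fraction_chg,methylated_fraction_chh
#'   fraction of background cytosines that are methylated at all; the rest
#'   sit at level 0 (plus bisulfite non-conversion error). Real methylomes
#'   are bimodal, and these fractions control the density of methylated
#'   sites, hence the chaining behaviour of the DMR caller.
#' @param dmr_delta signed shift applied to the treated sample inside
#'   planted DMRs (clipped to `[0,1]`).
#' @param mean_coverage mean read coverage per cytosine.
#' @param coverage_dispersion negative-binomial dispersion of coverage;
#'   0 degenerates to Poisson.
#' @param bisulfite_error bisulfite non-conversion rate, injected as
#'   false-positive methylation on unmethylated cytosines.
#' @param n_germline_variants germline variants per mouse (shared by both
#'   tissues at allele fraction 0.5 or 1.0).
#' @param n_somatic_variants somatic variants per mucosa sample.
#' @param somatic_af_range length-2 vector of somatic allele fractions.
#' @param n_mice number of mice (each contributes one mucosa/muscularis
#'   VCF pair).
#' @param sub_threshold_fraction fraction of somatic records deliberately
#'   written below the variant filter thresholds (MQ <= 20 or DP <= 4),
#'   to exercise the filters.
#' @param seed integer seed; all generator outputs are byte-identical for
#'   equal configurations.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_chroms = 1, chrom_length = 20000, n_genes = 3,
#'                   n_planted_dmrs = 2, seed = 7)
sim_config <- function(n_chroms = 2,
                       chrom_length = 300000L,
                       gc_fraction = 0.42,
                       n_genes = 40L,
                       gene_length_range = c(2000L, 8000L),
                       n_planted_dmrs = 20L,
                       dmr_host_gene_fraction = 0.35,
                       dmr_length_range = c(300L, 1000L),
                       baseline_level_cg = 0.2,
                       baseline_level_chg = 0.15,
                       baseline_level_chh = 0.1,
                       methylated_fraction_cg = 0.05,
                       methylated_fraction_chg = 0.02,
                       methylated_fraction_chh = 0.01,
                       dmr_delta = 0.4,
                       mean_coverage = 30,
                       coverage_dispersion = 0.2,
                       bisulfite_error = 0.005,
                       n_germline_variants = 500L,
                       n_somatic_variants = 100L,
                       somatic_af_range = c(0.05, 0.5),
                       n_mice = 3L,
                       sub_threshold_fraction = 0.1,
                       seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              gc_fraction = gc_fraction,
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_planted_dmrs = as.integer(n_planted_dmrs),
              dmr_host_gene_fraction = dmr_host_gene_fraction,
              dmr_length_range = as.integer(dmr_length_range),
              baseline_level_cg = baseline_level_cg,
              baseline_level_chg = baseline_level_chg,
              baseline_level_chh = baseline_level_chh,
              methylated_fraction_cg = methylated_fraction_cg,
              methylated_fraction_chg = methylated_fraction_chg,
              methylated_fraction_chh = methylated_fraction_chh,
              dmr_delta = dmr_delta,
              mean_coverage = mean_coverage,
              coverage_dispersion = coverage_dispersion,
              bisulfite_error = bisulfite_error,
              n_germline_variants = as.integer(n_germline_variants),
              n_somatic_variants = as.integer(n_somatic_variants),
              somatic_af_range = somatic_af_range,
              n_mice = as.integer(n_mice),
              sub_threshold_fraction = sub_threshold_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("gc_fraction", "baseline_level_cg", "baseline_level_chg",
                   "baseline_level_chh", "methylated_fraction_cg",
                   "methylated_fraction_chg", "methylated_fraction_chh",
                   "bisulfite_error", "sub_threshold_fraction",
                   "dmr_host_gene_fraction")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a fraction in [0, 1]")
  }
  if (cfg$n_chroms < 1) stop_field("n_chroms", "must be >= 1")
  if (cfg$n_genes < 0) stop_field("n_genes", "must be >= 0")
  if (cfg$n_planted_dmrs < 0) stop_field("n_planted_dmrs", "must be >= 0")
  if (cfg$n_mice < 1) stop_field("n_mice", "must be >= 1")
  if (length(cfg$gene_length_range) != 2 ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2] ||
      cfg$gene_length_range[1] < 1)
    stop_field("gene_length_range", "must be an increasing positive pair")
  if (length(cfg$dmr_length_range) != 2 ||
      cfg$dmr_length_range[1] > cfg$dmr_length_range[2])
    stop_field("dmr_length_range", "must be an increasing pair")
  if (cfg$dmr_length_range[1] < 40 || cfg$dmr_length_range[2] > 10000)
    stop_field("dmr_length_range", "must lie within [40, 10000] bp")
  if (abs(cfg$dmr_delta) > 1)
    stop_field("dmr_delta", "must be a signed fraction in [-1, 1]")
  if (cfg$mean_coverage <= 0) stop_field("mean_coverage", "must be > 0")
  if (cfg$coverage_dispersion < 0)
    stop_field("coverage_dispersion", "must be >= 0")
  if (length(cfg$somatic_af_range) != 2 ||
      any(cfg$somatic_af_range < 0) || any(cfg$somatic_af_range > 1) ||
      cfg$somatic_af_range[1] > cfg$somatic_af_range[2])
    stop_field("somatic_af_range", "must be an increasing pair in [0, 1]")
  if (cfg$n_genes > 0 &&
      cfg$chrom_length < cfg$gene_length_range[2] + 4000)
    stop_field("chrom_length",
               "must be >= max gene length + 4 kb of flanks")
  invisible(cfg)
}

#' Generate a random genome
#'
#' Draws each chromosome as an i.i.d. nucleotide string at the configured GC
#' fraction. Identical seeds give byte-identical sequences (and FASTA files).
#'
#' @param cfg a [sim_config()] object.
#' @param fasta_path optional path; when given, the genome is also written
#'   as FASTA.
#' @return a [Biostrings::DNAStringSet] named `chr1..chrN`.
#' @export
generate_genome <- function(cfg, fasta_path = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  gc <- cfg$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    paste(sample(names(probs), cfg$chrom_length, replace = TRUE,
                 prob = probs), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(genome, filepath = fasta_path, width = 80L)
  }
  genome
}

#' Generate non-overlapping gene models
#'
#' Places `n_genes` stranded, non-overlapping gene intervals, each at least
#' 2 kb from its chromosome ends so the 2-kb upstream/downstream zones fit,
#' and with more than 4 kb between neighbouring genes so that no position
#' belongs to the zones of two genes (flank regions never overlap another
#' gene's flanks or body).
#'
#' @param cfg a [sim_config()] object.
#' @param genome the genome from [generate_genome()].
#' @param bed_path optional path for a BED6 file (0-based half-open,
#'   name = gene id, strand column used).
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `gene_id`, sorted by coordinate.
#' @export
generate_gene_models <- function(cfg, genome, bed_path = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  chroms <- names(genome)
  lens <- Biostrings::width(genome)
  names(lens) <- chroms
  placed <- list()
  for (i in seq_len(cfg$n_genes)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      chrom <- sample(chroms, 1)
      glen <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]), 1)
      lo <- 2001L
      hi <- lens[[chrom]] - 2000L - glen + 1L
      if (hi < lo) next
      start <- sample(seq(lo, hi), 1)
      end <- start + glen - 1L
      clash <- FALSE
      margin <- 4200L  # keeps 2-kb zones of neighbouring genes disjoint
      for (g in placed) {
        if (g$chrom == chrom && start <= g$end + margin &&
            end >= g$start - margin) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        placed[[length(placed) + 1L]] <-
          list(chrom = chrom, start = start, end = end)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "gene placement failed: genome too small for %d genes", cfg$n_genes),
        call. = FALSE)
    }
  }
  if (length(placed) == 0) {
    genes <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        gene_id = character(0), stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(
      chrom = vapply(placed, `[[`, "", "chrom"),
      start = vapply(placed, `[[`, 0L, "start"),
      end = vapply(placed, `[[`, 0L, "end"),
      stringsAsFactors = FALSE)
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    rownames(genes) <- NULL
  }
  if (!is.null(bed_path)) write_gene_bed(genes, bed_path)
  genes
}

#' Write gene models as BED6
#'
#' @param genes data.frame from [generate_gene_models()] (1-based inclusive).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  if (nrow(genes) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = genes$chrom,
                    start = genes$start - 1L,
                    end = genes$end,
                    name = genes$gene_id,
                    score = 0L,
                    strand = genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED file
#'
#' Thin wrapper over [rtracklayer::import()]; converts to the package's
#' 1-based inclusive gene data.frame. The BED name column is the gene id.
#'
#' @param path a BED file.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = gr$name,
             stringsAsFactors = FALSE)
}

# Enumerate every cytosine on both strands with its sequence context.
# Cytosines within 2 bp of a chromosome end whose context cannot be resolved
# are omitted.
enumerate_cytosines <- function(genome) {
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    s <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]]
    n <- length(s)
    # plus strand: reference C, look ahead
    p <- which(s == "C")
    p <- p[p <= n - 2L]
    ctx_p <- ifelse(s[p + 1L] == "G", "CG",
                    ifelse(s[p + 2L] == "G", "CHG", "CHH"))
    # minus strand: reference G (C on the reverse strand), look behind
    m <- which(s == "G")
    m <- m[m >= 3L]
    ctx_m <- ifelse(s[m - 1L] == "C", "CG",
                    ifelse(s[m - 2L] == "C", "CHG", "CHH"))
    df <- data.frame(
      chrom = chrom,
      pos = c(p, m),
      strand = c(rep("+", length(p)), rep("-", length(m))),
      context = c(ctx_p, ctx_m),
      stringsAsFactors = FALSE)
    out[[i]] <- df[order(df$pos), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Derive the strand-aware zone interval of one gene (1-based inclusive).
zone_interval <- function(gene, zone) {
  if (zone == "body") return(c(gene$start, gene$end))
  if (gene$strand == "+") {
    if (zone == "up2k") c(gene$start - 2000L, gene$start - 1L)
    else c(gene$end + 1L, gene$end + 2000L)
  } else {
    if (zone == "up2k") c(gene$end + 1L, gene$end + 2000L)
    else c(gene$start - 2000L, gene$start - 1L)
  }
}

# Place non-overlapping DMR intervals per context across the zones of a
# host-gene subset, with a small intergenic share. Planted intervals keep
# >= 800 bp of separation so background chaining cannot fuse neighbours.
plant_dmrs <- function(cfg, genome, genes) {
  contexts <- c("CG", "CHG", "CHH")
  zones <- c("up2k", "body", "down2k", "intergenic")
  zone_prob <- c(0.3, 0.35, 0.3, 0.05)
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  n_host <- ceiling(cfg$dmr_host_gene_fraction * nrow(genes))
  hosts <- if (nrow(genes) > 0 && n_host > 0) {
    genes[sort(sample(nrow(genes), n_host)), , drop = FALSE]
  } else {
    genes[0, , drop = FALSE]
  }
  placed <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), context = character(0),
                       zone = character(0), gene_id = character(0),
                       stringsAsFactors = FALSE)
  base <- c(CG = cfg$baseline_level_cg, CHG = cfg$baseline_level_chg,
            CHH = cfg$baseline_level_chh)
  sep <- 800L
  for (ctx in contexts) {
    for (i in seq_len(cfg$n_planted_dmrs)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        zone <- sample(zones, 1, prob = zone_prob)
        if (zone != "intergenic" && nrow(hosts) == 0) zone <- "intergenic"
        dlen <- sample(seq(cfg$dmr_length_range[1], cfg$dmr_length_range[2]), 1)
        if (zone == "intergenic") {
          chrom <- sample(names(lens), 1)
          lo <- 1L
          hi <- lens[[chrom]] - dlen + 1L
          if (hi < lo) next
          start <- sample(seq(lo, hi), 1)
          end <- start + dlen - 1L
          gid <- NA_character_
          # must not touch any gene zone
          in_zone <- FALSE
          for (g in seq_len(nrow(genes))) {
            gz <- c(genes$start[g] - 2000L, genes$end[g] + 2000L)
            if (genes$chrom[g] == chrom && start <= gz[2] && end >= gz[1]) {
              in_zone <- TRUE
              break
            }
          }
          if (in_zone) next
        } else {
          g <- hosts[sample(nrow(hosts), 1), , drop = FALSE]
          gl <- list(chrom = g$chrom, start = g$start, end = g$end,
                     strand = g$strand)
          zi <- zone_interval(gl, zone)
          if (zi[2] - zi[1] + 1L < dlen) next
          start <- sample(seq(zi[1], zi[2] - dlen + 1L), 1)
          end <- start + dlen - 1L
          chrom <- g$chrom
          gid <- g$gene_id
        }
        clash <- any(placed$chrom == chrom &
                       start <= placed$end + sep &
                       end >= placed$start - sep)
        if (!clash) {
          lvl0 <- base[[ctx]]
          lvl1 <- min(1, max(0, lvl0 + cfg$dmr_delta))
          placed <- rbind(placed, data.frame(
            chrom = chrom, start = start, end = end, context = ctx,
            zone = zone, gene_id = gid, level_control = lvl0,
            level_treated = lvl1, stringsAsFactors = FALSE))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("DMR placement failed after bounded retries; ",
             "reduce n_planted_dmrs or enlarge the genome", call. = FALSE)
      }
    }
  }
  rownames(placed) <- NULL
  placed
}

#' Simulate two-condition methylomes with planted DMRs
#'
#' Emits one cytosine record per genomic cytosine (both strands) for a
#' control and a treated sample. Background cytosines are methylated with
#' the per-context `methylated_fraction` (at the context baseline level) and
#' are otherwise unmethylated; inside planted DMRs every cytosine of the
#' DMR's context is methylated at the baseline level in the control sample
#' and at `baseline + dmr_delta` in the treated sample. Coverage is
#' negative-binomial (Poisson when `coverage_dispersion = 0`); methylated
#' read counts are binomial at the site's true level, with the bisulfite
#' non-conversion rate injected as false-positive methylation.
#'
#' @param cfg a [sim_config()] object.
#' @param genome genome from [generate_genome()].
#' @param genes gene models from [generate_gene_models()].
#' @param outdir optional directory; when given, `control.cx.tsv` and
#'   `treated.cx.tsv` cytosine reports are written there.
#' @return list with elements `control`, `treated` (cytosine record
#'   data.frames) and `truth` (the planted-DMR table: chrom, start, end,
#'   context, zone, gene_id, level_control, level_treated).
#' @export
simulate_methylomes <- function(cfg, genome, genes, outdir = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  sites <- enumerate_cytosines(genome)
  truth <- plant_dmrs(cfg, genome, genes)
  base <- c(CG = cfg$baseline_level_cg, CHG = cfg$baseline_level_chg,
            CHH = cfg$baseline_level_chh)
  mfrac <- c(CG = cfg$methylated_fraction_cg,
             CHG = cfg$methylated_fraction_chg,
             CHH = cfg$methylated_fraction_chh)
  n <- nrow(sites)
  is_meth <- runif(n) < mfrac[sites$context]
  lvl_ctrl <- ifelse(is_meth, base[sites$context], 0)
  lvl_trt <- lvl_ctrl
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      idx <- sites$chrom == truth$chrom[i] &
        sites$pos >= truth$start[i] & sites$pos <= truth$end[i] &
        sites$context == truth$context[i]
      lvl_ctrl[idx] <- truth$level_control[i]
      lvl_trt[idx] <- truth$level_treated[i]
    }
  }
  draw_sample <- function(lvl) {
    cov <- if (cfg$coverage_dispersion > 0) {
      rnbinom(n, size = 1 / cfg$coverage_dispersion, mu = cfg$mean_coverage)
    } else {
      rpois(n, cfg$mean_coverage)
    }
    p_obs <- lvl + (1 - lvl) * cfg$bisulfite_error
    meth <- rbinom(n, cov, p_obs)
    data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
               context = sites$context, meth_count = meth,
               total_count = cov, stringsAsFactors = FALSE)
  }
  control <- draw_sample(lvl_ctrl)
  treated <- draw_sample(lvl_trt)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_cx_report(control, file.path(outdir, "control.cx.tsv"))
    write_cx_report(treated, file.path(outdir, "treated.cx.tsv"))
  }
  list(control = control, treated = treated, truth = truth)
}

# Build one variant at a genomic position: SNP or short insertion/deletion,
# alleles taken from the reference sequence.
make_variant_alleles <- function(seqchar, pos, want_indel) {
  refb <- seqchar[pos]
  if (!want_indel) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    return(list(ref = refb, alt = alt, vtype = "SNP"))
  }
  if (runif(1) < 0.5) {  # insertion
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                        replace = TRUE), collapse = "")
    list(ref = refb, alt = paste0(refb, ins), vtype = "InDel")
  } else {               # deletion
    dlen <- sample(1:3, 1)
    ref <- paste(seqchar[pos:(pos + dlen)], collapse = "")
    list(ref = ref, alt = refb, vtype = "InDel")
  }
}

#' Simulate paired mucosa/muscularis variant tables
#'
#' For each mouse, draws germline variants present in both tissues (allele
#' fraction 0.5 or 1.0) and somatic variants present only in the mucosa
#' (allele fraction drawn from `somatic_af_range`), as a mixture of SNPs and
#' InDels with DP/MQ INFO fields populated. A configurable fraction of the
#' somatic records is written deliberately below the filter thresholds
#' (MQ <= 20 or DP <= 4).
#'
#' @param cfg a [sim_config()] object.
#' @param genome genome from [generate_genome()].
#' @param outdir optional directory; when given, `mucosa_<i>.vcf` and
#'   `muscularis_<i>.vcf` are written per mouse.
#' @return list with per-mouse elements `mucosa` and `muscularis` (variant
#'   record data.frames) and `truth`: `germline_keys`, `somatic_keys`,
#'   `sub_threshold_keys` per mouse (keys are `chrom:pos:ref:alt`).
#' @export
simulate_variant_tables <- function(cfg, genome, outdir = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 3L)
  chroms <- names(genome)
  lens <- Biostrings::width(genome)
  names(lens) <- chroms
  seqchars <- lapply(seq_along(genome), function(i)
    strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1]])
  names(seqchars) <- chroms

  mice <- vector("list", cfg$n_mice)
  truth <- list(germline_keys = list(), somatic_keys = list(),
                sub_threshold_keys = list())
  for (m in seq_len(cfg$n_mice)) {
    n_total <- cfg$n_germline_variants + cfg$n_somatic_variants
    # distinct positions, away from chromosome ends so deletions fit
    pos_pool <- data.frame(chrom = character(0), pos = integer(0))
    for (try in seq_len(50L)) {
      chrom <- sample(chroms, n_total, replace = TRUE)
      pos <- vapply(chrom, function(cc) sample(5:(lens[[cc]] - 5L), 1), 0L)
      pos_pool <- unique(data.frame(chrom = chrom, pos = pos,
                                    stringsAsFactors = FALSE))
      if (nrow(pos_pool) >= n_total) break
    }
    if (nrow(pos_pool) < n_total) {
      stop("variant placement failed: could not draw distinct positions",
           call. = FALSE)
    }
    pos_pool <- pos_pool[seq_len(n_total), , drop = FALSE]
    want_indel <- runif(n_total) < 0.3
    alle <- lapply(seq_len(n_total), function(i)
      make_variant_alleles(seqchars[[pos_pool$chrom[i]]], pos_pool$pos[i],
                           want_indel[i]))
    rec <- data.frame(
      chrom = pos_pool$chrom,
      pos = pos_pool$pos,
      ref = vapply(alle, `[[`, "", "ref"),
      alt = vapply(alle, `[[`, "", "alt"),
      vtype = vapply(alle, `[[`, "", "vtype"),
      stringsAsFactors = FALSE)
    rec$depth <- rpois(n_total, 100) + 1L
    rec$mapping_quality <- pmin(60L, pmax(25L, round(rnorm(n_total, 50, 6))))
    is_germ <- seq_len(n_total) <= cfg$n_germline_variants
    rec$allele_fraction <- ifelse(
      is_germ, sample(c(0.5, 1.0), n_total, replace = TRUE),
      runif(n_total, cfg$somatic_af_range[1], cfg$somatic_af_range[2]))

    som_idx <- which(!is_germ)
    n_sub <- round(cfg$sub_threshold_fraction * length(som_idx))
    sub_idx <- if (n_sub > 0) sample(som_idx, n_sub) else integer(0)
    for (i in sub_idx) {
      if (runif(1) < 0.5) rec$mapping_quality[i] <- sample(5:20, 1)
      else rec$depth[i] <- sample(1:4, 1)
    }

    germline <- rec[is_germ, , drop = FALSE]
    somatic <- rec[!is_germ, , drop = FALSE]
    mucosa <- rbind(germline, somatic)
    mucosa <- mucosa[order(mucosa$chrom, mucosa$pos), , drop = FALSE]
    muscularis <- germline[order(germline$chrom, germline$pos), , drop = FALSE]
    rownames(mucosa) <- rownames(muscularis) <- NULL
    mice[[m]] <- list(mucosa = mucosa, muscularis = muscularis)
    truth$germline_keys[[m]] <- sort(variant_key(germline))
    truth$somatic_keys[[m]] <- sort(variant_key(somatic))
    truth$sub_threshold_keys[[m]] <-
      sort(variant_key(rec[sub_idx, , drop = FALSE]))
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_variant_vcf(mucosa, file.path(outdir, sprintf("mucosa_%d.vcf", m)),
                        genome)
      write_variant_vcf(muscularis,
                        file.path(outdir, sprintf("muscularis_%d.vcf", m)),
                        genome)
    }
  }
  names(mice) <- paste0("mouse", seq_len(cfg$n_mice))
  list(mice = mice, truth = truth)
}

#' Write variant records as VCF v4.2
#'
#' Minimal single-sample-free VCF with `DP`, `MQ` and `AF` INFO keys, as
#' produced by the simulator.
#'
#' @param records variant record data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `mapping_quality`, `allele_fraction`).
#' @param path output path.
#' @param genome optional genome used to emit `##contig` header lines.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(records, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=inflammeth-simulator")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          Biostrings::width(genome)))
  }
  hdr <- c(hdr,
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=MQ,Number=1,Type=Integer,Description="Mapping quality">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(records) == 0) character(0) else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;MQ=%d;AF=%.4f",
    records$chrom, records$pos, records$ref, records$alt,
    records$depth, records$mapping_quality, records$allele_fraction)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a gene-to-pathway map with one designated enriched pathway
#'
#' Every gene is assigned at least one pathway at random; one designated
#' pathway additionally contains a configurable fraction (default 90%) of
#' the genes hosting planted DMRs, plus a small random background, so that
#' hypergeometric enrichment of DMR genes has a known positive control.
#'
#' @param cfg a [sim_config()] object.
#' @param genes gene models data.frame.
#' @param dmr_gene_ids character vector of gene ids hosting planted DMRs.
#' @param path optional TSV output path (`gene_id`, `pathway_id`,
#'   `pathway_name`).
#' @param n_pathways number of pathways.
#' @param designated_fraction fraction of DMR-hosting genes placed in the
#'   designated pathway.
#' @return list with `map` (the data.frame) and `enriched_pathway_id`.
#' @export
write_pathway_map <- function(cfg, genes, dmr_gene_ids = character(0),
                              path = NULL, n_pathways = 8L,
                              designated_fraction = 0.9) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 4L)
  pid <- sprintf("path%02d", seq_len(n_pathways))
  pname <- sprintf("Synthetic pathway %02d", seq_len(n_pathways))
  designated <- pid[1]
  if (nrow(genes) == 0) {
    map <- data.frame(gene_id = character(0), pathway_id = character(0),
                      pathway_name = character(0), stringsAsFactors = FALSE)
  } else {
    # base assignment: every gene gets one non-designated pathway
    base_p <- sample(pid[-1], nrow(genes), replace = TRUE)
    map <- data.frame(gene_id = genes$gene_id, pathway_id = base_p,
                      stringsAsFactors = FALSE)
    dmr_genes <- intersect(unique(dmr_gene_ids), genes$gene_id)
    n_in <- ceiling(designated_fraction * length(dmr_genes))
    chosen <- if (n_in > 0) sample(dmr_genes, n_in) else character(0)
    other <- setdiff(genes$gene_id, dmr_genes)
    n_bg <- max(1L, round(0.1 * length(other)))
    bg <- if (length(other) > 0) sample(other, min(n_bg, length(other)))
          else character(0)
    extra <- data.frame(gene_id = c(chosen, bg),
                        pathway_id = designated, stringsAsFactors = FALSE)
    map <- unique(rbind(map, extra))
    map$pathway_name <- pname[match(map$pathway_id, pid)]
    map <- map[order(map$pathway_id, map$gene_id), , drop = FALSE]
    rownames(map) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(map, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  list(map = map, enriched_pathway_id = designated)
}

#' Read a gene-to-pathway map
#'
#' @param path TSV with columns `gene_id`, `pathway_id`, `pathway_name`.
#' @return the map data.frame.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "pathway_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pathway map lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Run every generator and assemble the full synthetic scenario
#'
#' Convenience wrapper producing the genome, gene models, two-condition
#' methylomes, paired variant tables and the pathway map, together with the
#' combined ground truth used by the recovery oracles. When `outdir` is
#' given, all standard files (FASTA, BED, cytosine reports, VCFs, pathway
#' TSV, truth tables) are written there.
#'
#' @param cfg a [sim_config()] object.
#' @param outdir optional output directory.
#' @return list with `genome`, `genes`, `methylomes`, `variants`,
#'   `pathways`, and `truth` (planted DMRs, variant keys per mouse,
#'   enriched pathway id).
#' @export
simulate_all <- function(cfg, outdir = NULL) {
  validate_sim_config(cfg)
  fasta <- if (is.null(outdir)) NULL else file.path(outdir, "genome.fa")
  bed <- if (is.null(outdir)) NULL else file.path(outdir, "genes.bed")
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  genome <- generate_genome(cfg, fasta_path = fasta)
  genes <- generate_gene_models(cfg, genome, bed_path = bed)
  meth <- simulate_methylomes(cfg, genome, genes, outdir = outdir)
  vars <- simulate_variant_tables(cfg, genome, outdir = outdir)
  dmr_genes <- meth$truth$gene_id[!is.na(meth$truth$gene_id)]
  pmap <- write_pathway_map(
    cfg, genes, dmr_gene_ids = dmr_genes,
    path = if (is.null(outdir)) NULL else file.path(outdir, "pathways.tsv"))
  truth <- list(planted_dmrs = meth$truth,
                germline_keys = vars$truth$germline_keys,
                somatic_keys = vars$truth$somatic_keys,
                sub_threshold_keys = vars$truth$sub_threshold_keys,
                enriched_pathway_id = pmap$enriched_pathway_id)
  if (!is.null(outdir)) {
    utils::write.table(meth$truth, file.path(outdir, "truth_dmrs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tv <- do.call(rbind, lapply(seq_along(vars$truth$somatic_keys),
      function(m) {
        rbind(
          data.frame(mouse = m, key = vars$truth$germline_keys[[m]],
                     class = "germline", stringsAsFactors = FALSE),
          data.frame(mouse = m, key = vars$truth$somatic_keys[[m]],
                     class = "somatic", stringsAsFactors = FALSE),
          if (length(vars$truth$sub_threshold_keys[[m]]) > 0)
            data.frame(mouse = m, key = vars$truth$sub_threshold_keys[[m]],
                       class = "sub_threshold", stringsAsFactors = FALSE))
      }))
    utils::write.table(tv, file.path(outdir, "truth_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(pmap$enriched_pathway_id,
               file.path(outdir, "truth_pathway.txt"))
  }
  list(genome = genome, genes = genes,
       methylomes = meth[c("control", "treated")],
       variants = vars$mice, pathways = pmap$map, truth = truth)
}
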