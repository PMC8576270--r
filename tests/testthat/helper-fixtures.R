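# Shared fixtures: a small configuration for fast unit tests and builders
# for hand-crafted cytosine / variant records.

tiny_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_chroms = 1L, chrom_length = 50000L, n_genes = 3L,
                   gene_length_range = c(2000L, 4000L), n_planted_dmrs = 2L,
                   n_germline_variants = 60L, n_somatic_variants = 20L,
                   sub_threshold_fraction = 0, n_mice = 2L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Build a cytosine record data.frame from parallel vectors.
cx_records <- function(pos, meth, total, chrom = "chr1", strand = "+",
                       context = "CG", methylated = NULL) {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                   strand = rep_len(strand, n),
                   context = rep_len(context, n),
                   meth_count = as.integer(rep_len(meth, n)),
                   total_count = as.integer(rep_len(total, n)),
                   stringsAsFactors = FALSE)
  if (!is.null(methylated)) df$methylated <- methylated
  df
}

# Minimal gene model table.
gene_table <- function(start, end, strand = "+", chrom = "chr1",
                       gene_id = NULL) {
  n <- max(length(start), length(end), length(strand))
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), strand = rep_len(strand, n),
             gene_id = gene_id %||% sprintf("g%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force classifier over an explicit trimer, used as the
# oracle for sequence-context classification. Plus strand reads the trimer
# left to right from its first base; minus strand reads the reverse
# complement from its last base.
oracle_context <- function(trimer, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(trimer, "", fixed = TRUE)[[1]]
  if (strand == "-") b <- rev(unname(comp[b]))
  if (b[1] != "C") return(NA_character_)
  if (b[2] == "G") "CG" else if (b[3] == "G") "CHG" else "CHH"
}

# Exact hypergeometric upper tail by direct enumeration, independent of
# stats::phyper.
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
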