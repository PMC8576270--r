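# Site-level and summary methylome statistics: sequence-context
# classification, binomial methylated-cytosine calling, mC-type ratios,
# chromosome-level mC density, 9-bp context matrices around CG sites, and
# strand-aware metagene profiles.

#' Read a cytosine report
#'
#' Reads the package's cytosine report dialect: a TSV with columns `chrom`,
#' `pos` (1-based), `strand` (`+`/`-`), `context` (`CG`/`CHG`/`CHH`),
#' `meth_count`, `unmeth_count`. Internally records carry `total_count`
#' (`meth + unmeth`) instead of the unmethylated count.
#'
#' @param path TSV path.
#' @return cytosine record data.frame.
#' @export
read_cx_report <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand",
                                                         "context")))
  df <- as.data.frame(dt)
  need <- c("chrom", "pos", "strand", "context", "meth_count", "unmeth_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("cytosine report lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$total_count <- df$meth_count + df$unmeth_count
  df$unmeth_count <- NULL
  check_cx_records(df, arg = path)
}

#' Write a cytosine report
#'
#' Inverse of [read_cx_report()]: writes `meth_count` and `unmeth_count`
#' columns.
#'
#' @param records cytosine record data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_cx_report <- function(records, path) {
  check_cx_records(records)
  out <- data.frame(chrom = records$chrom, pos = records$pos,
                    strand = records$strand, context = records$context,
                    meth_count = records$meth_count,
                    unmeth_count = records$total_count - records$meth_count)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Classify the sequence context of a cytosine
#'
#' Strand-aware classification into CG / CHG / CHH: on the forward strand a
#' cytosine at `pos` is CG when the next reference base is G, CHG when the
#' base after next is G, and CHH otherwise; on the reverse strand the same
#' logic runs on the reverse complement (reference G at `pos`, looking
#' leftwards). Returns `NA` when the base at `pos` does not read as C on the
#' requested strand, or when fewer than 2 bp of lookahead remain before the
#' chromosome end.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param chrom chromosome name.
#' @param pos 1-based position(s); vectorized.
#' @param strand `"+"` or `"-"`, recycled against `pos`.
#' @return character vector in `{"CG","CHG","CHH", NA}`.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' classify_context(g, "chr1", 2, "+")  # "CG"
classify_context <- function(genome, chrom, pos, strand) {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  s <- strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (any(pos < 1 | pos > n)) {
    stop("position outside chromosome ", chrom, call. = FALSE)
  }
  k <- max(length(pos), length(strand))
  pos <- rep_len(pos, k)
  strand <- rep_len(strand, k)
  out <- rep(NA_character_, k)
  for (i in seq_len(k)) {
    p <- pos[i]
    if (strand[i] == "+") {
      if (s[p] != "C") next
      if (p + 2L > n) next
      out[i] <- if (s[p + 1L] == "G") "CG"
                else if (s[p + 2L] == "G") "CHG" else "CHH"
    } else {
      if (s[p] != "G") next
      if (p - 2L < 1L) next
      out[i] <- if (s[p - 1L] == "C") "CG"
                else if (s[p - 2L] == "C") "CHG" else "CHH"
    }
  }
  out
}

#' Call methylated cytosines by binomial test
#'
#' Flags a cytosine as methylated when its methylated read count is
#' incompatible with pure bisulfite non-conversion error: one-sided binomial
#' tail `P(X >= meth_count | total_count, error_rate)`, Benjamini-Hochberg
#' adjusted across all tested sites, at significance `alpha`. Sites with
#' coverage below `min_coverage` (default 4) are never tested nor flagged.
#'
#' @param records cytosine record data.frame.
#' @param error_rate bisulfite non-conversion rate in (0,1).
#' @param alpha BH-adjusted significance threshold in (0,1).
#' @param min_coverage minimum total reads for a site to be testable.
#' @return `records` with columns `p_meth`, `q_meth` (NA for untested
#'   sites) and logical `methylated` appended.
#' @export
call_methylated_sites <- function(records, error_rate = 0.005, alpha = 0.05,
                                  min_coverage = 4L) {
  check_cx_records(records)
  if (error_rate <= 0 || error_rate >= 1) {
    stop_field("error_rate", "must be in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop_field("alpha", "must be in (0, 1)")
  n <- nrow(records)
  p <- rep(NA_real_, n)
  q <- rep(NA_real_, n)
  testable <- records$total_count >= min_coverage
  if (any(testable)) {
    p[testable] <- binom_upper_tail(records$meth_count[testable],
                                    records$total_count[testable],
                                    error_rate)
    q[testable] <- p.adjust(p[testable], method = "BH")
  }
  records$p_meth <- p
  records$q_meth <- q
  records$methylated <- !is.na(q) & q <= alpha & records$meth_count > 0
  records
}

#' Summarize a methylome
#'
#' Counts methylated cytosines per sequence context, their shares of total
#' mC, mean methylation level per context and per chromosome (levels over
#' covered sites only).
#'
#' @param records flagged records from [call_methylated_sites()].
#' @return object of class `methylome_summary`: list with `contexts`
#'   (context, n_mc, share, mean_level), `chroms` (chrom, mean_level) and
#'   `n_mc_total`.
#' @export
summarize_methylome <- function(records) {
  if (!"methylated" %in% names(records)) {
    stop("records must first be flagged by call_methylated_sites()",
         call. = FALSE)
  }
  contexts <- c("CG", "CHG", "CHH")
  covered <- records$total_count > 0
  lvl <- ifelse(covered, records$meth_count / records$total_count, NA_real_)
  n_mc <- vapply(contexts, function(cx)
    sum(records$methylated & records$context == cx), 0L)
  total <- sum(n_mc)
  share <- if (total > 0) n_mc / total else rep(0, 3)
  mean_level <- vapply(contexts, function(cx) {
    v <- lvl[records$context == cx & covered]
    if (length(v) == 0) NA_real_ else mean(v)
  }, 0)
  chroms <- sort(unique(records$chrom))
  chrom_level <- vapply(chroms, function(cc) {
    v <- lvl[records$chrom == cc & covered]
    if (length(v) == 0) NA_real_ else mean(v)
  }, 0)
  out <- list(contexts = data.frame(context = contexts, n_mc = n_mc,
                                    share = share, mean_level = mean_level,
                                    row.names = NULL),
              chroms = data.frame(chrom = chroms, mean_level = chrom_level,
                                  row.names = NULL),
              n_mc_total = total)
  class(out) <- "methylome_summary"
  out
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("Methylome summary:", x$n_mc_total, "methylated cytosines\n")
  print(x$contexts, row.names = FALSE)
  invisible(x)
}

#' Chromosome-level mC density
#'
#' Counts flagged methylated cytosines in fixed windows tiling each
#' chromosome left to right (0-based half-open windows).
#'
#' @param records flagged records from [call_methylated_sites()].
#' @param window window size in bp (> 0).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent, windows run to the last observed record position.
#' @return data.frame `chrom`, `window_start` (0-based), `window_end`,
#'   `n_mc`.
#' @export
chromosome_density <- function(records, window = 1000000L,
                               chrom_lengths = NULL) {
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop_field("window", "must be a positive number of bp")
  }
  window <- as.integer(window)
  if (!"methylated" %in% names(records)) {
    stop("records must first be flagged by call_methylated_sites()",
         call. = FALSE)
  }
  chroms <- sort(unique(records$chrom))
  out <- lapply(chroms, function(cc) {
    sub <- records[records$chrom == cc, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && cc %in% names(chrom_lengths)) {
      as.integer(chrom_lengths[[cc]])
    } else {
      max(sub$pos)
    }
    n_win <- max(1L, as.integer(ceiling(len / window)))
    bins <- (sub$pos[sub$methylated] - 1L) %/% window
    counts <- tabulate(bins + 1L, nbins = n_win)
    data.frame(chrom = cc,
               window_start = (seq_len(n_win) - 1L) * window,
               window_end = pmin(seq_len(n_win) * window, len),
               n_mc = counts, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Extract the -4..+4 flank around sites, strand-aware (reverse complement on
# the minus strand). Sites within 4 bp of a chromosome end are skipped.
flank_matrix <- function(genome, sites) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 4, ncol = 9,
                   dimnames = list(bases, as.character(-4:4)))
  skipped <- 0L
  for (cc in unique(sites$chrom)) {
    s <- as.character(genome[[cc]])
    n <- nchar(s)
    sub <- sites[sites$chrom == cc, , drop = FALSE]
    keep <- sub$pos >= 5L & sub$pos <= n - 4L
    skipped <- skipped + sum(!keep)
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) == 0) next
    fl <- substring(s, sub$pos - 4L, sub$pos + 4L)
    minus <- sub$strand == "-"
    if (any(minus)) {
      fl[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fl[minus])))
    }
    mat <- do.call(rbind, strsplit(fl, "", fixed = TRUE))
    for (j in 1:9) {
      tab <- table(factor(mat[, j], levels = bases))
      counts[, j] <- counts[, j] + as.integer(tab)
    }
  }
  freq <- counts
  tot <- colSums(counts)
  for (j in 1:9) if (tot[j] > 0) freq[, j] <- counts[, j] / tot[j]
  list(freq = freq, n_sites = if (length(tot) > 0) max(tot) else 0L,
       skipped = skipped)
}

#' 9-bp sequence context around CG cytosines
#'
#' Base frequencies at offsets -4..+4 around methylated CG cytosines
#' (mCG) and, for comparison, around all CG cytosines, strand-aware
#' (minus-strand flanks are reverse-complemented so the center base always
#' reads C). Sites within 4 bp of a chromosome end are skipped and counted.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param records flagged records from [call_methylated_sites()].
#' @return list with `mcg` and `cg`, each a 4x9 frequency matrix (rows
#'   A/C/G/T, columns offsets -4..+4; columns sum to 1), plus per-matrix
#'   `skipped` counts.
#' @export
context_matrix_9bp <- function(genome, records) {
  if (!"methylated" %in% names(records)) {
    stop("records must first be flagged by call_methylated_sites()",
         call. = FALSE)
  }
  cg <- records[records$context == "CG", , drop = FALSE]
  mcg <- cg[cg$methylated, , drop = FALSE]
  a <- flank_matrix(genome, mcg)
  b <- flank_matrix(genome, cg)
  list(mcg = a$freq, cg = b$freq,
       skipped = c(mcg = a$skipped, cg = b$skipped))
}

#' Metagene methylation profile
#'
#' Averages site methylation levels in fixed bins across aligned gene
#' regions: `flank/bin` upstream bins (20 for 2 kb at 100 bp), `body_bins`
#' equal fractions of the gene body, and `flank/bin` downstream bins, all in
#' 5'->3' gene orientation (strand-aware; the first upstream bin is the
#' farthest from the TSS). Bin values are per-gene means of site levels,
#' averaged across genes; bins with no covered site in a gene are excluded
#' from that average rather than zero-filled. Genes shorter than
#' `body_bins` bp are skipped with a warning.
#'
#' @param records cytosine record data.frame (coverage > 0 sites are used).
#' @param genes gene models data.frame (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`, 1-based inclusive).
#' @param flank flank width in bp; must be divisible by `bin`.
#' @param bin flank bin width in bp.
#' @param body_bins number of equal-fraction bins across the gene body.
#' @return object of class `metagene_profile`: data.frame with `context`,
#'   `segment` (`upstream`/`body`/`downstream`), `bin` (0-based within the
#'   full profile), `mean_level`, `n_genes`; geometry in attributes.
#' @export
metagene_profile <- function(records, genes, flank = 2000L, bin = 100L,
                             body_bins = 20L) {
  check_cx_records(records)
  if (flank %% bin != 0) {
    stop_field("flank", "must be divisible by bin")
  }
  nf <- as.integer(flank / bin)
  nb <- as.integer(body_bins)
  ntot <- 2L * nf + nb
  contexts <- c("CG", "CHG", "CHH")
  sum_means <- matrix(0, nrow = length(contexts), ncol = ntot,
                      dimnames = list(contexts, NULL))
  n_genes <- matrix(0L, nrow = length(contexts), ncol = ntot,
                    dimnames = list(contexts, NULL))
  covered <- records[records$total_count > 0, , drop = FALSE]
  covered$level <- covered$meth_count / covered$total_count
  skipped <- character(0)
  for (g in seq_len(nrow(genes))) {
    gs <- genes$start[g]; ge <- genes$end[g]
    glen <- ge - gs + 1L
    if (glen < nb) {
      skipped <- c(skipped, genes$gene_id[g])
      next
    }
    sub <- covered[covered$chrom == genes$chrom[g] &
                     covered$pos >= gs - flank &
                     covered$pos <= ge + flank, , drop = FALSE]
    if (nrow(sub) == 0) next
    pos <- sub$pos
    if (genes$strand[g] == "+") {
      idx <- ifelse(pos < gs,
                    (pos - (gs - flank)) %/% bin,
             ifelse(pos > ge,
                    nf + nb + (pos - ge - 1L) %/% bin,
                    nf + pmin(nb - 1L, ((pos - gs) * nb) %/% glen)))
    } else {
      idx <- ifelse(pos > ge,
                    (ge + flank - pos) %/% bin,
             ifelse(pos < gs,
                    nf + nb + (gs - 1L - pos) %/% bin,
                    nf + pmin(nb - 1L, ((ge - pos) * nb) %/% glen)))
    }
    for (cx in contexts) {
      m <- sub$context == cx
      if (!any(m)) next
      bm <- tapply(sub$level[m], idx[m], mean)
      cols <- as.integer(names(bm)) + 1L
      sum_means[cx, cols] <- sum_means[cx, cols] + as.numeric(bm)
      n_genes[cx, cols] <- n_genes[cx, cols] + 1L
    }
  }
  if (length(skipped) > 0) {
    warning(length(skipped), " gene(s) shorter than body_bins bp skipped: ",
            paste(head(skipped, 5), collapse = ", "), call. = FALSE)
  }
  segment <- c(rep("upstream", nf), rep("body", nb), rep("downstream", nf))
  out <- do.call(rbind, lapply(contexts, function(cx) {
    data.frame(context = cx, segment = segment, bin = seq_len(ntot) - 1L,
               mean_level = ifelse(n_genes[cx, ] > 0,
                                   sum_means[cx, ] / n_genes[cx, ],
                                   NA_real_),
               n_genes = n_genes[cx, ], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "flank_bins") <- nf
  attr(out, "body_bins") <- nb
  attr(out, "bin_width") <- as.integer(bin)
  attr(out, "skipped_genes") <- skipped
  class(out) <- c("metagene_profile", "data.frame")
  out
}
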