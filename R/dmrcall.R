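# Six-criterion DMR identification between two samples, per sequence
# context: (1) >= min_meth_sites methylated cytosines in at least one
# sample; (2) coverage >= min_site_coverage in both samples at every member
# site, and >= min_meth_reads methylated reads wherever a site is flagged;
# (3) region length within [min_len, max_len]; (4) adjacent methylated
# sites closer than max_gap; (5) fold change of the pooled methylation
# level > min_fold; (6) Pearson chi-square p <= max_p on the pooled 2x2
# read table.

#' DMR caller configuration
#'
#' All six criteria are configurable; the defaults are the thresholds of the
#' stringent region definition this caller implements (5 methylated sites,
#' 10x coverage, 4 methylated reads, 40 bp - 10 kb length window, 200 bp
#' maximum gap, fold change > 2, chi-square p <= 0.05). Site-level
#' methylation calling parameters (`error_rate`, `alpha`, `min_call_coverage`)
#' are those of [call_methylated_sites()] and are used when unflagged
#' records are handed to [call_dmrs()].
#'
#' @param min_meth_sites minimum flagged cytosines in at least one sample.
#' @param min_site_coverage minimum total reads per member site, both
#'   samples.
#' @param min_meth_reads minimum methylated reads at a flagged site in the
#'   sample where it is flagged.
#' @param min_len,max_len region length window in bp.
#' @param max_gap maximum distance between adjacent methylated sites; a gap
#'   of `max_gap` or more breaks the chain.
#' @param min_fold minimum fold change (strict) of pooled levels.
#' @param max_p maximum Pearson chi-square p-value.
#' @param bh_correct apply Benjamini-Hochberg across candidate regions
#'   before the `max_p` cut; off by default (the region p-value is used
#'   raw).
#' @param error_rate,alpha,min_call_coverage site-calling parameters, see
#'   [call_methylated_sites()].
#' @return object of class `dmr_config`.
#' @export
dmr_config <- function(min_meth_sites = 5L, min_site_coverage = 10L,
                       min_meth_reads = 4L, min_len = 40L, max_len = 10000L,
                       max_gap = 200L, min_fold = 2, max_p = 0.05,
                       bh_correct = FALSE, error_rate = 0.005, alpha = 0.05,
                       min_call_coverage = 4L) {
  cfg <- list(min_meth_sites = as.integer(min_meth_sites),
              min_site_coverage = as.integer(min_site_coverage),
              min_meth_reads = as.integer(min_meth_reads),
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              max_gap = as.integer(max_gap), min_fold = min_fold,
              max_p = max_p, bh_correct = isTRUE(bh_correct),
              error_rate = error_rate, alpha = alpha,
              min_call_coverage = as.integer(min_call_coverage))
  if (cfg$min_len > cfg$max_len) {
    stop_field("min_len", "must not exceed max_len")
  }
  for (f in c("min_meth_sites", "min_site_coverage", "min_meth_reads",
              "min_len", "max_len", "max_gap")) {
    if (cfg[[f]] < 1) stop_field(f, "must be a positive count")
  }
  if (cfg$min_fold < 1) stop_field("min_fold", "must be >= 1")
  if (cfg$max_p <= 0 || cfg$max_p > 1) stop_field("max_p", "must be in (0, 1]")
  class(cfg) <- "dmr_config"
  cfg
}

ensure_flagged <- function(records, cfg) {
  if (!"methylated" %in% names(records)) {
    records <- call_methylated_sites(records, error_rate = cfg$error_rate,
                                     alpha = cfg$alpha,
                                     min_coverage = cfg$min_call_coverage)
  }
  records
}

#' Build candidate DMR regions by chaining methylated sites
#'
#' Seed sites are cytosines of the requested context that are flagged
#' methylated in at least one sample, have coverage of at least
#' `min_site_coverage` in both samples, and carry at least `min_meth_reads`
#' methylated reads in each sample where they are flagged. Consecutive seed
#' sites closer than `max_gap` are chained; maximal chains whose span lies
#' within the length window become candidate regions (longer or shorter
#' chains are discarded whole, not split).
#'
#' @param sample_a,sample_b cytosine record data.frames (flagged or raw;
#'   raw records are flagged with the config's site-calling parameters).
#' @param cfg a [dmr_config()].
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @return list of candidate regions; each has `chrom`, `start`, `end`,
#'   `context` and `sites`, a merged per-site data.frame with `_a`/`_b`
#'   count columns and effective flag columns `flag_a`, `flag_b`.
#' @export
build_candidate_regions <- function(sample_a, sample_b, cfg = dmr_config(),
                                    context = "CG") {
  sample_a <- ensure_flagged(check_cx_records(sample_a, "sample_a"), cfg)
  sample_b <- ensure_flagged(check_cx_records(sample_b, "sample_b"), cfg)
  if (nrow(sample_a) > 0 && nrow(sample_b) > 0 &&
      length(intersect(unique(sample_a$chrom), unique(sample_b$chrom))) == 0) {
    stop("samples share no chromosomes; were they aligned to the same genome?",
         call. = FALSE)
  }
  a <- sample_a[sample_a$context == context,
                c("chrom", "pos", "strand", "context", "meth_count",
                  "total_count", "methylated")]
  b <- sample_b[sample_b$context == context,
                c("chrom", "pos", "strand", "context", "meth_count",
                  "total_count", "methylated")]
  m <- merge(a, b, by = c("chrom", "pos", "strand", "context"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) return(list())
  # effective flags: criterion 2's methylated-read floor applies in the
  # sample where the site is flagged
  m$flag_a <- m$methylated_a & m$meth_count_a >= cfg$min_meth_reads
  m$flag_b <- m$methylated_b & m$meth_count_b >= cfg$min_meth_reads
  seed <- (m$flag_a | m$flag_b) &
    m$total_count_a >= cfg$min_site_coverage &
    m$total_count_b >= cfg$min_site_coverage
  m <- m[seed, , drop = FALSE]
  if (nrow(m) == 0) return(list())
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  new_chain <- c(TRUE, diff(m$pos) >= cfg$max_gap |
                   m$chrom[-1] != m$chrom[-nrow(m)])
  chain_id <- cumsum(new_chain)
  out <- list()
  for (id in unique(chain_id)) {
    sites <- m[chain_id == id, , drop = FALSE]
    span <- sites$pos[nrow(sites)] - sites$pos[1] + 1L
    if (span < cfg$min_len || span > cfg$max_len) next
    out[[length(out) + 1L]] <- list(chrom = sites$chrom[1],
                                    start = sites$pos[1],
                                    end = sites$pos[nrow(sites)],
                                    context = context, sites = sites)
  }
  out
}

#' Evaluate one candidate region against the remaining DMR criteria
#'
#' Applies the methylated-site count, fold-change and chi-square criteria to
#' a candidate from [build_candidate_regions()]. Sample levels are pooled
#' (read-weighted) over member sites; the fold change is
#' `max(level) / min(level)`, with a zero denominator passing the criterion
#' whenever the other level is positive; the chi-square statistic is
#' Pearson's, without continuity correction, on the pooled 2x2
#' methylated/unmethylated read table at 1 df. All criteria are evaluated
#' (no short-circuit) so rejection reasons and the null behaviour of each
#' criterion are observable.
#'
#' @param region one candidate from [build_candidate_regions()].
#' @param cfg a [dmr_config()].
#' @return list with `status` (`"pass"` or the first failed criterion among
#'   `"zero_reads"`, `"too_few_meth_sites"`, `"fold_change"`,
#'   `"chi_square"`), logical flags `sites_pass`, `fold_pass`, `chi2_pass`,
#'   and `record`, a one-row DMR data.frame (also present on rejection,
#'   for inspection).
#' @export
evaluate_region <- function(region, cfg = dmr_config()) {
  s <- region$sites
  mA <- sum(s$meth_count_a); tA <- sum(s$total_count_a)
  mB <- sum(s$meth_count_b); tB <- sum(s$total_count_b)
  n_meth_a <- sum(s$flag_a); n_meth_b <- sum(s$flag_b)
  if (tA == 0 || tB == 0) {
    return(list(status = "zero_reads", sites_pass = FALSE,
                fold_pass = FALSE, chi2_pass = FALSE, record = NULL))
  }
  level_a <- mA / tA
  level_b <- mB / tB
  lo <- min(level_a, level_b); hi <- max(level_a, level_b)
  fold <- if (lo == 0) {
    if (hi > 0) Inf else 1
  } else {
    hi / lo
  }
  chi <- pearson_chi2_2x2(mA, tA - mA, mB, tB - mB)
  sites_pass <- max(n_meth_a, n_meth_b) >= cfg$min_meth_sites
  fold_pass <- fold > cfg$min_fold
  chi2_pass <- chi$p <= cfg$max_p
  status <- if (!sites_pass) "too_few_meth_sites"
            else if (!fold_pass) "fold_change"
            else if (!chi2_pass) "chi_square"
            else "pass"
  record <- data.frame(
    chrom = region$chrom, start = region$start, end = region$end,
    context = region$context, n_sites = nrow(s),
    n_meth_a = n_meth_a, n_meth_b = n_meth_b,
    level_a = level_a, level_b = level_b,
    fold_change = fold,
    direction = if (level_b >= level_a) "hyper" else "hypo",
    chi2 = chi$stat, p = chi$p,
    min_expected = chi$min_expected,
    stringsAsFactors = FALSE)
  list(status = status, sites_pass = sites_pass, fold_pass = fold_pass,
       chi2_pass = chi2_pass, record = record)
}

#' Call DMRs between two samples
#'
#' Runs candidate construction and evaluation over the requested sequence
#' contexts and concatenates the accepted regions, sorted by coordinate.
#' Every emitted record satisfies all six criteria simultaneously.
#' Rejection reasons are tallied in the `"rejections"` attribute; the number
#' of evaluated candidates per context in `"n_candidates"`. Candidates whose
#' pooled 2x2 table has an expected count below 5 are counted in the
#' `"low_expected"` attribute (the chi-square p is still used, as specified
#' by the region definition).
#'
#' @param sample_a,sample_b cytosine record data.frames (flagged or raw).
#' @param cfg a [dmr_config()].
#' @param contexts sequence contexts to scan.
#' @param keep_sites if `TRUE`, attach each DMR's member-site table as a
#'   list column `sites` (used by conformance checks).
#' @return data.frame of DMR records: `chrom`, `start`, `end`, `context`,
#'   `n_sites`, `n_meth_a`, `n_meth_b`, `level_a`, `level_b`,
#'   `fold_change`, `direction` (`hyper` = higher in sample B), `chi2`, `p`.
#' @export
call_dmrs <- function(sample_a, sample_b, cfg = dmr_config(),
                      contexts = c("CG", "CHG", "CHH"), keep_sites = FALSE) {
  sample_a <- ensure_flagged(check_cx_records(sample_a, "sample_a"), cfg)
  sample_b <- ensure_flagged(check_cx_records(sample_b, "sample_b"), cfg)
  rejections <- c(zero_reads = 0L, too_few_meth_sites = 0L,
                  fold_change = 0L, chi_square = 0L)
  n_cand <- integer(0)
  low_expected <- 0L
  rows <- list()
  sites_list <- list()
  for (cx in contexts) {
    cands <- build_candidate_regions(sample_a, sample_b, cfg, context = cx)
    n_cand[cx] <- length(cands)
    evals <- lapply(cands, evaluate_region, cfg = cfg)
    if (cfg$bh_correct && length(evals) > 0) {
      ps <- vapply(evals, function(e)
        if (is.null(e$record)) NA_real_ else e$record$p, 0)
      qs <- p.adjust(ps, method = "BH")
      for (i in seq_along(evals)) {
        if (!is.na(qs[i])) {
          evals[[i]]$chi2_pass <- qs[i] <= cfg$max_p
          if (evals[[i]]$status %in% c("pass", "chi_square")) {
            evals[[i]]$status <- if (evals[[i]]$chi2_pass) "pass"
                                 else "chi_square"
          }
        }
      }
    }
    for (i in seq_along(evals)) {
      e <- evals[[i]]
      if (!is.null(e$record) && e$record$min_expected < 5) {
        low_expected <- low_expected + 1L
      }
      if (e$status == "pass") {
        rows[[length(rows) + 1L]] <- e$record
        sites_list[[length(sites_list) + 1L]] <- cands[[i]]$sites
      } else {
        rejections[e$status] <- rejections[e$status] + 1L
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      n_sites = integer(0), n_meth_a = integer(0),
                      n_meth_b = integer(0), level_a = numeric(0),
                      level_b = numeric(0), fold_change = numeric(0),
                      direction = character(0), chi2 = numeric(0),
                      p = numeric(0), min_expected = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    ord <- order(out$chrom, out$start)
    out <- out[ord, , drop = FALSE]
    if (keep_sites) out$sites <- I(sites_list[ord])
    rownames(out) <- NULL
  }
  if (low_expected > 0) {
    message(low_expected,
            " region(s) had an expected 2x2 count below 5; ",
            "chi-square p-values used as configured")
  }
  attr(out, "rejections") <- rejections
  attr(out, "n_candidates") <- n_cand
  attr(out, "low_expected") <- low_expected
  out
}

#' Write DMRs as BED6
#'
#' Name is `context:direction`; score is `-log10(p)` capped at 1000.
#'
#' @param dmrs data.frame from [call_dmrs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- ifelse(dmrs$p <= 0, 1000, pmin(1000, round(-log10(dmrs$p), 2)))
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = paste(dmrs$context, dmrs$direction, sep = ":"),
                    score = score, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
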