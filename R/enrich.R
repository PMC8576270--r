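# DMR-to-gene zone assignment (2-kb upstream flank, gene body, 2-kb
# downstream flank, strand-aware) and hypergeometric pathway
# over-representation with multiple-testing correction.

#' Derive strand-aware gene zones
#'
#' For each gene: `up2k` is the 2 kb 5' of the TSS, `body` the gene
#' interval, `down2k` the 2 kb 3' of the TES; for a minus-strand gene the
#' upstream flank lies right of its body. Flank intervals are clipped at
#' position 1.
#'
#' @param genes gene models data.frame (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`, 1-based inclusive).
#' @param flank flank width in bp.
#' @return data.frame `gene_id`, `zone`, `chrom`, `start`, `end`.
#' @export
gene_zones <- function(genes, flank = 2000L) {
  if (nrow(genes) == 0) {
    return(data.frame(gene_id = character(0), zone = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  plus <- genes$strand == "+"
  up_start <- ifelse(plus, genes$start - flank, genes$end + 1L)
  up_end <- ifelse(plus, genes$start - 1L, genes$end + flank)
  dn_start <- ifelse(plus, genes$end + 1L, genes$start - flank)
  dn_end <- ifelse(plus, genes$end + flank, genes$start - 1L)
  out <- rbind(
    data.frame(gene_id = genes$gene_id, zone = "up2k", chrom = genes$chrom,
               start = pmax(1L, as.integer(up_start)),
               end = as.integer(up_end), stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, zone = "body", chrom = genes$chrom,
               start = genes$start, end = genes$end,
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, zone = "down2k", chrom = genes$chrom,
               start = pmax(1L, as.integer(dn_start)),
               end = as.integer(dn_end), stringsAsFactors = FALSE))
  out <- out[out$end >= out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign DMRs to gene zones
#'
#' A DMR is assigned to every (gene, zone) whose interval it overlaps by at
#' least 1 bp; one DMR may hit several genes and zones. DMRs overlapping no
#' zone are labelled intergenic.
#'
#' @param dmrs DMR data.frame from [call_dmrs()] (needs `chrom`, `start`,
#'   `end`; 1-based inclusive).
#' @param genes gene models data.frame.
#' @param flank flank width in bp (default 2 kb).
#' @return list with `assignments` (data.frame `dmr_idx`, `chrom`, `start`,
#'   `end`, `context`, `gene_id`, `zone`; intergenic DMRs carry `NA`
#'   gene_id and zone `"intergenic"`) and `zone_genes`, a list mapping each
#'   zone to its sorted gene id set.
#' @export
assign_dmr_genes <- function(dmrs, genes, flank = 2000L) {
  zones <- gene_zones(genes, flank = flank)
  ctx <- if ("context" %in% names(dmrs)) dmrs$context
         else rep(NA_character_, nrow(dmrs))
  if (nrow(dmrs) == 0 || nrow(zones) == 0) {
    assignments <- data.frame(
      dmr_idx = seq_len(nrow(dmrs)),
      chrom = dmrs$chrom %||% character(0),
      start = dmrs$start %||% integer(0),
      end = dmrs$end %||% integer(0),
      context = ctx, gene_id = NA_character_,
      zone = if (nrow(dmrs) > 0) "intergenic" else character(0),
      stringsAsFactors = FALSE)
    return(list(assignments = assignments,
                zone_genes = list(up2k = character(0), body = character(0),
                                  down2k = character(0))))
  }
  dr <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  zr <- GenomicRanges::GRanges(zones$chrom,
                               IRanges::IRanges(zones$start, zones$end))
  hits <- GenomicRanges::findOverlaps(dr, zr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  hit_df <- data.frame(dmr_idx = qi, chrom = dmrs$chrom[qi],
                       start = dmrs$start[qi], end = dmrs$end[qi],
                       context = ctx[qi],
                       gene_id = zones$gene_id[si], zone = zones$zone[si],
                       stringsAsFactors = FALSE)
  miss <- setdiff(seq_len(nrow(dmrs)), unique(qi))
  if (length(miss) > 0) {
    hit_df <- rbind(hit_df, data.frame(
      dmr_idx = miss, chrom = dmrs$chrom[miss], start = dmrs$start[miss],
      end = dmrs$end[miss], context = ctx[miss],
      gene_id = NA_character_, zone = "intergenic",
      stringsAsFactors = FALSE))
  }
  hit_df <- unique(hit_df[order(hit_df$dmr_idx, hit_df$zone,
                                hit_df$gene_id), , drop = FALSE])
  rownames(hit_df) <- NULL
  zone_genes <- lapply(c(up2k = "up2k", body = "body", down2k = "down2k"),
                       function(z)
                         sort(unique(hit_df$gene_id[hit_df$zone == z &
                                                      !is.na(hit_df$gene_id)])))
  list(assignments = hit_df, zone_genes = zone_genes)
}

#' Hypergeometric pathway enrichment
#'
#' For each pathway, tests over-representation of the hit genes against the
#' background: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where
#' `N` is the background size, `K` the pathway size within the background,
#' `n` the number of hit genes and `k` the hit genes in the pathway.
#' Results are sorted by p-value.
#'
#' @param hit_genes character vector of hit gene ids (a subset of
#'   `background`; genes outside the background are ignored).
#' @param pathway_map data.frame `gene_id`, `pathway_id` (and optionally
#'   `pathway_name`); memberships outside the background are ignored.
#' @param background character vector of background gene ids (the whole
#'   annotated gene universe).
#' @return data.frame `pathway_id`, `pathway_name`, `k`, `K`, `n`, `N`,
#'   `p`, sorted by `p`.
#' @export
hypergeometric_enrich <- function(hit_genes, pathway_map, background) {
  background <- unique(background)
  if (length(background) == 0) {
    stop("background gene set is empty", call. = FALSE)
  }
  hit <- unique(intersect(hit_genes, background))
  pm <- pathway_map[pathway_map$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(hit)
  ids <- unique(pm$pathway_id)
  rows <- lapply(ids, function(pid) {
    members <- unique(pm$gene_id[pm$pathway_id == pid])
    K <- length(members)
    k <- length(intersect(hit, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    pname <- if ("pathway_name" %in% names(pm)) {
      pm$pathway_name[match(pid, pm$pathway_id)]
    } else {
      NA_character_
    }
    data.frame(pathway_id = pid, pathway_name = pname, k = k, K = K,
               n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(0), pathway_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$p, out$pathway_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Correct enrichment p-values and flag significance
#'
#' Benjamini-Hochberg by default; a pathway is significant when its
#' Q-value falls below the cutoff.
#'
#' @param results data.frame from [hypergeometric_enrich()].
#' @param method a [stats::p.adjust()] method.
#' @param q_cutoff significance cutoff on the corrected value.
#' @return `results` with `q` and logical `significant` appended, sorted by
#'   `q` then `p`.
#' @export
adjust_q <- function(results, method = "BH", q_cutoff = 0.05) {
  if (any(results$p < 0 | results$p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  results$q <- p.adjust(results$p, method = method)
  results$significant <- results$q < q_cutoff
  out <- results[order(results$q, results$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
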