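# Paired-tissue exome analysis: VCF ingestion, mapping-quality/depth
# filtering, mucosa-minus-muscularis germline subtraction, SNP/InDel
# accounting with the allele-frequency SUM statistic, gene assignment and
# multi-sample gene intersection.

#' Read variant records from a VCF
#'
#' Parses a VCF v4.2 via [vcfR::read.vcfR()] and extracts the `DP`, `MQ`
#' and `AF` INFO annotations. Multi-allelic records are split into one
#' record per alternate allele (per-allele `AF` values are matched
#' positionally; `DP` and `MQ` are shared). Records missing any of the
#' three annotations are dropped, counted and reported in the
#' `"n_missing_info"` attribute.
#'
#' @param vcf_path path to a VCF file.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `vtype`
#'   (`SNP` iff both alleles are single bases, else `InDel`), `depth`,
#'   `mapping_quality`, `allele_fraction`.
#' @export
read_variants <- function(vcf_path) {
  v <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                error = function(e) {
                  stop("malformed VCF '", vcf_path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), depth = integer(0),
                      mapping_quality = numeric(0),
                      allele_fraction = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_missing_info") <- 0L
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  af_raw <- vcfR::extract.info(v, "AF")

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  afs <- strsplit(ifelse(is.na(af_raw), "", af_raw), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_flat <- unlist(alts)
  af_flat <- unlist(lapply(seq_along(afs), function(i) {
    a <- suppressWarnings(as.numeric(afs[[i]]))
    if (length(a) == 0) rep(NA_real_, n_alt[i])
    else rep_len(a, n_alt[i])
  }))
  out <- data.frame(chrom = fix$CHROM[idx],
                    pos = as.integer(fix$POS[idx]),
                    ref = fix$REF[idx],
                    alt = alt_flat,
                    depth = dp[idx],
                    mapping_quality = mq[idx],
                    allele_fraction = af_flat,
                    stringsAsFactors = FALSE)
  out$vtype <- ifelse(nchar(out$ref) == 1 & nchar(out$alt) == 1,
                      "SNP", "InDel")
  missing <- is.na(out$depth) | is.na(out$mapping_quality) |
    is.na(out$allele_fraction)
  if (any(missing)) {
    message(sum(missing), " record(s) in ", basename(vcf_path),
            " missing DP/MQ/AF dropped")
  }
  out <- out[!missing, c("chrom", "pos", "ref", "alt", "vtype", "depth",
                         "mapping_quality", "allele_fraction")]
  rownames(out) <- NULL
  attr(out, "n_missing_info") <- sum(missing)
  out
}

#' Filter variants on mapping quality and depth
#'
#' Keeps records with mapping quality strictly greater than `min_mq` and
#' depth strictly greater than `min_depth` (strict inequalities: MQ 20 and
#' DP 4 records are excluded at the defaults).
#'
#' @param records variant record data.frame.
#' @param min_mq mapping-quality threshold (exclusive).
#' @param min_depth depth threshold (exclusive).
#' @return the filtered data.frame, with counts in the `"n_removed"`
#'   attribute.
#' @export
filter_variants <- function(records, min_mq = 20, min_depth = 4) {
  keep <- records$mapping_quality > min_mq & records$depth > min_depth
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Subtract germline variants using the matched muscularis
#'
#' Somatic variants are the mucosa records whose exact key
#' (`chrom`, `pos`, `ref`, `alt`) is absent from the muscularis of the same
#' mouse; shared keys are taken as germline and removed.
#'
#' @param mucosa,muscularis filtered variant record data.frames from the
#'   same mouse.
#' @return the somatic subset of `mucosa`, with the number of
#'   germline-matched records in the `"n_germline_matched"` attribute.
#' @export
subtract_germline <- function(mucosa, muscularis) {
  mk <- variant_key(mucosa)
  sk <- variant_key(muscularis)
  keep <- !(mk %in% sk)
  out <- mucosa[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_germline_matched") <- sum(!keep)
  out
}

#' Summarize somatic variants for one sample
#'
#' Counts by variant type and the allele-frequency SUM statistic: the sum
#' of per-variant allele fractions over all somatic variants, reported to
#' three decimals.
#'
#' @param somatic somatic variant record data.frame.
#' @param sample_id sample label.
#' @param n_total optional total (pre-subtraction) variant count for the
#'   sample.
#' @return one-row data.frame `sample_id`, `n_total`, `n_somatic`,
#'   `n_snp`, `n_indel`, `freq_sum`.
#' @export
summarize_sample <- function(somatic, sample_id, n_total = NA_integer_) {
  n_snp <- sum(somatic$vtype == "SNP")
  n_indel <- sum(somatic$vtype == "InDel")
  data.frame(sample_id = sample_id,
             n_total = n_total,
             n_somatic = nrow(somatic),
             n_snp = n_snp, n_indel = n_indel,
             freq_sum = round(sum(somatic$allele_fraction), 3),
             stringsAsFactors = FALSE)
}

#' Assign variants to genes by interval containment
#'
#' A variant maps to every gene whose `[start, end]` interval (1-based
#' inclusive) contains its position; variants inside no gene are tallied as
#' intergenic.
#'
#' @param somatic somatic variant record data.frame.
#' @param genes gene models data.frame (`chrom`, `start`, `end`,
#'   `gene_id`).
#' @return list with `gene_set` (sorted unique gene ids hit),
#'   `assignments` (data.frame `key`, `gene_id`) and `n_intergenic`.
#' @export
assign_genes <- function(somatic, genes) {
  if (nrow(somatic) == 0 || nrow(genes) == 0) {
    return(list(gene_set = character(0),
                assignments = data.frame(key = character(0),
                                         gene_id = character(0),
                                         stringsAsFactors = FALSE),
                n_intergenic = nrow(somatic)))
  }
  vr <- GenomicRanges::GRanges(somatic$chrom,
                               IRanges::IRanges(somatic$pos, somatic$pos))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(vr, gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  assignments <- data.frame(key = variant_key(somatic)[qi],
                            gene_id = genes$gene_id[si],
                            stringsAsFactors = FALSE)
  list(gene_set = sort(unique(assignments$gene_id)),
       assignments = assignments,
       n_intergenic = nrow(somatic) - length(unique(qi)))
}

#' Intersect gene sets across samples
#'
#' Exact set intersection of two or more per-sample gene id sets, emitted
#' sorted.
#'
#' @param sets list of at least two character vectors.
#' @return sorted character vector of shared gene ids.
#' @export
intersect_gene_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    stop("at least two gene sets are required", call. = FALSE)
  }
  sort(Reduce(intersect, sets))
}
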