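# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson chi-square on a 2x2 table of pooled reads, 1 df, no continuity
# correction. Degenerate margins (an all-zero row or column) carry no
# information: statistic 0, p 1.
pearson_chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(stat = 0, p = 1, min_expected = 0))
  }
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  expected <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  list(stat = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       min_expected = min(expected))
}

# One-sided upper binomial tail P(X >= k | size, prob).
binom_upper_tail <- function(k, size, prob) {
  stats::pbinom(k - 1, size, prob, lower.tail = FALSE)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: %s %s", field, msg), call. = FALSE)
}

variant_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# Empty cytosine-record skeleton; the common currency of the methylome and
# DMR modules.
empty_cx_records <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             context = character(0), meth_count = integer(0),
             total_count = integer(0), stringsAsFactors = FALSE)
}

check_cx_records <- function(records, arg = "records") {
  need <- c("chrom", "pos", "strand", "context", "meth_count", "total_count")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop(sprintf("%s lacks required columns: %s", arg,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(records$meth_count > records$total_count)) {
    stop(sprintf("%s: meth_count exceeds total_count", arg), call. = FALSE)
  }
  invisible(records)
}
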