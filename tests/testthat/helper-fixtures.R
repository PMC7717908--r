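# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately avoid the package's code paths (plain loops over
# rows), so agreement is a genuine cross-check.

aln_fix <- function(chrom, start, end, strand, read_id = NULL,
                    is_primary = TRUE, library = "short") {
  n <- length(start)
  data.frame(read_id = read_id %||% sprintf("r%03d", seq_len(n)),
             chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), strand = rep_len(strand, n),
             is_primary = rep_len(is_primary, n),
             library = rep_len(library, n), stringsAsFactors = FALSE)
}

loci_fix <- function(start, end, strand, chrom = "chr1",
                     subfamily = "B2_Mm2") {
  n <- length(start)
  data.frame(locus_id = sprintf("%s:%d-%d:%s", rep_len(chrom, n),
                                as.integer(start), as.integer(end),
                                rep_len(strand, n)),
             chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), strand = rep_len(strand, n),
             subfamily = rep_len(subfamily, n),
             category = "unclassified", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n*m) interval-overlap oracle (1-based closed, >= 1 bp)
overlaps_any_oracle <- function(q, subjects) {
  any(vapply(seq_len(nrow(subjects)), function(j) {
    q$chrom == subjects$chrom[j] &&
      q$start <= subjects$end[j] && q$end >= subjects$start[j]
  }, logical(1)))
}

# two-sample KS D by explicit ECDF sweep over the pooled support
ks_D_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# Pearson r from the covariance/sd definition, p from the t transform
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2), t = t)
}

# brute-force element-relative 5'-end events: all reads x all loci scan
events_oracle <- function(aln, loci, W = 120L) {
  aln <- aln[aln$is_primary, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(aln))) {
    fp <- if (aln$strand[i] == "+") aln$start[i] else aln$end[i]
    best <- NULL
    for (j in seq_len(nrow(loci))) {
      if (aln$chrom[i] != loci$chrom[j]) next
      if (aln$strand[i] != loci$strand[j]) next
      pos <- if (loci$strand[j] == "+") fp - loci$start[j] + 1L
             else loci$end[j] - fp + 1L
      if (pos < 1L || pos > W) next
      cand <- list(locus_id = loci$locus_id[j], position = pos)
      if (is.null(best) || pos < best$position ||
          (pos == best$position && cand$locus_id < best$locus_id))
        best <- cand
    }
    if (!is.null(best))
      out <- rbind(out, data.frame(read_id = aln$read_id[i],
                                   locus_id = best$locus_id,
                                   position = best$position,
                                   stringsAsFactors = FALSE))
  }
  out
}

write_lines_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
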