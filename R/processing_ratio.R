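# Per-sample B2 RNA processing ratio: the five counts (F, T, Ns, B, Nl),
# the ratio estimator, sample orchestration and group comparison.

#' Count fragment 5' ends in the processing window
#'
#' Number of element-relative 5'-end events falling in the fragment window
#' (default positions 95-110, inclusive at both ends), the numerator count F
#' of the processing ratio.
#'
#' @param events event data.frame or integer position vector.
#' @param lo,hi inclusive window bounds in element coordinates.
#' @return integer count.
#' @export
count_fragment_window <- function(events, lo = 95L, hi = 110L) {
  if (lo > hi) stopf("fragment window: lo must be <= hi")
  pos <- if (is.data.frame(events)) events$position else as.integer(events)
  sum(pos >= lo & pos <= hi)
}

#' Count short reads at tRNA loci
#'
#' Number of distinct primary short reads whose 5' base falls within
#' `[start + lo, start + hi]` of any tRNA locus, offsets taken in the
#' locus's own orientation with 0 at the annotated first base (default
#' -5..15). This is the tRNA normalizer count T. A read matching several
#' tRNA loci counts once; read strand is not filtered.
#'
#' @param alignments short-read alignment data.frame.
#' @param trna_loci data.frame of stranded tRNA intervals (`chrom`, `start`,
#'   `end`, `strand`).
#' @param lo,hi inclusive offset window relative to the tRNA start.
#' @param count_secondary include non-primary records (default FALSE).
#' @return integer count.
#' @export
count_trna_short_reads <- function(alignments, trna_loci, lo = -5L, hi = 15L,
                                   count_secondary = FALSE) {
  if (!nrow(alignments) || is.null(trna_loci) || !nrow(trna_loci)) return(0L)
  aln <- if (count_secondary) alignments else
    alignments[alignments$is_primary, , drop = FALSE]
  if (!nrow(aln)) return(0L)
  fp <- five_prime_base(aln)
  # offset window in genomic coordinates per tRNA strand
  ws <- ifelse(trna_loci$strand == "-", trna_loci$end - hi, trna_loci$start + lo)
  we <- ifelse(trna_loci$strand == "-", trna_loci$end - lo, trna_loci$start + hi)
  win <- GenomicRanges::GRanges(trna_loci$chrom, IRanges::IRanges(ws, we))
  pts <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(fp, fp))
  hits <- find_overlaps(pts, win, ignore.strand = TRUE)
  length(unique(S4Vectors::queryHits(hits)))
}

#' Count long reads over B2 loci
#'
#' Number of distinct primary long reads overlapping at least one selected
#' locus by >= 1 bp (strand-blind): the full-length B2 count B. By default a
#' read spanning several loci counts once; `dedup = FALSE` instead sums
#' per-locus overlaps (a per-locus tally can double-count spanning reads).
#'
#' @param long_alignments long-read alignment data.frame.
#' @param loci locus data.frame.
#' @param dedup count each read once across loci (default TRUE).
#' @param count_secondary include non-primary records (default FALSE).
#' @return integer count.
#' @export
count_long_full_length <- function(long_alignments, loci, dedup = TRUE,
                                   count_secondary = FALSE) {
  if (!nrow(long_alignments) || !nrow(loci)) return(0L)
  aln <- if (count_secondary) long_alignments else
    long_alignments[long_alignments$is_primary, , drop = FALSE]
  if (!nrow(aln)) return(0L)
  hits <- find_overlaps(df_granges(aln, use_strand = FALSE),
                                      df_granges(loci, use_strand = FALSE),
                                      minoverlap = 1L, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  if (dedup) length(unique(aln$read_id[q])) else length(q)
}

#' Bundle the five processing-ratio counts
#'
#' @param F short-read 5' ends in the fragment window (positions 95-110).
#' @param T_ short reads at tRNA loci (window -5..15).
#' @param Ns short-library total read count.
#' @param B long reads overlapping B2 loci.
#' @param Nl long-library total read count.
#' @return named list of the five counts.
#' @export
processing_counts <- function(F, T_, Ns, B, Nl) {
  cts <- list(F = F, T = T_, Ns = Ns, B = B, Nl = Nl)
  if (any(vapply(cts, function(x) !is.finite(x) || x < 0, logical(1))))
    stopf("processing counts must be finite and >= 0")
  if (F > Ns) warnf("F (%g) exceeds Ns (%g): window count larger than library", F, Ns)
  cts
}

#' Compute the B2 RNA processing ratio
#'
#' The default `literal` mode implements the estimator
#' \deqn{ratio = \frac{F / (T / N_s)}{B / N_l}}
#' i.e. fragment 5'-end counts in the 95-110 window normalized by the
#' tRNA-per-short-library rate, divided by the long-read B2 rate. The
#' `trna_relative` mode drops the Ns factor (`(F/T) / (B/Nl)`), which makes
#' the estimator invariant to short-library depth; `literal = trna_relative
#' * Ns` exactly. Both require positive normalizers.
#'
#' @param counts list from [processing_counts()] (fields `F`, `T`, `Ns`,
#'   `B`, `Nl`).
#' @param mode `"literal"` or `"trna_relative"`.
#' @param sample_id optional id recorded on the result.
#' @return object of class `b2_ratio`: list with `sample_id`, `counts`,
#'   `ratio`, `mode`.
#' @export
compute_ratio <- function(counts, mode = c("literal", "trna_relative"),
                          sample_id = NA_character_) {
  mode <- match.arg(mode)
  for (nm in c("T", "B", "Ns", "Nl"))
    if (!isTRUE(counts[[nm]] > 0))
      stopf("insufficient normalizer: %s must be > 0 (got %s)",
            nm, format(counts[[nm]]))
  ratio <- if (mode == "literal") {
    (counts$F / (counts$T / counts$Ns)) / (counts$B / counts$Nl)
  } else {
    (counts$F / counts$T) / (counts$B / counts$Nl)
  }
  structure(list(sample_id = sample_id, counts = counts,
                 ratio = ratio, mode = mode),
            class = "b2_ratio")
}

#' Process one sample end to end
#'
#' Orchestrates event extraction, the three window/overlap counts and the
#' ratio for one manifest row: short alignments -> 5'-end events ->
#' fragment-window count F; short alignments vs tRNA loci -> T; long
#' alignments vs B2 loci -> B; Ns/Nl from the manifest -> ratio.
#' Alignments may be passed in memory (`short_alignments`/`long_alignments`)
#' or read from the manifest's `short_path`/`long_path`.
#'
#' @param sample one-row data.frame from [read_sample_manifest()].
#' @param loci,trna_loci annotation data.frames.
#' @param W metagene window width.
#' @param frag_window,trna_window inclusive count windows.
#' @param mode ratio mode, see [compute_ratio()].
#' @param short_alignments,long_alignments optional in-memory alignment
#'   data.frames overriding the manifest paths.
#' @param verbose log the five counts with `message()`.
#' @return `b2_ratio` for the sample.
#' @export
compute_sample <- function(sample, loci, trna_loci, W = 120L,
                           frag_window = c(95L, 110L),
                           trna_window = c(-5L, 15L),
                           mode = "literal",
                           short_alignments = NULL, long_alignments = NULL,
                           verbose = FALSE) {
  short <- short_alignments %||% read_alignments(sample$short_path, "short")
  long <- long_alignments %||% read_alignments(sample$long_path, "long")
  events <- extract_events(short, loci, W = W, sample_id = sample$sample_id)
  cts <- processing_counts(
    F = count_fragment_window(events, frag_window[1], frag_window[2]),
    T_ = count_trna_short_reads(short, trna_loci,
                                trna_window[1], trna_window[2]),
    Ns = sample$Ns,
    B = count_long_full_length(long, loci),
    Nl = sample$Nl)
  if (verbose)
    message(sprintf("%s: F=%d T=%d Ns=%g B=%d Nl=%g", sample$sample_id,
                    cts$F, cts$T, cts$Ns, cts$B, cts$Nl))
  compute_ratio(cts, mode = mode, sample_id = sample$sample_id)
}

#' Flatten per-sample ratio results into a table
#'
#' @param results list of `b2_ratio` objects.
#' @return data.frame with `sample_id`, the five counts, `mode`, `ratio`.
#' @export
ratio_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(sample_id = r$sample_id, F = r$counts$F, T = r$counts$T,
               Ns = r$counts$Ns, B = r$counts$B, Nl = r$counts$Nl,
               mode = r$mode, ratio = r$ratio, stringsAsFactors = FALSE)))
}

#' Compare processing ratios between two groups
#'
#' Unpaired t-test on per-sample ratios (Student pooled variance by default,
#' Welch optional). Directional alternatives are relative to the first group
#' in `group_order` (or first appearance order): `"greater"` tests group1 >
#' group2.
#'
#' @param ratios numeric vector of per-sample ratios.
#' @param groups group label per sample (exactly two distinct, each n >= 2).
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @param variance `"pooled"` or `"welch"`.
#' @param group_order optional length-2 character giving the group order.
#' @return object of class `b2_group_test`: list with group names, per-group
#'   `n`, `mean`, `sd`, and `t`, `df`, `p`, `sided`, `variance`.
#' @export
compare_groups <- function(ratios, groups, sided = c("two", "greater", "less"),
                           variance = c("pooled", "welch"),
                           group_order = NULL) {
  sided <- match.arg(sided)
  variance <- match.arg(variance)
  groups <- as.character(groups)
  gl <- group_order %||% unique(groups)
  if (length(gl) != 2)
    stopf("compare_groups needs exactly two groups, got: %s",
          paste(unique(groups), collapse = ", "))
  x <- ratios[groups == gl[1]]
  y <- ratios[groups == gl[2]]
  if (length(x) < 2 || length(y) < 2)
    stopf("each group needs n >= 2 (got %d and %d)", length(x), length(y))
  alt <- c(two = "two.sided", greater = "greater", less = "less")[[sided]]
  tt <- stats::t.test(x, y, alternative = alt,
                      var.equal = (variance == "pooled"))
  structure(list(groups = gl, n = c(length(x), length(y)),
                 mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = unname(tt$p.value), sided = sided, variance = variance),
            class = "b2_group_test")
}

#' Export a per-sample ratio table as TSV
#'
#' @param tab data.frame from [ratio_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
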