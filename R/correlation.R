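# Expression vs processing-ratio correlation: per-gene Pearson r,
# strength classification, gene-set overlap and peak-to-TSS metagenes.

#' Correlate one gene's expression with the processing ratio
#'
#' Pearson correlation between a gene's expression across samples and the
#' per-sample processing ratio, with the two-sided p-value from the
#' t-transform on n-2 df. Genes not expressed above `min_expr` in every
#' sample are excluded before testing; genes whose p exceeds `alpha` are
#' excluded as non-significant (set `alpha = 1` to keep all testable genes).
#'
#' @param expression_row numeric expression values, one per sample.
#' @param ratios numeric processing ratios in the same sample order.
#' @param min_expr exclusion floor: a gene must exceed this value in every
#'   sample (default 0).
#' @param alpha per-gene significance cut (default 0.05, uncorrected as a
#'   screening filter; apply [stats::p.adjust()] to the output for FDR
#'   control).
#' @param gene gene id recorded on the result.
#' @return one-row data.frame: `gene`, `r`, `p`, `n`, `status`
#'   (`classified` / `excluded_low_expression` / `excluded_nonsignificant`),
#'   `reason`.
#' @export
correlate_gene <- function(expression_row, ratios, min_expr = 0,
                           alpha = 0.05, gene = NA_character_) {
  if (length(expression_row) != length(ratios))
    stopf("expression and ratio vectors differ in length (%d vs %d)",
          length(expression_row), length(ratios))
  n <- length(ratios)
  if (n < 3) stopf("need at least 3 samples, got %d", n)
  row <- function(r, p, status, reason = NA_character_)
    data.frame(gene = gene, r = r, p = p, n = n, status = status,
               reason = reason, stringsAsFactors = FALSE)
  if (any(expression_row <= min_expr))
    return(row(NA_real_, NA_real_, "excluded_low_expression",
               "not expressed above floor in all samples"))
  if (stats::sd(expression_row) == 0 || stats::sd(ratios) == 0)
    return(row(NA_real_, NA_real_, "excluded_nonsignificant",
               "zero variance"))
  ct <- stats::cor.test(expression_row, ratios, method = "pearson")
  r <- unname(ct$estimate)
  p <- unname(ct$p.value)
  status <- if (p > alpha) "excluded_nonsignificant" else "classified"
  row(r, p, status)
}

#' Correlate every gene in an expression table
#'
#' @param expression `b2_expression` object or genes-by-samples matrix.
#' @param ratios per-sample ratios aligned to the table's sample order.
#' @param ... passed to [correlate_gene()].
#' @return data.frame, one row per gene.
#' @export
correlate_table <- function(expression, ratios, ...) {
  vals <- if (inherits(expression, "b2_expression")) expression$values
          else as.matrix(expression)
  if (ncol(vals) != length(ratios))
    stopf("expression table has %d samples but %d ratios given",
          ncol(vals), length(ratios))
  out <- lapply(rownames(vals) %||% seq_len(nrow(vals)), function(g)
    correlate_gene(vals[g, ], ratios, gene = as.character(g), ...))
  do.call(rbind, out)
}

#' Classify genes by correlation strength
#'
#' Partitions the classified genes by signed Pearson r: `strong` when
#' `r >= strong`, `weak` when `weak <= r < strong`, `none` when `r < weak`
#' (negative r falls in `none`). Percentages are over classified genes only,
#' rounded to one decimal.
#'
#' @param correlations data.frame from [correlate_table()] /
#'   [correlate_gene()].
#' @param strong,weak thresholds with `0 < weak < strong <= 1`
#'   (defaults 0.5 and 0.25).
#' @return object of class `b2_class_summary`: counts `n_strong`, `n_weak`,
#'   `n_none`, `n_excluded`, percentages, thresholds, and `table` (per-gene
#'   class assignments).
#' @export
classify_correlations <- function(correlations, strong = 0.5, weak = 0.25) {
  if (!(weak > 0 && weak < strong && strong <= 1))
    stopf("need 0 < weak < strong <= 1")
  cls <- correlations[correlations$status == "classified", , drop = FALSE]
  cls$class <- ifelse(cls$r >= strong, "strong",
                      ifelse(cls$r >= weak, "weak", "none"))
  n_cl <- nrow(cls)
  pct <- function(k) if (n_cl > 0) round(100 * k / n_cl, 1) else NA_real_
  ns <- sum(cls$class == "strong")
  nw <- sum(cls$class == "weak")
  nn <- sum(cls$class == "none")
  structure(list(n_strong = ns, n_weak = nw, n_none = nn,
                 n_classified = n_cl,
                 n_excluded = nrow(correlations) - n_cl,
                 pct_strong = pct(ns), pct_weak = pct(nw), pct_none = pct(nn),
                 thresholds = c(strong = strong, weak = weak),
                 table = cls),
            class = "b2_class_summary")
}

#' Overlap two gene sets
#'
#' Exact set intersection after upper-casing gene symbols.
#'
#' @param a,b `b2_geneset` objects or character vectors.
#' @return list with `count` and `members`.
#' @export
overlap_gene_sets <- function(a, b) {
  ma <- toupper(if (inherits(a, "b2_geneset")) a$members else a)
  mb <- toupper(if (inherits(b, "b2_geneset")) b$members else b)
  members <- intersect(ma, mb)
  list(count = length(members), members = members)
}

#' Peak-to-TSS relative-density profile
#'
#' For every (peak midpoint, TSS) pair on the same chromosome within
#' `half_window`, records the strand-aware signed offset (downstream of the
#' TSS positive), then bins the offsets into a density that sums to 1.
#'
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`).
#' @param tss data.frame with `chrom`, `position`, `strand`.
#' @param half_window maximum distance from the TSS in bp (default 5000).
#' @param bins number of equal-width bins (default 100).
#' @param set_name label for the gene set the TSS list came from.
#' @return object of class `b2_tss_profile`: `offsets`, `density`, `mids`,
#'   `breaks`, `half_window`, `set_name`.
#' @export
peak_tss_profile <- function(peaks, tss, half_window = 5000L, bins = 100L,
                             set_name = NA_character_) {
  if (half_window <= 0) stopf("half_window must be > 0")
  offsets <- numeric(0)
  if (nrow(peaks) && nrow(tss)) {
    mid <- floor((peaks$start + peaks$end) / 2)
    pts <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid, mid))
    win <- GenomicRanges::GRanges(tss$chrom,
                                  IRanges::IRanges(tss$position - half_window,
                                                   tss$position + half_window))
    hits <- find_overlaps(pts, win, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    offsets <- ifelse(tss$strand[s] == "-",
                      tss$position[s] - mid[q],
                      mid[q] - tss$position[s])
  }
  breaks <- seq(-half_window, half_window, length.out = bins + 1)
  h <- if (length(offsets)) {
    idx <- findInterval(offsets, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = bins)
  } else rep(0L, bins)
  density <- if (sum(h) > 0) h / sum(h) else as.numeric(h)
  structure(list(offsets = as.numeric(offsets), density = density,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 breaks = breaks, half_window = half_window,
                 set_name = set_name),
            class = "b2_tss_profile")
}

#' KS comparison of two peak-TSS profiles
#'
#' Two-sample KS on the raw signed offset samples (not the binned
#' densities).
#'
#' @param a,b `b2_tss_profile` objects.
#' @return `b2_ks` object (see [compare_profiles()]).
#' @export
compare_peak_profiles <- function(a, b) {
  if (!length(a$offsets) || !length(b$offsets))
    stopf("both profiles must contain offsets")
  ks <- suppressWarnings(stats::ks.test(a$offsets, b$offsets, exact = FALSE))
  structure(list(D = unname(ks$statistic), p = unname(ks$p.value),
                 n1 = length(a$offsets), n2 = length(b$offsets)),
            class = "b2_ks")
}
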