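# 5'-end fragment metagene over B2 loci: element-relative events, profiles,
# positional KS comparisons and processing-point calling.

# genomic coordinate of the 5' base of each alignment
five_prime_base <- function(aln) {
  ifelse(aln$strand == "+", aln$start, aln$end)
}

# element-start window of each locus in element orientation, as a GRanges:
# (+) [start, start+W-1]; (-) [end-W+1, end]. The window is anchored at the
# element start, so it can run past the annotated end of truncated copies.
locus_windows <- function(loci, W) {
  ws <- ifelse(loci$strand == "+", loci$start, loci$end - W + 1L)
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(ws, ws + W - 1L))
}

#' Element-relative position of a read's 5' end
#'
#' Maps the 5' base of an alignment onto the 1-based coordinate system of a
#' repeat element, with +1 at the element start in element orientation. By
#' default only sense reads (read strand equal to locus strand) are scored,
#' reflecting a directional library; reads whose 5' base falls outside
#' positions 1..`W` return `NA`.
#'
#' @param aln one-row alignment data.frame (see [read_alignments()]).
#' @param locus one-row locus data.frame (see [read_repeat_annotation()]).
#' @param W metagene window width in nt (default 120, chosen to avoid
#'   artifacts from partial mappings downstream of truncated copies; the
#'   full B2 consensus is 188 nt).
#' @param sense_only drop antisense reads (default TRUE).
#' @return integer position in 1..W, or `NA`.
#' @export
five_prime_position <- function(aln, locus, W = 120L, sense_only = TRUE) {
  if (W < 1) stopf("W must be >= 1")
  fp <- five_prime_base(aln)
  pos <- ifelse(locus$strand == "+",
                fp - locus$start + 1L,
                locus$end - fp + 1L)
  bad <- (sense_only & aln$strand != locus$strand) | pos < 1L | pos > W
  pos[bad] <- NA_integer_
  as.integer(pos)
}

#' Extract element-relative 5'-end events
#'
#' Converts short-read alignments into one event per primary sense read
#' whose 5' base lies in positions 1..`W` of some locus window. A read
#' overlapping several locus windows contributes exactly one event, assigned
#' to the locus whose element start is nearest its 5' base (ties broken by
#' lexicographically smallest `locus_id`).
#'
#' @param alignments alignment data.frame.
#' @param loci locus data.frame.
#' @param W window width in nt.
#' @param sample_id recorded on each event.
#' @param sense_only drop antisense reads (default TRUE).
#' @param count_secondary include secondary/supplementary records
#'   (default FALSE: one event per read at most).
#' @return data.frame of events with `locus_id`, `position`, `sample_id`,
#'   `read_id`.
#' @export
extract_events <- function(alignments, loci, W = 120L, sample_id = "sample",
                           sense_only = TRUE, count_secondary = FALSE) {
  if (W < 1) stopf("W must be >= 1")
  empty <- data.frame(locus_id = character(0), position = integer(0),
                      sample_id = character(0), read_id = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(alignments) || !nrow(loci)) return(empty)
  aln <- if (count_secondary) alignments else
    alignments[alignments$is_primary, , drop = FALSE]
  if (!nrow(aln)) return(empty)

  fp <- five_prime_base(aln)
  pts <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(fp, fp))
  hits <- find_overlaps(pts, locus_windows(loci, W),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(empty)

  pos <- ifelse(loci$strand[si] == "+",
                fp[qi] - loci$start[si] + 1L,
                loci$end[si] - fp[qi] + 1L)
  keep <- pos >= 1L & pos <= W
  if (sense_only) keep <- keep & aln$strand[qi] == loci$strand[si]
  qi <- qi[keep]; si <- si[keep]; pos <- pos[keep]
  if (!length(qi)) return(empty)

  # one event per read: nearest element start, then smallest locus_id
  ord <- order(qi, pos, loci$locus_id[si])
  qi <- qi[ord]; si <- si[ord]; pos <- pos[ord]
  first <- !duplicated(qi)
  data.frame(locus_id = loci$locus_id[si][first],
             position = as.integer(pos[first]),
             sample_id = sample_id,
             read_id = aln$read_id[qi][first],
             stringsAsFactors = FALSE)
}

#' Build a 5'-end metagene profile
#'
#' Tallies event positions into a vector over 1..`W` aligned at the element
#' start (+1), optionally scaled to unit mass or to counts per million
#' short-library reads.
#'
#' @param events event data.frame from [extract_events()], or an integer
#'   vector of positions.
#' @param W window width.
#' @param normalization `"raw"`, `"unit"` (sums to 1) or `"per_million"`
#'   (requires `Ns`).
#' @param Ns short-library total read count, for `per_million`.
#' @return object of class `b2_profile`: list with `counts` (length `W`),
#'   `n_events`, `normalization`, `W`.
#' @export
build_profile <- function(events, W = 120L,
                          normalization = c("raw", "unit", "per_million"),
                          Ns = NULL) {
  normalization <- match.arg(normalization)
  pos <- if (is.data.frame(events)) events$position else as.integer(events)
  if (length(pos) && (min(pos) < 1L || max(pos) > W))
    stopf("event positions outside 1..W")
  counts <- as.numeric(tabulate(pos, nbins = W))
  n <- length(pos)
  if (normalization == "unit") {
    if (n > 0) counts <- counts / n
  } else if (normalization == "per_million") {
    if (is.null(Ns)) stopf("per_million normalization requires Ns")
    counts <- counts / Ns * 1e6
  }
  structure(list(counts = counts, n_events = n,
                 normalization = normalization, W = as.integer(W)),
            class = "b2_profile")
}

profile_positions <- function(x) {
  if (inherits(x, "b2_profile"))
    stopf("need raw event positions, not a profile")
  if (is.data.frame(x)) x$position else as.numeric(x)
}

#' Two-sample KS test on positional distributions
#'
#' Compares the raw element-relative 5'-end position samples of two
#' conditions with a two-sample Kolmogorov-Smirnov test (D = supremum of the
#' ECDF difference; asymptotic p-value). Positions are tied integers, so the
#' p-value is approximate and D is the primary quantity.
#'
#' @param a_events,b_events event data.frames or integer position vectors.
#' @return object of class `b2_ks`: list with `D`, `p`, `n1`, `n2`.
#' @export
compare_profiles <- function(a_events, b_events) {
  a <- profile_positions(a_events)
  b <- profile_positions(b_events)
  if (!length(a) || !length(b)) stopf("both event samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(D = unname(ks$statistic), p = unname(ks$p.value),
                 n1 = length(a), n2 = length(b)),
            class = "b2_ks")
}

#' Call processing points from a metagene profile
#'
#' A position is a processing point when it is a local maximum over a
#' `±flank` window (clipped at the edges) and its height is at least
#' `min_frac` of the profile maximum. A plateau of equal qualifying
#' neighbours reports its smallest position only.
#'
#' @param profile `b2_profile` (raw or unit) or a numeric count vector.
#' @param min_frac minimum peak height as a fraction of the maximum
#'   (default 0.1, low enough to retain minor cleavage sites).
#' @param flank half-width of the local-maximum window (default 2).
#' @return object of class `b2_points`: list with sorted `positions` and
#'   matching `scores`.
#' @export
call_processing_points <- function(profile, min_frac = 0.1, flank = 2L) {
  counts <- if (inherits(profile, "b2_profile")) profile$counts
            else as.numeric(profile)
  W <- length(counts)
  mx <- max(counts)
  if (W == 0 || mx <= 0)
    return(structure(list(positions = integer(0), scores = numeric(0)),
                     class = "b2_points"))
  ok <- vapply(seq_len(W), function(p) {
    win <- counts[max(1L, p - flank):min(W, p + flank)]
    counts[p] > 0 && counts[p] >= max(win) && counts[p] >= min_frac * mx
  }, logical(1))
  q <- which(ok)
  # collapse plateaus: adjacent qualifying positions with equal counts
  keep <- q[c(TRUE, !(diff(q) == 1L & diff(counts[q]) == 0))]
  structure(list(positions = as.integer(keep), scores = counts[keep]),
            class = "b2_points")
}

#' Compare two processing-point sets
#'
#' Greedy nearest-first matching of positions within `tol` of each other;
#' unmatched positions are listed per side.
#'
#' @param a,b `b2_points` objects or integer position vectors.
#' @param tol maximum distance for a match (default 1).
#' @return list with `shared` (data.frame of matched `a`/`b` positions),
#'   `only_a`, `only_b`.
#' @export
diff_processing_points <- function(a, b, tol = 1L) {
  pa <- if (inherits(a, "b2_points")) a$positions else as.integer(a)
  pb <- if (inherits(b, "b2_points")) b$positions else as.integer(b)
  pairs <- expand.grid(i = seq_along(pa), j = seq_along(pb))
  if (nrow(pairs)) {
    pairs$d <- abs(pa[pairs$i] - pb[pairs$j])
    pairs <- pairs[pairs$d <= tol, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pa[pairs$i], pb[pairs$j]), , drop = FALSE]
  }
  used_a <- logical(length(pa)); used_b <- logical(length(pb))
  ma <- integer(0); mb <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      ma <- c(ma, i); mb <- c(mb, j)
    }
  }
  list(shared = data.frame(a = pa[ma], b = pb[mb]),
       only_a = pa[!used_a],
       only_b = pb[!used_b])
}

#' Export a profile as TSV
#'
#' Two columns: element-relative position and (normalized) count.
#'
#' @param profile `b2_profile`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(position = seq_len(profile$W), count = profile$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export events as BED6
#'
#' Each event's genomic 5' base is not retained on the event, so positions
#' are exported in element coordinates with the locus id as name; this is
#' the tally underlying the metagene, one 1-bp record per event.
#'
#' @param events event data.frame.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  out <- data.frame(events$locus_id, events$position - 1L, events$position,
                    events$read_id, 0L, "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
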