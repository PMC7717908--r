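# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom utils head tail
open_text <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

read_lines_any <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# reference span consumed by a CIGAR string (M/D/N/=/X operations)
cigar_ref_width <- function(cigar) {
  vapply(as.character(cigar), function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cg))
      stopf("malformed CIGAR: %s", cg)
    n <- as.integer(sub(".$", "", toks))
    op <- substring(toks, nchar(toks))
    as.integer(sum(n[op %in% c("M", "D", "N", "=", "X")]))
  }, integer(1), USE.NAMES = FALSE)
}

# independent per-task seeds derived from one master seed, all < 2^31
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1)
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}

# --- internal tabular containers ----------------------------------------

# alignments: one row per record, 1-based closed coordinates
alignment_frame <- function(read_id, chrom, start, end, strand,
                            is_primary = TRUE, library = "short") {
  n <- length(read_id)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(strand) == n)
  if (n && any(end < start)) stopf("alignment with end < start")
  if (n && !all(strand %in% c("+", "-"))) stopf("alignment strand must be + or -")
  data.frame(read_id = as.character(read_id), chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand),
             is_primary = rep_len(as.logical(is_primary), n),
             library = rep_len(as.character(library), n),
             stringsAsFactors = FALSE)
}

empty_alignments <- function(library = "short") {
  alignment_frame(character(0), character(0), integer(0), integer(0),
                  character(0), logical(0), library)
}

locus_frame <- function(chrom, start, end, strand, subfamily,
                        category = "unclassified") {
  n <- length(chrom)
  locus_id <- sprintf("%s:%d-%d:%s", chrom, as.integer(start),
                      as.integer(end), strand)
  if (anyDuplicated(locus_id))
    stopf("duplicate locus coordinates: %s",
          locus_id[duplicated(locus_id)][1])
  data.frame(locus_id = locus_id, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand),
             subfamily = as.character(subfamily),
             category = rep_len(as.character(category), n),
             stringsAsFactors = FALSE)
}

# findOverlaps without the disjoint-seqlevels warning (disjoint chromosomes
# between query and subject legitimately mean zero hits here)
find_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

# GRanges view of any frame with chrom/start/end (+ optional strand)
df_granges <- function(df, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(df)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         strand = strand)
}
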