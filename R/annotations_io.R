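#' Default B2 subfamilies
#'
#' The three mouse SINE B2 subfamilies quantified by the pipeline. All
#' annotation readers filter to this set unless overridden.
#' @export
B2_SUBFAMILIES <- c("B2_Mm1a", "B2_Mm1t", "B2_Mm2")

# split a BED-ish line on tabs or runs of spaces
split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

parse_bed6 <- function(lines, path, min_fields = 6) {
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track|browser)", lines))
  recs <- lapply(keep, function(i) {
    f <- split_fields(lines[i])
    if (length(f) < min_fields)
      stopf("%s: line %d: expected >= %d BED fields, got %d",
            path, i, min_fields, length(f))
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stopf("%s: line %d: bad BED interval [%s, %s)", path, i, f[2], f[3])
    list(chrom = f[1], start = s + 1L, end = e, name = f[4],
         score = f[5], strand = f[6], line = i)
  })
  do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

looks_like_repeatmasker <- function(lines) {
  head <- lines[nzchar(trimws(lines))]
  length(head) > 0 &&
    grepl("^\\s*(SW|score)\\s+(perc|div)", head[1], ignore.case = TRUE)
}

parse_repeatmasker <- function(lines, path) {
  body <- which(nzchar(trimws(lines)))
  # drop the two header rows of the .out table
  body <- body[!grepl("^\\s*(SW|score)\\s|^\\s*(div\\.?|del\\.?|perc)\\s",
                      lines[body], ignore.case = TRUE)]
  recs <- lapply(body, function(i) {
    f <- split_fields(lines[i])
    if (length(f) < 11)
      stopf("%s: line %d: expected >= 11 RepeatMasker fields, got %d",
            path, i, length(f))
    s <- suppressWarnings(as.integer(f[6]))
    e <- suppressWarnings(as.integer(f[7]))
    if (is.na(s) || is.na(e) || s < 1 || e < s)
      stopf("%s: line %d: bad RepeatMasker interval [%s, %s]",
            path, i, f[6], f[7])
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    list(chrom = f[5], start = s, end = e, name = f[10],
         strand = strand, line = i)
  })
  do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Read a B2 repeat annotation
#'
#' Reads repeat element loci from BED6 (name column = subfamily) or from a
#' RepeatMasker `.out`-style table (auto-detected by its header row), keeping
#' only the requested subfamilies. Locus identifiers are assigned
#' deterministically from the coordinates as `chrom:start-end:strand`
#' (1-based closed, the package-internal convention); the genic/intergenic
#' category starts as `"unclassified"` until [categorize_loci()] is run.
#'
#' @param path BED6 or RepeatMasker file, optionally gzip-compressed.
#' @param subfamilies character vector of subfamily names to retain.
#' @return data.frame of loci with columns `locus_id`, `chrom`, `start`,
#'   `end`, `strand`, `subfamily`, `category`.
#' @export
read_repeat_annotation <- function(path, subfamilies = B2_SUBFAMILIES) {
  lines <- read_lines_any(path)
  tab <- if (looks_like_repeatmasker(lines)) {
    parse_repeatmasker(lines, path)
  } else {
    parse_bed6(lines, path)
  }
  if (is.null(tab) || !nrow(tab))
    stopf("%s: no records found", path)
  tab <- tab[tab$name %in% subfamilies, , drop = FALSE]
  if (!nrow(tab))
    stopf("%s: no loci left after filtering to subfamilies {%s}",
          path, paste(subfamilies, collapse = ", "))
  bad <- !tab$strand %in% c("+", "-")
  if (any(bad))
    stopf("%s: line %d: locus strand must be + or -", path,
          tab$line[bad][1])
  locus_frame(tab$chrom, tab$start, tab$end, tab$strand, tab$name)
}

#' Read a BED6 file of generic intervals
#'
#' Used for genic intervals, tRNA loci and peak files. Coordinates are
#' converted from BED's 0-based half-open to 1-based closed.
#'
#' @param path BED file (>= 3 columns; name/score/strand optional),
#'   optionally gzipped.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed_intervals <- function(path) {
  lines <- read_lines_any(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines))
  recs <- lapply(keep, function(i) {
    f <- split_fields(lines[i])
    if (length(f) < 3)
      stopf("%s: line %d: expected >= 3 BED fields", path, i)
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stopf("%s: line %d: bad BED interval", path, i)
    data.frame(chrom = f[1], start = s + 1L, end = e,
               name = if (length(f) >= 4) f[4] else ".",
               strand = if (length(f) >= 6) f[6] else ".",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write intervals as BED6
#'
#' Converts the internal 1-based closed coordinates back to BED's 0-based
#' half-open convention. For repeat loci the name column carries the
#' subfamily, so a written annotation re-reads to an identical locus table.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `strand` plus a name column (`subfamily`, `name` or `read_id`).
#' @param path output path (plain text).
#' @param name_col column to place in the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path, name_col = NULL) {
  name_col <- name_col %||%
    intersect(c("subfamily", "name", "read_id", "locus_id"), names(df))[1]
  name <- if (!is.na(name_col) && !is.null(name_col)) df[[name_col]] else "."
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$chrom, df$start - 1L, df$end, name, 0L, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Split loci into genic and intergenic
#'
#' A locus is `genic` when it overlaps at least one genic interval by >= 1 bp
#' (strand-blind); otherwise `intergenic`. Input order is preserved; with an
#' empty genic list every locus is intergenic.
#'
#' @param loci locus data.frame from [read_repeat_annotation()].
#' @param genic data.frame of genic intervals (`chrom`, `start`, `end`).
#' @return `loci` with the `category` column filled in.
#' @export
categorize_loci <- function(loci, genic) {
  if (is.null(genic) || !nrow(genic)) {
    loci$category <- "intergenic"
    return(loci)
  }
  hits <- find_overlaps(df_granges(loci),
                                      df_granges(genic),
                                      minoverlap = 1L,
                                      ignore.strand = TRUE)
  loci$category <- "intergenic"
  loci$category[unique(S4Vectors::queryHits(hits))] <- "genic"
  loci
}

read_sam_bam <- function(path, library) {
  bam <- if (grepl("\\.sam(\\.gz)?$", path)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- x$flag
  mapped <- bitwAnd(flag, 4L) == 0L & !is.na(x$pos)
  flag <- flag[mapped]
  width <- cigar_ref_width(x$cigar[mapped])
  alignment_frame(
    read_id = x$qname[mapped],
    chrom = as.character(x$rname[mapped]),
    start = x$pos[mapped],
    end = x$pos[mapped] + width - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    is_primary = bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L,
    library = library)
}

read_bed_alignments <- function(path, library) {
  lines <- read_lines_any(path)
  tab <- parse_bed6(lines, path)
  if (is.null(tab) || !nrow(tab)) return(empty_alignments(library))
  bad <- !tab$strand %in% c("+", "-")
  if (any(bad))
    stopf("%s: line %d: BED alignments need an explicit +/- strand",
          path, tab$line[bad][1])
  alignment_frame(tab$name, tab$chrom, tab$start, tab$end, tab$strand,
                  is_primary = TRUE, library = library)
}

#' Read short- or long-RNA-seq alignments
#'
#' Accepts SAM/BAM (standard flags; unmapped records dropped, secondary and
#' supplementary records kept with `is_primary = FALSE`) or a
#' `bamToBed`-style BED6 where the name column is the read id and the strand
#' column is required. Every record is tagged with the library it came from.
#'
#' @param path `.sam`, `.bam`, `.bed` or `.bed.gz` file.
#' @param library `"short"` or `"long"`.
#' @return alignment data.frame (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `is_primary`, `library`), 1-based closed coordinates.
#' @export
read_alignments <- function(path, library = c("short", "long")) {
  library <- match.arg(library)
  if (grepl("\\.(sam|bam)(\\.gz)?$", path)) {
    read_sam_bam(path, library)
  } else if (grepl("\\.bed(\\.gz)?$", path)) {
    read_bed_alignments(path, library)
  } else {
    stopf("%s: unknown alignment format; accepted dialects are SAM/BAM and BED6 (name = read id)",
          path)
  }
}

#' Read a genes-by-samples expression table
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' Values must be non-negative (TPM or FPKM). Duplicate gene ids keep the
#' last row, with a warning.
#'
#' @param path TSV file, optionally gzipped.
#' @param unit expression unit recorded on the object (`"TPM"` or `"FPKM"`).
#' @return an object of class `b2_expression`: list with `genes`, `samples`,
#'   `values` (matrix, genes x samples) and `unit`.
#' @export
read_expression_table <- function(path, unit = "TPM") {
  con <- open_text(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stopf("%s: expression table needs gene id + >=1 sample", path)
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stopf("%s: non-numeric or missing expression values", path)
  if (any(vals < 0)) stopf("%s: negative expression values", path)
  if (anyDuplicated(genes)) {
    warnf("%s: %d duplicate gene ids, keeping last occurrence",
          path, sum(duplicated(genes)))
    keep <- !duplicated(genes, fromLast = TRUE)
    genes <- genes[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- genes
  structure(list(genes = genes, samples = colnames(vals), values = vals,
                 unit = unit),
            class = "b2_expression")
}

#' Read a gene set (one id per line)
#'
#' Blank lines and `#` comments are dropped; members are unique.
#'
#' @param path plain-text file, optionally gzipped.
#' @param name set name (defaults to the file name).
#' @return object of class `b2_geneset`: list with `name` and `members`.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  lines <- trimws(read_lines_any(path))
  members <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (!length(members)) stopf("%s: empty gene set", path)
  structure(list(name = name, members = members), class = "b2_geneset")
}

#' Read a sample manifest
#'
#' Flat TSV with one row per sample. Required columns: `sample_id`, `group`,
#' `Ns` (short-library total read count) and `Nl` (long-library total read
#' count); `short_path`/`long_path` locate the alignments when samples are
#' processed from files; any extra columns are carried as covariates.
#'
#' @param path TSV file, optionally gzipped.
#' @return data.frame, one row per sample.
#' @export
read_sample_manifest <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "Ns", "Nl")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("%s: manifest missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stopf("%s: duplicate sample_id: %s", path,
          tab$sample_id[duplicated(tab$sample_id)][1])
  if (any(!is.finite(tab$Ns)) || any(!is.finite(tab$Nl)) ||
      any(tab$Ns <= 0) || any(tab$Nl <= 0))
    stopf("%s: Ns and Nl must be positive", path)
  # resolve relative alignment paths against the manifest's directory
  for (col in intersect(c("short_path", "long_path"), names(tab))) {
    rel <- !is.na(tab[[col]]) & !grepl("^(/|[A-Za-z]:)", tab[[col]])
    tab[[col]][rel] <- file.path(dirname(path), tab[[col]][rel])
  }
  tab
}

#' Count records in a FASTQ file
#'
#' Convenience counter for library sizes when a manifest does not carry
#' `Ns`/`Nl` directly (4 lines per record).
#'
#' @param path FASTQ file, optionally gzipped.
#' @return integer record count.
#' @export
count_fastq_records <- function(path) {
  n <- length(read_lines_any(path))
  if (n %% 4L != 0L) warnf("%s: line count %d not a multiple of 4", path, n)
  n %/% 4L
}
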