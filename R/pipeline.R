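# Pipeline configuration, cohort-level orchestration and on-disk cohort
# serialization (SAM/BED/TSV/JSON).

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Values are
#' validated against the preconditions of the operations they parameterize;
#' the configuration serializes to JSON next to any outputs so a run can be
#' reproduced from its own records.
#'
#' @param W metagene window width (nt).
#' @param frag_window inclusive fragment-count window in element
#'   coordinates.
#' @param trna_window inclusive tRNA offset window.
#' @param subfamilies repeat subfamilies to quantify.
#' @param ratio_mode `"literal"` or `"trna_relative"`.
#' @param sided,variance group-test defaults, see [compare_groups()].
#' @param peak_min_frac,peak_flank processing-point calling parameters.
#' @param cor_strong,cor_weak,cor_alpha correlation classification
#'   parameters.
#' @param seed default RNG seed for simulation steps.
#' @return named list of class `b2_config`.
#' @export
pipeline_config <- function(W = 120L, frag_window = c(95L, 110L),
                            trna_window = c(-5L, 15L),
                            subfamilies = B2_SUBFAMILIES,
                            ratio_mode = "literal",
                            sided = "two", variance = "pooled",
                            peak_min_frac = 0.1, peak_flank = 2L,
                            cor_strong = 0.5, cor_weak = 0.25,
                            cor_alpha = 0.05, seed = 1L) {
  stopifnot(W >= 1,
            length(frag_window) == 2, frag_window[1] <= frag_window[2],
            length(trna_window) == 2, trna_window[1] <= trna_window[2],
            ratio_mode %in% c("literal", "trna_relative"),
            sided %in% c("two", "greater", "less"),
            variance %in% c("pooled", "welch"),
            peak_min_frac >= 0, peak_min_frac <= 1, peak_flank >= 0,
            cor_weak > 0, cor_weak < cor_strong, cor_strong <= 1,
            cor_alpha > 0, cor_alpha <= 1)
  structure(list(W = as.integer(W), frag_window = as.integer(frag_window),
                 trna_window = as.integer(trna_window),
                 subfamilies = subfamilies, ratio_mode = ratio_mode,
                 sided = sided, variance = variance,
                 peak_min_frac = peak_min_frac,
                 peak_flank = as.integer(peak_flank),
                 cor_strong = cor_strong, cor_weak = cor_weak,
                 cor_alpha = cor_alpha, seed = as.integer(seed)),
            class = "b2_config")
}

#' Write a configuration as JSON
#' @param config `b2_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Quantify every sample of a cohort
#'
#' Runs the event-extraction and counting pipeline over each sample of an
#' in-memory [simulate_cohort()] cohort (or any object with the same shape)
#' and returns the per-sample count/ratio table.
#'
#' @param cohort `b2_cohort`.
#' @param config `b2_config`.
#' @return data.frame with `sample_id`, `group`, `F`, `T`, `Ns`, `B`, `Nl`,
#'   `mode`, `ratio`.
#' @export
process_cohort <- function(cohort, config = pipeline_config()) {
  res <- lapply(seq_len(nrow(cohort$manifest)), function(i) {
    row <- cohort$manifest[i, , drop = FALSE]
    aln <- cohort$alignments[[row$sample_id]]
    compute_sample(row, cohort$loci, cohort$trna_loci,
                   W = config$W, frag_window = config$frag_window,
                   trna_window = config$trna_window,
                   mode = config$ratio_mode,
                   short_alignments = aln$short,
                   long_alignments = aln$long)
  })
  tab <- ratio_table(res)
  tab$group <- cohort$manifest$group[match(tab$sample_id,
                                           cohort$manifest$sample_id)]
  tab[, c("sample_id", "group", setdiff(names(tab),
                                        c("sample_id", "group")))]
}

#' Write alignments as SAM
#'
#' Minimal SAM 1.6 writer (header + one line per record, `<len>M` CIGAR,
#' `*` sequence), sufficient for round-tripping through any SAM-aware
#' reader.
#'
#' @param alignments alignment data.frame.
#' @param path output `.sam` path.
#' @param chrom_lengths named integer vector for the `@SQ` header lines
#'   (defaults to the maximum end per chromosome).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(alignments$end, alignments$chrom, max)
    chrom_lengths <- chrom_lengths + 1000L
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  flag <- ifelse(alignments$strand == "-", 16L, 0L) +
    ifelse(alignments$is_primary, 0L, 256L)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                  alignments$read_id, flag, alignments$chrom,
                  alignments$start,
                  alignments$end - alignments$start + 1L)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Serializes annotation (BED6), per-sample alignments (SAM or BED6),
#' manifest (TSV with paths filled in) and ground truth (JSON) under one
#' directory, the structure the file-based readers consume.
#'
#' @param cohort `b2_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"sam"` or `"bed"` for alignments.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("sam", "bed")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed6(cohort$loci, file.path(dir, "loci.bed"), name_col = "subfamily")
  write_bed6(cohort$trna_loci, file.path(dir, "trna_loci.bed"),
             name_col = "name")
  if (!is.null(cohort$genic) && nrow(cohort$genic))
    write_bed6(cohort$genic, file.path(dir, "genic.bed"), name_col = "name")
  chrom_len <- max(vapply(cohort$alignments,
                          function(a) max(a$short$end, a$long$end),
                          numeric(1))) + 1000L
  names(chrom_len) <- cohort$loci$chrom[1]
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    aln <- cohort$alignments[[sid]]
    ext <- format
    sp <- file.path(dir, sprintf("%s.short.%s", sid, ext))
    lp <- file.path(dir, sprintf("%s.long.%s", sid, ext))
    if (format == "sam") {
      write_sam(aln$short, sp, chrom_len)
      write_sam(aln$long, lp, chrom_len)
    } else {
      write_bed6(aln$short, sp, name_col = "read_id")
      write_bed6(aln$long, lp, name_col = "read_id")
    }
    # manifest paths are relative to the cohort directory (portable);
    # read_sample_manifest resolves them against its own location
    man$short_path[i] <- basename(sp)
    man$long_path[i] <- basename(lp)
  }
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man_path)
}
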