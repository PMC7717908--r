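# Ground-truth simulator: a toy chromosome carrying diverged B2 copies and
# tRNA loci, directional short/long reads with a configurable cleavage
# landscape and processing fraction, multi-group cohorts, and expression
# tables with target correlations to the per-sample processing ratio.
#
# Layout of the toy chromosome: B2 loci first (>= 1 kb apart), then a tRNA
# block, then a reserved background region; background reads never touch a
# locus or tRNA window, so pipeline counts reconstruct the realized truth
# counts exactly.

#' Default cleavage-site landscape
#'
#' Element-relative cleavage positions and their probabilities: the two
#' prominent processing points near 99 and 33 plus the two minor sites near
#' 90 and 47.
#' @export
DEFAULT_CLEAVAGE_PROBS <- c(`99` = 0.5, `33` = 0.3, `90` = 0.1, `47` = 0.1)

#' Simulate diverged B2 repeat loci
#'
#' Places `n_loci` non-overlapping copies on a toy chromosome with >= 1 kb
#' spacing and random strands. Copy lengths start from the 188-nt consensus,
#' shrink by binomial deletions at `del_rate`, and with probability
#' `truncation_prob` lose a geometric tail (3'-truncated copies). A
#' `genic_fraction` of loci is wrapped by a synthetic gene interval.
#'
#' @param n_loci number of copies.
#' @param consensus_length element consensus length in nt (default 188).
#' @param snp_rate nominal per-base substitution rate (recorded only;
#'   alignments are emitted directly, so SNPs do not alter coordinates).
#' @param del_rate per-base deletion rate shrinking copy length.
#' @param truncation_prob probability a copy is tail-truncated.
#' @param genic_fraction expected fraction of loci inside a gene.
#' @param spacing minimum gap between copies in bp (default 1000).
#' @param chrom chromosome name.
#' @param chrom_length optional cap; placement past it is an error.
#' @param seed RNG seed.
#' @return list with `loci` (locus data.frame, category unclassified),
#'   `genic` (gene intervals), `chrom`, `region_end`.
#' @export
simulate_repeat_loci <- function(n_loci, consensus_length = 188L,
                                 snp_rate = 0.1, del_rate = 0.02,
                                 truncation_prob = 0.2,
                                 genic_fraction = 0.3,
                                 spacing = 1000L, chrom = "chrS",
                                 chrom_length = NULL, seed = 1L) {
  stopifnot(n_loci >= 1,
            all(c(snp_rate, del_rate, truncation_prob, genic_fraction) >= 0),
            all(c(snp_rate, del_rate, truncation_prob, genic_fraction) <= 1))
  set.seed(seed)
  dels <- stats::rbinom(n_loci, consensus_length, del_rate)
  trunc <- ifelse(stats::runif(n_loci) < truncation_prob,
                  stats::rgeom(n_loci, 1 / 40), 0L)
  len <- pmax(consensus_length - dels - trunc, 40L)
  gaps <- spacing + floor(stats::runif(n_loci, 0, 500))
  starts <- cumsum(gaps) + cumsum(c(0L, len[-n_loci]))
  ends <- starts + len - 1L
  if (!is.null(chrom_length) && max(ends) > chrom_length)
    stopf("cannot place %d loci within %d bp; use a longer chromosome",
          n_loci, chrom_length)
  strands <- sample(c("+", "-"), n_loci, replace = TRUE)
  subfam <- sample(B2_SUBFAMILIES, n_loci, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
  loci <- locus_frame(chrom, starts, ends, strands, subfam)
  genic_idx <- which(stats::runif(n_loci) < genic_fraction)
  genic <- data.frame(chrom = chrom,
                      start = pmax(starts[genic_idx] - 200L, 1L),
                      end = ends[genic_idx] + 200L,
                      name = sprintf("gene%04d", seq_along(genic_idx)),
                      strand = strands[genic_idx],
                      stringsAsFactors = FALSE)
  list(loci = loci, genic = genic, chrom = chrom,
       region_end = max(ends) + spacing)
}

#' Simulate tRNA loci
#'
#' A block of fixed-length stranded tRNA genes downstream of the repeat
#' region, used as the short-library normalizer class.
#'
#' @param n_trna number of tRNA genes.
#' @param region_start first coordinate of the tRNA block.
#' @param length tRNA length in nt (default 72).
#' @param spacing gap between tRNAs (default 500).
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return data.frame of stranded intervals.
#' @export
simulate_trna_loci <- function(n_trna = 20L, region_start = 1e6, length = 72L,
                               spacing = 500L, chrom = "chrS", seed = 1L) {
  set.seed(seed)
  starts <- as.integer(region_start + (seq_len(n_trna) - 1L) * (length + spacing))
  data.frame(chrom = chrom, start = starts, end = starts + length - 1L,
             name = sprintf("tRNA%03d", seq_len(n_trna)),
             strand = sample(c("+", "-"), n_trna, replace = TRUE),
             stringsAsFactors = FALSE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample() that never falls into the length-1 "1:x" trap
resample <- function(v, n, prob = NULL) {
  v[sample.int(length(v), n, replace = TRUE, prob = prob)]
}

#' Simulate one sample's short and long libraries
#'
#' Each of `n_b2_transcripts` B2 transcripts is, with probability
#' `processing_fraction`, emitted as a short sense fragment whose
#' element-relative 5' end is drawn from `cleavage_site_probs` with +/-
#' `jitter` positional noise; otherwise it is emitted as a long read
#' spanning its locus. tRNA reads start within 2 bp of a tRNA start;
#' background reads fall in a reserved off-locus region. Realized truth
#' counts (F in the fragment window, T, B) and library totals (Ns, Nl) are
#' recorded.
#'
#' @param loci locus data.frame.
#' @param trna_loci tRNA data.frame.
#' @param processing_fraction probability a transcript is processed into a
#'   fragment.
#' @param cleavage_site_probs named numeric: position -> probability,
#'   summing to 1.
#' @param n_b2_transcripts,n_trna_reads,n_background_short,n_background_long
#'   library composition.
#' @param fragment_length_range inclusive short-fragment length range in nt
#'   (default 18-45, matching a sub-100-nt size selection).
#' @param jitter half-width of cleavage positional noise (default 1).
#' @param W metagene window width (positions clamped into 1..W).
#' @param frag_window window used for the realized F count.
#' @param background_region length-2 vector of the reserved background
#'   coordinates (defaults to past the annotated features).
#' @param sample_id sample name.
#' @param seed RNG seed.
#' @return list with `short`/`long` alignment data.frames, `truth` (realized
#'   `F`, `T`, `B`, `Ns`, `Nl`, `processing_fraction`), `sample_id`.
#' @export
simulate_sample <- function(loci, trna_loci, processing_fraction,
                            cleavage_site_probs = DEFAULT_CLEAVAGE_PROBS,
                            n_b2_transcripts = 2000L, n_trna_reads = 1000L,
                            n_background_short = 2000L,
                            n_background_long = 2000L,
                            fragment_length_range = c(18L, 45L),
                            jitter = 1L, W = 120L,
                            frag_window = c(95L, 110L),
                            background_region = NULL,
                            sample_id = "s1", seed = 1L) {
  if (!nrow(loci)) stopf("simulate_sample needs at least one locus")
  stopifnot(processing_fraction >= 0, processing_fraction <= 1,
            abs(sum(cleavage_site_probs) - 1) < 1e-9)
  set.seed(seed)
  feat_end <- max(loci$end, if (nrow(trna_loci)) trna_loci$end else 0L)
  bg <- background_region %||% c(feat_end + 10000L, feat_end + 110000L)

  processed <- stats::runif(n_b2_transcripts) < processing_fraction
  nfrag <- sum(processed)

  # short B2 fragments: sense reads with 5' end at a cleavage position
  sites <- as.integer(names(cleavage_site_probs))
  li <- if (nfrag) sample.int(nrow(loci), nfrag, replace = TRUE) else integer(0)
  pos <- if (nfrag) clamp(
    resample(sites, nfrag, prob = cleavage_site_probs) +
      resample(seq(-jitter, jitter), nfrag),
    1L, W) else integer(0)
  flen <- if (nfrag) resample(seq(fragment_length_range[1],
                                  fragment_length_range[2]),
                              nfrag) else integer(0)
  plus <- loci$strand[li] == "+"
  fp <- ifelse(plus, loci$start[li] + pos - 1L, loci$end[li] - pos + 1L)
  frag <- alignment_frame(
    read_id = sprintf("%s_frag%06d", sample_id, seq_len(nfrag)),
    chrom = loci$chrom[li],
    start = as.integer(ifelse(plus, fp, fp - flen + 1L)),
    end = as.integer(ifelse(plus, fp + flen - 1L, fp)),
    strand = loci$strand[li], library = "short")

  # tRNA reads: 5' ends within 2 bp of the annotated tRNA start
  ti <- if (n_trna_reads) sample.int(nrow(trna_loci), n_trna_reads,
                                     replace = TRUE) else integer(0)
  toff <- resample(-2:2, n_trna_reads)
  tplus <- trna_loci$strand[ti] == "+"
  tfp <- ifelse(tplus, trna_loci$start[ti] + toff, trna_loci$end[ti] - toff)
  trna <- alignment_frame(
    read_id = sprintf("%s_trna%06d", sample_id, seq_len(n_trna_reads)),
    chrom = trna_loci$chrom[ti],
    start = as.integer(ifelse(tplus, tfp, tfp - 69L)),
    end = as.integer(ifelse(tplus, tfp + 69L, tfp)),
    strand = trna_loci$strand[ti], library = "short")

  # background reads in the reserved region
  bg_read <- function(n, len_lo, len_hi, prefix, library) {
    if (!n) return(empty_alignments(library))
    len <- resample(seq(len_lo, len_hi), n)
    st <- floor(stats::runif(n, bg[1], bg[2] - len))
    alignment_frame(sprintf("%s_%s%06d", sample_id, prefix, seq_len(n)),
                    rep(loci$chrom[1], n), as.integer(st),
                    as.integer(st + len - 1L),
                    sample(c("+", "-"), n, replace = TRUE), library = library)
  }
  bg_short <- bg_read(n_background_short, fragment_length_range[1],
                      fragment_length_range[2], "bgs", "short")

  # long reads: unprocessed transcripts span their locus
  lli <- if (any(!processed)) sample.int(nrow(loci), sum(!processed),
                                         replace = TRUE) else integer(0)
  long_b2 <- alignment_frame(
    read_id = sprintf("%s_full%06d", sample_id, seq_along(lli)),
    chrom = loci$chrom[lli], start = loci$start[lli], end = loci$end[lli],
    strand = loci$strand[lli], library = "long")
  bg_long <- bg_read(n_background_long, 150L, 400L, "bgl", "long")

  short <- rbind(frag, trna, bg_short)
  long <- rbind(long_b2, bg_long)
  truth <- list(F = sum(pos >= frag_window[1] & pos <= frag_window[2]),
                T = n_trna_reads,
                B = nrow(long_b2),
                Ns = nrow(short), Nl = nrow(long),
                processing_fraction = processing_fraction)
  list(short = short, long = long, truth = truth, sample_id = sample_id)
}

#' Simulate a multi-group cohort
#'
#' Generates a shared locus/tRNA annotation and, for each group spec,
#' `n_samples` independent samples at that group's processing fraction.
#' Per-sample seeds are derived from the master seed, so the whole cohort is
#' a pure function of `seed`.
#'
#' @param group_specs data.frame with columns `group`, `n_samples`,
#'   `processing_fraction`.
#' @param n_loci,n_trna annotation sizes.
#' @param cleavage_site_probs shared cleavage landscape.
#' @param depth named list overriding library composition, see
#'   [simulate_sample()].
#' @param genic_fraction fraction of loci wrapped by a gene.
#' @param seed master RNG seed.
#' @return object of class `b2_cohort`: list with `manifest`, `loci`,
#'   `genic`, `trna_loci`, `alignments` (per-sample list of `short`/`long`),
#'   `truth` (per-sample realized counts + group truths), `seed`.
#' @export
simulate_cohort <- function(group_specs, n_loci = 60L, n_trna = 20L,
                            cleavage_site_probs = DEFAULT_CLEAVAGE_PROBS,
                            depth = list(), genic_fraction = 0.3,
                            seed = 1L) {
  stopifnot(nrow(group_specs) >= 1,
            all(c("group", "n_samples", "processing_fraction") %in%
                  names(group_specs)))
  n_total <- sum(group_specs$n_samples)
  seeds <- derive_seeds(seed, n_total + 2L)
  anno <- simulate_repeat_loci(n_loci, genic_fraction = genic_fraction,
                               seed = seeds[n_total + 1L])
  trna <- simulate_trna_loci(n_trna, region_start = anno$region_end + 10000L,
                             chrom = anno$chrom, seed = seeds[n_total + 2L])
  loci <- categorize_loci(anno$loci, anno$genic)

  depth_args <- utils::modifyList(
    list(n_b2_transcripts = 2000L, n_trna_reads = 1000L,
         n_background_short = 2000L, n_background_long = 2000L), depth)

  alignments <- list()
  truth_samples <- list()
  manifest <- NULL
  k <- 0L
  for (g in seq_len(nrow(group_specs))) {
    for (i in seq_len(group_specs$n_samples[g])) {
      k <- k + 1L
      sid <- sprintf("%s_%d", group_specs$group[g], i)
      sim <- do.call(simulate_sample, c(
        list(loci = loci, trna_loci = trna,
             processing_fraction = group_specs$processing_fraction[g],
             cleavage_site_probs = cleavage_site_probs,
             sample_id = sid, seed = seeds[k]),
        depth_args))
      alignments[[sid]] <- list(short = sim$short, long = sim$long)
      truth_samples[[sid]] <- sim$truth
      manifest <- rbind(manifest, data.frame(
        sample_id = sid, group = group_specs$group[g],
        Ns = sim$truth$Ns, Nl = sim$truth$Nl,
        short_path = NA_character_, long_path = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(manifest = manifest, loci = loci, genic = anno$genic,
                 trna_loci = trna, alignments = alignments,
                 truth = list(samples = truth_samples,
                              groups = group_specs,
                              cleavage_site_probs = cleavage_site_probs),
                 seed = seed),
            class = "b2_cohort")
}

#' Simulate expression correlated with the processing ratio
#'
#' Builds a genes-by-samples table where each gene's expression is
#' `base + amplitude * (r* z + sqrt(1 - r*^2) e)`, with `z` the standardized
#' per-sample ratio and `e` Gaussian noise. With `empirical = TRUE`
#' (default) the noise is residualized against `z` and rescaled so the
#' realized sample correlation equals `r*` exactly (the
#' `mvrnorm(empirical = TRUE)` construction); with `empirical = FALSE` only
#' the population correlation is `r*` and the sample correlation fluctuates
#' with n. Negative draws are clamped at 0 and counted.
#'
#' @param n_genes number of genes.
#' @param ratios per-sample processing ratios (length >= 3, non-constant).
#' @param r_targets target correlation per gene (recycled to `n_genes`).
#' @param base_expression mean expression level (default 100).
#' @param noise_sd expression spread (amplitude of the standardized signal,
#'   default 10).
#' @param empirical calibrate the sample correlation exactly (default TRUE).
#' @param seed RNG seed.
#' @return `b2_expression` with an extra `truth` field: data.frame of
#'   per-gene `r_target`, plus attribute `n_clamped`.
#' @export
simulate_expression <- function(n_genes, ratios, r_targets,
                                base_expression = 100, noise_sd = 10,
                                empirical = TRUE, seed = 1L) {
  n <- length(ratios)
  if (n < 3) stopf("need at least 3 samples, got %d", n)
  if (stats::sd(ratios) == 0) stopf("ratios must not be constant")
  if (any(abs(r_targets) > 1)) stopf("|r_target| must be <= 1")
  r_targets <- rep_len(r_targets, n_genes)
  set.seed(seed)
  zs <- as.numeric(scale(ratios))
  vals <- matrix(NA_real_, n_genes, n)
  for (g in seq_len(n_genes)) {
    r <- r_targets[g]
    e <- stats::rnorm(n)
    if (empirical) {
      e <- e - mean(e)
      e <- e - zs * sum(e * zs) / sum(zs * zs)
      if (stats::sd(e) == 0) e <- rep(0, n) else e <- e / stats::sd(e)
    }
    y <- r * zs + sqrt(1 - r^2) * e
    vals[g, ] <- base_expression + noise_sd * y
  }
  n_clamped <- sum(vals < 0)
  if (n_clamped > 0) {
    warnf("%d negative expression draws clamped at 0", n_clamped)
    vals[vals < 0] <- 0
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  rownames(vals) <- genes
  colnames(vals) <- names(ratios) %||% sprintf("s%02d", seq_len(n))
  structure(list(genes = genes, samples = colnames(vals), values = vals,
                 unit = "TPM",
                 truth = data.frame(gene = genes, r_target = r_targets,
                                    stringsAsFactors = FALSE)),
            class = "b2_expression")
}
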