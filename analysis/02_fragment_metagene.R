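#!/usr/bin/env Rscript
# 5'-end fragment metagene over B2 loci for the simulated cohort: per-group
# profiles aligned at the element start (+1), KS comparison of the two
# positional distributions, and processing-point calls per group.
# Reads results/cohort/ written by 01_simulate_cohort.R; writes profile
# TSVs and a processing-point summary under results/.

suppressPackageStartupMessages(library(sineb2))

man <- read_sample_manifest("results/cohort/manifest.tsv")
loci <- read_repeat_annotation("results/cohort/loci.bed")

events_by_group <- lapply(split(man, man$group), function(m) {
  do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    aln <- read_alignments(m$short_path[i], "short")
    extract_events(aln, loci, sample_id = m$sample_id[i])
  }))
})

for (g in names(events_by_group)) {
  prof <- build_profile(events_by_group[[g]], normalization = "unit")
  write_profile_tsv(prof, sprintf("results/metagene_%s.tsv", g))
  pts <- call_processing_points(prof)
  cat(sprintf("%s: %d events; processing points at {%s}\n", g,
              prof$n_events, paste(pts$positions, collapse = ", ")))
}

ks <- compare_profiles(events_by_group[[1]], events_by_group[[2]])
cat(sprintf("KS comparison %s vs %s: D = %.4f, p = %.3g (n = %d, %d)\n",
            names(events_by_group)[1], names(events_by_group)[2],
            ks$D, ks$p, ks$n1, ks$n2))
cat("Both simulated groups draw cleavage positions from the same landscape,",
    "\nso their positional distributions agree (large KS p); the group",
    "\ndifference is in fragment abundance and shows up in the processing",
    "\nratio (03_processing_ratio.R), not in the metagene shape.\n")
cat("Profiles written to results/metagene_<group>.tsv\n")
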