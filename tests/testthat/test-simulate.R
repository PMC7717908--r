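# Ground-truth simulator: determinism, boundary behaviour, closure of the
# realized counts, and expression calibration.

test_that("simulated loci respect truncation and placement settings", {
  sim <- simulate_repeat_loci(10, truncation_prob = 0, del_rate = 0,
                              seed = 3)
  expect_true(all(sim$loci$end - sim$loci$start + 1L == 188L))
  gaps <- sim$loci$start[-1] - sim$loci$end[-10]
  expect_true(all(gaps >= 1000))
  expect_error(simulate_repeat_loci(100, chrom_length = 10000, seed = 3),
               "longer chromosome")
})

test_that("loci generation is deterministic and genic fraction is binomial", {
  a <- simulate_repeat_loci(30, seed = 12)
  b <- simulate_repeat_loci(30, seed = 12)
  expect_identical(a, b)

  sim <- simulate_repeat_loci(100, genic_fraction = 0.3, seed = 4)
  cat100 <- categorize_loci(sim$loci, sim$genic)
  n_genic <- sum(cat100$category == "genic")
  # 3 sd binomial band around 30
  expect_true(abs(n_genic - 30) <= 3 * sqrt(100 * 0.3 * 0.7))
})

test_that("processing fraction 0 and 1 are degenerate as specified", {
  anno <- simulate_repeat_loci(15, seed = 5)
  trna <- simulate_trna_loci(5, region_start = anno$region_end + 10000,
                             seed = 5)
  none <- simulate_sample(anno$loci, trna, processing_fraction = 0,
                          n_b2_transcripts = 300, n_trna_reads = 50,
                          n_background_short = 50, n_background_long = 50,
                          seed = 6)
  expect_equal(none$truth$F, 0)
  expect_equal(none$truth$B, 300)
  expect_false(any(grepl("frag", none$short$read_id)))

  all_99 <- simulate_sample(anno$loci, trna, processing_fraction = 1,
                            cleavage_site_probs = c(`99` = 1),
                            jitter = 0, n_b2_transcripts = 300,
                            n_trna_reads = 50, n_background_short = 50,
                            n_background_long = 50, seed = 7)
  ev <- extract_events(all_99$short, anno$loci, sample_id = "s")
  expect_equal(nrow(ev), 300)
  expect_true(all(ev$position == 99L))
  expect_equal(count_fragment_window(ev), 300)
  expect_equal(all_99$truth$B, 0)
})

test_that("same seed reproduces identical samples and cohorts", {
  anno <- simulate_repeat_loci(10, seed = 8)
  trna <- simulate_trna_loci(5, region_start = anno$region_end + 10000,
                             seed = 8)
  s1 <- simulate_sample(anno$loci, trna, 0.2, n_b2_transcripts = 200,
                        n_trna_reads = 50, n_background_short = 50,
                        n_background_long = 50, seed = 9)
  s2 <- simulate_sample(anno$loci, trna, 0.2, n_b2_transcripts = 200,
                        n_trna_reads = 50, n_background_short = 50,
                        n_background_long = 50, seed = 9)
  expect_identical(s1, s2)

  gs <- data.frame(group = c("WT", "APP"), n_samples = c(2, 2),
                   processing_fraction = c(0.05, 0.15))
  c1 <- simulate_cohort(gs, n_loci = 15, n_trna = 5,
                        depth = list(n_b2_transcripts = 200,
                                     n_trna_reads = 100,
                                     n_background_short = 100,
                                     n_background_long = 100), seed = 10)
  c2 <- simulate_cohort(gs, n_loci = 15, n_trna = 5,
                        depth = list(n_b2_transcripts = 200,
                                     n_trna_reads = 100,
                                     n_background_short = 100,
                                     n_background_long = 100), seed = 10)
  expect_identical(c1$alignments, c2$alignments)
  expect_identical(c1$truth, c2$truth)

  # byte-identical on disk too
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  for (f in f1) {
    g <- file.path(d2, basename(f))
    expect_identical(readLines(f, warn = FALSE), readLines(g, warn = FALSE))
  }
})

test_that("pipeline recovers the realized truth counts exactly", {
  gs <- data.frame(group = c("WT", "APP"), n_samples = c(2, 2),
                   processing_fraction = c(0.05, 0.2))
  co <- simulate_cohort(gs, n_loci = 30, n_trna = 10,
                        depth = list(n_b2_transcripts = 800,
                                     n_trna_reads = 300,
                                     n_background_short = 400,
                                     n_background_long = 400), seed = 21)
  tab <- process_cohort(co)
  for (i in seq_len(nrow(tab))) {
    tr <- co$truth$samples[[tab$sample_id[i]]]
    expect_equal(tab$F[i], tr$F)
    expect_equal(tab$T[i], tr$T)
    expect_equal(tab$B[i], tr$B)
    expect_equal(tab$Ns[i], tr$Ns)
    expect_equal(tab$Nl[i], tr$Nl)
  }
  # same counts after a SAM round trip
  d <- tempfile()
  man <- read_sample_manifest(write_cohort(co, d))
  row <- man[man$sample_id == tab$sample_id[1], ]
  res <- compute_sample(row, co$loci, co$trna_loci)
  expect_equal(res$counts$F, tab$F[1])
  expect_equal(res$counts$B, tab$B[1])
  expect_equal(res$ratio, tab$ratio[1])
})

test_that("groups ordered by processing fraction are ordered by mean ratio", {
  for (seed in c(31, 32, 33)) {
    gs <- data.frame(group = c("lo", "mid", "hi"), n_samples = 2,
                     processing_fraction = c(0.05, 0.15, 0.3))
    co <- simulate_cohort(gs, n_loci = 25, n_trna = 8,
                          depth = list(n_b2_transcripts = 800,
                                       n_trna_reads = 300,
                                       n_background_short = 400,
                                       n_background_long = 400),
                          seed = seed)
    tab <- process_cohort(co)
    means <- tapply(tab$ratio, tab$group, mean)[c("lo", "mid", "hi")]
    expect_true(all(diff(means) > 0))
  }
})

test_that("expression generator calibrates the sample correlation exactly", {
  ratios <- c(2.1, 3.4, 1.2, 5.6, 4.4, 2.8, 3.9, 1.9, 4.9, 3.1, 2.5)
  expr <- simulate_expression(30, ratios, r_targets = c(0, 0.35, 0.7),
                              seed = 41)
  got_r <- vapply(seq_len(30), function(g)
    suppressWarnings(cor(expr$values[g, ], ratios)), numeric(1))
  expect_equal(got_r, expr$truth$r_target, tolerance = 1e-10)

  one <- simulate_expression(1, ratios, r_targets = 1, seed = 42)
  expect_equal(correlate_gene(one$values[1, ], ratios)$r, 1)

  # population mode fluctuates but stays inside the Fisher-z band mostly
  hits <- 0
  for (s in 1:50) {
    e0 <- simulate_expression(1, ratios, r_targets = 0, empirical = FALSE,
                              seed = 500 + s)
    r_hat <- cor(e0$values[1, ], ratios)
    if (abs(atanh(r_hat)) <= 2 / sqrt(length(ratios) - 3)) hits <- hits + 1
  }
  expect_gte(hits, 45)

  expect_error(simulate_expression(5, c(1, 2), r_targets = 0.5), "3 samples")
  expect_error(simulate_expression(5, ratios, r_targets = 1.2), "r_target")
})
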