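# Input readers: repeat annotation dialects, alignment dialects,
# expression/gene-set/manifest tables, and the genic/intergenic split.

test_that("BED6 repeat annotation is filtered by subfamily", {
  path <- write_lines_tmp(c(
    "chr1\t100\t288\tB2_Mm2\t0\t+",
    "chr1\t5000\t5180\tB1_Mus1\t0\t-",
    "chr2\t900\t1088\tB2_Mm1t\t0\t-"))
  loci <- read_repeat_annotation(path)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$end - loci$start + 1L, c(188L, 188L))
  expect_equal(loci$subfamily, c("B2_Mm2", "B2_Mm1t"))
  expect_equal(loci$locus_id[1], "chr1:101-288:+")
  expect_equal(loci$category, c("unclassified", "unclassified"))

  one <- read_repeat_annotation(path, subfamilies = "B2_Mm1t")
  expect_equal(nrow(one), 1)
  expect_error(read_repeat_annotation(path, subfamilies = "B2_Mm1a"),
               "no loci left")
})

test_that("malformed BED lines are reported with their line number", {
  path <- write_lines_tmp(c("chr1\t100\t288\tB2_Mm2\t0\t+",
                            "chr1\t300\t200\tB2_Mm2\t0\t+"))
  expect_error(read_repeat_annotation(path), "line 2")
  short <- write_lines_tmp("chr1\t100")
  expect_error(read_repeat_annotation(short), "line 1")
})

test_that("RepeatMasker tables are auto-detected and parsed", {
  path <- write_lines_tmp(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin  end  (left)   repeat  class/family",
    "",
    "  225   10.0  2.1  0.0  chr1      101    288  (1000) + B2_Mm2  SINE/B2  1 188 (0) 1",
    "  180   12.0  1.0  0.5  chr1      900   1060  (500)  C B2_Mm1a SINE/B2  (0) 188 20 2",
    "  140    9.0  0.0  0.0  chr1     2000   2100  (300)  + B1_Mus1 SINE/Alu 1 100 (8) 3"))
  loci <- read_repeat_annotation(path)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$start, c(101L, 900L))
  expect_equal(loci$strand, c("+", "-"))
  expect_equal(loci$subfamily, c("B2_Mm2", "B2_Mm1a"))
})

test_that("annotation round-trips through BED unchanged", {
  sim <- simulate_repeat_loci(25, seed = 11)
  path <- tempfile(fileext = ".bed")
  write_bed6(sim$loci, path, name_col = "subfamily")
  back <- read_repeat_annotation(path)
  expect_identical(back, sim$loci)
})

test_that("gzipped inputs are accepted", {
  path <- tempfile(fileext = ".bed.gz")
  con <- gzfile(path, "wt")
  writeLines("chr1\t100\t288\tB2_Mm2\t0\t+", con)
  close(con)
  expect_equal(nrow(read_repeat_annotation(path)), 1)
})

test_that("genic categorization follows >=1 bp strand-blind overlap", {
  loci <- loci_fix(start = 101, end = 288, strand = "+")
  genic_in <- data.frame(chrom = "chr1", start = 201, end = 400)
  genic_touch <- data.frame(chrom = "chr1", start = 289, end = 400)
  expect_equal(categorize_loci(loci, genic_in)$category, "genic")
  expect_equal(categorize_loci(loci, genic_touch)$category, "intergenic")
  expect_equal(categorize_loci(loci, NULL)$category, "intergenic")
  # opposite strand still counts
  genic_minus <- data.frame(chrom = "chr1", start = 250, end = 260,
                            strand = "-")
  expect_equal(categorize_loci(loci, genic_minus)$category, "genic")
})

test_that("categorization equals the all-pairs overlap oracle", {
  set.seed(301)
  for (rep in 1:3) {
    st <- sort(sample.int(5000, 10))
    loci <- loci_fix(start = st, end = st + sample(50:200, 10, TRUE),
                     strand = sample(c("+", "-"), 10, TRUE))
    gs <- sort(sample.int(5000, 3))
    genic <- data.frame(chrom = "chr1", start = gs,
                        end = gs + sample(100:800, 3, TRUE))
    got <- categorize_loci(loci, genic)$category
    want <- vapply(seq_len(nrow(loci)), function(i) {
      if (overlaps_any_oracle(loci[i, ], genic)) "genic" else "intergenic"
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("SAM and converted BED6 yield identical primary records", {
  aln <- aln_fix("chr1", start = c(150, 400, 900),
                 end = c(179, 429, 969), strand = c("+", "-", "+"))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sam, c(chr1 = 5000L))
  from_sam <- read_alignments(sam, "short")
  expect_equal(from_sam$start, aln$start)
  expect_equal(from_sam$end, aln$end)
  expect_equal(from_sam$strand, aln$strand)
  expect_true(all(from_sam$is_primary))

  bed <- tempfile(fileext = ".bed")
  write_bed6(aln, bed, name_col = "read_id")
  from_bed <- read_alignments(bed, "short")
  ord <- function(x) {
    x <- x[order(x$read_id), c("read_id", "chrom", "start", "end", "strand")]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(from_bed), ord(from_sam))
})

test_that("secondary SAM records are kept but flagged non-primary", {
  aln <- aln_fix("chr1", start = c(100, 100), end = c(129, 129),
                 strand = "+", read_id = c("r1", "r1"),
                 is_primary = c(TRUE, FALSE))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sam, c(chr1 = 1000L))
  back <- read_alignments(sam, "short")
  expect_equal(sum(back$is_primary), 1)
  expect_equal(nrow(back), 2)
})

test_that("alignment reader rejects unknown formats and strandless BED", {
  expect_error(read_alignments(write_lines_tmp("x", ext = ".txt"), "short"),
               "SAM/BAM and BED6")
  nostrand <- write_lines_tmp("chr1\t10\t40\tr1\t0\t.")
  expect_error(read_alignments(nostrand, "short"), "strand")
})

test_that("expression tables validate values and deduplicate genes", {
  path <- write_lines_tmp(c("gene\ts1\ts2", "Gfap\t1.5\t2.0",
                            "Actb\t10\t11", "Gfap\t3\t4"), ext = ".tsv")
  expect_warning(tab <- read_expression_table(path), "duplicate")
  expect_equal(dim(tab$values), c(2L, 2L))
  expect_equal(unname(tab$values["Gfap", ]), c(3, 4))
  neg <- write_lines_tmp(c("gene\ts1", "Gfap\t-1"), ext = ".tsv")
  expect_error(read_expression_table(neg), "negative")
})

test_that("gene sets drop blanks and comments, manifest is validated", {
  gs <- read_gene_set(write_lines_tmp(c("Gfap", "", "Actb", "# note",
                                        "Gfap", "  ")))
  expect_equal(sort(gs$members), c("Actb", "Gfap"))

  man <- write_lines_tmp(c("sample_id\tgroup\tNs\tNl",
                           "s1\tWT\t1000\t2000",
                           "s2\tAPP\t1000\t2000"), ext = ".tsv")
  expect_equal(nrow(read_sample_manifest(man)), 2)
  dup <- write_lines_tmp(c("sample_id\tgroup\tNs\tNl",
                           "s1\tWT\t1000\t2000",
                           "s1\tAPP\t1000\t2000"), ext = ".tsv")
  expect_error(read_sample_manifest(dup), "duplicate sample_id")
  miss <- write_lines_tmp(c("sample_id\tgroup\tNl", "s1\tWT\t2000"),
                          ext = ".tsv")
  expect_error(read_sample_manifest(miss), "Ns")
})

test_that("FASTQ record counter divides lines by four", {
  fq <- write_lines_tmp(rep(c("@r", "ACGT", "+", "IIII"), 3), ext = ".fastq")
  expect_equal(count_fastq_records(fq), 3)
})
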