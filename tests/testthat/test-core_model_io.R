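test_that("genome_model enforces its invariants", {
  expect_s3_class(genome_model("chr1", 1e8, 4.9e7, 5.1e7), "genome_model")
  expect_error(genome_model(c("chr1", "chr1"), c(1e8, 1e8), c(1, 1), c(2, 2)),
               "unique")
  expect_error(genome_model("chr1", -5, 1, 2), "length")
  expect_error(genome_model("chr1", 1e8, 5e7, 4e7), "cen_start")
})

test_that("read_segments converts coordinates and sorts per-sample profiles", {
  g <- make_toy_genome(2, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
    "S1\tchr1\t1\t1000\t2\t1",
    "S3\tchr2\t5001\t9000\t3\t1",
    "S2\tchr1\t2001\t4000\t2\t0",
    "S1\tchr1\t1001\t2000\t2\t2"
  ), path)
  segs <- read_segments(path, g)
  s1 <- segs[segs$sample == "S1", ]
  expect_equal(s1$start, c(0, 1000))
  expect_equal(s1$end, c(1000, 2000))
  # minor 2 of total 2 swapped to 0 (lesser allele)
  expect_equal(s1$minor_cn, c(1, 0))
  expect_equal(length(unique(segs$sample)), 3)
  expect_true(all(diff(s1$start) > 0))
})

test_that("read_segments swap is warned and overlaps / unknown chroms are errors", {
  g <- make_toy_genome(1, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "S1\tchr1\t1\t1000\t3\t2"), path)
  expect_warning(read_segments(path, g), "swap")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "S1\tchr1\t1\t1000\t2\t1",
               "S1\tchr1\t500\t2000\t2\t1"), path)
  expect_error(read_segments(path, g), "overlap")
  writeLines(c("sample\tchrom\tstart\tend\ttotal_cn\tminor_cn",
               "S1\tchrX\t1\t1000\t2\t1"), path)
  expect_error(read_segments(path, g), "chrX")
})

test_that("segment coordinate round-trip is the identity", {
  g <- make_toy_genome(4, 200)
  sim <- simulate_profile(g, 2, 1, 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(sim$segments, path)
  back <- read_segments(path, g)
  expect_equal(back$start, sim$segments$start)
  expect_equal(back$end, sim$segments$end)
  expect_equal(back$minor_cn, sim$segments$minor_cn)
})

test_that("VCF reader classifies SNVs, deletions and rejections", {
  ref <- c(chr1 = "GGACCTGGATTGCAGT")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t3\t.\tA\tT\t.\tPASS\t.",
    "chr1\t4\t.\tCCTG\tC\t.\tPASS\t.",     # deletion of CTG at pos 5
    "chr1\t8\t.\tG\tGA\t.\tPASS\t.",       # insertion -> rejected
    "chr1\t9\t.\tA\tC\t.\tPASS\t.",
    "chr1\t10\t.\tT\tG\t.\tPASS\t.",
    "chr1\t11\t.\tT\tA\t.\tPASS\t.",
    "chr1\t12\t.\tGC\tG\t.\tPASS\t.",      # deletion of C at pos 13
    "chr1\t14\t.\tA\tG\t.\tPASS\t."
  ), path)
  out <- read_vcf_small_variants(path, ref)
  expect_equal(nrow(out$snvs), 5)
  expect_equal(nrow(out$deletions), 2)
  expect_equal(out$n_rejected, 1)
  expect_equal(out$deletions$pos[1], 5)
  expect_equal(out$deletions$deleted_seq[1], "CTG")
})

test_that("VCF deletion parsing reconstructs the original REF string", {
  ref <- c(chr1 = paste(rep("ACGTTGCA", 20), collapse = ""))
  pos <- c(10L, 50L, 101L)
  len <- c(4L, 2L, 6L)
  dels <- tibble::tibble(chrom = "chr1", pos = pos,
                         deleted_seq = substring(ref, pos, pos + len - 1))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tibble::tibble(chrom = character(), pos = integer(),
                           ref = character(), alt = character()),
            path, deletions = dels, reference = ref)
  out <- read_vcf_small_variants(path, ref)
  expect_equal(out$deletions$pos, dels$pos)
  expect_equal(out$deletions$deleted_seq, dels$deleted_seq)
  # anchor + deleted_seq equals the reference at the VCF record span
  for (i in seq_len(nrow(dels))) {
    span <- unname(substr(ref, dels$pos[i] - 1,
                          dels$pos[i] + nchar(dels$deleted_seq[i]) - 1))
    expect_equal(span, paste0(unname(substr(ref, dels$pos[i] - 1, dels$pos[i] - 1)),
                              dels$deleted_seq[i]))
  }
})

test_that("VCF reader rejects REF disagreeing with the reference", {
  ref <- c(chr1 = "AAAAAAAA")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t3\t.\tC\tT\t.\tPASS\t.",
               "chr1\t4\t.\tA\tG\t.\tPASS\t."), path)
  out <- read_vcf_small_variants(path, ref)
  expect_equal(nrow(out$snvs), 1)
  expect_equal(out$n_rejected, 1)
  expect_error(read_vcf_small_variants(path, c(chr2 = "AAAA")), "contig")
})

test_that("signature matrix reader validates and renormalizes columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- toy_sbs_sigs
  readr::write_tsv(m, path)
  ok <- read_signature_matrix(path)
  expect_equal(colSums(as.matrix(ok[, -1])), setNames(rep(1, 10), names(ok)[-1]))

  m_bad <- m
  m_bad$SBS1 <- m_bad$SBS1 * 0.9
  readr::write_tsv(m_bad, path)
  expect_error(read_signature_matrix(path), "sums to")

  m_close <- m
  m_close$SBS1 <- m_close$SBS1 * 0.9995
  readr::write_tsv(m_close, path)
  renorm <- read_signature_matrix(path)
  expect_equal(sum(renorm$SBS1), 1, tolerance = 1e-9)

  m_neg <- m
  m_neg$SBS2[1] <- -0.01
  readr::write_tsv(m_neg, path)
  expect_error(read_signature_matrix(path), "negative")

  readr::write_tsv(m[1:40, ], path)
  expect_error(read_signature_matrix(path), "96")
})

test_that("clinical table reader groups lines and enforces dates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(clinical_fixture(), path)
  cl <- read_clinical_table(path)
  counts <- dplyr::count(cl, patient_id)
  expect_equal(nrow(counts), 4)
  expect_equal(sort(counts$n, decreasing = TRUE), c(2, 2, 2, 1))

  bad <- clinical_fixture()
  bad$end[1] <- as.Date("2014-01-01")
  readr::write_tsv(bad, path)
  expect_error(read_clinical_table(path), "P1 line 1")

  bad2 <- clinical_fixture()
  bad2$last_followup[7] <- NA
  readr::write_tsv(bad2, path)
  expect_error(read_clinical_table(path), "last_followup")
})

test_that("results writer round-trips metrics and handles an empty cohort", {
  withr::with_seed(9, {
    metrics <- tibble::tibble(
      sample = sprintf("S%02d", 1:10),
      loh = rpois(10, 3), tai = rpois(10, 2), lst = rpois(10, 4),
      hrd_index = NA_integer_, sbs3 = runif(10), sbs8 = runif(10),
      sv3 = runif(10), sv5 = runif(10), mh_fraction = runif(10),
      hrdetect = runif(10), hrd_high = rpois(10, 1) > 0
    )
    metrics$hrd_index <- metrics$loh + metrics$tai + metrics$lst
    stem <- withr::local_tempfile()
    write_results(metrics, stem)
    back <- read_results(stem)
    expect_equal(as.data.frame(back), as.data.frame(metrics))
    json <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
    expect_equal(json$sample, metrics$sample)
    expect_equal(json$sbs3, metrics$sbs3)

    empty <- metrics[0, ]
    write_results(empty, stem)
    expect_equal(nrow(read_results(stem)), 0)
  })
})
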