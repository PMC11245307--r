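test_that("trimming strips adapters, records the barcode, rejects with reasons", {
  sch <- adapter_scheme(linker3 = "TGGAATTCTCGG")
  insert <- "ACGTACGTACGTACGTACGTACGTAC"   # 26 nt
  raw <- paste0("ACGT", insert, "NNNNNN", "CGTAC", sch$linker3)
  got <- trim_reads(c(r1 = raw), sch)
  expect_equal(got$status, "ok")
  expect_equal(got$insert, insert)
  expect_equal(got$barcode, "CGTAC")

  # no linker anywhere
  no_link <- trim_reads(c(r2 = paste0("ACGT", insert, strrep("A", 20))), sch)
  expect_equal(no_link$status, "no_adapter")

  # insert too short after trimming
  shorty <- paste0("ACGT", "ACGTACGTAC", "NNNNNN", "CGTAC", sch$linker3)
  expect_equal(trim_reads(c(r3 = shorty), sch)$status, "too_short")

  # one linker mismatch tolerated
  mm <- sub("TGGA", "TGCA", sch$linker3)
  expect_equal(trim_reads(c(r4 = paste0("ACGT", insert, "NNNNNN", "CGTAC",
                                        mm)), sch)$status, "ok")
})

test_that("re-wrapping a trimmed insert in the adapter architecture round-trips", {
  set.seed(5)
  sch <- adapter_scheme()
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    len <- sample(18:30, 1)
    insert <- paste(sample(bases, len, TRUE), collapse = "")
    barcode <- paste(sample(bases, sch$barcode_len, TRUE), collapse = "")
    raw <- paste0(paste(sample(bases, sch$random5, TRUE), collapse = ""),
                  insert,
                  paste(sample(bases, sch$random3, TRUE), collapse = ""),
                  barcode, sch$linker3)
    got <- trim_reads(setNames(raw, sprintf("r%d", i)), sch)
    expect_equal(got$status, "ok")
    expect_equal(got$insert, insert)
    expect_equal(got$barcode, barcode)
  }
})

test_that("FASTQ reading validates structure with record numbers", {
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(c(a = "ACGTACGT", b = "TTTTCCCC"), path)
  got <- read_fastq(path)
  expect_equal(got, c(a = "ACGTACGT", b = "TTTTCCCC"))

  writeLines(c("@a", "ACGT", "+", "IIII", "bad_header", "ACGT", "+", "IIII"),
             path)
  expect_error(read_fastq(path), "record 2")
  writeLines(c("@a", "ACGT", "+", "III"), path)  # quality length mismatch
  expect_error(read_fastq(path), "record 1")
})

test_that("ncRNA filtering categorizes by annotation overlap, then by length", {
  ann <- data.frame(
    chrom = "chr", start = c(0, 1000), end = c(100, 1100),
    feature_type = c("rRNA", "miRNA"), stringsAsFactors = FALSE)
  reads <- data.frame(read_id = c("r1", "r2", "r3", "r4"),
                      length = c(26L, 22L, 26L, 31L),
                      stringsAsFactors = FALSE)
  aln <- aln_df(c("r1", "r2", "r3", "r4"), "chr",
                c(50, 1010, 5000, 6000), c(76, 1032, 5026, 6031))
  expect_warning(
    got <- filter_ncrna(reads, aln, ann, mito_chrom = "chrM"),
    "tRNA")  # categories absent from the annotation are reported
  expect_equal(got$category,
               c("filtered_ncrna", "mirna", "pirna_candidate", "other"))

  # a mitochondrial hit overrides everything else
  mito <- suppressWarnings(
    filter_ncrna(reads[1, ], aln_df("r1", "chrM", 0, 26), ann["2", ],
                 mito_chrom = "chrM"))
  expect_equal(mito$category, "filtered_ncrna")
})

test_that("miRNA normalization scales to one million sequenced miRNA reads", {
  cfg <- pipeline_config()
  expect_equal(mirna_norm_factor(2e6, cfg), 0.5)
  expect_equal(50 * mirna_norm_factor(2e6, cfg), 25)
  expect_equal(mirna_norm_factor(1e6, cfg), 1)
  expect_error(mirna_norm_factor(0, cfg), "no miRNA reads")
})

test_that("the small-RNA pipeline conserves reads and normalizes consistently", {
  sg <- sim_genome(seed = 3)
  ss <- sim_srna(sg, composition = list(n_mirna = 2000), seed = 5)
  cfg <- pipeline_config()
  res <- run_smallrna_pipeline(cfg, ss$fastq, adapter_scheme(), ss$genome_aln,
                               sg$annotations, te_hits = ss$te_aln,
                               te_lengths = sg$te_lengths,
                               clusters = sg$clusters,
                               mito_chrom = sg$mito_chrom)
  rep <- res$report
  total <- rep$reads[rep$stage == "raw"]
  expect_equal(sum(rep$reads[rep$stage != "raw"]), total)
  # category counts equal the generator truth exactly
  expect_equal(res$library$mirna_reads,
               unname(ss$expected$categories["mirna"]))
  expect_equal(res$library$norm_factor, ss$expected$norm_factor)
  # normalized miRNA total is the normalization target exactly
  expect_equal(res$library$mirna_reads * res$library$norm_factor,
               cfg$mirna_norm_target)
  expect_equal(res$te_counts, ss$expected$te_antisense_norm)
  expect_equal(res$cluster_counts, ss$expected$cluster_unique_norm)
})

test_that("a miRNA-only library yields empty piRNA tables but a defined factor", {
  sg <- sim_genome(seed = 3)
  ss <- sim_srna(sg, composition = list(
    n_mirna = 500, n_ncrna = 0,
    te_antisense = setNames(rep(0L, 3), names(sg$te_lengths)),
    te_sense = setNames(rep(0L, 3), names(sg$te_lengths)),
    cluster_unique = setNames(rep(0L, 2), sg$clusters$name)), seed = 6)
  res <- run_smallrna_pipeline(pipeline_config(), ss$fastq, adapter_scheme(),
                               ss$genome_aln, sg$annotations,
                               te_hits = ss$te_aln,
                               te_lengths = sg$te_lengths,
                               clusters = sg$clusters,
                               mito_chrom = sg$mito_chrom)
  expect_equal(res$library$norm_factor, 2000)
  expect_true(all(res$te_counts == 0))
  expect_true(all(res$cluster_counts == 0))
})

test_that("a library with zero miRNA reads is a hard error", {
  sg <- sim_genome(seed = 3)
  expect_error(sim_srna(sg, composition = list(n_mirna = 0), seed = 1),
               "miRNA")
  expect_error(mirna_norm_factor(0), "normalization undefined")
})
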