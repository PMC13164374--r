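write_se_fixture <- function(path, rows) {
  header <- paste(c("ID", "GeneID", "geneSymbol", "chr", "strand",
                    "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
                    "downstreamES", "downstreamEE", "ID", "IJC_SAMPLE_1",
                    "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
                    "IncFormLen", "SkipFormLen", "PValue", "FDR", "IncLevel1",
                    "IncLevel2", "IncLevelDifference"), collapse = "\t")
  writeLines(c(header, rows), path)
}

test_that("rMATS SE parsing maps count lists and coordinates", {
  path <- withr::local_tempfile(fileext = ".txt")
  row <- paste(c("7", "ENSG1", "FOO", "chr2", "-", "1300", "1400", "1000",
                 "1100", "1600", "1700", "7", "30,28,31", "10,12,9",
                 "20,22,25", "20,18,15", "198", "99", "0.001", "0.01",
                 "0.6,NA,0.62", "0.4,0.41,0.43", "0.19"), collapse = "\t")
  write_se_fixture(path, row)
  ev <- read_rmats_jc(path, "SE")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ijc_g1[[1]], c(30L, 28L, 31L))
  expect_equal(ev$sjc_g1[[1]], c(10L, 12L, 9L))
  expect_equal(ev$exon_start, 1300L)
  expect_equal(ev$upstream_ee, 1100L)
  expect_true(is.na(ev$inc_level_g1[[1]][2]))
  expect_equal(ev$inc_level_difference, 0.19)
  expect_equal(ev$event_type, "SE")
})

test_that("rMATS parsing: header-only file gives an empty table, missing column errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_se_fixture(path, character())
  expect_equal(nrow(read_rmats_jc(path, "SE")), 0L)
  # drop a mandatory column
  lines <- readLines(path)
  writeLines(sub("\tIncLevelDifference", "", lines), path)
  expect_error(read_rmats_jc(path, "SE"), "IncLevelDifference")
})

test_that("rMATS tables round-trip through the writer for every event class", {
  cfg <- sim_config(seed = 3, n_events_per_type = 10L)
  genome <- make_toy_genome(cfg)
  sim <- simulate_events(genome, cfg)
  for (tp in cfg$event_types) {
    path <- withr::local_tempfile(fileext = ".txt")
    orig <- sim$events[sim$events$event_type == tp, , drop = FALSE]
    rownames(orig) <- NULL
    write_rmats_jc(orig, path)
    back <- read_rmats_jc(path, tp)
    for (col in c("event_id", "gene_id", "chrom", "strand", "ijc_g1",
                  "sjc_g1", "ijc_g2", "sjc_g2", "fdr", "p_value",
                  "inc_level_difference"))
      expect_identical(back[[col]], orig[[col]], info = paste(tp, col))
    expect_equal(back$inc_level_g1, orig$inc_level_g1, tolerance = 0)
    for (col in names(splicedit:::rmats_coord_cols[[tp]]))
      expect_identical(back[[col]], orig[[col]], info = paste(tp, col))
  }
})

test_that("DEU tables parse with the sign-based direction rule", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(featureID = c("E001", "E002", "E003"),
                   groupID = c("g1", "g1", "g2"),
                   "genomicData.seqnames" = "chr1",
                   "genomicData.start" = c(101L, 501L, 901L),
                   "genomicData.end" = c(200L, 600L, 1000L),
                   "genomicData.strand" = "+",
                   log2fold = c(1.2, -0.4, 0.01),
                   pvalue = c(1e-4, 0.2, 0.01),
                   padj = c(1e-3, 0.4, 0.04), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  deu <- read_dexseq(path)
  expect_equal(deu$direction, c("included", "excluded", "included"))
  expect_equal(deu$start, c(100L, 500L, 900L))  # 1-based -> 0-based
  expect_equal(deu$end, c(200L, 600L, 1000L))
  expect_equal(sum(deu$fdr < 0.05), 2L)
})

test_that("BED6 round-trips bit-exactly and bad rows error", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t100\t.\t0\t+", path)
  iv <- read_bed(path)
  expect_equal(iv$start, 99L)
  expect_equal(iv$end, 100L)
  expect_equal(iv$strand, "+")
  set.seed(5)
  iv <- random_intervals(500)
  write_bed(iv, path)
  expect_identical(read_bed(iv_path <- path), iv)
  content1 <- readLines(path)
  write_bed(read_bed(path), path)
  expect_identical(readLines(path), content1)
  writeLines("chr1\t50\t40\tx\t0\t+", path)
  expect_error(read_bed(path), "start >= end")
})

test_that("database BEDs merge with provenance flags, shared sites stored once", {
  radar <- withr::local_tempfile(fileext = ".bed")
  darned <- withr::local_tempfile(fileext = ".bed")
  # 10 RADAR sites, 3 on minus strand; 4 shared with DARNED
  strands <- c(rep("+", 7), rep("-", 3))
  write_bed(gintervals("chr1", seq(100, 1000, by = 100),
                       seq(101, 1001, by = 100), strands, "r"), radar)
  write_bed(gintervals("chr1", seq(100, 400, by = 100),
                       seq(101, 401, by = 100), "+", "d"), darned)
  db <- load_db_sites(radar, darned)
  expect_equal(nrow(db), 10L)
  expect_equal(sum(db$strand == "-"), 3L)
  expect_equal(sum(db$in_radar), 10L)
  expect_equal(sum(db$in_darned), 4L)
  expect_equal(sum(db$in_radar & db$in_darned), 4L)
})

test_that("editing tables round-trip and compute replicate support", {
  sites <- make_sites("chr1", c(100L, 250L, 400L),
                      depth = matrix(c(5L, 0L, 8L,
                                       3L, 2L, 0L,
                                       9L, 9L, 9L), 3, 3, byrow = TRUE,
                                     dimnames = list(NULL, paste0("s", 1:3))),
                      edited = matrix(c(2L, 0L, 1L,
                                        0L, 1L, 0L,
                                        0L, 0L, 0L), 3, 3, byrow = TRUE,
                                      dimnames = list(NULL, paste0("s", 1:3))))
  expect_equal(sites$replicate_support, c(2L, 1L, 0L))
  paths <- file.path(withr::local_tempdir(), paste0("s", 1:3, ".tsv"))
  write_editing_table(sites, paths)
  back <- read_editing_table(paths, paste0("s", 1:3))
  expect_identical(back$pos, sites$pos)
  expect_identical(unclass(back$depth), unclass(sites$depth))
  expect_identical(unclass(back$edited), unclass(sites$edited))
  expect_identical(back$replicate_support, sites$replicate_support)
})

test_that("VCF positions convert from 1-based and AD fields populate depths", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:6,4\t0/0:9,0",
    "chr1\t250\t.\tT\tC\t.\tPASS\t.\tGT:AD\t0/1:2,3\t0/1:5,5"), path)
  sites <- read_vcf_sites(path)
  expect_equal(sites$pos, c(99L, 249L))
  expect_equal(unname(sites$depth[1, ]), c(10L, 9L))
  expect_equal(unname(sites$edited[1, ]), c(4L, 0L))
  expect_equal(sites$replicate_support, c(1L, 2L))
  expect_equal(sites$strand, c(".", "."))
})

test_that("VCF without depth information warns and marks depths missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), path)
  expect_warning(sites <- read_vcf_sites(path), "depth")
  expect_true(all(is.na(sites$depth)))
})

test_that("toy-genome GTF reads back through rtracklayer with matching coordinates", {
  cfg <- sim_config(seed = 2, n_genes = 6L, n_chromosomes = 2L)
  genome <- make_toy_genome(cfg)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  alu <- withr::local_tempfile(fileext = ".bed")
  write_genome(genome, gtf, alu)
  gm <- read_gtf(gtf)
  expect_equal(nrow(gm$genes), 6L)
  expect_equal(nrow(gm$exons), nrow(genome$exons))
  g1 <- genome$genes[1, ]
  got <- gm$genes[gm$genes$label == g1$gene_id, ]
  expect_equal(got$start, g1$start)
  expect_equal(got$end, g1$end)
  expect_equal(got$strand, g1$strand)
})
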