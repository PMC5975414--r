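test_that("GTF coordinates convert to 0-based half-open on read", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, data.frame(
    chrom = "chr1", start1 = c(101, 301), end1 = c(200, 400), strand = "+",
    gene_id = "g1", tx_id = "t1", symbol = "SYM1"))
  models <- read_gene_models(gtf)
  expect_length(models, 1)
  tx <- models[["g1"]]$transcripts[["t1"]]
  expect_equal(tx$exons$start, c(100, 300))
  expect_equal(tx$exons$end, c(200, 400))
  expect_equal(unname(tx$span), c(100, 400))
})

test_that("empty GTF yields an empty model list", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(), gtf)
  expect_identical(read_gene_models(gtf), list())
})

test_that("malformed GTF lines are reported with their line number", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\texon\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1:banana"), gtf)
  expect_error(read_gene_models(gtf), "line 2")

  writeLines(c(
    "# comment",
    'chr1\tt\texon\tfoo\t10\t.\t+\t.\tgene_id "g"; transcript_id "t";'), gtf)
  expect_error(read_gene_models(gtf), "line 2")
})

test_that("duplicate transcript IDs across genes are an error", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, data.frame(
    chrom = "chr1", start1 = c(1, 1001), end1 = c(100, 1100), strand = "+",
    gene_id = c("g1", "g2"), tx_id = "t1", symbol = c("A", "B")))
  expect_error(read_gene_models(gtf), "duplicate transcript ID")
})

test_that("book-ended and overlapping exon records are merged", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, data.frame(
    chrom = "chr1", start1 = c(1, 101, 301, 350), end1 = c(100, 200, 400, 450),
    strand = "+", gene_id = "g1", tx_id = "t1", symbol = "SYM1"))
  tx <- read_gene_models(gtf)[["g1"]]$transcripts[["t1"]]
  expect_equal(tx$exons$start, c(0, 300))
  expect_equal(tx$exons$end, c(200, 450))
})

test_that("synthetic fixture GTF parses back to the generator manifest", {
  dir <- withr::local_tempdir()
  cfg <- fixture_config(seed = 11, n_genes = 3, transcripts_per_gene = 2,
                        n_samples = 4)
  models_out <- make_gene_models(cfg, dir)
  models <- read_gene_models(models_out$gtf)
  expect_length(models, 3)
  expect_equal(sum(lengths(lapply(models, `[[`, "transcripts"))), 6)
  for (g in models_out$genes) {
    parsed <- models[[g$gene_id]]
    expect_equal(parsed$symbol, g$symbol)
    expect_equal(parsed$aliases, g$alias)
    for (t in g$transcripts) {
      expect_equal(nrow(parsed$transcripts[[t$transcript_id]]$exons),
                   t$n_exons)
    }
  }
})

test_that("models round-trip through the GTF dialect", {
  dir <- withr::local_tempdir()
  cfg <- fixture_config(seed = 3, n_genes = 2, n_samples = 4)
  models <- read_gene_models(make_gene_models(cfg, dir)$gtf)
  out <- file.path(dir, "roundtrip.gtf")
  write_gene_models_gtf(models, out)
  expect_equal(read_gene_models(out), models)
})

test_that("parsing agrees with rtracklayer on the fixture GTF", {
  skip_if_not_installed("rtracklayer")
  dir <- withr::local_tempdir()
  cfg <- fixture_config(seed = 5, n_genes = 2, n_samples = 4)
  gtf <- make_gene_models(cfg, dir)$gtf
  models <- read_gene_models(gtf)
  gr <- rtracklayer::import(gtf)
  gr <- gr[gr$type == "exon"]
  for (gm in models) {
    for (tx in gm$transcripts) {
      ref <- gr[gr$transcript_id == tx$transcript_id]
      ref <- ref[order(GenomicRanges::start(ref))]
      expect_equal(tx$exons$start, GenomicRanges::start(ref) - 1)
      expect_equal(tx$exons$end, GenomicRanges::end(ref))
    }
  }
})

test_that("feature ID grammar parses exons, junctions and rejects junk", {
  f <- parse_feature_id("chr1:1000-1099:+")
  expect_equal(f$kind, "exon")
  expect_equal(f$interval$start, 999)
  expect_equal(f$interval$end, 1099)
  expect_equal(f$interval$strand, "+")

  j <- parse_feature_id("chr1:1099:+,chr1:2000:+")
  expect_equal(j$kind, "junction")
  expect_equal(j$interval$donor, 1098)
  expect_equal(j$interval$acceptor, 1999)

  expect_error(parse_feature_id("chr1:banana"), "expected")
  expect_error(parse_feature_id("chr1:5:+,chr2:9:+"), "chromosome")
})

make_two_tx_gene <- function() {
  gtf <- tempfile(fileext = ".gtf")
  write_test_gtf(gtf, data.frame(
    chrom = "chr1",
    start1 = c(101, 501, 901, 501),
    end1 = c(200, 600, 1000, 600),
    strand = "+", gene_id = "g1",
    tx_id = c("tA", "tA", "tA", "tB"), symbol = "SYM1"))
  on.exit(unlink(gtf))
  read_gene_models(gtf)[["g1"]]
}

test_that("exon features assign by span overlap, junctions need both anchors", {
  gene <- make_two_tx_gene()   # tA span [100,1000), tB span [500,600)
  feats <- parse_feature_table(c(
    "chr1:151-250:+",           # inside tA span only
    "chr1:2001-2100:+",         # outside both
    "chr1:550-580:+",           # inside both spans
    "chr1:200:+,chr1:501:+",    # both anchors in tA span only
    "chr1:550:+,chr1:1500:+"    # acceptor outside both spans
  ))
  ann <- annotate_features(feats, gene)
  expect_equal(ann$transcript_ids[[1]], "tA")
  expect_length(ann$transcript_ids[[2]], 0)
  expect_true(is.na(ann$gene_id[2]))
  expect_equal(ann$transcript_ids[[3]], c("tA", "tB"))
  expect_equal(ann$transcript_ids[[4]], "tA")
  expect_length(ann$transcript_ids[[5]], 0)
  expect_equal(ann$feature_id, feats$feature_id)  # input order kept
})

test_that("strand rule: unknown matches either, known mismatch excludes", {
  gene <- make_two_tx_gene()
  feats <- parse_feature_table(c("chr1:151-250:.", "chr1:151-250:-"))
  ann <- annotate_features(feats, gene)
  expect_equal(ann$transcript_ids[[1]], "tA")
  expect_length(ann$transcript_ids[[2]], 0)
})

test_that("annotation equals the brute-force all-pairs oracle", {
  gene <- make_two_tx_gene()
  set.seed(42)
  for (rep in 1:4) {
    n <- 50
    start1 <- sample(1:2500, n)
    len <- sample(10:400, n, replace = TRUE)
    kind <- sample(c("exon", "junction"), n, replace = TRUE)
    strand <- sample(c("+", "-", "."), n, replace = TRUE)
    ids <- ifelse(kind == "exon",
                  sprintf("chr1:%d-%d:%s", start1, start1 + len, strand),
                  sprintf("chr1:%d:%s,chr1:%d:%s", start1, strand,
                          start1 + len, strand))
    feats <- parse_feature_table(ids)
    ann <- annotate_features(feats, gene)
    expect_identical(lapply(ann$transcript_ids, identity),
                     oracle_annotate(feats, gene))
  }
})

test_that("enlarging a feature interval never shrinks its assignment set", {
  gene <- make_two_tx_gene()
  set.seed(7)
  for (rep in 1:20) {
    s1 <- sample(1:1500, 1); len <- sample(10:200, 1)
    ids <- c(sprintf("chr1:%d-%d:+", s1, s1 + len),
             sprintf("chr1:%d-%d:+", max(1, s1 - 50), s1 + len + 50))
    ann <- annotate_features(parse_feature_table(ids), gene)
    expect_true(all(ann$transcript_ids[[1]] %in% ann$transcript_ids[[2]]))
  }
})

test_that("BED12 export has one well-formed line per transcript", {
  dir <- withr::local_tempdir()
  cfg <- fixture_config(seed = 3, n_genes = 2, n_samples = 4)
  models <- read_gene_models(make_gene_models(cfg, dir)$gtf)
  bed <- file.path(dir, "models.bed")
  export_bed12(models, bed)
  lines <- readLines(bed)
  expect_length(lines, 4)
  fields <- strsplit(lines, "\t")
  expect_true(all(lengths(fields) == 12))
  # block count matches comma-separated block sizes
  for (f in fields) {
    expect_length(strsplit(f[11], ",")[[1]], as.integer(f[10]))
  }
})
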