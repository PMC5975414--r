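make_viz_fixture <- function(seed = 12, n_samples = 12) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- fixture_config(seed = seed, n_samples = n_samples)
  man <- simulate_cohort(cfg, dir)
  gene <- read_gene_models(man$files$gtf)[[1]]
  u <- usage(read_quant_tsv(man$files$exon))
  groups <- split(man$samples, man$groups)[unique(man$groups)]
  list(gene = gene, usage = u, groups = groups, manifest = man, cfg = cfg)
}

test_that("samples order by gene expression within groups, ties by ID", {
  e <- c(A = 3, B = 1, C = 2)
  ord <- order_samples(list(g = c("A", "B", "C")), e)
  expect_equal(ord$sample_id, c("B", "C", "A"))

  e2 <- c(X = 5, Y = 5)
  expect_equal(order_samples(list(g = c("Y", "X")), e2)$sample_id, c("X", "Y"))

  set.seed(40)
  ids <- sprintf("S%03d", 1:150)
  e3 <- stats::setNames(sample(rep(1:30, 5)), ids)
  groups <- split(ids, rep(c("a", "b", "c"), each = 50))
  ord3 <- order_samples(groups, e3)
  # independent stable sort oracle
  oracle <- unlist(lapply(names(groups), function(g) {
    df <- data.frame(id = groups[[g]], e = e3[groups[[g]]])
    df$id[order(df$e, df$id)]
  }))
  expect_equal(ord3$sample_id, oracle)
})

test_that("transcript layout maps genomic positions linearly to pixels", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, data.frame(
    chrom = "chr1", start1 = 1001, end1 = 2000, strand = "+",
    gene_id = "g", tx_id = "t", symbol = "S"))
  gene <- read_gene_models(gtf)[["g"]]
  lay <- layout_transcripts(gene, 500)
  expect_length(lay$transcripts, 1)
  tx <- lay$transcripts[[1]]
  expect_equal(nrow(tx$boxes), 1)
  expect_equal(tx$boxes$x, 0)
  expect_equal(tx$boxes$width, 500)
  expect_equal(unname(tx$line), c(0, 500))

  # exon centered at the span midpoint lands at pixel_width / 2
  write_test_gtf(gtf, data.frame(
    chrom = "chr1", start1 = c(1, 451, 901), end1 = c(100, 550, 1000),
    strand = "+", gene_id = "g", tx_id = "t", symbol = "S"))
  lay2 <- layout_transcripts(read_gene_models(gtf)[["g"]], 400)
  mid <- lay2$transcripts[[1]]$boxes
  expect_equal(mid$x[2] + mid$width[2] / 2, 200)
  # hand-computed linear interpolation: (450 - 0) / 1000 * 400
  expect_equal(mid$x[2], 450 / 1000 * 400)
})

test_that("usage marks are proportional and the document is well-formed XML", {
  skip_if_not_installed("xml2")
  v <- matrix(c(0, 10), 1, dimnames = list("F1", c("sA", "sB")))
  u <- usage(quant_matrix(v, "exon"))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_test_gtf(gtf, data.frame(chrom = "chr1", start1 = 1, end1 = 100,
                                 strand = "+", gene_id = "g", tx_id = "t",
                                 symbol = "S"))
  gene <- read_gene_models(gtf)[["g"]]
  doc <- render_main(plot_spec(gene, u, list(grp = c("sA", "sB")),
                               options = list(row_h = 30)))
  xml <- xml2::read_xml(as.character(doc))   # errors if not well-formed
  cells <- xml2::xml_find_all(xml, "//*[@class='usage-cell']")
  expect_length(cells, 2)
  h <- as.numeric(xml2::xml_attr(cells, "height"))
  ids <- xml2::xml_attr(cells, "data-sample-id")
  expect_equal(h[ids == "sA"], 0)
  expect_equal(h[ids == "sB"], 30)
})

test_that("usage cell data attributes round-trip the usage matrix", {
  skip_if_not_installed("xml2")
  fx <- make_viz_fixture()
  doc <- render_main(plot_spec(fx$gene, fx$usage, fx$groups))
  xml <- xml2::read_xml(as.character(doc))
  cells <- xml2::xml_find_all(xml, "//*[@class='usage-cell']")
  expect_length(cells, nrow(fx$usage$values) * ncol(fx$usage$values))
  y_back <- as.numeric(xml2::xml_attr(cells, "data-y"))
  fid <- xml2::xml_attr(cells, "data-feature-id")
  sid <- xml2::xml_attr(cells, "data-sample-id")
  y_true <- fx$usage$values[cbind(fid, sid)]
  expect_equal(y_back, unname(y_true), tolerance = 1e-9)
})

test_that("rendered sample order equals order_samples output", {
  skip_if_not_installed("xml2")
  fx <- make_viz_fixture()
  doc <- render_main(plot_spec(fx$gene, fx$usage, fx$groups))
  xml <- xml2::read_xml(as.character(doc))
  bars <- xml2::xml_find_all(xml, "//*[@class='expr-bar']")
  rendered <- xml2::xml_attr(bars, "data-sample-id")
  expect_equal(rendered,
               order_samples(fx$groups, fx$usage$gene_expr)$sample_id)
})

test_that("rendering a plot_spec is byte-deterministic", {
  fx <- make_viz_fixture()
  s1 <- as.character(render_main(plot_spec(fx$gene, fx$usage, fx$groups)))
  s2 <- as.character(render_main(plot_spec(fx$gene, fx$usage, fx$groups)))
  expect_identical(s1, s2)
  dir <- withr::local_tempdir()
  write_svg(render_main(plot_spec(fx$gene, fx$usage, fx$groups)),
            file.path(dir, "a.svg"))
  write_svg(render_main(plot_spec(fx$gene, fx$usage, fx$groups)),
            file.path(dir, "b.svg"))
  expect_identical(unname(tools::md5sum(file.path(dir, "a.svg"))),
                   unname(tools::md5sum(file.path(dir, "b.svg"))))
})

test_that("plot_spec rejects bad groupings", {
  fx <- make_viz_fixture()
  expect_error(plot_spec(fx$gene, fx$usage, list(g = character())), "empty group")
  expect_error(plot_spec(fx$gene, fx$usage,
                         list(a = fx$groups[[1]], b = fx$groups[[1]])),
               "disjoint")
  expect_error(plot_spec(fx$gene, fx$usage, list(g = c("nope"))), "absent")
})

test_that("box plots carry order-statistic summaries (Tukey convention)", {
  skip_if_not_installed("xml2")
  doc <- render_boxplot(list(g1 = c(1, 2, 3, 4, 5), g2 = 7))
  xml <- xml2::read_xml(as.character(doc))
  boxes <- xml2::xml_find_all(xml, "//*[@class='box']")
  expect_length(boxes, 2)
  expect_equal(as.numeric(xml2::xml_attr(boxes[1], "data-median")), 3)
  # degenerate single-value group: zero-height box
  expect_equal(as.numeric(xml2::xml_attr(boxes[2], "height")), 0)

  set.seed(41)
  vals <- list(a = stats::rlnorm(40), b = stats::rlnorm(25, 1))
  xml2 <- xml2::read_xml(as.character(render_boxplot(vals)))
  bx <- xml2::xml_find_all(xml2, "//*[@class='box']")
  for (k in 1:2) {
    v <- sort(vals[[k]])
    m <- length(v)
    q_or <- function(p) {                 # independent order-stat oracle
      h <- (m - 1) * p; lo <- floor(h)
      v[lo + 1] + (h - lo) * (v[min(lo + 2, m)] - v[lo + 1])
    }
    expect_equal(as.numeric(xml2::xml_attr(bx[k], "data-q1")), q_or(0.25),
                 tolerance = 1e-9)
    expect_equal(as.numeric(xml2::xml_attr(bx[k], "data-median")), q_or(0.5),
                 tolerance = 1e-9)
    expect_equal(as.numeric(xml2::xml_attr(bx[k], "data-q3")), q_or(0.75),
                 tolerance = 1e-9)
  }
})

test_that("KM rendering steps once per event time and parses back", {
  skip_if_not_installed("xml2")
  cv <- km_estimate(survival_samples(letters[1:6], c(2, 4, 4, 7, 9, 12),
                                     c(1, 1, 0, 1, 0, 0), rep(1, 6)),
                    group_label = "grp")
  doc <- render_km(cv, options = list(cutoff = 5))
  xml <- xml2::read_xml(as.character(doc))
  path <- xml2::xml_find_first(xml, "//*[@class='km-curve']")
  d <- xml2::xml_attr(path, "d")
  expect_equal(lengths(regmatches(d, gregexpr("V", d))), 3)  # 3 event times
  t_back <- as.numeric(strsplit(xml2::xml_attr(path, "data-times"), ",")[[1]])
  s_back <- as.numeric(strsplit(xml2::xml_attr(path, "data-survival"), ",")[[1]])
  expect_equal(t_back, cv$times)
  expect_equal(s_back, cv$survival, tolerance = 1e-9)
  ticks <- xml2::xml_find_all(xml, "//*[@class='censor-tick']")
  expect_length(ticks, 3)
  legend <- xml2::xml_find_all(xml, "//*[@class='legend-cutoff']")
  expect_match(xml2::xml_text(legend), "cutoff = 5.000")
})

test_that("an all-censored curve renders without steps", {
  skip_if_not_installed("xml2")
  cv <- km_estimate(survival_samples(c("a", "b"), c(3, 8), c(0, 0), c(1, 2)))
  xml <- xml2::read_xml(as.character(render_km(cv)))
  d <- xml2::xml_attr(xml2::xml_find_first(xml, "//*[@class='km-curve']"), "d")
  expect_false(grepl("V", d))
  expect_length(xml2::xml_find_all(xml, "//*[@class='axis-x']"), 1)
})
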