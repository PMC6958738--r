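# On-disk dialect readers/writers: totality, located errors, round trips.

test_that("spatial BED parses valid rows in order and rejects bad rows by line", {
  p <- write_bed_fixture(c(
    "# a comment",
    "chr1\t100\t148\tr1\t0\t+\tGENE1\t3\t4",
    "chr1\t200\t248\tr2\t0\t-\t.\t1\t1",
    "chr2\t5\t6\tr3\t0\t+\t.\t33\t35"))
  rd <- read_spatial_bed(p)
  expect_equal(nrow(rd), 3)
  expect_equal(rd$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(rd$gene_tag, c("GENE1", "", ""))
  expect_equal(rd$x, c(3L, 1L, 33L))

  bad_strand <- write_bed_fixture(c(
    "chr1\t100\t148\tr1\t0\t+\t.\t1\t1",
    "chr1\t100\t148\tr1\t0\t.\t.\t1\t1"))
  expect_error(read_spatial_bed(bad_strand), "line 2.*strand")

  bad_int <- write_bed_fixture("chr1\tabc\t148\tr1\t0\t+\t.\t1\t1")
  expect_error(read_spatial_bed(bad_int), "line 1.*start")

  short_row <- write_bed_fixture(c(
    "chr1\t100\t148\tr1\t0\t+\t.\t1\t1",
    "chr1\t100\t148\tr1\t0\t+\t.\t1"))
  expect_error(read_spatial_bed(short_row), "line 2")

  oob <- write_bed_fixture("chr1\t100\t148\tr1\t0\t+\t.\t34\t1")
  expect_error(read_spatial_bed(oob, array_bounds = c(33, 35)), "bounds")
})

test_that("a one-molecule-per-spot file for a full 1007-spot array yields 1007 reads", {
  # 19 x 53 = 1007 spot coordinates, one molecule each
  xy <- expand.grid(x = 1:19, y = 1:53)
  lines <- sprintf("chr1\t%d\t%d\t.\t0\t+\t.\t%d\t%d",
                   100 + seq_len(nrow(xy)), 200 + seq_len(nrow(xy)),
                   xy$x, xy$y)
  p <- write_bed_fixture(lines)
  rd <- read_spatial_bed(p)
  expect_equal(nrow(rd), 1007)
  expect_equal(nrow(unique(rd[, c("x", "y")])), 1007)
})

test_that("spatial BED write -> read round-trips", {
  rd <- make_reads("chr1", c(10, 50), c(58, 98), c("+", "-"),
                   x = c(2, 3), y = c(4, 5), gene_tag = c("", "G1"))
  p <- withr::local_tempfile(fileext = ".bed")
  write_spatial_bed(rd, p)
  back <- read_spatial_bed(p)
  expect_equal(back, rd[, !"dataset"], ignore_attr = TRUE)
})

test_that("GTF coordinates convert to 0-based half-open and transcripts union per gene", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\tgene\t101\t200\t.\t+\t.\tgene_id "G1"; gene_name "ALPHA";',
    'chr1\tx\ttranscript\t301\t400\t.\t-\t.\tgene_id "G2"; gene_name "BETA";',
    'chr1\tx\ttranscript\t351\t500\t.\t-\t.\tgene_id "G2"; gene_name "BETA";',
    'chr1\tx\tgene\t601\t700\t.\t+\t.\tgene_id "G3"; gene_name "MALAT1";'),
    p)
  g <- read_gene_annotation(p)
  expect_equal(nrow(g), 3)
  g1 <- g[g$gene_id == "G1"]
  expect_equal(c(g1$start, g1$end), c(100L, 200L))
  g2 <- g[g$gene_id == "G2"]
  expect_equal(c(g2$start, g2$end), c(300L, 500L))  # union of transcripts
  expect_true("MALAT1" %in% g$gene_name)            # name preserved for removal
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_error(read_gene_annotation(empty))
})

test_that("labels are canonicalized case-insensitively and duplicates rejected", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("dataset\tx\ty\tlabel",
               "d1\t1\t1\tdcis",
               "d1\t1\t2\tNON-MALIGNANT",
               "d1\t2\t1\tidc",
               "d1\t2\t2\tUnassigned"), p)
  lab <- read_labels(p)
  expect_equal(lab$label, c("DCIS", "non-malignant", "IDC", "unassigned"))

  writeLines(c("dataset\tx\ty\tlabel", "d1\t1\t1\ttumor"), p)
  expect_error(read_labels(p), "allowed.*non-malignant")

  writeLines(c("dataset\tx\ty\tlabel",
               "d1\t1\t1\tDCIS", "d1\t1\t1\tIDC"), p)
  expect_error(read_labels(p), "duplicate")
})

test_that("matrix, cluster and prediction writers round-trip on randomized content", {
  withr::local_seed(11)
  # raw 5 x 7 count matrix
  m <- random_spot_matrix(5, 7)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, p)
  back <- read_matrix(p, dataset = "d1")
  expect_equal(back$values, m$values)
  expect_equal(back$spots, m$spots)
  expect_equal(back$space, "raw")

  # log-normalized floats at full precision
  ml <- normalize_log(m, stats::setNames(rep(1.7, 5), rownames(m$values)))
  write_matrix(ml, p)
  backl <- read_matrix(p, dataset = "d1")
  expect_identical(unname(backl$values), unname(ml$values))
  expect_equal(backl$space, "lognorm")

  # cluster BED
  cl <- data.table::data.table(
    id = c("c:10-21:+", "c:40-61:-"), chrom = "c", strand = c("+", "-"),
    start = c(10L, 40L), end = c(21L, 61L), n_sites = c(2L, 3L),
    total_count = c(8L, 12L), min_density = c(0, 0.25),
    max_density = c(0.4, Inf), summit = c(10L, 50L),
    gene_id = c("G1", ""), gene_name = c("ALPHA", ""))
  write_clusters(cl, p)
  backc <- read_clusters(p)
  for (col in c("chrom", "start", "end", "id", "total_count", "strand",
                "n_sites", "min_density", "max_density", "gene_id",
                "gene_name")) {
    expect_identical(backc[[col]], cl[[col]], label = col)
  }

  # predictions
  pr <- data.table::data.table(dataset = "d1", x = 1:3, y = 1L)
  probs <- matrix(stats::runif(9), 3)
  probs <- probs / rowSums(probs)
  for (k in 1:3) pr[[paste0("p_", canonical_classes()[k])]] <- probs[, k]
  pr$predicted_label <- canonical_classes()[max.col(probs)]
  write_predictions(pr, p)
  backp <- read_predictions(p)
  expect_identical(backp[[paste0("p_", "DCIS")]], pr$p_DCIS)
  expect_equal(backp$predicted_label, pr$predicted_label)
})

test_that("spot ids format and parse as <x>x<y>", {
  expect_equal(spot_id(17, 21), "17x21")
  expect_equal(parse_spot_id(c("17x21", "1x2")),
               data.table::data.table(x = c(17L, 1L), y = c(21L, 2L)))
  expect_error(parse_spot_id("17:21"), "malformed")
})
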