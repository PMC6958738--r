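# Tag clustering: 3'-end conventions, gene removal, the density
# decomposition against its brute-force oracle, filtering, gene
# association and the count matrix.

test_that("3'-end site convention and aggregation", {
  rd <- make_reads("c", 100, 148, "+")
  s <- reads_to_sites(rd)
  expect_equal(s$position, 147L)
  expect_equal(s$count, 1L)

  rd <- make_reads("c", 100, 148, "-")
  expect_equal(reads_to_sites(rd)$position, 100L)

  rd <- make_reads("c", 100, 148, "+", x = 1:5)  # 5 reads ending at 148
  s <- reads_to_sites(rd)
  expect_equal(nrow(s), 1)
  expect_equal(s$count, 5L)

  expect_error(reads_to_sites(make_reads("c", 1, 2, "+")[0]), "no reads")
})

test_that("gene-read removal drops 3'-ends inside the gene and tagged reads", {
  genes <- make_genes("G1", "MALAT1", "c", "+", 1000, 2000)
  # 4 reads ending inside MALAT1 on +, 6 outside
  rd <- make_reads("c",
                   start = c(1500, 1600, 1700, 1800, 100, 200, 300, 400, 500, 2500),
                   end = c(1548, 1648, 1748, 1848, 148, 248, 348, 448, 548, 2548),
                   strand = "+")
  out <- remove_gene_reads(rd, genes, "MALAT1")
  expect_equal(nrow(out), 6)

  # removal is strand-specific: '-' reads never match the '+' gene model
  rd_minus <- data.table::copy(rd)[, strand := "-"]
  expect_equal(nrow(remove_gene_reads(rd_minus, genes, "MALAT1")), 10)
  # with a '-' gene the 3' end is the read start
  genes_minus <- make_genes("G1", "MALAT1", "c", "-", 1000, 2000)
  expect_equal(nrow(remove_gene_reads(rd_minus, genes_minus, "MALAT1")), 6)

  # absent gene: no-op with warning
  expect_warning(out2 <- remove_gene_reads(rd, genes, "NOSUCH"), "absent")
  expect_equal(out2, rd)

  # tag rule removes reads outside any model
  tagged <- make_reads("c", c(100, 200), c(148, 248), "+",
                       gene_tag = c("malat1", ""))
  expect_equal(nrow(remove_gene_reads(tagged, genes, "MALAT1")), 1)
})

test_that("single-site and two-site decompositions match the hand derivation", {
  one <- data.table::data.table(chrom = "c", strand = "+",
                                position = 500L, count = 7L)
  n1 <- paraclu_decompose(one)
  expect_equal(nrow(n1), 1)
  expect_equal(n1$min_density, 0)
  expect_equal(n1$max_density, Inf)
  expect_true(n1$reportable)

  two <- data.table::data.table(chrom = "c", strand = "+",
                                position = c(10L, 20L), count = c(4L, 4L))
  n2 <- paraclu_decompose(two)
  root <- n2[is.na(n2$parent_id)]
  expect_equal(root$max_density, 0.4)   # 4 / 10 on both sides
  expect_equal(root$min_density, 0)
  kids <- n2[!is.na(n2$parent_id)]
  expect_equal(kids$min_density, c(0.4, 0.4))
  expect_equal(kids$max_density, c(Inf, Inf))

  expect_error(paraclu_decompose(one[0]), "empty")
})

test_that("reportable segments equal the brute-force density-sweep oracle", {
  withr::local_seed(2024)
  for (rep in 1:60) {
    n <- sample(1:40, 1)
    s <- random_sites(n)
    nodes <- paraclu_decompose(s)
    rec <- unique(nodes[nodes$reportable, c("i", "j")])
    data.table::setorder(rec, i, j)
    ora <- oracle_density_sweep(as.numeric(s$position), as.numeric(s$count))
    expect_equal(as.data.frame(rec), as.data.frame(ora),
                 ignore_attr = TRUE,
                 label = paste("instance", rep, "n =", n))
  }
})

test_that("decomposition is laminar with non-decreasing min_density down the tree", {
  withr::local_seed(7)
  for (rep in 1:20) {
    s <- random_sites(sample(2:50, 1), max_pos = 500)
    nodes <- paraclu_decompose(s)
    # children nested in parents, min_density monotone
    for (r in which(!is.na(nodes$parent_id))) {
      p <- nodes$parent_id[r]
      expect_true(nodes$start[r] >= nodes$start[p] &&
                    nodes$end[r] <= nodes$end[p])
      expect_gte(nodes$min_density[r], nodes$min_density[p])
      expect_gte(nodes$min_density[r], nodes$max_density[p])
    }
    # any two nodes nested or disjoint
    idx <- seq_len(nrow(nodes))
    for (a in idx) {
      overl <- nodes$start < nodes$end[a] & nodes$end > nodes$start[a]
      nested <- (nodes$start >= nodes$start[a] & nodes$end <= nodes$end[a]) |
        (nodes$start <= nodes$start[a] & nodes$end >= nodes$end[a])
      expect_true(all(!overl | nested))
    }
    expect_equal(nodes$total_count[1], sum(s$count))
  }
})

test_that("cluster filters apply fold, span and count rules with outermost-only emission", {
  two <- data.table::data.table(chrom = "c", strand = "+",
                                position = c(10L, 20L), count = c(4L, 4L))
  nodes <- paraclu_decompose(two)
  cl <- filter_clusters(nodes, two, min_fold = 2, max_span = 200, min_count = 1)
  # root passes (min_density 0), children suppressed as nested
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(10L, 21L))
  expect_equal(cl$total_count, 8L)

  # min_count removes low-count clusters
  expect_equal(nrow(filter_clusters(nodes, two, min_count = 10)), 0)

  # with no constraints, emitted set is the outermost shell covering all sites
  withr::local_seed(5)
  s <- random_sites(30, max_pos = 300)
  nodes <- paraclu_decompose(s)
  cl <- filter_clusters(nodes, s, min_fold = 1, max_span = .Machine$integer.max,
                        min_count = 1)
  expect_equal(nrow(cl), 1)  # the root shell
  expect_equal(cl$total_count, sum(s$count))

  # nested survivors kept when keep_nested = TRUE
  cl_nested <- filter_clusters(nodes, s, min_fold = 1,
                               max_span = .Machine$integer.max,
                               min_count = 1, keep_nested = TRUE)
  expect_gt(nrow(cl_nested), nrow(cl))
})

test_that("gene association uses the summit, downstream slack and nearest 3' end", {
  genes <- make_genes(c("G1", "G2"), c("ALPHA", "BETA"), "c", "+",
                      c(1000, 5000), c(2000, 6000))
  cl <- data.table::data.table(
    id = c("a", "b", "c", "d"), chrom = "c",
    strand = c("+", "+", "+", "-"),
    start = c(1500L, 2200L, 9000L, 1500L), end = c(1510L, 2210L, 9010L, 1510L),
    n_sites = 1L, total_count = 5L, min_density = 0, max_density = Inf,
    summit = c(1500L, 2300L, 9000L, 1500L), gene_id = "", gene_name = "")
  out <- associate_genes(cl, genes, downstream_slack = 500)
  expect_equal(out$gene_id, c("G1", "G1", "", ""))  # body, slack, desert, strand
  # nearest 3' end wins among overlapping candidates
  genes2 <- make_genes(c("GA", "GB"), c("A", "B"), "c", "+",
                       c(1000, 1200), c(2000, 1600))
  cl2 <- cl[1]
  cl2$summit <- 1550L
  out2 <- associate_genes(cl2, genes2, downstream_slack = 0)
  expect_equal(out2$gene_id, "GB")  # 3' end 1599 nearer than 1999
})

test_that("count matrix assigns 3'-end sites to clusters and conserves reads", {
  cl <- data.table::data.table(
    id = c("c:100-150:+", "c:300-350:+"), chrom = "c", strand = "+",
    start = c(100L, 300L), end = c(150L, 350L), n_sites = 1L,
    total_count = 0L, min_density = 0, max_density = Inf,
    summit = c(120L, 320L), gene_id = "", gene_name = "")
  rd <- rbind(
    make_reads("c", 60, 108, "+", x = 1, y = 1),                    # 1 x c1
    make_reads("c", c(60, 70, 80), c(108, 118, 128), "+", x = 1, y = 1),
    make_reads("c", c(260, 270, 280, 290, 295), c(308, 318, 328, 338, 343),
               "+", x = 2, y = 1),
    make_reads("c", 900, 948, "+", x = 1, y = 1))                   # discarded
  m <- build_matrix(rd, cl)
  expect_equal(dim(m$values), c(2L, 2L))
  expect_equal(unname(m$values[1, ]), c(4L, 0L))
  expect_equal(unname(m$values[2, ]), c(0L, 5L))
  expect_equal(attr(m, "discarded"), 1L)
  expect_equal(sum(m$values) + attr(m, "discarded"), nrow(rd))

  # overlapping clusters rejected
  cl_bad <- data.table::copy(cl)
  cl_bad$start[2] <- 140L
  expect_error(build_matrix(rd, cl_bad), "overlap")
})

test_that("pooled pipeline conserves reads end-to-end and is deterministic", {
  sim <- small_sim()
  reads <- sim$reads
  tc <- small_tc()
  expect_equal(sum(tc$matrix$values) + tc$n_discarded + tc$n_removed,
               nrow(reads))
  # column sums equal independent per-cluster tallies on the same input
  kept <- remove_gene_reads(reads, sim$genes, "MALAT1")
  pos <- tts_position(kept)
  for (cid in sample(colnames(tc$matrix$values), 5)) {
    cc <- tc$clusters[tc$clusters$id == cid]
    tally <- sum(kept$chrom == cc$chrom & kept$strand == cc$strand &
                   pos >= cc$start & pos < cc$end)
    expect_equal(unname(colSums(tc$matrix$values)[cid]), tally)
  }
  # byte-identical outputs across repeated runs on the same input
  tc2 <- call_tag_clusters(sim$reads, sim$genes)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_clusters(tc$clusters, f1)
  write_clusters(tc2$clusters, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(tc$matrix$values, tc2$matrix$values)
})
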