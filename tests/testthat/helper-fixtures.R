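# Fixture builders, all programmatic.  The small simulation is computed
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small 4-section simulation used across module tests (the full default
# scene is exercised in the acceptance tests).
small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_st(sim_config(
      seed = 101, grid_width = 10, grid_height = 10, n_genes = 80,
      n_signature_per_class = 8))
  }
  .fixture_cache$sim
}

small_tc <- function() {
  if (is.null(.fixture_cache$tc)) {
    sim <- small_sim()
    reads <- sim$reads
    .fixture_cache$tc <- call_tag_clusters(reads, sim$genes)
  }
  .fixture_cache$tc
}

# hand-built spatial reads table
make_reads <- function(chrom, start, end, strand, x = 1L, y = 1L,
                       gene_tag = "", dataset = "d1") {
  n <- max(length(chrom), length(start), length(end), length(strand),
           length(x), length(y), length(gene_tag))
  data.table::data.table(
    chrom = rep_len(chrom, n), start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)), name = paste0("r", seq_len(n)),
    score = "0", strand = rep_len(strand, n),
    gene_tag = rep_len(gene_tag, n), x = as.integer(rep_len(x, n)),
    y = as.integer(rep_len(y, n)), dataset = rep_len(dataset, n))
}

# hand-built gene model table (0-based half-open)
make_genes <- function(gene_id, gene_name, chrom, strand, start, end) {
  data.table::data.table(gene_id = gene_id, gene_name = gene_name,
                         chrom = chrom, strand = strand,
                         start = as.integer(start), end = as.integer(end))
}

# random site profile for one chrom/strand
random_sites <- function(n, max_pos = 200, max_count = 9) {
  pos <- sort(sample.int(max_pos, n))
  data.table::data.table(chrom = "c", strand = "+",
                         position = as.integer(pos),
                         count = sample.int(max_count, n, replace = TRUE))
}

# random small spot matrix
random_spot_matrix <- function(n_spots = 6, n_tcs = 8, lambda = 20,
                               dataset = "d1") {
  vals <- matrix(stats::rpois(n_spots * n_tcs, lambda), nrow = n_spots,
                 dimnames = list(NULL, sprintf("c:%d-%d:+",
                                               seq_len(n_tcs) * 100,
                                               seq_len(n_tcs) * 100 + 10)))
  spot_matrix(vals, data.table::data.table(
    dataset = dataset, x = seq_len(n_spots), y = 1L), space = "raw")
}

# labels table for a spot matrix
labels_for_matrix <- function(m, labels) {
  data.table::data.table(dataset = m$spots$dataset, x = m$spots$x,
                         y = m$spots$y, label = labels)
}

# write a minimal well-formed spatial BED file, returns path
write_bed_fixture <- function(lines, path = withr::local_tempfile(
                                fileext = ".bed", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# planted two-group scene builder: n TCs, first n_sig carry the effect
planted_matrix <- function(n_tc, n_sig, n_per_class, log2fc = 3,
                           alpha = 0.2, base_range = c(4, 64)) {
  cls <- canonical_classes()
  base <- stats::runif(n_tc, base_range[1], base_range[2])
  lab <- rep(cls, each = n_per_class)
  mu <- matrix(rep(base, each = 3 * n_per_class), ncol = n_tc)
  if (n_sig > 0) {
    class_of_sig <- rep_len(1:3, n_sig)
    for (s in seq_len(n_sig)) {
      mu[lab == cls[class_of_sig[s]], s] <- base[s] * 2^log2fc
    }
  }
  vals <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / alpha),
                 nrow = nrow(mu),
                 dimnames = list(NULL, sprintf("c:%d-%d:+", 1:n_tc * 100,
                                               1:n_tc * 100 + 10)))
  m <- spot_matrix(vals, data.table::data.table(
    dataset = "d1", x = seq_len(nrow(mu)), y = 1L), space = "raw")
  list(m = m, labels = labels_for_matrix(m, lab),
       sig_ids = colnames(vals)[seq_len(n_sig)])
}
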