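# Synthetic ST data generator: a toy annotation, per-section spatial BED
# reads and truth labels with the statistical structure the pipeline
# assumes -- negative-binomial molecule counts with class-specific
# signature genes, per-spot library-size variation, one MALAT1-like
# ultra-high expressor and 3'-end positions scattered around gene
# termination sites.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: four sections on a
#' 33 x 35 spot array, three spatially contiguous region classes per
#' section, 300 genes of which 20 per class carry a log2 fold-change 3
#' signature, negative-binomial dispersion 0.2, lognormal per-spot depth
#' (sigma 0.35), a MALAT1-like gene receiving 15% of all molecules,
#' 48 bp reads and Gaussian 3'-end jitter with sd 8 bp.
#'
#' @param seed Integer RNG seed (default 17).
#' @param n_datasets Number of tissue sections (default 4).
#' @param grid_width,grid_height Spot array dimensions (default 33 x 35).
#' @param n_genes Number of ordinary genes, excluding the MALAT1-like
#'   gene (default 300).
#' @param n_signature_per_class Signature genes per class (default 20).
#' @param log2fc_effect Planted log2 fold change of signature genes in
#'   their class (default 3).
#' @param nb_dispersion NB dispersion alpha; variance = mu + alpha mu^2
#'   (default 0.2).
#' @param base_mean_log_range Range of log2 base means per spot and gene
#'   (default `c(0, 4)`, i.e. 1-16 molecules).
#' @param spot_depth_lognormal_sigma Lognormal sigma of per-spot depth
#'   factors (default 0.35).
#' @param malat1_fraction Expected fraction of all molecules from the
#'   MALAT1-like gene (default 0.15).
#' @param read_span Read length in bp (default 48).
#' @param tts_jitter_sd Gaussian sd of 3'-end scatter around the TTS in
#'   bp (default 8).
#' @param region_layout `"stripes"` (three vertical bands, 0.6/0.2/0.2)
#'   or `"blobs"` (two grown blobs on a non-malignant background).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 17, n_datasets = 4, grid_width = 33,
                       grid_height = 35, n_genes = 300,
                       n_signature_per_class = 20, log2fc_effect = 3.0,
                       nb_dispersion = 0.2, base_mean_log_range = c(0, 4),
                       spot_depth_lognormal_sigma = 0.35,
                       malat1_fraction = 0.15, read_span = 48,
                       tts_jitter_sd = 8,
                       region_layout = c("stripes", "blobs")) {
  region_layout <- match.arg(region_layout)
  cfg <- list(seed = as.integer(seed), n_datasets = as.integer(n_datasets),
              grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              n_genes = as.integer(n_genes),
              n_signature_per_class = as.integer(n_signature_per_class),
              log2fc_effect = log2fc_effect, nb_dispersion = nb_dispersion,
              base_mean_log_range = base_mean_log_range,
              spot_depth_lognormal_sigma = spot_depth_lognormal_sigma,
              malat1_fraction = malat1_fraction,
              read_span = as.integer(read_span),
              tts_jitter_sd = tts_jitter_sd, region_layout = region_layout)
  with(cfg, {
    stopifnot(n_datasets >= 1, grid_width >= 3, grid_height >= 1,
              n_genes >= 1, n_signature_per_class >= 0,
              3 * n_signature_per_class <= n_genes,
              log2fc_effect >= 0, nb_dispersion >= 0,
              length(base_mean_log_range) == 2,
              base_mean_log_range[1] <= base_mean_log_range[2],
              spot_depth_lognormal_sigma >= 0,
              malat1_fraction >= 0, malat1_fraction < 1,
              read_span >= 1, tts_jitter_sd >= 0)
  })
  structure(cfg, class = "sim_config")
}

#' Assign a region class to every spot of the grid
#'
#' `stripes`: three vertical bands covering ~60/20/20% of the columns
#' (non-malignant, DCIS, IDC), mimicking the class imbalance of annotated
#' breast-cancer sections.  `blobs`: two spatially contiguous blobs (DCIS
#' ~13% of spots, IDC ~26%) grown by seeded random walks on a
#' non-malignant background.
#'
#' @param grid_width,grid_height Array dimensions.
#' @param kind `"stripes"` or `"blobs"`.
#' @param seed RNG seed (only the blob growth is stochastic).
#' @return A `data.table` with columns `x`, `y`, `label` covering every
#'   spot.
#' @export
layout_regions <- function(grid_width, grid_height,
                           kind = c("stripes", "blobs"), seed = 17) {
  kind <- match.arg(kind)
  cls <- canonical_classes()
  grid <- data.table::CJ(x = seq_len(grid_width), y = seq_len(grid_height))
  if (kind == "stripes") {
    n1 <- round(0.6 * grid_width)
    n2 <- round(0.2 * grid_width)
    band <- ifelse(grid$x <= n1, 1L, ifelse(grid$x <= n1 + n2, 2L, 3L))
    grid$label <- cls[band]
    return(grid[])
  }
  set.seed(seed)
  lab <- matrix(1L, nrow = grid_width, ncol = grid_height)
  grow <- function(lab, class_id, target) {
    free <- which(lab == 1L)
    start <- free[sample.int(length(free), 1)]
    lab[start] <- class_id
    members <- start
    while (length(members) < target) {
      # frontier: unassigned 4-neighbors of current members
      xs <- ((members - 1L) %% grid_width) + 1L
      ys <- ((members - 1L) %/% grid_width) + 1L
      nb <- unique(c(
        ifelse(xs > 1L, members - 1L, NA),
        ifelse(xs < grid_width, members + 1L, NA),
        ifelse(ys > 1L, members - grid_width, NA),
        ifelse(ys < grid_height, members + grid_width, NA)))
      nb <- nb[!is.na(nb) & lab[nb] == 1L]
      if (length(nb) == 0) break
      pick <- nb[sample.int(length(nb), 1)]
      lab[pick] <- class_id
      members <- c(members, pick)
    }
    lab
  }
  n_spots <- grid_width * grid_height
  lab <- grow(lab, 2L, round(0.13 * n_spots))
  lab <- grow(lab, 3L, round(0.26 * n_spots))
  grid$label <- cls[lab[cbind(grid$x, grid$y)]]
  grid[]
}

#' Simulate a multi-section ST experiment
#'
#' Places `n_genes + 1` non-overlapping genes with alternating strands on
#' a toy chromosome, assigns every spot a region class by the configured
#' layout, draws per-(spot, gene) molecule counts from a negative
#' binomial whose mean is `base_mean * 2^effect * depth(spot)` (`effect`
#' applies when the gene belongs to the spot class's signature), and
#' turns each molecule into a spatial BED read whose 3' end is the gene
#' TTS plus rounded Gaussian jitter (clipped inside the gene plus 100 bp
#' of downstream slack).  The MALAT1-like gene's mean is scaled so it
#' receives the configured fraction of all molecules.  Fully reproducible
#' from the seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genes.gtf`,
#'   `dataset_<i>.bed`, `labels.tsv` and `truth.json`.
#' @return A list with `genes` (gene models, 0-based half-open), `reads`
#'   (one pooled spatial-read `data.table` with a `dataset` column),
#'   `labels`, and `truth` (per-spot class and depth, per-gene signature
#'   class, base mean and TTS).
#' @export
simulate_st <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cls <- canonical_classes()
  ng <- config$n_genes
  gene_len <- 2000L
  gap <- 100000L  # intergenic spacing on the toy chromosome (realistic
                  # 100-kb scale; short gaps would let deep tag peaks of
                  # neighboring genes destabilize each other)
  total_genes <- ng + 1L  # ordinary genes + the MALAT1-like expressor
  gstart <- 1000L + (seq_len(total_genes) - 1L) * (gene_len + gap)
  genes <- data.table::data.table(
    gene_id = sprintf("SIMG%04d", seq_len(total_genes)),
    gene_name = c(sprintf("GENE%04d", seq_len(ng)), "MALAT1"),
    chrom = "chrT",
    strand = rep(c("+", "-"), length.out = total_genes),
    start = gstart,
    end = gstart + gene_len)
  tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)

  base_mean <- 2^stats::runif(ng, config$base_mean_log_range[1],
                              config$base_mean_log_range[2])
  # disjoint signature gene sets, one per class, drawn from genes whose
  # base expression is high enough that the planted effect is observable
  # as a pseudocounted fold change in the stated 2-4 range (a gene with
  # per-spot mean << 1 cannot realize |log2FC| > 2 after "+1")
  sig_genes <- list()
  if (config$n_signature_per_class > 0) {
    eligible <- which(base_mean >= 2)
    if (length(eligible) < 3 * config$n_signature_per_class) {
      eligible <- order(base_mean, decreasing = TRUE)[
        seq_len(3 * config$n_signature_per_class)]
    }
    perm <- sample(eligible)
    for (k in seq_along(cls)) {
      idx <- perm[seq_len(config$n_signature_per_class) +
                    (k - 1L) * config$n_signature_per_class]
      sig_genes[[cls[k]]] <- genes$gene_id[idx]
    }
  } else {
    for (k in seq_along(cls)) sig_genes[[cls[k]]] <- character(0)
  }
  sig_idx <- lapply(sig_genes, function(ids) match(ids, genes$gene_id))
  # MALAT1-like mean chosen so its expected share of molecules is
  # malat1_fraction (relative to the class-averaged ordinary total)
  mean_total_ordinary <- sum(base_mean) *
    (1 + (2^config$log2fc_effect - 1) *
       config$n_signature_per_class / max(ng, 1))
  malat_mean <- if (config$malat1_fraction > 0) {
    config$malat1_fraction / (1 - config$malat1_fraction) * mean_total_ordinary
  } else 0

  slack_clip <- 100L
  reads <- list(); labels_list <- list(); truth_spots <- list()
  for (d in seq_len(config$n_datasets)) {
    dname <- paste0("dataset_", d)
    layout <- layout_regions(config$grid_width, config$grid_height,
                             config$region_layout, seed = config$seed + d)
    n_spots <- nrow(layout)
    depth <- stats::rlnorm(n_spots, 0, config$spot_depth_lognormal_sigma)
    mu <- matrix(rep(base_mean, each = n_spots), nrow = n_spots)
    for (k in seq_along(cls)) {
      in_class <- layout$label == cls[k]
      if (any(in_class) && length(sig_idx[[k]])) {
        mu[in_class, sig_idx[[k]]] <- mu[in_class, sig_idx[[k]]] *
          2^config$log2fc_effect
      }
    }
    mu <- cbind(mu, malat_mean)  # MALAT1-like column
    mu <- mu * depth
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu,
                     size = if (config$nb_dispersion > 0)
                       1 / config$nb_dispersion else Inf),
      nrow = n_spots)
    nz <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[nz]
    spot_i <- rep(nz[, 1], reps)
    gene_i <- rep(nz[, 2], reps)
    n_mol <- length(spot_i)
    jitter <- as.integer(round(stats::rnorm(n_mol, 0, config$tts_jitter_sd)))
    end3 <- tts[gene_i] + jitter
    plus <- genes$strand[gene_i] == "+"
    end3 <- pmax(end3, ifelse(plus, genes$start[gene_i],
                              genes$start[gene_i] - slack_clip))
    end3 <- pmin(end3, ifelse(plus, genes$end[gene_i] - 1L + slack_clip,
                              genes$end[gene_i] - 1L))
    rstart <- ifelse(plus, end3 - config$read_span + 1L, end3)
    rd <- data.table::data.table(
      chrom = "chrT",
      start = as.integer(pmax(rstart, 0L)),
      end = as.integer(ifelse(plus, end3 + 1L, end3 + config$read_span)),
      name = ".",
      score = "0",
      strand = genes$strand[gene_i],
      gene_tag = genes$gene_name[gene_i],
      x = layout$x[spot_i],
      y = layout$y[spot_i],
      dataset = dname)
    reads[[dname]] <- rd
    rm(rd, counts, mu, nz, reps, spot_i, gene_i, jitter, end3, rstart, plus)
    labels_list[[dname]] <- data.table::data.table(
      dataset = dname, x = layout$x, y = layout$y, label = layout$label)
    truth_spots[[dname]] <- data.table::data.table(
      dataset = dname, x = layout$x, y = layout$y,
      class = layout$label, depth = depth)
  }
  labels <- data.table::rbindlist(labels_list)
  dnames <- names(reads)
  reads <- data.table::rbindlist(reads)
  truth <- list(
    spots = data.table::rbindlist(truth_spots),
    signature_genes = sig_genes,
    genes = data.table::data.table(genes, tts = tts,
                                   base_mean = c(base_mean, malat_mean)))
  out <- list(genes = genes, reads = reads, labels = labels, truth = truth,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(genes, file.path(out_dir, "genes.gtf"))
    for (dname in dnames) {
      write_spatial_bed(reads[reads$dataset == dname],
                        file.path(out_dir, paste0(dname, ".bed")))
    }
    write_labels(labels, file.path(out_dir, "labels.tsv"))
    jsonlite::write_json(
      list(spots = truth$spots, signature_genes = truth$signature_genes,
           genes = truth$genes),
      file.path(out_dir, "truth.json"), dataframe = "columns", digits = NA)
    out$paths <- list(
      gtf = file.path(out_dir, "genes.gtf"),
      beds = file.path(out_dir, paste0(dnames, ".bed")),
      labels = file.path(out_dir, "labels.tsv"),
      truth = file.path(out_dir, "truth.json"))
  }
  out
}

#' Write gene models as a GTF file
#'
#' One `gene` feature row per model; internal 0-based half-open
#' coordinates are converted back to GTF's 1-based closed convention.
#'
#' @param genes Gene model `data.table` ([read_gene_annotation()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$gene_name)
  writeLines(lines, path)
  invisible(path)
}
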