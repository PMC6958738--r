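# ST tag clusters (ST-TCs): gene-model-independent expression features
# built by parametric density clustering of 3'-end read positions, in the
# style of the paraclu method for CAGE-like tag data.  A segment of sites
# is a cluster over a density interval [min_density, max_density]: it
# first becomes a maximal segment when the density parameter drops to
# max_density and splits into two children below min_density.

#' 3'-end position of each read
#'
#' The capture chemistry anchors at the polyA tail, so the informative
#' coordinate of a molecule is its 3' end: `end - 1` on the `+` strand,
#' `start` on the `-` strand (0-based).
#'
#' @param reads A spatial-read `data.table` ([read_spatial_bed()]).
#' @return Integer vector of 3'-end positions.
#' @export
tts_position <- function(reads) {
  if (!is.null(reads$pos)) return(reads$pos)  # precomputed slim form
  ifelse(reads$strand == "+", reads$end - 1L, reads$start)
}

#' Remove all reads attributable to one gene
#'
#' Drops every read whose 3'-end position falls inside a matching gene's
#' interval on the same strand, or whose `gene_tag` equals the gene name
#' (case-insensitive).  Used to discard the MALAT1-like ultra-high
#' expressor whose overexpression and internal priming would otherwise
#' dominate the tag clusters.
#'
#' @param reads Spatial reads (`data.table`).
#' @param genes Gene models ([read_gene_annotation()]), or `NULL`.
#' @param gene_name Gene to remove (default `"MALAT1"`).
#' @return The surviving reads, in input order.
#' @export
remove_gene_reads <- function(reads, genes = NULL, gene_name = "MALAT1") {
  tag_hit <- tolower(reads$gene_tag) == tolower(gene_name)
  pos_hit <- rep(FALSE, nrow(reads))
  matched <- NULL
  if (!is.null(genes)) {
    name_match <- tolower(genes$gene_name) == tolower(gene_name)
    matched <- genes[which(name_match)]
  }
  if (is.null(matched) || nrow(matched) == 0) {
    if (!any(tag_hit)) {
      warning("remove_gene_reads: gene '", gene_name,
              "' absent from annotation and tags; nothing removed")
      return(reads)
    }
  } else {
    pos <- tts_position(reads)
    for (g in seq_len(nrow(matched))) {
      pos_hit <- pos_hit | (reads$chrom == matched$chrom[g] &
                              reads$strand == matched$strand[g] &
                              pos >= matched$start[g] & pos < matched$end[g])
    }
  }
  reads[!(tag_hit | pos_hit)]
}

#' Aggregate reads into 3'-end sites
#'
#' Each read contributes one count at its 3'-end position; counts are
#' summed per `(chrom, strand, position)` over all spots of the pooled
#' input, and sites are sorted by position within `(chrom, strand)`.
#'
#' @param reads Spatial reads (`data.table`), non-empty.
#' @return A `data.table` with columns `chrom`, `strand`, `position`,
#'   `count`; `sum(count)` equals `nrow(reads)`.
#' @export
reads_to_sites <- function(reads) {
  if (nrow(reads) == 0) stop("reads_to_sites: no reads")
  dt <- data.table::data.table(chrom = reads$chrom, strand = reads$strand,
                               position = tts_position(reads))
  sites <- dt[, list(count = .N), by = c("chrom", "strand", "position")]
  data.table::setorder(sites, chrom, strand, position)
  sites[]
}

#' Recursive maximal-segment decomposition of one site profile
#'
#' Decomposes the sorted sites of a single `(chrom, strand)` into the
#' laminar tree of density-maximal segments.  For a segment of sites
#' `i..j` the weakest prefix break minimizes
#' `sum(count[i..k-1]) / (pos[k] - pos[i])` over `k` in `(i..j]` and the
#' weakest suffix break minimizes `sum(count[k+1..j]) / (pos[j] - pos[k])`
#' over `k` in `[i..j)`; ties go to the leftmost `k` and the prefix side
#' beats the suffix side on equal densities.  The segment's `max_density`
#' is the smaller of the two minima and the segment splits there into two
#' children whose `min_density` is the running maximum
#' `max(parent min_density, parent max_density)` -- the density at which
#' the child first becomes a maximal segment once every enclosing segment
#' has broken up.  Singleton segments are leaves with
#' `max_density = Inf`; the root has `min_density = 0`.  Nodes exist as
#' maximal segments only over a non-empty density interval, so a node is
#' reportable iff `max_density > min_density`; unreportable nodes are
#' still recursed through.
#'
#' @param sites A `data.table` of one chromosome and strand, sorted by
#'   position, with positive `count`s ([reads_to_sites()]).
#' @return A `data.table` of nodes, parents before children, with columns
#'   `node_id`, `parent_id` (`NA` for the root), `i`, `j` (site index
#'   range), `start`, `end` (0-based half-open genomic interval delimited
#'   by the member sites), `n_sites`, `total_count`, `min_density`,
#'   `max_density`, `reportable`.
#' @export
paraclu_decompose <- function(sites) {
  n <- nrow(sites)
  if (n == 0) stop("paraclu_decompose: empty input")
  if (length(unique(sites$chrom)) > 1 || length(unique(sites$strand)) > 1) {
    stop("paraclu_decompose: sites must come from a single chrom and strand")
  }
  pos <- as.numeric(sites$position)
  cnt <- as.numeric(sites$count)
  if (any(cnt <= 0)) stop("paraclu_decompose: site counts must be positive")
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("paraclu_decompose: sites must be sorted by position, unique")
  }
  cum <- c(0, cumsum(cnt))  # cum[k+1] = sum(cnt[1..k])

  n_nodes <- 2L * n - 1L
  node_i <- integer(n_nodes); node_j <- integer(n_nodes)
  node_parent <- rep(NA_integer_, n_nodes)
  node_min <- numeric(n_nodes); node_max <- numeric(n_nodes)
  # explicit worklist (avoids deep recursion on long site runs)
  stack_i <- integer(n_nodes); stack_j <- integer(n_nodes)
  stack_min <- numeric(n_nodes); stack_parent <- integer(n_nodes)
  top <- 1L
  stack_i[1] <- 1L; stack_j[1] <- n; stack_min[1] <- 0; stack_parent[1] <- NA_integer_
  next_id <- 0L
  while (top > 0L) {
    i <- stack_i[top]; j <- stack_j[top]
    mind <- stack_min[top]; par <- stack_parent[top]
    top <- top - 1L
    next_id <- next_id + 1L
    id <- next_id
    node_i[id] <- i; node_j[id] <- j
    node_parent[id] <- par; node_min[id] <- mind
    if (i == j) {
      node_max[id] <- Inf
      next
    }
    ks_p <- (i + 1L):j
    pd <- (cum[ks_p] - cum[i]) / (pos[ks_p] - pos[i])
    bp <- which.min(pd)                       # leftmost tie by which.min
    ks_s <- i:(j - 1L)
    sd <- (cum[j + 1L] - cum[ks_s + 1L]) / (pos[j] - pos[ks_s])
    bs <- which.min(sd)
    maxd <- min(pd[bp], sd[bs])
    node_max[id] <- maxd
    if (pd[bp] <= sd[bs]) {                   # prefix side wins ties
      brk <- ks_p[bp]                         # children [i..brk-1], [brk..j]
      left <- c(i, brk - 1L); right <- c(brk, j)
    } else {
      brk <- ks_s[bs]                         # children [i..brk], [brk+1..j]
      left <- c(i, brk); right <- c(brk + 1L, j)
    }
    # push right then left so the left child is processed first (DFS order)
    child_min <- max(mind, maxd)
    top <- top + 1L
    stack_i[top] <- right[1]; stack_j[top] <- right[2]
    stack_min[top] <- child_min; stack_parent[top] <- id
    top <- top + 1L
    stack_i[top] <- left[1]; stack_j[top] <- left[2]
    stack_min[top] <- child_min; stack_parent[top] <- id
  }
  data.table::data.table(
    node_id = seq_len(n_nodes),
    parent_id = node_parent,
    i = node_i, j = node_j,
    start = as.integer(pos[node_i]),
    end = as.integer(pos[node_j]) + 1L,
    n_sites = node_j - node_i + 1L,
    total_count = as.integer(cum[node_j + 1L] - cum[node_i]),
    min_density = node_min,
    max_density = node_max,
    reportable = node_max > node_min)
}

# internal: decompose every (chrom, strand) group of a site table.
.decompose_all <- function(sites) {
  groups <- unique(sites[, c("chrom", "strand")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- sites[chrom == groups$chrom[g] & strand == groups$strand[g]]
    nodes <- paraclu_decompose(sub)
    nodes[, `:=`(chrom = groups$chrom[g], strand = groups$strand[g])]
    out[[g]] <- nodes
  }
  data.table::rbindlist(out)
}

#' Filter a decomposition into reported tag clusters
#'
#' Emits nodes that satisfy the paraclu-convention stability and size
#' filters: density fold `max_density >= min_fold * min_density` (leaves
#' with infinite `max_density` always pass, as does the root whose
#' `min_density` is 0), genomic span `end - start <= max_span`, and
#' `total_count >= min_count`.  When a surviving node is nested inside
#' another surviving node only the outermost is kept, so the emitted
#' clusters are disjoint (set `keep_nested = TRUE` to keep sub-clusters).
#'
#' @param nodes Node table from [paraclu_decompose()] (one group) or an
#'   rbind of per-group tables with `chrom`/`strand` columns.
#' @param sites The site table the decomposition was built from (used to
#'   locate each cluster's summit: the highest-count member site,
#'   leftmost on ties).
#' @param min_fold Minimum stability fold (default 2).
#' @param max_span Maximum cluster span in bp (default 200).
#' @param min_count Minimum total molecule count (default 2).
#' @param keep_nested Keep surviving sub-clusters of surviving clusters.
#' @return A `data.table` of tag clusters with columns `id`, `chrom`,
#'   `strand`, `start`, `end`, `n_sites`, `total_count`, `min_density`,
#'   `max_density`, `summit`, `gene_id`, `gene_name` (gene fields empty
#'   until [associate_genes()]).
#' @export
filter_clusters <- function(nodes, sites, min_fold = 2, max_span = 200,
                            min_count = 2, keep_nested = FALSE) {
  stopifnot(min_fold >= 1, max_span >= 1, min_count >= 1)
  nodes <- data.table::as.data.table(nodes)
  if (!("chrom" %in% names(nodes))) {
    nodes <- data.table::copy(nodes)
    nodes[, `:=`(chrom = sites$chrom[1], strand = sites$strand[1])]
  }
  pass <- (nodes$max_density >= min_fold * nodes$min_density) &
    ((nodes$end - nodes$start) <= max_span) &
    (nodes$total_count >= min_count)
  if (!keep_nested) {
    # parents precede children within each group, so one forward pass
    # propagates "has a surviving ancestor" down the tree
    anc <- rep(FALSE, nrow(nodes))
    grp_off <- match(paste(nodes$chrom, nodes$strand),
                     unique(paste(nodes$chrom, nodes$strand)))
    offset <- c(0L, cumsum(tabulate(grp_off)))[grp_off]
    for (r in seq_len(nrow(nodes))) {
      p <- nodes$parent_id[r]
      if (!is.na(p)) {
        pr <- offset[r] + p
        anc[r] <- pass[pr] || anc[pr]
      }
    }
    pass <- pass & !anc
  }
  kept <- nodes[pass]
  if (nrow(kept) == 0) {
    return(data.table::data.table(
      id = character(0), chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0), n_sites = integer(0),
      total_count = integer(0), min_density = numeric(0),
      max_density = numeric(0), summit = integer(0),
      gene_id = character(0), gene_name = character(0)))
  }
  # summit: highest-count site inside the cluster, leftmost on ties
  data.table::setkey(sites, chrom, strand, position)
  summit <- integer(nrow(kept))
  for (r in seq_len(nrow(kept))) {
    sub <- sites[chrom == kept$chrom[r] & strand == kept$strand[r] &
                   position >= kept$start[r] & position < kept$end[r]]
    summit[r] <- sub$position[which.max(sub$count)]
  }
  out <- data.table::data.table(
    id = paste0(kept$chrom, ":", kept$start, "-", kept$end, ":", kept$strand),
    chrom = kept$chrom, strand = kept$strand,
    start = kept$start, end = kept$end,
    n_sites = kept$n_sites, total_count = kept$total_count,
    min_density = kept$min_density, max_density = kept$max_density,
    summit = summit, gene_id = "", gene_name = "")
  data.table::setorder(out, chrom, strand, start)
  out[]
}

#' Associate tag clusters to nearby genes
#'
#' A cluster is assigned to a same-strand gene whose interval, extended by
#' `downstream_slack` bp past its 3' end (to absorb termination-site
#' scatter), contains the cluster's summit.  Among several candidates the
#' gene whose 3' end is nearest the summit wins (first by start position,
#' then gene id, on exact ties).  Clusters with no candidate stay
#' unassociated -- the "non-annotated" ST-TC category.
#'
#' @param clusters Tag clusters from [filter_clusters()].
#' @param genes Gene models ([read_gene_annotation()]).
#' @param downstream_slack Extension past the gene 3' end in bp
#'   (default 500).
#' @return `clusters` with `gene_id` / `gene_name` filled in (empty
#'   string when unassociated).
#' @export
associate_genes <- function(clusters, genes, downstream_slack = 500) {
  if (nrow(clusters) == 0) return(clusters)
  g <- data.table::as.data.table(genes)
  g <- g[, list(gene_id, gene_name, chrom, strand,
                gstart = start, gend = end,
                lo = ifelse(strand == "+", start, start - downstream_slack),
                hi = ifelse(strand == "+", end + downstream_slack, end),
                tts = ifelse(strand == "+", end - 1L, start))]
  cl <- data.table::copy(clusters)
  cl[, row := .I]
  hits <- g[cl, on = list(chrom, strand, lo <= summit, hi > summit),
            nomatch = NULL,
            list(row = i.row, summit = i.summit, gene_id = x.gene_id,
                 gene_name = x.gene_name, gstart = x.gstart, tts = x.tts)]
  cl[, `:=`(gene_id = "", gene_name = "")]
  if (nrow(hits)) {
    hits[, dist := abs(summit - tts)]
    data.table::setorder(hits, row, dist, gstart, gene_id)
    best <- hits[!duplicated(row)]
    cl[best$row, `:=`(gene_id = best$gene_id, gene_name = best$gene_name)]
  }
  cl[, row := NULL]
  cl[]
}

#' Build the spot-by-tag-cluster count matrix
#'
#' Counts, for every spot, the molecules whose 3'-end site falls inside
#' each tag cluster (same chromosome and strand, `start <= site < end`).
#' Reads covered by no cluster are dropped and tallied in the
#' `"discarded"` attribute of the result, so that
#' `sum(matrix) + discarded == nrow(reads)`.
#'
#' @param reads Spatial reads; a `dataset` column identifies the section
#'   each read came from (added automatically with value `"data"` when
#'   absent).
#' @param clusters Tag clusters; must be disjoint within each
#'   `(chrom, strand)`.
#' @return A raw-space [spot_matrix()] covering every spot present in
#'   `reads` and every cluster, with attribute `discarded`.
#' @export
build_matrix <- function(reads, clusters) {
  reads <- data.table::as.data.table(reads)
  if (!("dataset" %in% names(reads))) reads$dataset <- "data"
  cl <- data.table::as.data.table(clusters)
  data.table::setorder(cl, chrom, strand, start)
  if (any(cl[, if (.N > 1) any(start[-1] < end[-.N]) else FALSE,
             by = c("chrom", "strand")]$V1)) {
    stop("build_matrix: clusters overlap within one chrom/strand")
  }
  rd <- data.table::data.table(
    dataset = reads$dataset, x = reads$x, y = reads$y,
    chrom = reads$chrom, strand = reads$strand, pos = tts_position(reads))
  rd[, tc := NA_integer_]
  for (grp in split(seq_len(nrow(cl)), paste(cl$chrom, cl$strand))) {
    sub <- cl[grp]
    sel <- rd$chrom == sub$chrom[1] & rd$strand == sub$strand[1]
    if (!any(sel)) next
    idx <- findInterval(rd$pos[sel], sub$start)
    inside <- idx >= 1L & rd$pos[sel] < sub$end[pmax(idx, 1L)]
    hit <- which(sel)[inside]
    rd$tc[hit] <- grp[idx[inside]]
  }
  n_discarded <- sum(is.na(rd$tc))
  counts <- rd[!is.na(tc), list(n = .N), by = c("dataset", "x", "y", "tc")]
  spots <- unique(rd[, c("dataset", "x", "y")])
  data.table::setorder(spots, dataset, x, y)
  skey <- paste0(spots$dataset, ":", spot_id(spots$x, spots$y))
  vals <- matrix(0L, nrow = nrow(spots), ncol = nrow(cl),
                 dimnames = list(skey, cl$id))
  if (nrow(counts)) {
    ri <- match(paste0(counts$dataset, ":", spot_id(counts$x, counts$y)), skey)
    vals[cbind(ri, counts$tc)] <- counts$n
  }
  m <- spot_matrix(vals, spots, space = "raw")
  attr(m, "discarded") <- n_discarded
  m
}

#' Pooled tag-cluster calling pipeline
#'
#' End-to-end wrapper: remove the ultra-expressed gene's reads, pool all
#' sections' reads into 3'-end sites (all sections share one ST-TC
#' coordinate system), decompose, filter, associate to genes and build
#' the spot-by-cluster count matrix.
#'
#' @param reads Pooled spatial reads with a `dataset` column.
#' @param genes Gene models, or `NULL` to skip gene removal/association.
#' @param remove_gene Gene name to strip before clustering (default
#'   `"MALAT1"`; `NULL` to skip).
#' @param min_fold,max_span,min_count,keep_nested See [filter_clusters()].
#' @param downstream_slack See [associate_genes()].
#' @return A list with `clusters`, `matrix` (raw [spot_matrix()]),
#'   `sites`, `n_removed` (reads dropped by gene removal) and
#'   `n_discarded` (reads outside every cluster).
#' @export
call_tag_clusters <- function(reads, genes = NULL, remove_gene = "MALAT1",
                              min_fold = 2, max_span = 200, min_count = 2,
                              downstream_slack = 500, keep_nested = FALSE) {
  n_in <- nrow(reads)
  # slim working copy: only the columns the clustering needs, with the
  # 3'-end position precomputed (keeps peak memory low on large inputs)
  reads <- data.table::data.table(
    dataset = if (is.null(reads$dataset)) "data" else reads$dataset,
    x = reads$x, y = reads$y, chrom = reads$chrom, strand = reads$strand,
    pos = tts_position(reads), gene_tag = reads$gene_tag)
  if (!is.null(remove_gene)) {
    reads <- remove_gene_reads(reads, genes, remove_gene)
  }
  reads[, gene_tag := NULL]
  n_removed <- n_in - nrow(reads)
  sites <- reads_to_sites(reads)
  nodes <- .decompose_all(sites)
  clusters <- filter_clusters(nodes, sites, min_fold = min_fold,
                              max_span = max_span, min_count = min_count,
                              keep_nested = keep_nested)
  if (!is.null(genes)) {
    clusters <- associate_genes(clusters, genes, downstream_slack)
  }
  m <- build_matrix(reads, clusters)
  list(clusters = clusters, matrix = m, sites = sites,
       n_removed = n_removed, n_discarded = attr(m, "discarded"))
}
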