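# On-disk dialects.  Every artifact of the workflow is a plain TSV with a
# fixed, documented column layout; all genomic coordinates are 0-based
# half-open internally and in every file this package writes.  Parsers are
# total: a file either parses completely or the reader raises an error
# naming the offending line -- rows are never silently dropped.

# internal: fread a TSV keeping physical line numbers (header=FALSE files
# with possible '#' comment lines anywhere).
.fread_lines <- function(path, n_fields, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  # leading comment lines confuse fread's column detection; skip them
  # explicitly and keep the offset for line numbering
  con <- file(path, "r")
  n_skip <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    n_skip <- n_skip + 1L
  }
  close(con)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", quote = "",
                      colClasses = "character", fill = TRUE, skip = n_skip,
                      blank.lines.skip = FALSE, strip.white = FALSE),
    error = function(e) stop(what, ": cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0) return(list(dt = dt[0], line = integer(0)))
  line <- seq_len(nrow(dt)) + n_skip
  is_comment <- startsWith(dt[[1]], "#")
  is_blank <- dt[[1]] == "" & (ncol(dt) == 1 | {
    other <- as.matrix(dt[, -1, with = FALSE]); rowSums(other != "" & !is.na(other)) == 0
  })
  keep <- !is_comment & !is_blank
  dt <- dt[keep]
  line <- line[keep]
  if (ncol(dt) < n_fields) {
    stop(what, ": expected at least ", n_fields, " tab-separated fields, found ",
         ncol(dt), " (line ", if (length(line)) line[1] else 1, ")")
  }
  # rows shorter than the modal width are padded with NA by fread
  if (n_fields >= 1) {
    sub <- as.matrix(dt[, seq_len(n_fields), with = FALSE])
    bad <- which(rowSums(is.na(sub) | sub == "") > 0)
    if (length(bad)) {
      stop(what, ": line ", line[bad[1]], " has fewer than ", n_fields, " fields")
    }
  }
  list(dt = dt, line = line)
}

# internal: strict integer conversion with located errors.
.as_int <- function(x, line, what, field) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad)) {
    stop(what, ": line ", line[bad[1]], ": non-integer ", field, " '", x[bad[1]], "'")
  }
  as.integer(v)
}

#' Read a spatial BED file of 3'-end molecules
#'
#' One row per UMI-collapsed molecule, in the nine-column spatial BED
#' dialect: `chrom, start, end, name, score, strand, gene_tag, x, y`,
#' tab-separated, `#` comment lines allowed.  Coordinates are 0-based
#' half-open; `gene_tag` is `"."` when the upstream pipeline assigned no
#' gene; `x`/`y` are the positive integer array coordinates of the ST spot
#' that captured the molecule.
#'
#' @param path Path to the BED file.
#' @param array_bounds Optional integer vector `c(max_x, max_y)`; when
#'   given, coordinates outside `1..max_x` / `1..max_y` are an error.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `gene_tag` (empty string when absent), `x`, `y`,
#'   in file order.
#' @export
read_spatial_bed <- function(path, array_bounds = NULL) {
  parsed <- .fread_lines(path, 9L, "spatial BED")
  dt <- parsed$dt
  line <- parsed$line
  out <- data.table::data.table(
    chrom = dt[[1]],
    start = .as_int(dt[[2]], line, "spatial BED", "start"),
    end = .as_int(dt[[3]], line, "spatial BED", "end"),
    name = dt[[4]],
    score = dt[[5]],
    strand = dt[[6]],
    gene_tag = ifelse(dt[[7]] == ".", "", dt[[7]]),
    x = .as_int(dt[[8]], line, "spatial BED", "x"),
    y = .as_int(dt[[9]], line, "spatial BED", "y"))
  bad <- which(!(out$strand %in% c("+", "-")))
  if (length(bad)) {
    stop("spatial BED: line ", line[bad[1]], ": unknown strand '",
         out$strand[bad[1]], "' (must be + or -)")
  }
  bad <- which(out$start < 0L | out$end <= out$start)
  if (length(bad)) {
    stop("spatial BED: line ", line[bad[1]], ": invalid interval [",
         out$start[bad[1]], ",", out$end[bad[1]], ")")
  }
  bad <- which(out$x < 1L | out$y < 1L)
  if (length(bad)) {
    stop("spatial BED: line ", line[bad[1]], ": spot coordinates must be positive")
  }
  if (!is.null(array_bounds)) {
    stopifnot(length(array_bounds) == 2)
    bad <- which(out$x > array_bounds[1] | out$y > array_bounds[2])
    if (length(bad)) {
      stop("spatial BED: line ", line[bad[1]], ": spot (", out$x[bad[1]], ",",
           out$y[bad[1]], ") outside array bounds ",
           array_bounds[1], "x", array_bounds[2])
    }
  }
  out[]
}

#' Write a spatial BED file
#'
#' Inverse of [read_spatial_bed()]; empty `gene_tag` is written as `"."`.
#'
#' @param reads A `data.table` as returned by [read_spatial_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spatial_bed <- function(reads, path) {
  out <- data.table::data.table(
    reads$chrom, reads$start, reads$end, reads$name, reads$score,
    reads$strand, ifelse(reads$gene_tag == "", ".", reads$gene_tag),
    reads$x, reads$y)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from a GTF annotation
#'
#' Produces one gene model per `gene_id`.  Rows with feature type `gene`
#' are used directly; for genes that only have transcript/exon rows the
#' model is the union (min start, max end) of those rows.  GTF 1-based
#' closed coordinates are converted to the package's 0-based half-open
#' convention.
#'
#' @param path Path to a GTF file.
#' @return A `data.table` with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) stop("GTF: no features in ", path)
  meta <- as.data.frame(gr)
  if (is.null(meta$gene_id)) stop("GTF: no gene_id attributes; cannot derive gene models")
  dt <- data.table::data.table(
    chrom = as.character(meta$seqnames),
    start1 = meta$start, end1 = meta$end,
    strand = as.character(meta$strand),
    type = if (is.null(meta$type)) "" else as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    gene_name = if (is.null(meta$gene_name)) NA_character_ else as.character(meta$gene_name))
  dt <- dt[!is.na(gene_id) & gene_id != ""]
  if (nrow(dt) == 0) stop("GTF: no gene-like features in ", path)
  # prefer explicit gene rows; otherwise the union of the gene's rows
  gene_rows <- dt[type == "gene",
                  list(gene_id, chrom, strand, start1, end1, gene_name)]
  rest <- dt[!(gene_id %in% gene_rows$gene_id)]
  pieces <- list(gene_rows)
  if (nrow(rest)) {
    pieces <- c(pieces, list(rest[, list(
      chrom = chrom[1], strand = strand[1],
      start1 = min(start1), end1 = max(end1),
      gene_name = gene_name[1]), by = "gene_id"]))
  }
  models <- data.table::rbindlist(pieces, use.names = TRUE)
  if (anyDuplicated(models$gene_id)) {
    stop("GTF: duplicate gene rows for gene_id ",
         models$gene_id[duplicated(models$gene_id)][1])
  }
  if (any(!(models$strand %in% c("+", "-")))) {
    stop("GTF: gene with strand other than +/-")
  }
  out <- models[, list(
    gene_id,
    gene_name = ifelse(is.na(gene_name) | gene_name == "", gene_id, gene_name),
    chrom, strand,
    start = as.integer(start1 - 1L),
    end = as.integer(end1))]
  if (any(out$end <= out$start)) stop("GTF: gene with end <= start")
  data.table::setkey(out, chrom, strand, start)
  out[]
}

#' Read a spot label table
#'
#' Tab-separated with header `dataset, x, y, label`.  Labels are matched
#' case-insensitively against the canonical classes plus `unassigned` and
#' returned in canonical spelling; anything else is an error.  Duplicate
#' `(dataset, x, y)` keys are an error.
#'
#' @param path Path to the labels TSV.
#' @return A `data.table` with columns `dataset`, `x`, `y`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  names(dt) <- sub("^dataset_id$", "dataset", names(dt))
  need <- c("dataset", "x", "y", "label")
  if (!all(need %in% names(dt))) {
    stop("labels: header must contain columns ", paste(need, collapse = ", "))
  }
  line <- seq_len(nrow(dt)) + 1L  # header is line 1
  out <- data.table::data.table(
    dataset = dt$dataset,
    x = .as_int(dt$x, line, "labels", "x"),
    y = .as_int(dt$y, line, "labels", "y"),
    label = canonicalize_labels(dt$label))
  key <- paste0(out$dataset, ":", spot_id(out$x, out$y))
  if (anyDuplicated(key)) {
    stop("labels: duplicate (dataset, x, y) key ", key[duplicated(key)][1])
  }
  out[]
}

#' Write a spot label table
#'
#' @param labels A `data.table` with columns `dataset`, `x`, `y`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(labels[, c("dataset", "x", "y", "label")], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}

# internal: full-precision float formatting so that write->read round-trips
# are the identity on doubles.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.infinite(x) & x > 0] <- "Inf"
  out[is.infinite(x) & x < 0] <- "-Inf"
  out
}

#' Write a spot-by-tag-cluster matrix to TSV
#'
#' One file per dataset (dataset identity is carried by the file name).
#' First column `spot` holds the `"<x>x<y>"` id; remaining columns are the
#' ST-TC ids.  Counts are written as integers, log-normalized values at
#' full precision, so the write/read round-trip is the identity.
#'
#' @param m A single-dataset [spot_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "spot_matrix"))
  if (length(unique(m$spots$dataset)) > 1) {
    stop("write_matrix: matrix spans several datasets; write one file per dataset")
  }
  vals <- m$values
  dt <- if (m$space == "raw") {
    data.table::as.data.table(vals)
  } else {
    data.table::as.data.table(apply(vals, 2, .fmt_num, simplify = FALSE))
  }
  dt <- cbind(data.table::data.table(spot = spot_id(m$spots$x, m$spots$y)), dt)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a spot-by-tag-cluster matrix from TSV
#'
#' @param path Path to a matrix TSV written by [write_matrix()].
#' @param dataset Dataset identifier to attach to every spot (defaults to
#'   the file name without extension).
#' @param space `"auto"` infers raw counts when every value is a
#'   non-negative integer; override with `"raw"` or `"lognorm"`.
#' @return A [spot_matrix()].
#' @export
read_matrix <- function(path, dataset = NULL,
                        space = c("auto", "raw", "lognorm")) {
  space <- match.arg(space)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(dataset)) dataset <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "spot") stop("matrix: first column must be 'spot'")
  xy <- parse_spot_id(dt$spot)
  vals <- as.matrix(dt[, -1, with = FALSE])
  if (space == "auto") {
    space <- if (all(vals >= 0 & vals == round(vals))) "raw" else "lognorm"
  }
  spot_matrix(vals,
              data.table::data.table(dataset = dataset, x = xy$x, y = xy$y),
              space = space)
}

#' Write tag clusters as an extended BED file
#'
#' Columns: `chrom, start, end, id, total_count, strand, n_sites,
#' min_density, max_density, gene_id, gene_name` (0-based half-open,
#' densities at full precision, `.` for absent gene association).
#'
#' @param clusters A `data.table` of tag clusters (see [filter_clusters()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  dt <- data.table::data.table(
    clusters$chrom, clusters$start, clusters$end, clusters$id,
    clusters$total_count, clusters$strand, clusters$n_sites,
    .fmt_num(clusters$min_density), .fmt_num(clusters$max_density),
    ifelse(clusters$gene_id == "", ".", clusters$gene_id),
    ifelse(clusters$gene_name == "", ".", clusters$gene_name))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tag-cluster BED file written by [write_clusters()]
#'
#' @param path Path to the cluster BED.
#' @return A `data.table` with the tag-cluster columns.
#' @export
read_clusters <- function(path) {
  parsed <- .fread_lines(path, 11L, "cluster BED")
  dt <- parsed$dt
  line <- parsed$line
  out <- data.table::data.table(
    chrom = dt[[1]],
    start = .as_int(dt[[2]], line, "cluster BED", "start"),
    end = .as_int(dt[[3]], line, "cluster BED", "end"),
    id = dt[[4]],
    total_count = .as_int(dt[[5]], line, "cluster BED", "total_count"),
    strand = dt[[6]],
    n_sites = .as_int(dt[[7]], line, "cluster BED", "n_sites"),
    min_density = as.numeric(dt[[8]]),
    max_density = as.numeric(dt[[9]]),
    gene_id = ifelse(dt[[10]] == ".", "", dt[[10]]),
    gene_name = ifelse(dt[[11]] == ".", "", dt[[11]]))
  if (any(!(out$strand %in% c("+", "-")))) {
    stop("cluster BED: unknown strand")
  }
  out[]
}

#' Write per-spot class predictions
#'
#' Columns: `dataset, x, y, p_non-malignant, p_DCIS, p_IDC,
#' predicted_label`; probabilities at full precision.
#'
#' @param pred A prediction `data.table` (see [svm_predict()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  cls <- canonical_classes()
  pcols <- paste0("p_", cls)
  dt <- data.table::data.table(dataset = pred$dataset, x = pred$x, y = pred$y)
  for (pc in pcols) dt[[pc]] <- .fmt_num(pred[[pc]])
  dt$predicted_label <- pred$predicted_label
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a predictions table written by [write_predictions()]
#'
#' @param path Path to the predictions TSV.
#' @return A prediction `data.table`.
#' @export
read_predictions <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("dataset", "x", "y", paste0("p_", canonical_classes()), "predicted_label")
  if (!all(need %in% names(dt))) {
    stop("predictions: header must contain ", paste(need, collapse = ", "))
  }
  dt$dataset <- as.character(dt$dataset)
  dt$predicted_label <- canonicalize_labels(as.character(dt$predicted_label))
  dt[]
}
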