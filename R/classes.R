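# Core containers and identifiers shared by every stage of the workflow.

#' Canonical region class labels
#'
#' The three tissue region classes, in canonical order.  This order is the
#' tie-break order everywhere in the package: majority votes, argmax over
#' class probabilities and report columns all resolve ties by taking the
#' earliest class in this vector.
#'
#' @return Character vector `c("non-malignant", "DCIS", "IDC")`.
#' @export
canonical_classes <- function() {
  c("non-malignant", "DCIS", "IDC")
}

#' Spot identifier string
#'
#' Builds the `"<x>x<y>"` spot identifier used in matrix files (e.g.
#' `"17x21"`).  Dataset identity is carried by the file or section name,
#' never embedded in the spot id.
#'
#' @param x,y Positive integer array coordinates.
#' @return Character vector of spot ids.
#' @export
spot_id <- function(x, y) {
  paste0(as.integer(x), "x", as.integer(y))
}

#' Parse spot identifier strings
#'
#' @param ids Character vector of `"<x>x<y>"` ids.
#' @return A `data.table` with integer columns `x` and `y`.
#' @export
parse_spot_id <- function(ids) {
  ok <- grepl("^[0-9]+x[0-9]+$", ids)
  if (!all(ok)) {
    stop("malformed spot id(s): ", paste(utils::head(ids[!ok], 3), collapse = ", "))
  }
  parts <- data.table::tstrsplit(ids, "x", fixed = TRUE)
  data.table::data.table(x = as.integer(parts[[1]]), y = as.integer(parts[[2]]))
}

# internal: canonicalize class labels (case-insensitive); allow_unassigned
# controls whether the "unassigned" bucket is legal in this context.
canonicalize_labels <- function(labels, allow_unassigned = TRUE) {
  allowed <- canonical_classes()
  if (allow_unassigned) allowed <- c(allowed, "unassigned")
  idx <- match(tolower(labels), tolower(allowed))
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  }
  allowed[idx]
}

#' Construct a spot-by-tag-cluster matrix
#'
#' The central expression container: a numeric matrix with one row per ST
#' spot and one column per ST tag cluster (ST-TC), together with the
#' `(dataset, x, y)` key of every row and a flag saying whether the values
#' are raw molecule counts or log2 median-of-ratios-normalized values.
#'
#' @param values Numeric matrix, spots in rows, tag clusters in columns.
#'   Column names must be ST-TC ids (`"chrom:start-end:strand"`).
#' @param spots A data.frame/data.table with columns `dataset`, `x`, `y`,
#'   one row per matrix row, in matrix row order.
#' @param space `"raw"` (integer counts) or `"lognorm"`.
#' @return An object of class `spot_matrix` with fields `values`, `spots`
#'   and `space`.
#' @export
spot_matrix <- function(values, spots, space = c("raw", "lognorm")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  spots <- data.table::as.data.table(spots)[, list(
    dataset = as.character(dataset), x = as.integer(x), y = as.integer(y))]
  if (nrow(values) != nrow(spots)) {
    stop("values has ", nrow(values), " rows but spots has ", nrow(spots))
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique column names (ST-TC ids)")
  }
  keys <- paste0(spots$dataset, ":", spot_id(spots$x, spots$y))
  if (anyDuplicated(keys)) {
    stop("duplicate spot keys: ", paste(utils::head(keys[duplicated(keys)], 3), collapse = ", "))
  }
  rownames(values) <- keys
  if (space == "raw") {
    if (any(values < 0) || any(values != round(values))) {
      stop("raw-space values must be non-negative integers")
    }
    storage.mode(values) <- "integer"
  }
  structure(list(values = values, spots = spots, space = space),
            class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot_matrix: %d spots x %d tag clusters [%s space]\n",
              nrow(x$values), ncol(x$values), x$space))
  cat("datasets:", paste(unique(x$spots$dataset), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spot_matrix <- function(x) dim(x$values)

#' Subset a spot matrix
#'
#' @param x A [spot_matrix()].
#' @param i Row (spot) index, logical or integer.
#' @param j Column (tag-cluster) index, logical, integer or character.
#' @param ... Unused.
#' @return A `spot_matrix` with the selected spots/features.
#' @export
`[.spot_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  spot_matrix(x$values[i, j, drop = FALSE], x$spots[i, ], space = x$space)
}

#' Row-bind spot matrices from several datasets
#'
#' All inputs must share the same feature columns (same ids, same order)
#' and the same space.
#'
#' @param mats List of [spot_matrix()] objects.
#' @return A pooled `spot_matrix`.
#' @export
sm_rbind <- function(mats) {
  stopifnot(length(mats) >= 1)
  ids <- colnames(mats[[1]]$values)
  space <- mats[[1]]$space
  for (m in mats) {
    if (!identical(colnames(m$values), ids)) stop("feature columns differ across matrices")
    if (!identical(m$space, space)) stop("spaces differ across matrices")
  }
  spot_matrix(do.call(rbind, lapply(mats, function(m) m$values)),
              data.table::rbindlist(lapply(mats, function(m) m$spots)),
              space = space)
}

#' Align a spot matrix onto a fixed feature universe
#'
#' Reorders columns to `feature_ids`; features absent from `x` are imputed
#' as `fill` (0 raw counts / 0 log-normalized value, matching the shared
#' pooled feature-universe convention for train/test splits).
#'
#' @param x A [spot_matrix()].
#' @param feature_ids Character vector of ST-TC ids.
#' @param fill Value for absent features (default 0).
#' @return A `spot_matrix` with exactly `feature_ids` as columns.
#' @export
sm_align_features <- function(x, feature_ids, fill = 0) {
  out <- matrix(fill, nrow = nrow(x$values), ncol = length(feature_ids),
                dimnames = list(rownames(x$values), feature_ids))
  shared <- intersect(feature_ids, colnames(x$values))
  out[, shared] <- x$values[, shared, drop = FALSE]
  spot_matrix(out, x$spots, space = x$space)
}

#' Align a label table to the rows of a spot matrix
#'
#' @param m A [spot_matrix()] (or any list with a `spots` table).
#' @param labels A label table ([read_labels()]).
#' @return Character vector of labels aligned to the rows of `m`, `NA`
#'   where no label exists.
#' @export
labels_for_spots <- function(m, labels) {
  labels <- data.table::as.data.table(labels)
  key_m <- paste0(m$spots$dataset, ":", spot_id(m$spots$x, m$spots$y))
  key_l <- paste0(labels$dataset, ":", spot_id(labels$x, labels$y))
  labels$label[match(key_m, key_l)]
}
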