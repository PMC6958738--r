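# Label-free grouping of spots: PCA to two components, Ward (ward.D2)
# agglomeration into k groups, and majority-vote mapping of groups to
# region classes where expert labels exist.

#' PCA embedding of the log-normalized matrix
#'
#' Columns are centered (not scaled); coordinates are the projections on
#' the top right singular directions.  A deterministic sign convention
#' makes runs reproducible across platforms: each component's loading
#' vector is flipped so that its largest-magnitude entry is positive.
#'
#' @param m Lognorm-space [spot_matrix()] with at least 3 spots.
#' @param n_components Number of components (default 2).
#' @return An object of class `st_embedding`: list with `spots`,
#'   `coordinates` (spots x components), `explained_variance` (variance
#'   of each retained component) and `total_variance`.
#' @export
pca_embed <- function(m, n_components = 2) {
  stopifnot(inherits(m, "spot_matrix"), m$space == "lognorm")
  if (nrow(m$values) < max(3, n_components)) {
    stop("pca_embed: need at least max(3, n_components) spots")
  }
  n <- nrow(m$values)
  p <- ncol(m$values)
  if (p <= max(n, 1000L)) {
    pc <- stats::prcomp(m$values, center = TRUE, scale. = FALSE,
                        rank. = n_components)
    rot <- pc$rotation
    scores <- pc$x[, seq_len(n_components), drop = FALSE]
    ev <- pc$sdev[seq_len(n_components)]^2
    total <- sum(pc$sdev^2)
  } else {
    # dual route for wide matrices (features >> spots): eigendecompose the
    # n x n Gram matrix of the centered data instead of the p x p
    # covariance; identical components, far smaller working set
    xc <- sweep(m$values, 2, colMeans(m$values), "-")
    G <- tcrossprod(xc)
    eg <- eigen(G, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    sigma <- sqrt(lam[seq_len(n_components)])
    scores <- sweep(eg$vectors[, seq_len(n_components), drop = FALSE],
                    2, sigma, "*")
    rot <- crossprod(xc, sweep(eg$vectors[, seq_len(n_components),
                                          drop = FALSE],
                               2, ifelse(sigma > 0, 1 / sigma, 0), "*"))
    ev <- lam[seq_len(n_components)] / (n - 1)
    total <- sum(lam) / (n - 1)
    rownames(scores) <- rownames(m$values)
    colnames(scores) <- paste0("PC", seq_len(n_components))
    colnames(rot) <- colnames(scores)
  }
  for (k in seq_len(ncol(rot))) {
    top <- which.max(abs(rot[, k]))
    if (rot[top, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(spots = m$spots,
                 coordinates = scores,
                 explained_variance = ev,
                 total_variance = total),
            class = "st_embedding")
}

#' Ward agglomeration of an embedding
#'
#' Hierarchical agglomerative clustering minimizing Ward's increase in
#' within-cluster sum of squares (the `ward.D2` convention: Euclidean
#' distances, Lance-Williams update on their squares), cut at `k` groups.
#' Deterministic under a fixed input order.
#'
#' @param embedding An `st_embedding` ([pca_embed()]) or a numeric matrix
#'   of coordinates.
#' @param k Number of groups (default 3).
#' @return An object of class `st_groups`: list with `spots`, `group`
#'   (integer in `1..k`, renumbered by first appearance in input order)
#'   and the `hclust` tree.
#' @export
ward_cluster <- function(embedding, k = 3) {
  coords <- if (inherits(embedding, "st_embedding")) embedding$coordinates
            else as.matrix(embedding)
  spots <- if (inherits(embedding, "st_embedding")) embedding$spots else NULL
  if (k < 1) stop("ward_cluster: k must be >= 1")
  if (k > nrow(coords)) stop("ward_cluster: k exceeds number of spots")
  tree <- stats::hclust(stats::dist(coords), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  # renumber groups by first appearance so output is order-deterministic
  grp <- match(raw, unique(raw))
  structure(list(spots = spots, group = grp, tree = tree, k = k),
            class = "st_groups")
}

#' Map unsupervised groups to region classes by majority vote
#'
#' Each group is mapped to the majority class among its labeled members
#' (ties resolved in canonical class order); a group with no labeled
#' member maps to `"unassigned"` with a warning.  Agreement is the
#' fraction of labeled spots whose group's class equals their own label.
#'
#' @param groups An `st_groups` from [ward_cluster()] (with `spots`).
#' @param labels Label table; `unassigned` labels are ignored.
#' @return `groups` extended with `class_map` (named character vector per
#'   group), `assigned_class` (per spot), `agreement`, and `ari`
#'   (adjusted Rand index between groups and labels over labeled spots).
#' @export
map_groups_to_classes <- function(groups, labels) {
  stopifnot(inherits(groups, "st_groups"), !is.null(groups$spots))
  lab <- labels_for_spots(list(spots = groups$spots), labels)
  lab[!is.na(lab) & lab == "unassigned"] <- NA
  cls <- canonical_classes()
  gids <- sort(unique(groups$group))
  class_map <- stats::setNames(rep("unassigned", length(gids)), gids)
  for (g in gids) {
    member <- groups$group == g & !is.na(lab)
    if (!any(member)) {
      warning("map_groups_to_classes: group ", g, " has no labeled member")
      next
    }
    votes <- table(factor(lab[member], levels = cls))
    class_map[as.character(g)] <- cls[which.max(votes)]  # canonical tie-break
  }
  assigned <- class_map[as.character(groups$group)]
  labeled <- !is.na(lab)
  agreement <- mean(assigned[labeled] == lab[labeled])
  ari <- mclust::adjustedRandIndex(groups$group[labeled], lab[labeled])
  groups$class_map <- class_map
  groups$assigned_class <- unname(assigned)
  groups$agreement <- agreement
  groups$ari <- ari
  groups
}

#' Unsupervised classification pipeline
#'
#' [pca_embed()] then [ward_cluster()]; when labels are supplied the
#' groups are mapped to classes with [map_groups_to_classes()].
#'
#' @param m Lognorm-space [spot_matrix()].
#' @param labels Optional label table.
#' @param k Number of groups (default 3).
#' @param n_components PCA components (default 2).
#' @return An `st_groups`, with class mapping when labels were given.
#' @export
unsupervised_classify <- function(m, labels = NULL, k = 3, n_components = 2) {
  emb <- pca_embed(m, n_components = n_components)
  grp <- ward_cluster(emb, k = k)
  grp$embedding <- emb
  if (!is.null(labels)) grp <- map_groups_to_classes(grp, labels)
  grp
}

#' @export
print.st_groups <- function(x, ...) {
  cat(sprintf("st_groups: %d spots in %d groups\n", length(x$group), x$k))
  print(table(group = x$group))
  if (!is.null(x$agreement)) {
    cat(sprintf("label agreement: %.3f, ARI: %.3f\n", x$agreement, x$ari))
    cat("class map:", paste(names(x$class_map), "->", x$class_map,
                            collapse = ", "), "\n")
  }
  invisible(x)
}
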