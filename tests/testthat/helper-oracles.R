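# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: the density-sweep cluster oracle enumerates
# segments exhaustively, and the Ward oracle agglomerates with the direct
# SSE-increase formula instead of a Lance-Williams update.

# Brute-force density-sweep oracle for the tag-cluster decomposition.
# At density d a segment [i..j] is admissible iff every prefix and suffix
# trim density is >= d (no trim increases score total - d * span); the
# clusters at d are the inclusion-maximal admissible segments.  Sweeps d
# over 0, every segment's stability density and a supremum value, and
# unions the results.
oracle_density_sweep <- function(pos, cnt) {
  n <- length(pos)
  cum <- c(0, cumsum(cnt))
  PMIN <- matrix(Inf, n, n)
  SMIN <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    if (i < n) {
      ks <- (i + 1):n
      pd <- (cum[ks] - cum[i]) / (pos[ks] - pos[i])
      PMIN[i, ks] <- cummin(pd)
    }
  }
  for (j in seq_len(n)) {
    if (j > 1) {
      ks <- (j - 1):1
      sd <- (cum[j + 1] - cum[ks + 1]) / (pos[j] - pos[ks])
      SMIN[rev(ks), j] <- rev(cummin(sd))
    }
  }
  MD <- pmin(PMIN, SMIN)
  diag(MD) <- Inf
  segs <- data.table::data.table(i = rep(seq_len(n), times = n),
                                 j = rep(seq_len(n), each = n))
  segs <- segs[j >= i]
  segs[, md := MD[cbind(i, j)]]
  dens <- sort(unique(c(0, segs$md[is.finite(segs$md)])))
  dens <- c(dens, if (length(dens)) max(dens) + 1 else 1)
  out <- vector("list", length(dens))
  for (di in seq_along(dens)) {
    adm <- segs[md >= dens[di]]
    if (nrow(adm) == 0) next
    data.table::setorder(adm, i, -j)
    prevmax <- c(-Inf, cummax(adm$j)[-nrow(adm)])
    out[[di]] <- adm[adm$j > prevmax, c("i", "j")]
  }
  res <- unique(data.table::rbindlist(out))
  data.table::setorder(res, i, j)
  res
}

# Naive Ward agglomeration: keeps explicit cluster member lists and at
# each step merges the pair with the smallest increase in within-cluster
# sum of squares, Delta = |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2,
# breaking ties by the smallest pair index.  Returns the sequence of
# partitions (as membership vectors) after each merge.
oracle_ward_partitions <- function(X) {
  n <- nrow(X)
  members <- as.list(seq_len(n))
  partitions <- list()
  while (length(members) > 1) {
    k <- length(members)
    best <- NULL
    best_d <- Inf
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        ma <- colMeans(X[members[[a]], , drop = FALSE])
        mb <- colMeans(X[members[[b]], , drop = FALSE])
        na <- length(members[[a]]); nb <- length(members[[b]])
        d <- na * nb / (na + nb) * sum((ma - mb)^2)
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    merged <- c(members[[best[1]]], members[[best[2]]])
    members <- members[-best]
    members[[length(members) + 1]] <- merged
    memb <- integer(n)
    for (ci in seq_along(members)) memb[members[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- memb
  }
  partitions
}

# canonical form of a partition: relabel groups by first appearance
canon_partition <- function(memb) match(memb, unique(memb))
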