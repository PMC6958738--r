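# Class-specific expression signatures by pairwise differential
# expression.  The test is a transparent negative-binomial Wald test:
# moment-matched dispersion, pseudocounted log2 fold change, delta-method
# variance, two-sided normal p-value -- self-contained and fully
# inspectable, in place of calling out to an external DE package.

#' Negative-binomial Wald test per tag cluster
#'
#' For each feature (row of `counts`): normalized counts `y = k / sf`,
#' group means `m_a`, `m_b`,
#' `log2fc = log2((m_b + 1) / (m_a + 1))` (pseudocount 1 keeps it finite
#' on zero means), dispersion `alpha` by method of moments on the pooled
#' within-group residuals, `alpha = max(0, (s^2 - mbar) / mbar^2)` with
#' floor `1e-8`, then a Wald statistic on the log2 fold change whose
#' variance follows the NB model `Var(y_ij) = mu / sf_j + alpha * mu^2`
#' through the delta method, with a two-sided p-value from the normal
#' reference.
#'
#' @param counts Integer matrix, features x spots (a vector is treated as
#'   one feature).
#' @param group Factor (or vector) with exactly two levels; the first
#'   level is group A, the second group B, and the fold change is B over
#'   A.  Each group needs at least 2 spots.
#' @param sf Positive size factors, one per spot (default all 1).
#' @return A `data.table` with one row per feature: `base_mean_a`,
#'   `base_mean_b` (normalized means), `log2fc`, `dispersion`, `p_value`.
#' @export
nb_test <- function(counts, group, sf = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("nb_test: group must have exactly 2 levels")
  ga <- group == levels(group)[1]
  gb <- group == levels(group)[2]
  if (sum(ga) < 2 || sum(gb) < 2) {
    stop("nb_test: each group needs at least 2 spots")
  }
  if (length(group) != ncol(counts)) {
    stop("nb_test: group length does not match number of spots")
  }
  if (is.null(sf)) sf <- rep(1, ncol(counts))
  if (length(sf) != ncol(counts) || any(!is.finite(sf) | sf <= 0)) {
    stop("nb_test: size factors must be positive, one per spot")
  }
  # process features in blocks to bound the size of dense temporaries
  blocks <- split(seq_len(nrow(counts)),
                  ceiling(seq_len(nrow(counts)) / 4000))
  out <- vector("list", length(blocks))
  na <- sum(ga); nb <- sum(gb)
  inv_a <- sum(1 / sf[ga]); inv_b <- sum(1 / sf[gb])
  for (bi in seq_along(blocks)) {
    y <- sweep(counts[blocks[[bi]], , drop = FALSE], 2, sf, "/")
    m_a <- rowMeans(y[, ga, drop = FALSE])
    m_b <- rowMeans(y[, gb, drop = FALSE])
    log2fc <- log2((m_b + 1) / (m_a + 1))
    # pooled within-group residual variance, method-of-moments dispersion
    ss <- rowSums((y[, ga, drop = FALSE] - m_a)^2) +
      rowSums((y[, gb, drop = FALSE] - m_b)^2)
    s2 <- ss / (na + nb - 2)
    mbar <- rowMeans(y)
    alpha <- ifelse(mbar > 0, pmax(1e-8, (s2 - mbar) / mbar^2), 1e-8)
    # Var(mean_g) = (1/n_g^2) * sum_j (mu/sf_j + alpha mu^2), delta method
    var_ma <- (m_a * inv_a + alpha * m_a^2 * na) / na^2
    var_mb <- (m_b * inv_b + alpha * m_b^2 * nb) / nb^2
    var_fc <- (var_ma / (m_a + 1)^2 + var_mb / (m_b + 1)^2) / log(2)^2
    z <- ifelse(var_fc > 0, log2fc / sqrt(var_fc), 0)
    p <- 2 * stats::pnorm(-abs(z))
    out[[bi]] <- data.table::data.table(
      base_mean_a = m_a, base_mean_b = m_b,
      log2fc = log2fc, dispersion = alpha, p_value = p)
  }
  data.table::rbindlist(out)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (`stats::p.adjust(method = "BH")`)
#' with input validation: `q_(i) = min_{j >= i} (m * p_(j) / j)` capped
#' at 1, mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Derive the class-specific tag-cluster signature
#'
#' Runs the NB Wald test per ST-TC for each of the three pairwise
#' contrasts (non-malignant vs DCIS, DCIS vs IDC, non-malignant vs IDC)
#' on the labeled spots of the two classes, adjusts p-values by
#' Benjamini-Hochberg within each contrast, selects ST-TCs with
#' `|log2fc| > lfc_threshold` and `q < fdr_threshold`, and unions the
#' three selections.
#'
#' @param m Raw-space [spot_matrix()].
#' @param labels Label table ([read_labels()]); spots labeled
#'   `unassigned` (and unlabeled spots) are ignored.  All three classes
#'   must be present.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold (default 0.01).
#' @param sf Size factors aligned to the rows of `m`; computed with
#'   [size_factors()] when `NULL`.
#' @return An object of class `st_signature`: list with `contrasts` (one
#'   `data.table` of per-TC statistics per contrast, with `q_value` and
#'   `selected`), `selected_tc_ids` (ordered union) and the thresholds.
#' @export
derive_signature <- function(m, labels, lfc_threshold = 2,
                             fdr_threshold = 0.01, sf = NULL) {
  stopifnot(inherits(m, "spot_matrix"), m$space == "raw")
  lab <- labels_for_spots(m, labels)
  keep <- !is.na(lab) & lab %in% canonical_classes()
  cls <- canonical_classes()
  present <- cls %in% lab[keep]
  if (!all(present)) {
    stop("derive_signature: class(es) missing from labeled spots: ",
         paste(cls[!present], collapse = ", "))
  }
  if (is.null(sf)) sf <- size_factors(m)
  contrasts <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  res <- list()
  selected <- character(0)
  counts_t <- t(m$values)  # features x spots
  for (ct in contrasts) {
    a <- cls[ct[1]]; b <- cls[ct[2]]
    sel <- keep & lab %in% c(a, b)
    tab <- nb_test(counts_t[, sel, drop = FALSE],
                   factor(lab[sel], levels = c(a, b)), sf[sel])
    tab[, `:=`(tc_id = rownames(counts_t), group_a = a, group_b = b)]
    tab[, q_value := bh_adjust(p_value)]
    tab[, selected := abs(log2fc) > lfc_threshold & q_value < fdr_threshold]
    data.table::setcolorder(tab, c("tc_id", "group_a", "group_b"))
    res[[paste(a, "vs", b)]] <- tab
    selected <- union(selected, tab$tc_id[tab$selected])
  }
  structure(list(contrasts = res,
                 selected_tc_ids = selected[order(match(selected, rownames(counts_t)))],
                 lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold),
            class = "st_signature")
}

#' @export
print.st_signature <- function(x, ...) {
  cat(sprintf("st_signature: %d ST-TCs selected (|log2FC| > %g, FDR < %g)\n",
              length(x$selected_tc_ids), x$lfc_threshold, x$fdr_threshold))
  for (nm in names(x$contrasts)) {
    cat(sprintf("  %-28s %d selected of %d tested\n", nm,
                sum(x$contrasts[[nm]]$selected), nrow(x$contrasts[[nm]])))
  }
  invisible(x)
}

#' Write a signature table to TSV
#'
#' One row per contrast x ST-TC with the test statistics and a `selected`
#' flag.
#'
#' @param sig An `st_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  tab <- data.table::rbindlist(sig$contrasts)
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}
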