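# Bundled benchmark tables from the published four-section breast-cancer
# ST study this workflow emulates: per-class spot counts (manual expert
# annotation and automatic PCA-based annotation), leave-one-dataset-out
# F1 scores for the three feature modes, and the headline totals.  They
# let reported summary rows (totals, averages, percentages) be recomputed
# and checked as plain arithmetic, without access to the raw sequencing
# data.

#' Bundled benchmark reference tables
#'
#' @return A list of `data.table`s: `spot_counts` (per-section spot
#'   counts by class, for `manual` and `automatic` annotation),
#'   `f1_scores` (per held-out dataset and class, for `signature`, `all`
#'   and `unsupervised` feature modes, including the published `Avg`
#'   row) and `headline` (quantity/value pairs: totals of annotated and
#'   pooled spots, correctly classified spot counts, signature
#'   composition).
#' @export
reference_tables <- function() {
  pth <- function(f) system.file("extdata", f, package = "stsig",
                                 mustWork = TRUE)
  list(
    spot_counts = data.table::fread(pth("reference_spot_counts.tsv")),
    f1_scores = data.table::fread(pth("reference_f1_scores.tsv")),
    headline = data.table::fread(pth("reference_headline.tsv")))
}

#' Truncate to a fixed number of decimals
#'
#' Rounds toward zero at `digits` decimals (e.g. 0.975 -> 0.97).  The
#' benchmark F1 tables display their `Avg` row with this truncation
#' convention rather than round-half-even, so recomputing their summary
#' rows needs it; this package's own reports use [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimals (default 2).
#' @return Truncated values.
#' @export
truncate_decimals <- function(x, digits = 2) {
  trunc(x * 10^digits + sign(x) * 1e-9) / 10^digits
}

#' Recompute the summary row of an F1 table
#'
#' Column means of the per-dataset rows, at full precision and truncated
#' to 2 decimals (the display convention of the benchmark tables).
#'
#' @param tab A `data.table` with a `dataset` column and one numeric
#'   column per class; any `Avg` row is excluded from the means.
#' @return A list with `mean` (full precision, named by class),
#'   `truncated` (2 decimals) and `overall` (mean of the class means).
#' @export
f1_table_means <- function(tab) {
  tab <- data.table::as.data.table(tab)
  body <- tab[dataset != "Avg"]
  cols <- setdiff(names(tab), c("features", "dataset"))
  m <- vapply(cols, function(cl) mean(body[[cl]]), numeric(1))
  list(mean = m, truncated = truncate_decimals(m, 2), overall = mean(m))
}
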