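# Supervised label transfer: one-vs-rest linear support vector machines
# over log-normalized tag-cluster expression, softmax probability
# calibration, per-class F1 and the leave-one-dataset-out evaluation.

#' Train a linear multi-class SVM on labeled spots
#'
#' One linear maximum-margin classifier per class (one-vs-rest) at fixed
#' cost `C = 1` on the pooled training spots; class probabilities come
#' from a softmax over the three decision values (temperature 1), which
#' keeps runs deterministic.  Features are either a signature id set or
#' all columns of the training matrix.
#'
#' @param m Lognorm-space [spot_matrix()] of training spots.
#' @param labels Label table; `unassigned` and unlabeled spots are
#'   excluded from training.  At least 2 classes must remain.
#' @param features Character vector of ST-TC ids to train on, or `NULL`
#'   for all columns of `m`.  Unknown ids are an error.
#' @param cost SVM cost parameter (default 1).
#' @return An object of class `st_svm`: `classes` (canonical order),
#'   `feature_ids`, `weights` (features x classes), `intercepts`,
#'   `cost`, `feature_mode`, and `train_datasets`.
#' @export
svm_train <- function(m, labels, features = NULL, cost = 1) {
  stopifnot(inherits(m, "spot_matrix"), m$space == "lognorm")
  if (is.null(features)) {
    features <- colnames(m$values)
    mode <- "all"
  } else {
    if (length(features) == 0) stop("svm_train: empty feature set")
    unknown <- setdiff(features, colnames(m$values))
    if (length(unknown)) {
      stop("svm_train: unknown feature id(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    mode <- "signature"
  }
  lab <- labels_for_spots(m, labels)
  keep <- !is.na(lab) & lab %in% canonical_classes()
  if (sum(keep) == 0) stop("svm_train: no labeled training spots")
  lab <- lab[keep]
  if (length(unique(lab)) < 2) {
    stop("svm_train: training spots cover a single class")
  }
  X <- m$values[keep, features, drop = FALSE]
  cls <- canonical_classes()
  weights <- matrix(0, nrow = length(features), ncol = length(cls),
                    dimnames = list(features, cls))
  intercepts <- stats::setNames(numeric(length(cls)), cls)
  for (cl in cls) {
    yc <- factor(ifelse(lab == cl, "pos", "neg"), levels = c("neg", "pos"))
    if (length(unique(yc)) < 2) next  # absent class: zero machine
    fit <- e1071::svm(X, yc, type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1, ]
    b <- -fit$rho
    # orient so that decision values are positive for the target class
    dv <- as.vector(X %*% w) + b
    if (mean(dv[yc == "pos"]) < mean(dv[yc == "neg"])) {
      w <- -w; b <- -b
    }
    weights[, cl] <- w
    intercepts[cl] <- b
  }
  structure(list(classes = cls, feature_ids = features,
                 weights = weights, intercepts = intercepts,
                 cost = cost, feature_mode = mode,
                 train_datasets = unique(m$spots$dataset[keep])),
            class = "st_svm")
}

#' @export
print.st_svm <- function(x, ...) {
  cat(sprintf("st_svm: linear one-vs-rest, %d features (%s mode), C = %g\n",
              length(x$feature_ids), x$feature_mode, x$cost))
  cat("trained on:", paste(x$train_datasets, collapse = ", "), "\n")
  invisible(x)
}

#' Predict class probabilities for spots
#'
#' Aligns the test matrix onto the model's feature ids (absent features
#' contribute a log-normalized value of 0), computes the three decision
#' values and softmaxes them into probabilities.  Each probability row is
#' non-negative and sums to 1; the predicted label is the argmax,
#' resolved in canonical class order on exact ties.
#'
#' @param model An `st_svm` from [svm_train()].
#' @param m Lognorm-space [spot_matrix()] (normalized with its own
#'   per-dataset size factors).
#' @return A `data.table` with columns `dataset`, `x`, `y`,
#'   `p_non-malignant`, `p_DCIS`, `p_IDC`, `predicted_label`.
#' @export
svm_predict <- function(model, m) {
  stopifnot(inherits(model, "st_svm"), inherits(m, "spot_matrix"),
            m$space == "lognorm")
  if (nrow(m$values) == 0) stop("svm_predict: empty test matrix")
  Xa <- sm_align_features(m, model$feature_ids)$values
  dec <- Xa %*% model$weights
  dec <- sweep(dec, 2, model$intercepts, "+")
  stable <- dec - apply(dec, 1, max)          # numerically safe softmax
  probs <- exp(stable) / rowSums(exp(stable))
  pred_idx <- apply(probs, 1, which.max)      # first max = canonical order
  out <- data.table::data.table(dataset = m$spots$dataset,
                                x = m$spots$x, y = m$spots$y)
  for (k in seq_along(model$classes)) {
    out[[paste0("p_", model$classes[k])]] <- probs[, k]
  }
  out$predicted_label <- model$classes[pred_idx]
  out[]
}

#' Per-class F1 scores
#'
#' `F1 = 2 TP / (2 TP + FP + FN)` per class, defined as 0 when the
#' denominator is 0 (class never predicted and never true).  Spots whose
#' truth is `unassigned` (or `NA`) are excluded.
#'
#' @param predicted Character vector of predicted classes.
#' @param truth Character vector of true classes, same length.
#' @return Named numeric vector of F1 scores in canonical class order.
#' @export
f1_per_class <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("f1_per_class: length mismatch")
  }
  keep <- !is.na(truth) & truth %in% canonical_classes()
  predicted <- predicted[keep]
  truth <- truth[keep]
  vapply(canonical_classes(), function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }, numeric(1))
}

# internal: per-dataset filter + size factors + log normalization, then
# alignment to a shared feature universe (absent features = 0 raw counts).
.normalize_per_dataset <- function(raw_list, feature_ids, filter_args) {
  lapply(raw_list, function(m) {
    f <- do.call(filter_matrix, c(list(m), filter_args))
    sf <- size_factors(f)
    list(norm = sm_align_features(normalize_log(f, sf), feature_ids),
         filtered = sm_align_features(f, feature_ids),
         sf = sf)
  })
}

#' Leave-one-dataset-out cross-validated evaluation
#'
#' For each dataset `d`: normalize every dataset independently (filter,
#' median-of-ratios size factors, log2 with pseudocount, per dataset);
#' when `feature_mode = "signature"`, derive the DE signature from the
#' other datasets only; train the one-vs-rest linear SVM on the pooled
#' other datasets; predict `d`'s labeled spots and score per-class F1.
#' The report appends an arithmetic mean row.
#'
#' @param raw_list Named list of raw-space single-dataset
#'   [spot_matrix()] objects sharing the pooled ST-TC feature universe.
#' @param labels Label table covering (some of) the spots.
#' @param feature_mode `"signature"` (per-fold DE selection) or `"all"`.
#' @param lfc_threshold,fdr_threshold Signature thresholds (defaults 2 /
#'   0.01), used in signature mode.
#' @param filter_args List of arguments for [filter_matrix()] applied to
#'   every dataset (default `list()` keeps the filter defaults).
#' @param cost SVM cost (default 1).
#' @return An object of class `st_lodo_report`: `f1` (`data.table` with
#'   `dataset` + one column per class, plus an `Avg` row), `predictions`
#'   (per-fold prediction tables), `signatures` (per-fold signatures, in
#'   signature mode) and `feature_mode`.
#' @export
leave_one_dataset_out <- function(raw_list, labels,
                                  feature_mode = c("signature", "all"),
                                  lfc_threshold = 2, fdr_threshold = 0.01,
                                  filter_args = list(), cost = 1) {
  feature_mode <- match.arg(feature_mode)
  if (length(raw_list) < 2) {
    stop("leave_one_dataset_out: need at least 2 datasets")
  }
  if (is.null(names(raw_list))) {
    names(raw_list) <- vapply(raw_list, function(m) m$spots$dataset[1], "")
  }
  feature_ids <- Reduce(union, lapply(raw_list, function(m) colnames(m$values)))
  prep <- .normalize_per_dataset(raw_list, feature_ids, filter_args)
  cls <- canonical_classes()
  rows <- list(); preds <- list(); sigs <- list()
  for (d in names(raw_list)) {
    test_norm <- prep[[d]]$norm
    test_lab <- labels_for_spots(test_norm, labels)
    has_label <- !is.na(test_lab) & test_lab %in% cls
    if (!any(has_label)) {
      warning("leave_one_dataset_out: dataset '", d,
              "' has no labeled spot; skipped")
      next
    }
    train_names <- setdiff(names(raw_list), d)
    train_norm <- sm_rbind(lapply(prep[train_names], `[[`, "norm"))
    features <- NULL
    if (feature_mode == "signature") {
      # pooled raw training counts on the shared universe, with each
      # dataset's own size factors, per the separate-inputs convention
      train_raw <- sm_rbind(lapply(prep[train_names], `[[`, "filtered"))
      sf_train <- unname(unlist(lapply(prep[train_names], `[[`, "sf")))
      names(sf_train) <- rownames(train_raw$values)
      sig <- derive_signature(train_raw, labels, lfc_threshold,
                              fdr_threshold, sf = sf_train)
      sigs[[d]] <- sig
      features <- sig$selected_tc_ids
      if (length(features) == 0) {
        stop("leave_one_dataset_out: empty signature for fold '", d, "'")
      }
    }
    model <- svm_train(train_norm, labels, features = features, cost = cost)
    pred <- svm_predict(model, test_norm[has_label, ])
    preds[[d]] <- pred
    f1 <- f1_per_class(pred$predicted_label, test_lab[has_label])
    rows[[d]] <- c(list(dataset = d), as.list(f1))
  }
  f1_tab <- data.table::rbindlist(rows)
  avg <- c(list(dataset = "Avg"),
           as.list(colMeans(as.matrix(f1_tab[, -1, with = FALSE]))))
  f1_tab <- data.table::rbindlist(list(f1_tab, avg))
  structure(list(f1 = f1_tab, predictions = preds, signatures = sigs,
                 feature_mode = feature_mode),
            class = "st_lodo_report")
}

#' @export
print.st_lodo_report <- function(x, ...) {
  cat("leave-one-dataset-out F1 (", x$feature_mode, " features)\n", sep = "")
  disp <- data.table::copy(x$f1)
  for (cl in canonical_classes()) {
    # display at 2 decimals, round-half-even; full precision kept in $f1
    disp[[cl]] <- formatC(round(disp[[cl]], 2), format = "f", digits = 2)
  }
  print(as.data.frame(disp), row.names = FALSE)
  invisible(x)
}
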