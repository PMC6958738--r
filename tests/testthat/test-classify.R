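# Linear one-vs-rest SVM, probability calibration, F1 and the
# leave-one-dataset-out evaluation.

make_toy_training <- function(n_per_class = 10, margin = 5, sd = 0.3,
                              dataset = "d1", seed = 42) {
  withr::local_seed(seed, .local_envir = parent.frame())
  cls <- canonical_classes()
  centers <- rbind(c(0, 0), c(margin, 0), c(0, margin))
  X <- centers[rep(1:3, each = n_per_class), ] +
    matrix(stats::rnorm(6 * n_per_class, sd = sd), 3 * n_per_class)
  colnames(X) <- c("c:100-110:+", "c:200-210:+")
  m <- spot_matrix(X, data.table::data.table(
    dataset = dataset, x = seq_len(nrow(X)), y = 1L), space = "lognorm")
  lab <- data.table::data.table(dataset = dataset, x = seq_len(nrow(X)),
                                y = 1L, label = rep(cls, each = n_per_class))
  list(m = m, labels = lab)
}

test_that("separable classes are fit perfectly and duplication changes nothing", {
  toy <- make_toy_training()
  model <- svm_train(toy$m, toy$labels)
  pred <- svm_predict(model, toy$m)
  expect_equal(pred$predicted_label,
               labels_for_spots(toy$m, toy$labels))

  # duplicating every training spot leaves the decision boundary unchanged
  m2 <- sm_rbind(list(toy$m, spot_matrix(
    toy$m$values, data.table::data.table(
      dataset = "d1", x = toy$m$spots$x + 100L, y = 2L), space = "lognorm")))
  lab2 <- rbind(toy$labels,
                data.table::data.table(dataset = "d1",
                                       x = toy$labels$x + 100L, y = 2L,
                                       label = toy$labels$label))
  model2 <- svm_train(m2, lab2)
  expect_equal(model2$weights, model$weights, tolerance = 1e-6)
  expect_equal(model2$intercepts, model$intercepts, tolerance = 1e-6)

  # single-class training set is rejected
  lab_one <- data.table::copy(toy$labels)[, label := "DCIS"]
  expect_error(svm_train(toy$m, lab_one), "single class")
  # unknown feature ids are rejected
  expect_error(svm_train(toy$m, toy$labels, features = "nope"), "unknown")
})

test_that("probabilities are a proper softmax distribution with argmax prediction", {
  toy <- make_toy_training()
  model <- svm_train(toy$m, toy$labels)
  pred <- svm_predict(model, toy$m)
  pcols <- paste0("p_", canonical_classes())
  probs <- as.matrix(pred[, pcols, with = FALSE])
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  expect_equal(pred$predicted_label,
               canonical_classes()[apply(probs, 1, which.max)])

  # permuting test spots permutes output rows identically
  perm <- sample(nrow(toy$m$values))
  pred_perm <- svm_predict(model, toy$m[perm, ])
  expect_equal(pred_perm$x, pred$x[perm])
  expect_equal(pred_perm$predicted_label, pred$predicted_label[perm])

  # an all-zero spot still gets a valid distribution (intercept-only scores)
  zero <- spot_matrix(matrix(0, 1, 2, dimnames = list(NULL, model$feature_ids)),
                      data.table::data.table(dataset = "dz", x = 1L, y = 1L),
                      space = "lognorm")
  pz <- svm_predict(model, zero)
  expect_equal(sum(as.matrix(pz[, pcols, with = FALSE])), 1, tolerance = 1e-9)

  # features absent from the test matrix are imputed as 0
  one_feat <- spot_matrix(
    matrix(1.5, 1, 1, dimnames = list(NULL, model$feature_ids[1])),
    data.table::data.table(dataset = "dz", x = 1L, y = 1L), space = "lognorm")
  p1 <- svm_predict(model, one_feat)
  manual <- spot_matrix(
    matrix(c(1.5, 0), 1, 2, dimnames = list(NULL, model$feature_ids)),
    data.table::data.table(dataset = "dz", x = 1L, y = 1L), space = "lognorm")
  expect_equal(as.matrix(p1[, pcols, with = FALSE]),
               as.matrix(svm_predict(model, manual)[, pcols, with = FALSE]))
})

test_that("per-class F1 follows 2TP/(2TP+FP+FN) with the zero convention", {
  cls <- canonical_classes()
  truth <- rep(cls, times = c(11, 5, 4))
  pred <- truth
  expect_equal(unname(f1_per_class(pred, truth)), c(1, 1, 1))

  # one class with TP=8, FP=1, FN=3 -> F1 = 16/20 = 0.8
  truth2 <- c(rep("non-malignant", 11), rep("DCIS", 9))
  pred2 <- c(rep("non-malignant", 8), rep("DCIS", 3),
             rep("DCIS", 8), "non-malignant")
  expect_equal(unname(f1_per_class(pred2, truth2)["non-malignant"]),
               16 / 20)

  # class never predicted and never true -> 0
  expect_equal(unname(f1_per_class(c("DCIS", "DCIS"),
                                   c("DCIS", "DCIS"))["IDC"]), 0)
  # unassigned truth is excluded
  expect_equal(unname(f1_per_class(c("DCIS", "IDC"),
                                   c("DCIS", "unassigned"))["DCIS"]), 1)
  expect_error(f1_per_class("DCIS", c("DCIS", "IDC")), "length")
})

test_that("leave-one-dataset-out on identical separable datasets is perfect", {
  toys <- lapply(c("d1", "d2"), function(d) {
    t <- make_toy_training(n_per_class = 30, dataset = d, seed = 5)
    # raw counts version: exponentiate to get an integer count structure
    vals <- matrix(as.integer(round(2^t$m$values * 20)),
                   nrow = nrow(t$m$values),
                   dimnames = dimnames(t$m$values))
    list(m = spot_matrix(vals, t$m$spots, space = "raw"), labels = t$labels)
  })
  raw_list <- stats::setNames(lapply(toys, `[[`, "m"), c("d1", "d2"))
  labels <- data.table::rbindlist(lapply(toys, `[[`, "labels"))
  rep <- leave_one_dataset_out(raw_list, labels, feature_mode = "all",
                               filter_args = list(min_spot_counts = 0,
                                                  min_spot_features = 0,
                                                  min_tc_spots = 0))
  body <- rep$f1[rep$f1$dataset != "Avg"]
  expect_equal(nrow(body), 2)
  expect_equal(unname(as.matrix(body[, -1])),
               matrix(1, 2, 3), ignore_attr = TRUE)
  # mean row equals independently recomputed column means
  avg <- rep$f1[rep$f1$dataset == "Avg"]
  for (cl in canonical_classes()) {
    expect_equal(avg[[cl]], mean(body[[cl]]))
  }
  # report shape: one row per dataset + Avg, one column per class
  expect_equal(names(rep$f1), c("dataset", canonical_classes()))
})

test_that("shuffling training labels destroys transfer on the small scene", {
  sim <- small_sim()
  tc <- small_tc()
  m <- tc$matrix
  raw_list <- lapply(split(seq_len(nrow(m$values)), m$spots$dataset),
                     function(ix) m[ix, ])
  filter_args <- list(min_spot_counts = 20, min_spot_features = 10)
  rep_true <- leave_one_dataset_out(raw_list, sim$labels,
                                    feature_mode = "all",
                                    filter_args = filter_args)
  withr::local_seed(13)
  shuffled <- data.table::copy(sim$labels)
  shuffled[, label := sample(label)]
  rep_shuf <- leave_one_dataset_out(raw_list, shuffled, feature_mode = "all",
                                    filter_args = filter_args)
  mean_true <- mean(as.matrix(rep_true$f1[dataset == "Avg", -1]))
  mean_shuf <- mean(as.matrix(rep_shuf$f1[dataset == "Avg", -1]))
  expect_gte(mean_true, 0.9)
  expect_lt(mean_shuf, 0.5)
})
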