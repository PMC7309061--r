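test_that("base learners honor the probability contract on separable data", {
  toy <- toy_clusters(n_per = 15, gap = 6, seed = 2)
  for (name in c("svm_linear", "knn", "decision_stump", "logistic", "flda",
                 "bayes_net", "random_forest", "lwl", "voted_perceptron",
                 "sgd_linear", "naive_bayes", "lda", "j48_tree", "lmt")) {
    m <- train_base(base_learner_spec(name), toy$X, toy$y, seed = 4)
    p <- predict_proba(m, toy$X)
    expect_identical(dim(p), c(30L, 2L))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
    expect_true(all(p >= 0))
  }
  svm <- train_base(base_learner_spec("svm_linear"), toy$X, toy$y)
  expect_equal(as.integer(predict_proba(svm, toy$X)[, "1"] >= 0.5), toy$y)
})

test_that("1-NN memorizes its training labels", {
  toy <- toy_clusters(n_per = 12, gap = 1.5, seed = 3)   # overlapping classes
  m <- train_base(base_learner_spec("knn", list(k = 1)), toy$X, toy$y)
  expect_equal(as.integer(predict_proba(m, toy$X)[, "1"] >= 0.5), toy$y)
})

test_that("single-class training data is rejected", {
  toy <- toy_clusters(n_per = 10)
  expect_error(train_base(base_learner_spec("logistic"), toy$X, rep(0L, 20)),
               class = "cogscreen_validation_error")
  expect_error(train_sequence_classifier(list(matrix(1, 2, 3)), 0L),
               class = "cogscreen_validation_error")
})

test_that("the PCA preprocessor reduces dimension by explained variance", {
  set.seed(6)
  base <- matrix(rnorm(60 * 2), 60)
  X <- cbind(base, base %*% matrix(rnorm(4), 2) + matrix(rnorm(60 * 2, 0, 1e-4), 60))
  y <- as.integer(base[, 1] > 0)
  m <- train_base(base_learner_spec("logistic", pca_vc = 0.95), X, y)
  expect_lte(m$pca$ncomp, 3)
  expect_lt(max(abs(rowSums(predict_proba(m, X)) - 1)), 1e-9)
})

test_that("AdaBoost.M1 weight update matches the hand-computed toy example", {
  # 4 instances, uniform weights, one miss: eps 0.25, beta 1/3, and the
  # missed instance ends at weight 0.5 after renormalization
  upd <- adaboost_weight_update(rep(0.25, 4), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(upd$eps, 0.25)
  expect_equal(upd$beta, 1 / 3)
  expect_equal(upd$alpha, log(3))
  expect_equal(upd$w_new, c(1 / 6, 1 / 6, 1 / 6, 1 / 2))
  expect_equal(sum(upd$w_new), 1)
  expect_error(adaboost_weight_update(rep(0.25, 4), rep(TRUE, 4)),
               class = "cogscreen_domain_error")
})

test_that("AdaBoost.M1 stops early on a perfect or chance-level weak learner", {
  toy <- toy_clusters(n_per = 15, gap = 8, seed = 5)
  boosted <- adaboost_m1(base_learner_spec("svm_linear"), toy$X, toy$y, rounds = 10)
  expect_length(boosted$models, 1)   # eps = 0 in round 1

  # balanced XOR checkerboard: no axis-aligned stump beats chance
  g <- expand.grid(x1 = seq(-1, 1, length.out = 8), x2 = seq(-1, 1, length.out = 8))
  Xx <- as.matrix(g)
  yx <- as.integer(xor(g$x1 > 0, g$x2 > 0))
  expect_warning(
    weak <- adaboost_m1(base_learner_spec("decision_stump"), Xx, yx, rounds = 3),
    "chance")
  expect_length(weak$models, 1)
})

test_that("boosting training error is non-increasing on structured data", {
  set.seed(8)
  X <- matrix(rnorm(80 * 2), 80)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  errs <- sapply(c(1, 5, 15), function(r) {
    b <- adaboost_m1(base_learner_spec("decision_stump"), X, y, rounds = r, seed = 3)
    mean(as.integer(predict_proba(b, X)[, "1"] >= 0.5) != y)
  })
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("fusion rules average probabilities and break ties toward healthy", {
  p1 <- cbind(`0` = 0.4, `1` = 0.6)
  p2 <- cbind(`0` = 0.2, `1` = 0.8)
  f <- fuse(list(p1, p2))
  expect_equal(f$p1, 0.7)
  expect_identical(f$pred, 1L)
  expect_equal(f$confidence, 0.7)

  tie <- fuse(list(cbind(`0` = 0.5, `1` = 0.5)))
  expect_identical(tie$pred, 0L)

  votes <- lapply(c(rep(0.9, 7), rep(0.2, 6)), function(p) cbind(`0` = 1 - p, `1` = p))
  expect_identical(fuse(votes, "majority_vote")$pred, 1L)

  # averaging identical members reproduces the single member
  same <- fuse(list(p1, p1, p1))
  expect_equal(same$p1, 0.6)
})

test_that("the metric suite reproduces hand-checkable extremes", {
  perfect <- evaluate(c(0, 0, 1, 1), c(0, 0, 1, 1),
                      cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc_roc, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)

  set.seed(10)
  n <- 4000
  y <- rep(c(0L, 1L), n / 2)
  pred <- sample(c(0L, 1L), n, replace = TRUE)
  chance <- evaluate(y, pred)
  expect_lt(abs(chance$kappa), 0.05)
  expect_lt(abs(chance$mcc), 0.05)
  expect_error(evaluate(c(0, 1), c(0, 1, 1)), class = "cogscreen_validation_error")
})

test_that("stratified cross-validation is deterministic and supports leave-one-out", {
  toy <- toy_clusters(n_per = 12, gap = 5, seed = 11)
  spec <- base_learner_spec("lda")
  m1 <- kfold_cv(spec, toy$X, toy$y, k = 4, seed = 9)
  m2 <- kfold_cv(spec, toy$X, toy$y, k = 4, seed = 9)
  expect_identical(attr(m1, "predictions")$fold, attr(m2, "predictions")$fold)
  expect_identical(attr(m1, "predictions")$y_pred, attr(m2, "predictions")$y_pred)
  expect_gt(m1$accuracy, 0.9)
  loo <- kfold_cv(spec, toy$X, toy$y, k = 24, seed = 9)
  expect_identical(sort(unique(attr(loo, "predictions")$fold)), 1:24)
  expect_error(kfold_cv(spec, toy$X, toy$y, k = 25), class = "cogscreen_domain_error")
})

test_that("leave-subjects-out keeps subjects disjoint and reports EC / mean PrC", {
  tab <- tibble::tibble(subject_id = rep(sprintf("s%02d", 1:10), each = 3),
                        label = rep(c(0L, 1L), each = 15))
  sp <- leave_subjects_out_split(tab, c("s01", "s06"))
  expect_length(intersect(sp$train$subject_id,
                          c(sp$test_healthy$subject_id, sp$test_impaired$subject_id)), 0)
  expect_true(all(sp$test_healthy$label == 0))
  expect_true(all(sp$test_impaired$label == 1))
  expect_error(leave_subjects_out_split(tab, "nope"),
               class = "cogscreen_validation_error")
  expect_error(leave_subjects_out_split(tab, sprintf("s%02d", 1:5)),
               class = "cogscreen_validation_error")
})

test_that("feature selection recovers trivial and planted structure", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40)
  y <- as.integer(X[, 4] > 0)
  X[, 4] <- y + rnorm(40, 0, 0.05)   # feature 4 is (almost) the label
  expect_identical(select_features(X, y, "correlation_rank", k = 1), 4L)
  expect_error(select_features(X, y, "correlation_rank", k = 10),
               class = "cogscreen_domain_error")

  tr <- select_features(X, y, "pca_vc", vc = 1.0)
  expect_identical(tr$ncomp, 6L)   # all non-degenerate components retained
  expect_identical(ncol(tr$transform(X)), tr$ncomp)
  half <- select_features(X, y, "pca_vc", vc = 0.5)
  expect_lt(half$ncomp, 6L)

  sel <- select_features(X, y, "wrapper_subset", spec = base_learner_spec("lda"),
                         max_features = 3, seed = 2)
  expect_true(4L %in% sel)

  bg <- select_features(X, y, "bgwopso", spec = base_learner_spec("lda"),
                        n_agents = 8, n_iter = 8, seed = 2)
  expect_true(4L %in% bg)
})

test_that("the hybrid13 preset has exactly the published member structure", {
  cfg <- hybrid13_config()
  members <- tidy(cfg)
  expect_identical(nrow(members), 13L)
  expect_identical(members$learner,
                   c("decision_stump", "random_forest", "mlp", "smo", "knn",
                     "lwl", "bayes_net", "svm_sigmoid", "svm_linear", "svm_linear",
                     "flda", "lstm_seq", "voted_perceptron"))
  expect_identical(sum(!is.na(members$boost_rounds)), 7L)
  expect_identical(sum(!is.na(members$pca_vc)), 4L)
  expect_identical(cfg$fusion, "average_of_probabilities")
})

test_that("tidiers and plots produce well-formed objects", {
  m <- metrics_from_confusion(8, 1, 7, 2)
  td <- tidy(m)
  expect_identical(names(td), c("metric", "value"))
  expect_true("kappa" %in% td$metric)
  gl <- glance(m)
  expect_false(inherits(gl, "cogscreen_metrics"))
  expect_s3_class(autoplot(m), "ggplot")
  sp <- generate_spiral(c(0, 0), 50, 2, n_points = 64)
  expect_s3_class(plot_trajectory_match(sp, sp), "ggplot")
})
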