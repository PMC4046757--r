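# SVM training, cross-validation schemes and evaluation metrics.

test_that("separable blobs are fit perfectly and deterministically", {
  blobs <- separable_blobs(10, seed = 1)
  model <- train_svm(blobs)
  p1 <- predict(model, blobs)
  expect_equal(p1, blobs$class)
  model2 <- train_svm(blobs)
  expect_equal(predict(model2, blobs), p1)
})

test_that("single-class training is rejected", {
  blobs <- separable_blobs(5)
  expect_error(train_svm(blobs[blobs$class == "all-alpha", ]),
               "at least two classes")
})

test_that("well-separated synthetic classes are learned almost perfectly", {
  ds <- generate_dataset(n_per_class = 6, length_range = c(40, 80),
                         noise = 0.05, seed = 3)
  feats <- extract_dataset(ds)
  model <- train_svm(feats)
  acc <- mean(predict(model, feats) == feats$class)
  expect_gt(acc, 0.95)
})

test_that("metrics of a perfect predictor are all at their maxima", {
  conf <- diag(c(5L, 6L, 7L, 8L))
  dimnames(conf) <- list(structural_classes(), structural_classes())
  rep <- compute_metrics(conf)
  expect_equal(rep$overall_accuracy, 100)
  expect_equal(rep$per_class$sensitivity, rep(1, 4))
  expect_equal(rep$per_class$specificity, rep(1, 4))
  expect_equal(rep$per_class$mcc, rep(1, 4))
})

test_that("uninformative confusion gives zero MCC for the active classes", {
  conf <- matrix(0L, 4, 4, dimnames = list(structural_classes(),
                                           structural_classes()))
  conf[1:2, 1:2] <- 5L
  rep <- compute_metrics(conf)
  expect_equal(rep$per_class$mcc[1:2], c(0, 0))
  expect_equal(rep$overall_accuracy, 50)
  expect_error(compute_metrics(matrix(0L, 4, 4)), "all zero")
})

test_that("metrics match the per-sample recount oracle on random matrices", {
  withr::with_seed(67, {
    for (i in 1:40) {
      conf <- matrix(rpois(16, 3), 4, 4,
                     dimnames = list(structural_classes(),
                                     structural_classes()))
      if (sum(conf) == 0) conf[1, 1] <- 1
      rep <- compute_metrics(conf)
      want <- oracle_metrics(conf)
      expect_equal(rep$overall_accuracy, want$overall)
      for (k in 1:4) {
        w <- want$per_class[[structural_classes()[k]]]
        expect_equal(rep$per_class$sensitivity[k], w$sensitivity)
        expect_equal(rep$per_class$specificity[k], w$specificity)
        expect_equal(rep$per_class$mcc[k], w$mcc)
      }
    }
  })
})

test_that("overall accuracy is invariant under class relabeling", {
  withr::with_seed(71, {
    conf <- matrix(rpois(16, 4), 4, 4,
                   dimnames = list(structural_classes(),
                                   structural_classes()))
    perm <- sample(4)
    q1 <- compute_metrics(conf)$overall_accuracy
    q2 <- compute_metrics(conf[perm, perm])$overall_accuracy
    expect_equal(q1, q2)
  })
})

test_that("jackknife classifies separable samples perfectly", {
  blobs <- separable_blobs(4, seed = 5)
  rep <- cross_validate(blobs, scheme = "jackknife")
  expect_equal(rep$overall_accuracy, 100)
  expect_equal(rep$n, 8L)
})

test_that("out-of-fold predictions cover every sample exactly once", {
  ds <- generate_dataset(n_per_class = 5, length_range = c(30, 60),
                         noise = 0.5, seed = 8)
  feats <- extract_dataset(ds)
  for (scheme in c("jackknife", "kfold")) {
    rep <- cross_validate(feats, scheme = scheme, k = 5, seed = 2)
    expect_equal(sort(rep$predictions$protein_id), sort(feats$protein_id))
    expect_equal(sum(rep$confusion), nrow(feats))
  }
})

test_that("seeded k-fold runs are reproducible", {
  ds <- generate_dataset(n_per_class = 5, length_range = c(30, 60),
                         noise = 0.5, seed = 9)
  feats <- extract_dataset(ds)
  r1 <- cross_validate(feats, scheme = "kfold", k = 5, seed = 4)
  r2 <- cross_validate(feats, scheme = "kfold", k = 5, seed = 4)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(glance(r1), glance(r2))
})

test_that("classes smaller than k fall back to round-robin with a warning", {
  blobs <- separable_blobs(3, seed = 6)  # 3 per class, k = 5
  w <- capture_warnings(
    rep <- cross_validate(blobs, scheme = "kfold", k = 5, seed = 1))
  expect_length(w, 2L)  # one warning per undersized class
  expect_match(w, "fewer than k", all = TRUE)
  expect_equal(sum(rep$confusion), 6)
})

test_that("grid search returns the single pair, and breaks ties downward", {
  blobs <- separable_blobs(10, seed = 7)
  single <- grid_search(blobs, cost_grid = 500, gamma_grid = 0.055,
                        k = 5, seed = 1)
  expect_equal(single$cost, 500)
  expect_equal(single$gamma, 0.055)

  gs <- grid_search(blobs, cost_grid = c(8, 2), gamma_grid = c(1, 0.25),
                    k = 5, seed = 1)
  expect_equal(gs$cv_accuracy, 100)
  # all four pairs separate the blobs; the smallest cost then gamma wins
  expect_equal(gs$cost, 2)
  expect_equal(gs$gamma, 0.25)
  expect_error(grid_search(blobs, cost_grid = numeric(0)), "non-empty")
})

test_that("report accessors expose tidy, glance and a confusion heatmap", {
  blobs <- separable_blobs(4, seed = 8)
  rep <- cross_validate(blobs, scheme = "jackknife")
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(names(td), c("class", "sensitivity", "specificity", "mcc"))
  gl <- glance(rep)
  expect_equal(gl$overall_accuracy, 100)
  expect_equal(gl$scheme, "jackknife")
  expect_s3_class(autoplot(rep), "ggplot")
})
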