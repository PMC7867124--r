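gauss_table <- function(n_per = c(healthy = 8, tremor = 8, bradykinesia = 8),
                        sep = 10, seed = 1, p = 4) {
  withr::with_seed(seed, {
    centers <- list(healthy = rep(0, p), tremor = rep(sep, p),
                    bradykinesia = rep(c(sep, -sep), length.out = p))
    rows <- purrr::imap(centers, function(mu, cls) {
      m <- matrix(rnorm(n_per[[cls]] * p), ncol = p) +
        matrix(mu, n_per[[cls]], p, byrow = TRUE)
      colnames(m) <- paste0("f", seq_len(p))
      tibble::tibble(subject_id = paste0(cls, seq_len(n_per[[cls]])),
                     class_label = cls, !!!as.data.frame(m))
    })
    dplyr::bind_rows(rows)
  })
}

test_that("stratified hold-out draws round(n * fraction) per class", {
  tbl <- gauss_table(c(healthy = 20, tremor = 10, bradykinesia = 10))
  sp <- stratified_holdout_split(tbl, 0.30, seed = 1)
  expect_equal(nrow(sp$test), 12)
  expect_equal(as.numeric(table(sp$test$class_label)), c(3, 6, 3))
  expect_equal(nrow(sp$train), 28)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  tbl$subject_id)

  sp2 <- stratified_holdout_split(gauss_table(c(healthy = 4, tremor = 4,
                                                bradykinesia = 4)), 0.5,
                                  seed = 2)
  expect_equal(as.numeric(table(sp2$test$class_label)), c(2, 2, 2))

  a <- stratified_holdout_split(tbl, 0.3, seed = 9)
  b <- stratified_holdout_split(tbl, 0.3, seed = 9)
  expect_identical(a$test$subject_id, b$test$subject_id)

  tiny <- gauss_table(c(healthy = 1, tremor = 4, bradykinesia = 4))
  expect_error(stratified_holdout_split(tiny, 0.3),
               class = "pdmotor_invalid_argument")
})

test_that("KNN recovers exact matches and separates distant clusters", {
  tbl <- gauss_table(seed = 3)
  res1 <- knn_fit_predict(tbl, tbl[5, ], k = 1)
  expect_equal(res1$predicted, tbl$class_label[5])

  sp <- stratified_holdout_split(tbl, 0.25, seed = 4)
  res <- knn_fit_predict(sp$train, sp$test, k = 10)
  expect_equal(mean(res$true == res$predicted), 1)
  expect_true(all(rowSums(as.matrix(res[grep("^score_", names(res))])) == 1))

  expect_error(knn_fit_predict(sp$train, sp$test, k = 100),
               class = "pdmotor_invalid_argument")
})

test_that("KNN matches the exhaustive-distance oracle on a 2-D fixture", {
  # hand-placed 12-point training fixture
  train <- tibble::tibble(
    subject_id = sprintf("t%02d", 1:12),
    class_label = rep(c("healthy", "tremor", "bradykinesia"), each = 4),
    f1 = c(0.0, 0.2, -0.1, 0.1, 3.0, 3.2, 2.9, 3.1, 0.0, 0.2, -0.2, 0.1),
    f2 = c(0.0, -0.1, 0.2, 0.1, 0.0, 0.2, -0.2, 0.1, 3.0, 2.8, 3.1, 3.2))
  queries <- tibble::tibble(
    subject_id = c("q1", "q2", "q3"),
    class_label = c("healthy", "tremor", "bradykinesia"),  # placeholder truths
    f1 = c(0.4, 2.5, 1.4), f2 = c(0.3, 0.4, 2.2))
  # standardize exactly as the implementation specifies, then brute force
  mu <- colMeans(train[c("f1", "f2")])
  sg <- sapply(train[c("f1", "f2")], sd)
  std <- function(df) sweep(sweep(as.matrix(df[c("f1", "f2")]), 2, mu), 2,
                            sg, "/")
  res <- knn_fit_predict(train, queries, k = 3)
  for (i in 1:3)
    expect_equal(res$predicted[i],
                 knn_oracle(std(train), train$class_label, std(queries)[i, ],
                            k = 3))
})

test_that("KNN agrees with an independent library implementation", {
  skip_if_not_installed("class")
  tbl <- gauss_table(sep = 3, seed = 5, p = 3)
  sp <- stratified_holdout_split(tbl, 0.25, seed = 6)
  res <- knn_fit_predict(sp$train, sp$test, k = 5)
  z <- pdmotor:::standardizer(sp$train[c("f1", "f2", "f3")])
  ref <- class::knn(pdmotor:::apply_standardizer(z, sp$train),
                    pdmotor:::apply_standardizer(z, sp$test),
                    cl = sp$train$class_label, k = 5)
  agree <- res$predicted == as.character(ref)
  # vote ties may break differently; require agreement wherever votes are clear
  clear <- apply(as.matrix(res[grep("^score_", names(res))]), 1,
                 function(s) sum(s == max(s)) == 1)
  expect_true(all(agree[clear]))
})

test_that("the batch SOM quantizes separated clusters with full purity", {
  tbl <- gauss_table(seed = 7)
  model <- som_fit(tbl, seed = 1)
  pred <- som_predict(model, tbl)
  expect_equal(mean(pred$true == pred$predicted), 1)
  expect_setequal(model$neuron_class,
                  c("healthy", "tremor", "bradykinesia"))
  expect_setequal(model$sample_hits, c(8, 8, 8))
})

test_that("SOM training is seed-deterministic with non-increasing late-phase MSE", {
  tbl <- gauss_table(seed = 8, sep = 4)
  m1 <- som_fit(tbl, seed = 5)
  m2 <- som_fit(tbl, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$mse, m2$mse)
  # once the neighborhood radius reaches zero the updates are Lloyd steps
  late <- m1$mse_history[(m1$epochs / 2 + 1):m1$epochs]
  expect_true(all(diff(late) <= 1e-12))
})

test_that("degenerate SOM inputs follow their contracts", {
  same <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                         class_label = rep(c("healthy", "tremor"), 3),
                         f1 = rep(2, 6), f2 = rep(-1, 6))
  # identical samples collapse onto one neuron: expect both the
  # no-standardization warning and the empty-neuron labeling warning
  expect_warning(
    expect_warning(m <- som_fit(same, seed = 1),
                   class = "pdmotor_degenerate_features"),
    class = "pdmotor_empty_neuron")
  expect_equal(m$mse, 0)
  expect_true(all(abs(sweep(m$weights, 2, c(2, -1))) < 1e-12))
  expect_error(som_fit(gauss_table()[1:2, ], n_neurons = 3),
               class = "pdmotor_invalid_argument")
})

test_that("evaluation metrics satisfy their defining identities", {
  tr <- c("healthy", "tremor", "bradykinesia", "healthy", "tremor",
          "bradykinesia")
  all_right <- evaluate(tr, tr)
  expect_equal(all_right$accuracy, 1)
  expect_true(all(all_right$metrics$sensitivity == 1))
  expect_true(all(all_right$metrics$specificity == 1))

  withr::local_seed(25)
  true <- sample(rep(c("healthy", "tremor", "bradykinesia"), each = 10))
  pred <- sample(true)
  ev <- evaluate(true, pred)
  expect_equal(ev$metrics$ppv + ev$metrics$fdr, rep(1, 3))
  expect_equal(ev$metrics$tpr + ev$metrics$fnr, rep(1, 3))
  expect_equal(ev$metrics$sensitivity, ev$metrics$tpr)
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion), ev$accuracy)
  expect_equal(as.numeric(rowSums(ev$confusion)),
               as.numeric(table(factor(true, levels = ev$classes))))

  expect_error(evaluate(true, replace(pred, 1, "unknown")),
               class = "pdmotor_invalid_argument")
  expect_error(evaluate(true, pred[-1]),
               class = "pdmotor_invalid_argument")
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  tbl <- gauss_table(sep = 2, seed = 26)
  sp <- stratified_holdout_split(tbl, 0.4, seed = 27)
  res <- knn_fit_predict(sp$train, sp$test, k = 5)
  ev <- evaluate(res$true, res$predicted,
                 scores = res[grep("^score_", names(res))])
  for (cls in unique(res$true)) {
    pts <- ev$roc[ev$roc$class == cls, ]
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
  }
})
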