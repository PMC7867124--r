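#' Stratified hold-out split
#'
#' Splits a feature table into train and test sets, drawing
#' `round(class size x holdout_fraction)` test subjects per class
#' (stratified), disjointly and exhaustively, reproducibly under the seed.
#' The default 30% hold-out on the 20/10/10 study gives a 12-subject test
#' set (6/3/3).
#'
#' @param table A feature table.
#' @param holdout_fraction Test fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with `train` and `test` feature tables.
#' @export
stratified_holdout_split <- function(table, holdout_fraction = 0.30,
                                     seed = 1) {
  check_feature_table(table)
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    abort_invalid("`holdout_fraction` must be in (0, 1).")
  sizes <- table(table$class_label)
  if (any(sizes < 2))
    abort_invalid("every class needs >= 2 samples to split.")
  test_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(names(sizes), function(cls) {
      idx <- which(table$class_label == cls)
      n_test <- round(length(idx) * holdout_fraction)
      sample(idx, n_test)
    }))
  })
  list(train = table[-sort(test_idx), ], test = table[sort(test_idx), ])
}

# Per-feature z-scoring parameters learned on the training split only.
standardizer <- function(train_x) {
  mu <- vapply(train_x, mean, numeric(1))
  sg <- vapply(train_x, sd, numeric(1))
  keep <- sg > 0
  if (!all(keep))
    warn(sprintf("dropping zero-variance feature(s): %s",
                 paste(names(train_x)[!keep], collapse = ", ")))
  list(mu = mu[keep], sg = sg[keep], features = names(train_x)[keep])
}

apply_standardizer <- function(z, x) {
  m <- as.matrix(x[z$features])
  sweep(sweep(m, 2, z$mu), 2, z$sg, "/")
}

#' K-nearest-neighbour classification
#'
#' Fits nothing and predicts everything: each test subject is assigned the
#' majority class among its `k` nearest training subjects in Euclidean
#' distance on z-scored features (standardization learned on the training
#' split only — no leakage). Vote ties are broken by the class of the
#' single nearest neighbour. Per-class neighbour vote fractions are
#' returned as scores for ROC analysis.
#'
#' @param train,test Feature tables (e.g. from
#'   [stratified_holdout_split()]).
#' @param k Number of neighbours (default 10).
#' @return A `pd_knn_result`: tibble with `subject_id`, `true`,
#'   `predicted` and one `score_<class>` vote-fraction column per class.
#' @export
knn_fit_predict <- function(train, test, k = 10) {
  check_feature_table(train)
  check_feature_table(test)
  if (k < 1 || k > nrow(train))
    abort_invalid(sprintf("`k` must be in 1..%d (training size).", nrow(train)))
  z <- standardizer(train[feature_names(train)])
  if (length(z$features) == 0) abort_invalid("no usable features remain.")
  tr <- apply_standardizer(z, train)
  te <- apply_standardizer(z, test)
  classes <- sort(unique(train$class_label))
  pred <- character(nrow(te))
  scores <- matrix(0, nrow(te), length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(nrow(te))) {
    d2 <- colSums((t(tr) - te[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(factor(train$class_label[nn], levels = classes))
    scores[i, ] <- as.numeric(votes) / k
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else {
      # tie: the single nearest neighbour among the tied classes decides
      first <- nn[train$class_label[nn] %in% top][1]
      train$class_label[first]
    }
  }
  out <- tibble::tibble(subject_id = test$subject_id,
                        true = test$class_label, predicted = pred)
  for (cls in classes) out[[paste0("score_", cls)]] <- scores[, cls]
  class(out) <- c("pd_knn_result", class(out))
  attr(out, "k") <- k
  out
}

#' @export
#' @method glance pd_knn_result
glance.pd_knn_result <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"), n_test = nrow(x),
                 accuracy = mean(x$true == x$predicted))
}
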