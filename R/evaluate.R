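#' Evaluate predicted against true class labels
#'
#' Builds the full evaluation report: the confusion matrix (rows = true
#' class, columns = predicted), overall accuracy, per predicted class PPV
#' and FDR (`PPV + FDR = 1`), per true class TPR and FNR (`TPR + FNR = 1`),
#' one-vs-rest sensitivity (= TPR) and specificity (`TN / (TN + FP)`), and,
#' when per-class scores are supplied, one-vs-rest ROC points obtained by
#' sweeping the score threshold over its distinct values (for KNN vote
#' fractions these are `0, 1/k, ..., 1`).
#'
#' @param true,predicted Equal-length character vectors of class labels;
#'   every predicted label must occur in the true label set.
#' @param scores Optional data frame / tibble with one `score_<class>`
#'   column per class (e.g. from [knn_fit_predict()]).
#' @return A `pd_eval_report` with elements `confusion` (matrix),
#'   `accuracy`, `metrics` (per-class tibble), `roc` (tibble, possibly
#'   empty).
#' @examples
#' evaluate(c("healthy", "tremor", "tremor"),
#'          c("healthy", "tremor", "healthy"))
#' @export
evaluate <- function(true, predicted, scores = NULL) {
  if (length(true) != length(predicted))
    abort_invalid("`true` and `predicted` must have equal length.")
  classes <- sort(unique(true))
  bad <- setdiff(unique(predicted), classes)
  if (length(bad) > 0)
    abort_invalid(sprintf("predicted label '%s' never occurs among the true labels.",
                          bad[1]))
  tf <- factor(true, levels = classes)
  pf <- factor(predicted, levels = classes)
  M <- table(true = tf, predicted = pf)
  M <- matrix(as.integer(M), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  total <- sum(M)
  metrics <- purrr::map_dfr(classes, function(cls) {
    tp <- M[cls, cls]
    fn <- sum(M[cls, ]) - tp
    fp <- sum(M[, cls]) - tp
    tn <- total - tp - fn - fp
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    tpr <- tp / (tp + fn)
    tibble::tibble(class = cls, n_true = tp + fn,
                   ppv = ppv, fdr = 1 - ppv,
                   tpr = tpr, fnr = 1 - tpr,
                   sensitivity = tpr,
                   specificity = tn / (tn + fp),
                   fpr = fp / (fp + tn))
  })
  roc <- if (!is.null(scores)) roc_points(true, scores, classes)
         else tibble::tibble(class = character(), threshold = numeric(),
                             fpr = numeric(), tpr = numeric())
  structure(list(confusion = M, accuracy = sum(diag(M)) / total,
                 metrics = metrics, roc = roc, classes = classes),
            class = "pd_eval_report")
}

# one-vs-rest ROC by sweeping the distinct score values as thresholds
roc_points <- function(true, scores, classes) {
  purrr::map_dfr(classes, function(cls) {
    s <- scores[[paste0("score_", cls)]]
    if (is.null(s)) return(NULL)
    pos <- true == cls
    ths <- c(sort(unique(s), decreasing = TRUE), -Inf)
    pts <- purrr::map_dfr(ths, function(th) {
      call_pos <- s >= th
      tibble::tibble(threshold = th,
                     fpr = sum(call_pos & !pos) / max(1, sum(!pos)),
                     tpr = sum(call_pos & pos) / max(1, sum(pos)))
    })
    dplyr::bind_rows(
      tibble::tibble(class = cls, threshold = Inf, fpr = 0, tpr = 0),
      tibble::tibble(class = cls, threshold = pts$threshold,
                     fpr = pts$fpr, tpr = pts$tpr))
  })
}

#' @export
print.pd_eval_report <- function(x, ...) {
  cat(sprintf("<pd_eval_report> accuracy %.1f%% (%d/%d)\n",
              100 * x$accuracy, sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  print(as.data.frame(x$metrics), digits = 3)
  invisible(x)
}

#' @export
#' @method tidy pd_eval_report
tidy.pd_eval_report <- function(x, ...) x$metrics

#' @export
#' @method glance pd_eval_report
glance.pd_eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$confusion),
                 n_classes = length(x$classes))
}
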