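#' Rank features by one-way ANOVA
#'
#' For every feature column, the classic one-way ANOVA F statistic across
#' the class labels (between-group mean square over within-group mean
#' square, `k - 1` and `N - k` degrees of freedom, via
#' [stats::oneway.test()] with equal variances) with its p-value, a
#' normalized importance score `F / max(F)`, and the rank (1 = largest F).
#' ANOVA is used purely as a ranking filter here, so no multiple-testing
#' correction is applied. Degenerate features follow a sentinel contract:
#' a feature identical everywhere gets `F = 0`; zero within-group variance
#' with unequal group means gets `F = Inf`, `p = 0` and a warning. Ties in
#' F are broken by feature name for reproducibility.
#'
#' @param table A feature table (`subject_id`, `class_label`, features).
#' @return A `pd_anova_ranking` tibble with columns `feature`, `F`,
#'   `p_value`, `normalized_score`, `rank`, sorted by rank.
#' @export
anova_rank <- function(table) {
  check_feature_table(table)
  g <- factor(table$class_label)
  if (nlevels(g) < 2) abort_invalid("need at least 2 classes.")
  if (any(tabulate(g) < 2)) abort_invalid("every class needs >= 2 samples.")
  feats <- feature_names(table)
  res <- purrr::map(feats, function(nm) {
    x <- table[[nm]]
    within_var <- tapply(x, g, var)
    if (all(within_var == 0)) {
      if (var(x) == 0) return(list(F = 0, p_value = 1))       # flat feature
      warn(sprintf("feature '%s': zero within-group variance with unequal means; F reported as Inf.", nm),
           class = "pdmotor_degenerate_feature")
      return(list(F = Inf, p_value = 0))
    }
    ow <- oneway.test(x ~ g, var.equal = TRUE)
    list(F = unname(ow$statistic), p_value = unname(ow$p.value))
  })
  out <- tibble::tibble(feature = feats,
                        F = purrr::map_dbl(res, "F"),
                        p_value = purrr::map_dbl(res, "p_value"))
  fmax <- max(out$F[is.finite(out$F)], 0)
  out$normalized_score <- ifelse(is.infinite(out$F), 1,
                                 if (fmax > 0) out$F / fmax else 0)
  ord <- order(-out$F, out$feature)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- dplyr::arrange(out, .data$rank)
  class(out) <- c("pd_anova_ranking", class(out))
  out
}

#' Keep the top-k ranked features
#'
#' Reduces a feature table to the `k` top-ranked features, columns ordered
#' by rank; rows and labels untouched. The default `k = 24` corresponds to
#' the four discriminative feature types (approximate entropy, correlation
#' dimension, spectral peak amplitude, band power) over six channels.
#'
#' @param ranking A [anova_rank()] result.
#' @param table The feature table the ranking was computed on.
#' @param k Number of features to keep, `1 <= k <= n_features`.
#' @return The reduced feature table.
#' @export
select_features <- function(ranking, table, k = 24) {
  check_feature_table(table)
  nf <- length(feature_names(table))
  if (k < 1 || k > nf)
    abort_invalid(sprintf("`k` must be in 1..%d.", nf))
  keep <- ranking$feature[ranking$rank <= k]
  table[c("subject_id", "class_label", keep)]
}

#' @export
#' @method tidy pd_anova_ranking
tidy.pd_anova_ranking <- function(x, ...) tibble::as_tibble(x)

#' @export
#' @method glance pd_anova_ranking
glance.pd_anova_ranking <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 max_F = max(x$F[is.finite(x$F)]),
                 n_significant_05 = sum(x$p_value < 0.05))
}
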