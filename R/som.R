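#' Fit a 1x3 batch self-organizing map
#'
#' Competitive clustering of the standardized feature vectors onto three
#' neurons arranged on a line (a 1x3 hexagonal map degenerates to a
#' chain with inter-neuron grid distances 0/1/2). Training uses the batch
#' algorithm: each epoch assigns every sample to its best-matching neuron,
#' then replaces each neuron's weight by the Gaussian
#' neighborhood-weighted mean of all samples; the neighborhood radius
#' decays linearly from `radius0` to 0 over the first half of the epochs,
#' after which updates are plain k-means (Lloyd) steps. Weights are
#' initialized by k-means++-style sampling of data points under the seed.
#' After training, each neuron is named by the majority true class of its
#' assigned samples — labels are used only for naming clusters, never for
#' fitting. Performance is summarized by the mean squared quantization
#' error (MSE), the mean squared distance of samples to their
#' best-matching neuron.
#'
#' @param table A feature table; features are z-scored internally over all
#'   rows (unsupervised, no hold-out).
#' @param n_neurons Number of neurons (default 3, one per class).
#' @param epochs Training epochs.
#' @param radius0 Initial neighborhood radius (grid units).
#' @param seed Integer seed for the weight initialization.
#' @return A `pd_som_model` with elements `weights` (neurons x features),
#'   `neuron_class` (majority labels), `assignments`, `sample_hits`,
#'   `mse`, `mse_history`, and the standardization parameters.
#' @export
som_fit <- function(table, n_neurons = 3, epochs = 200, radius0 = 1,
                    seed = 1) {
  check_feature_table(table)
  if (nrow(table) < n_neurons)
    abort_invalid("need at least as many samples as neurons.")
  feats <- table[feature_names(table)]
  if (all(vapply(feats, sd, numeric(1)) == 0)) {
    # degenerate data: nothing varies, so quantize the raw feature space
    warn("all features constant: skipping standardization.",
         class = "pdmotor_degenerate_features")
    z <- list(mu = rep(0, ncol(feats)), sg = rep(1, ncol(feats)),
              features = names(feats))
    names(z$mu) <- names(z$sg) <- names(feats)
  } else {
    z <- standardizer(feats)
  }
  x <- apply_standardizer(z, table)
  n <- nrow(x)
  grid_d <- abs(outer(seq_len(n_neurons), seq_len(n_neurons), "-"))
  w <- withr::with_seed(as.integer(seed), kmeanspp_init(x, n_neurons))
  mse_history <- numeric(epochs)
  bmu <- integer(n)
  for (e in seq_len(epochs)) {
    d2 <- pairwise_sq_dist(x, w)
    bmu <- max.col(-d2, ties.method = "first")
    mse_history[e] <- mean(d2[cbind(seq_len(n), bmu)])
    sigma <- radius0 * max(0, 1 - (e - 1) / max(1, floor(epochs / 2)))
    h <- if (sigma > 0) exp(-grid_d^2 / (2 * sigma^2)) else diag(n_neurons)
    H <- h[, bmu, drop = FALSE]              # neurons x samples
    denom <- rowSums(H)
    upd <- (H %*% x) / denom
    nonempty <- denom > 0
    w[nonempty, ] <- upd[nonempty, ]
  }
  d2 <- pairwise_sq_dist(x, w)
  bmu <- max.col(-d2, ties.method = "first")
  mse <- mean(d2[cbind(seq_len(n), bmu)])
  neuron_class <- label_neurons(bmu, table$class_label, w, n_neurons)
  model <- list(weights = w, neuron_class = neuron_class,
                assignments = bmu,
                sample_hits = tabulate(bmu, n_neurons),
                mse = mse, mse_history = mse_history,
                standardizer = z, epochs = epochs, radius0 = radius0,
                seed = as.integer(seed))
  class(model) <- "pd_som_model"
  model
}

# squared Euclidean distances samples x neurons (clamped: the expanded
# form can go epsilon-negative in floating point)
pairwise_sq_dist <- function(x, w) {
  xn <- rowSums(x^2)
  wn <- rowSums(w^2)
  pmax(outer(xn, wn, "+") - 2 * x %*% t(w), 0)
}

# k-means++-style seeding: first weight uniform, then data points drawn
# with probability proportional to squared distance from chosen weights.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(pairwise_sq_dist(x, x[idx, , drop = FALSE]), 1, min)
    if (sum(d2) == 0) idx <- c(idx, sample.int(n, 1))
    else idx <- c(idx, sample.int(n, 1, prob = d2))
  }
  x[idx, , drop = FALSE]
}

label_neurons <- function(bmu, labels, w, n_neurons) {
  cls <- rep(NA_character_, n_neurons)
  for (j in seq_len(n_neurons)) {
    lab <- labels[bmu == j]
    if (length(lab) > 0) {
      tab <- sort(table(lab), decreasing = TRUE)
      cls[j] <- names(tab)[1]
    }
  }
  if (anyNA(cls)) {
    warn("empty neuron at labeling time; inheriting the nearest labeled neuron's class.",
         class = "pdmotor_empty_neuron")
    for (j in which(is.na(cls))) {
      labeled <- which(!is.na(cls))
      d <- rowSums((w[labeled, , drop = FALSE] -
                      matrix(w[j, ], length(labeled), ncol(w), byrow = TRUE))^2)
      cls[j] <- cls[labeled[which.min(d)]]
    }
  }
  cls
}

#' Predict classes with a fitted SOM
#'
#' Assigns each row to its best-matching neuron (in the model's
#' standardized space) and returns that neuron's class label.
#'
#' @param model A [som_fit()] model.
#' @param table A feature table with the model's features.
#' @return A `pd_som_result` tibble: `subject_id`, `true`, `neuron`,
#'   `predicted`.
#' @export
som_predict <- function(model, table) {
  check_feature_table(table)
  x <- apply_standardizer(model$standardizer, table)
  d2 <- pairwise_sq_dist(x, model$weights)
  bmu <- max.col(-d2, ties.method = "first")
  out <- tibble::tibble(subject_id = table$subject_id,
                        true = table$class_label, neuron = bmu,
                        predicted = model$neuron_class[bmu])
  class(out) <- c("pd_som_result", class(out))
  out
}

#' @export
print.pd_som_model <- function(x, ...) {
  cat(sprintf("<pd_som_model> %d neurons (%s), MSE %.4f, %d epochs\n",
              nrow(x$weights), paste(x$neuron_class, collapse = "/"),
              x$mse, x$epochs))
  invisible(x)
}

#' @export
#' @method tidy pd_som_model
tidy.pd_som_model <- function(x, ...) {
  tibble::tibble(neuron = seq_len(nrow(x$weights)),
                 class = x$neuron_class,
                 sample_hits = x$sample_hits)
}

#' @export
#' @method glance pd_som_model
glance.pd_som_model <- function(x, ...) {
  tibble::tibble(n_neurons = nrow(x$weights), mse = x$mse,
                 epochs = x$epochs)
}
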