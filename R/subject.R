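#' Leave-one-pair-out cross-validated subject classification accuracy
#'
#' Subjects are classified as belonging to one of two equal-sized groups from
#' their feature vectors (e.g. a contrast map restricted to an ROI or the
#' whole brain).  In each repeat, subjects are randomly paired across groups;
#' for each pair the classifier is trained on all remaining subjects and
#' tested on the held-out pair, so every subject is held out exactly once per
#' repeat and both classes stay balanced in every training fold.  The
#' reported accuracy is the mean over repeats.
#'
#' @param features Numeric matrix, subjects x features.
#' @param groups Factor/character with two equal-sized classes.
#' @param spec A [classifier_spec()].
#' @param n_repeats Number of random pairings to average over (the full
#'   analysis uses 1000).
#' @param seed Integer seed for the pairings.
#' @return List with `accuracy` (mean over repeats), `per_repeat`
#'   (accuracy of each repeat) and `n_folds` (pairs per repeat).
#' @export
lpocv_accuracy <- function(features, groups, spec = classifier_spec(),
                           n_repeats = 1000, seed = 1L) {
  features <- as.matrix(features)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  idx1 <- which(groups == levels(groups)[1])
  idx2 <- which(groups == levels(groups)[2])
  if (length(idx1) != length(idx2)) {
    stop("groups must be equal-sized: leave-one-pair-out holds one subject ",
         "per group to avoid class imbalance in the training folds")
  }
  set.seed(as.integer(seed))
  n_pairs <- length(idx1)
  per_repeat <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    pairing <- cbind(sample(idx1), sample(idx2))
    correct <- 0L
    for (k in seq_len(n_pairs)) {
      hold <- pairing[k, ]
      keep <- setdiff(seq_along(groups), hold)
      model <- train_binary_classifier(features[keep, , drop = FALSE],
                                       groups[keep], spec)
      pred <- predict(model, features[hold, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == as.character(groups[hold]))
    }
    per_repeat[rep_i] <- correct / (2 * n_pairs)
  }
  list(accuracy = mean(per_repeat), per_repeat = per_repeat,
       n_folds = n_pairs)
}

#' Monte Carlo permutation test for subject classification
#'
#' Group labels are randomly permuted once per iteration and the identical
#' LPOCV procedure is applied; the p-value is the number of permutation
#' accuracies greater than or equal to the observed accuracy, divided by the
#' number of permutations.  That formula can return exactly 0; the
#' `corrected` flag switches to the (b+1)/(N+1) small-sample version.
#'
#' @inheritParams lpocv_accuracy
#' @param n_permutations Number of label permutations.
#' @param lpocv_repeats LPOCV repeats inside each permutation iteration (and
#'   for the observed accuracy); the full 1000 x 1000 analysis is rarely
#'   needed to estimate the null.
#' @param corrected Use the (b+1)/(N+1) small-sample p-value.
#' @return List with `observed`, `null` (permutation accuracies), `p`.
#' @export
permutation_test <- function(features, groups, spec = classifier_spec(),
                             n_permutations = 1000, lpocv_repeats = 20,
                             seed = 1L, corrected = FALSE) {
  groups <- factor(groups)
  obs <- lpocv_accuracy(features, groups, spec, n_repeats = lpocv_repeats,
                        seed = derive_seed(seed, "observed"))$accuracy
  null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(derive_seed(seed, paste0("perm_labels/", b)))
    perm <- sample(groups)
    null[b] <- lpocv_accuracy(features, perm, spec,
                              n_repeats = lpocv_repeats,
                              seed = derive_seed(seed, paste0("perm_cv/", b))
    )$accuracy
  }
  ge <- sum(null >= obs)
  p <- if (corrected) (ge + 1) / (n_permutations + 1) else ge / n_permutations
  list(observed = obs, null = null, p = p)
}
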