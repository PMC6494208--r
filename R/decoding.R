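#' Standardize a voxel pattern
#'
#' Subtracts the mean across voxels and divides by the standard deviation
#' across voxels (population SD, i.e. divisor `n`), per condition pattern.
#'
#' @param pattern Numeric vector of voxel values (length >= 2).
#' @param label Optional label (condition/run) used in the error message for
#'   constant patterns.
#' @return Standardized vector with mean 0 and population SD 1.
#' @examples
#' standardize_pattern(c(1, 2, 3))   # -1.2247, 0, 1.2247
#' @export
standardize_pattern <- function(pattern, label = NULL) {
  stopifnot(length(pattern) >= 2)
  m <- mean(pattern)
  s <- sqrt(mean((pattern - m)^2))
  if (s == 0) {
    stop(sprintf("constant pattern%s has zero SD and carries no decodable shape",
                 if (is.null(label)) "" else paste0(" (", label, ")")))
  }
  (pattern - m) / s
}

#' Classifier specification
#'
#' C-SVC support vector machine with regularization constant 1, fixed across
#' all regions, subjects and cross-validation repeats of one analysis.  The
#' default kernel is linear; a radial-basis kernel with width parameter
#' (gamma) 1 is available for sensitivity analysis.
#'
#' @param kernel `"linear"` or `"radial"`.
#' @param cost Regularization constant C.
#' @param gamma RBF width (used only for the radial kernel).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kernel = c("linear", "radial"), cost = 1,
                            gamma = 1) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, gamma > 0)
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "classifier_spec")
}

#' Cross-validation specification for repeated random subsampling
#'
#' Runs are randomly split into 70% training and 30% test; the test runs'
#' patterns are averaged to one response pattern per condition; the split is
#' repeated `n_repeats` times and accuracies averaged.
#'
#' @param train_fraction Fraction of runs used for training.
#' @param n_repeats Number of random splits.
#' @param seed Integer seed for the splits.
#' @return A `cv_spec`.
#' @export
cv_spec <- function(train_fraction = 0.7, n_repeats = 100, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  structure(list(train_fraction = train_fraction, n_repeats = n_repeats,
                 split_unit = "run", seed = as.integer(seed)),
            class = "cv_spec")
}

#' Train a binary classifier
#'
#' @param train Numeric matrix, samples x features.
#' @param labels Factor/character of two classes, one per sample.
#' @param spec A [classifier_spec()].
#' @return A fitted model usable with `predict()`.
#' @export
train_binary_classifier <- function(train, labels, spec = classifier_spec()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    stop("training set contains a single class; cannot fit a binary classifier")
  }
  e1071::svm(x = as.matrix(train), y = labels, type = "C-classification",
             kernel = spec$kernel, cost = spec$cost, gamma = spec$gamma,
             scale = FALSE)
}

# split n runs into train/test; train size = round(fraction * n), clamped so
# that at least one run lands on each side
split_runs <- function(n_runs, fraction) {
  n_train <- round(fraction * n_runs)
  n_train <- min(max(n_train, 1), n_runs - 1)
  train <- sample.int(n_runs, n_train)
  list(train = train, test = setdiff(seq_len(n_runs), train))
}

#' Pairwise decoding matrix for one subject and region
#'
#' Standardizes every run-by-condition pattern, then for each condition pair
#' and each of `cv$n_repeats` random 70/30 run splits trains the classifier
#' on the training runs' patterns and scores the two test patterns obtained
#' by averaging the test runs per condition.  Cells hold the mean accuracy
#' over repeats; the matrix is symmetric with an undefined diagonal.
#'
#' @param patterns Numeric array `run x condition x voxel` (condition
#'   dimnames required).
#' @param cv A [cv_spec()].
#' @param spec A [classifier_spec()].
#' @param pairs Optional 2-column matrix of condition-name pairs to compute
#'   (others stay `NA`); default all pairs.
#' @return Symmetric condition x condition accuracy matrix, `NA` diagonal.
#' @export
pairwise_decoding_matrix <- function(patterns, cv = cv_spec(),
                                     spec = classifier_spec(),
                                     pairs = NULL) {
  stopifnot(length(dim(patterns)) == 3)
  n_runs <- dim(patterns)[1]
  conds <- dimnames(patterns)[[2]]
  if (is.null(conds)) stop("patterns must carry condition dimnames")
  if (n_runs < 4) {
    stop(sprintf("need at least 4 runs for a 70/30 run split; got %d", n_runs))
  }
  # standardize each run x condition pattern once, up front
  std <- patterns
  for (r in seq_len(n_runs)) {
    for (ci in seq_along(conds)) {
      std[r, ci, ] <- standardize_pattern(patterns[r, ci, ],
                                          label = sprintf("run %d, %s", r, conds[ci]))
    }
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(conds, 2))
  }
  acc <- matrix(NA_real_, length(conds), length(conds),
                dimnames = list(conds, conds))
  set.seed(cv$seed)
  splits <- replicate(cv$n_repeats, split_runs(n_runs, cv$train_fraction),
                      simplify = FALSE)
  slice <- function(runs, ci) matrix(std[runs, ci, ], nrow = length(runs))
  for (k in seq_len(nrow(pairs))) {
    ci <- match(pairs[k, 1], conds); cj <- match(pairs[k, 2], conds)
    cell <- 0
    for (sp in splits) {
      xtr <- rbind(slice(sp$train, ci), slice(sp$train, cj))
      ytr <- factor(rep(c(conds[ci], conds[cj]), each = length(sp$train)))
      model <- train_binary_classifier(xtr, ytr, spec)
      xte <- rbind(colMeans(slice(sp$test, ci)), colMeans(slice(sp$test, cj)))
      pred <- predict(model, xte)
      cell <- cell + mean(pred == c(conds[ci], conds[cj]))
    }
    acc[ci, cj] <- acc[cj, ci] <- cell / length(splits)
  }
  acc
}

#' Mean within-format decoding accuracy
#'
#' Arithmetic mean of the pairwise cells among the numerosities of one
#' format (6 cells for 4 numerosities).
#'
#' @param matrix Condition x condition accuracy matrix.
#' @param format Format label.
#' @param conditions Condition table (`condition`, `format`, `numerosity`),
#'   e.g. `experiment_design()$conditions`.
#' @return Scalar mean accuracy.
#' @export
within_format_accuracy <- function(matrix, format, conditions) {
  cc <- conditions$condition[conditions$format == format]
  cc <- intersect(cc, rownames(matrix))
  if (length(cc) < 2) stop(sprintf("fewer than 2 conditions of format '%s'", format))
  prs <- t(utils::combn(cc, 2))
  mean(matrix[prs])
}

#' Group comparison of decoding accuracies
#'
#' Two-sided pooled-variance two-sample t-test between the per-subject
#' accuracies of the two groups, as fed into the gated hierarchical FDR.
#'
#' @param a,b Numeric vectors of per-subject accuracies.
#' @return List with `t`, `df`, `p`.
#' @export
group_compare_accuracy <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  res <- two_sample_t(a, b)
  if (is.na(res$p)) {
    warning("zero variance in both groups; p undefined")
  }
  res
}

#' One-sample test of decoding accuracy against chance
#'
#' @param x Per-subject accuracies.
#' @param chance Chance level (0.5 for pairwise decoding).
#' @return List with `t`, `df`, `p` (two-sided one-sample t-test).
#' @export
chance_test <- function(x, chance = 0.5) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  se <- sd(x) / sqrt(n)
  t <- (mean(x) - chance) / se
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

#' Within-format decoding accuracies for every subject of a cohort
#'
#' Convenience wrapper running [pairwise_decoding_matrix()] per subject on
#' one region and averaging within each format.
#'
#' @param dataset A `pattern_dataset` from [generate_condition_patterns()].
#' @param region Region name.
#' @param cv,spec Cross-validation and classifier specifications.
#' @param formats Formats to average within; default all in the dataset.
#' @return Data frame `subject, group, format, accuracy`.
#' @export
cohort_within_format_accuracy <- function(dataset, region,
                                          cv = cv_spec(),
                                          spec = classifier_spec(),
                                          formats = NULL) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  conds <- dataset$conditions
  if (is.null(formats)) formats <- unique(conds$format)
  pairs <- do.call(rbind, lapply(formats, function(f) {
    t(utils::combn(conds$condition[conds$format == f], 2))
  }))
  rows <- list()
  for (si in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[si]]
    cv_s <- cv_spec(cv$train_fraction, cv$n_repeats,
                    seed = derive_seed(cv$seed, paste0("cv/", sub$id)))
    m <- pairwise_decoding_matrix(sub$patterns[[region]], cv_s, spec,
                                  pairs = pairs)
    for (f in formats) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub$id, group = sub$group, format = f,
        accuracy = within_format_accuracy(m, f, conds),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
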