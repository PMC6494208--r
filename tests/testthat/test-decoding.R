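test_that("pattern standardization uses the population SD and rejects constants", {
  expect_equal(standardize_pattern(c(1, 2, 3)),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  z <- c(-1, 0, 1) / sqrt(2 / 3)
  expect_equal(standardize_pattern(z), z)
  x <- standardize_pattern(rnorm(50))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-12)
  expect_error(standardize_pattern(rep(2, 5), label = "run 3, sym_2"),
               "constant pattern \\(run 3, sym_2\\)")
})

test_that("the SVM surface behaves as a maximum-margin linear classifier on toys", {
  # 2-point separable toy
  x <- rbind(c(-1, 0), c(1, 0))
  m <- train_binary_classifier(x, c("a", "b"), classifier_spec())
  expect_equal(as.character(predict(m, x)), c("a", "b"))
  expect_error(train_binary_classifier(x, c("a", "a")), "single class")

  # label-flip symmetry
  set.seed(10)
  xt <- matrix(rnorm(12), 6, 2)
  y <- rep(c("a", "b"), 3)
  yf <- ifelse(y == "a", "b", "a")
  te <- matrix(rnorm(10), 5, 2)
  p1 <- as.character(predict(train_binary_classifier(xt, y), te))
  p2 <- as.character(predict(train_binary_classifier(xt, yf), te))
  expect_true(all(p1 != p2))

  # brute-force search over weight directions: on random separable 6-point
  # 2-D toys the SVM must reach the best (zero) training error the grid finds
  for (i in 1:5) {
    set.seed(100 + i)
    xt <- rbind(matrix(rnorm(6, -2), 3, 2), matrix(rnorm(6, 2), 3, 2))
    y <- rep(c("a", "b"), each = 3)
    ang <- seq(0, pi, length.out = 181)
    best_err <- min(sapply(ang, function(a) {
      w <- c(cos(a), sin(a))
      proj <- xt %*% w
      min(sapply(proj, function(b0) {
        pred <- ifelse(proj > b0, "b", "a")
        min(mean(pred != y), mean(pred == y))
      }))
    }))
    svm_err <- mean(as.character(predict(train_binary_classifier(xt, y),
                                         xt)) != y)
    expect_lte(svm_err, best_err + 1e-9)
  }
})

test_that("noiseless separable patterns decode perfectly and fill 28 informative cells", {
  spec <- tiny_cohort(seed = 5, n_per_group = 1, voxels = 16)
  spec$noise_sd <- 1e-4
  spec$separation$separation <- 10
  pd <- generate_condition_patterns(spec)
  m <- pairwise_decoding_matrix(pd$subjects[[1]]$patterns$all_regions,
                                cv_spec(n_repeats = 5, seed = 2))
  expect_equal(sum(!is.na(m)) / 2, choose(8, 2))
  expect_true(all(is.na(diag(m))))
  expect_equal(m, t(m))
  expect_true(all(m[!is.na(m)] == 1))
})

test_that("zero-separation patterns decode at chance", {
  spec <- tiny_cohort(seed = 6, n_per_group = 1, n_runs = 8,
                      separation = sep_table(0, 0, 0, 0))
  pd <- generate_condition_patterns(spec)
  m <- pairwise_decoding_matrix(pd$subjects[[1]]$patterns$all_regions,
                                cv_spec(n_repeats = 30, seed = 3))
  grand <- mean(m[upper.tri(m)])
  # 28 cells x 30 repeats of 2 test patterns; binomial-ish CI around 0.5
  expect_lt(abs(grand - 0.5), 0.1)
})

test_that("too few runs or missing dimnames are rejected", {
  arr <- array(rnorm(3 * 2 * 5), c(3, 2, 5),
               dimnames = list(NULL, c("a", "b"), NULL))
  expect_error(pairwise_decoding_matrix(arr), "at least 4 runs")
  arr2 <- array(rnorm(4 * 2 * 5), c(4, 2, 5))
  expect_error(pairwise_decoding_matrix(arr2), "condition dimnames")
})

test_that("within-format accuracy equals the mean over enumerated same-format pairs", {
  conds <- experiment_design()$conditions
  m <- matrix(0.5, 8, 8, dimnames = list(conds$condition, conds$condition))
  diag(m) <- NA
  expect_equal(within_format_accuracy(m, "symbolic", conds), 0.5)

  sym <- conds$condition[conds$format == "symbolic"]
  prs <- t(combn(sym, 2))
  vals <- c(1, 1, 1, 0, 0, 0)
  for (k in 1:6) m[prs[k, 1], prs[k, 2]] <- m[prs[k, 2], prs[k, 1]] <- vals[k]
  expect_equal(within_format_accuracy(m, "symbolic", conds), 0.5)

  set.seed(9)
  m[upper.tri(m)] <- runif(28)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  oracle <- mean(sapply(1:6, function(k) m[prs[k, 1], prs[k, 2]]))
  expect_equal(within_format_accuracy(m, "symbolic", conds), oracle)
})

test_that("group accuracy comparison reproduces closed-form summary t and a permutation oracle", {
  expect_equal(group_compare_accuracy(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(group_compare_accuracy(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # raw samples constructed to have the printed French Kit summaries
  mk <- function(mean, sd, n) {
    x <- rnorm(n)
    mean + sd * (x - mean(x)) / sd(x)
  }
  set.seed(12)
  a <- mk(35.00, 7.97, 24); b <- mk(54.50, 15.86, 24)
  res <- group_compare_accuracy(a, b)
  expect_equal(abs(res$t), 5.38, tolerance = 0.005)
  expect_equal(res$df, 46)

  # two-sided p close to a permutation p on modest samples
  set.seed(13)
  x <- rnorm(10); y <- rnorm(10) + 1.2
  res2 <- group_compare_accuracy(x, y)
  pool <- c(x, y)
  perm <- replicate(4000, {
    idx <- sample(20, 10)
    abs(t_oracle(pool[idx], pool[-idx]))
  })
  p_perm <- mean(perm >= abs(res2$t))
  expect_lt(abs(res2$p - p_perm), 0.03)
})

test_that("within-format accuracy increases with the separation parameter", {
  seps <- c(0, 1, 2.5)
  accs <- sapply(seq_along(seps), function(i) {
    spec <- tiny_cohort(seed = 30 + i, n_per_group = 1, voxels = 16,
                        separation = sep_table(seps[i], seps[i],
                                               seps[i], seps[i]))
    pd <- generate_condition_patterns(spec)
    m <- pairwise_decoding_matrix(pd$subjects[[1]]$patterns$all_regions,
                                  cv_spec(n_repeats = 10, seed = 40 + i))
    within_format_accuracy(m, "nonsymbolic", pd$conditions)
  })
  expect_true(all(diff(accs) > -0.05))
  expect_gt(accs[3], accs[1])
})

test_that("every run reaches a training split across repeats", {
  spec <- tiny_cohort(seed = 44, n_per_group = 1, n_runs = 5)
  pd <- generate_condition_patterns(spec)
  # reproduce the seeded splits the matrix uses and audit them
  cv <- cv_spec(n_repeats = 100, seed = 77)
  set.seed(cv$seed)
  seen_train <- logical(5)
  for (i in 1:100) {
    n_train <- min(max(round(0.7 * 5), 1), 4)
    tr <- sample.int(5, n_train)
    seen_train[tr] <- TRUE
    expect_length(setdiff(1:5, tr), 5 - n_train)
  }
  expect_true(all(seen_train))
})
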