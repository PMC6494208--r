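test_that("band-pass filtering removes DC and respects the pass band", {
  tr <- 1                              # Nyquist 0.5 Hz
  t <- seq(0, 299, by = tr)
  const <- matrix(5, 1, length(t))
  out <- bandpass(const, c(0.01, 0.2), tr)
  expect_lt(max(abs(out)), 1e-6)

  amp_ratio <- function(freq) {
    x <- matrix(sin(2 * pi * freq * t), 1)
    y <- bandpass(x, c(0.01, 0.2), tr)
    # FFT amplitude at the stimulus frequency, before vs after
    k <- which.min(abs(seq(0, 1 / tr, length.out = length(t) + 1)[1:length(t)] - freq))
    abs(fft(y[1, ]))[k] / abs(fft(x[1, ]))[k]
  }
  expect_gt(amp_ratio(0.10), 0.9)
  expect_lt(amp_ratio(0.30), 0.2)

  # filtering twice changes little within the pass band
  x <- matrix(sin(2 * pi * 0.1 * t) + 0.3 * sin(2 * pi * 0.05 * t), 1)
  once <- bandpass(x, c(0.01, 0.2), tr)
  twice <- bandpass(once, c(0.01, 0.2), tr)
  expect_lt(mean((twice - once)^2) / mean(once^2), 0.05)
})

test_that("bands above Nyquist error (low cut) or fall back to high-pass (high cut)", {
  ts <- matrix(rnorm(200), 2, 100)
  expect_error(bandpass(ts, c(0.2, 0.4), tr = 3), "Nyquist")
  expect_warning(out <- bandpass(ts, c(0.01, 0.2), tr = 3), "high-pass")
  expect_equal(dim(out), dim(ts))
  expect_error(bandpass(ts[, 1:10, drop = FALSE], c(0.01, 0.1), tr = 1),
               "too short")
})

test_that("nuisance regression leaves residuals orthogonal to every confound", {
  set.seed(1)
  n_t <- 120
  ts <- matrix(rnorm(4 * n_t), 4, n_t)
  conf <- matrix(rnorm(n_t * 3), n_t, 3)
  res <- nuisance_regress(ts, conf)
  X <- cbind(1, conf, rbind(0, diff(conf)))
  expect_lt(max(abs(res %*% X)), 1e-8)

  # a signal equal to a confound is annihilated
  ts2 <- matrix(conf[, 1], 1, n_t, byrow = TRUE)
  res2 <- nuisance_regress(ts2, conf, add_derivatives = FALSE)
  expect_lt(max(abs(res2)), 1e-10)

  # a signal orthogonal to the confounds passes through
  q <- qr.Q(qr(cbind(1, conf)))
  orth <- rnorm(n_t)
  orth <- orth - q %*% (t(q) %*% orth)
  res3 <- nuisance_regress(matrix(orth, 1), conf, add_derivatives = FALSE)
  expect_equal(as.numeric(res3), as.numeric(orth), tolerance = 1e-8)

  expect_warning(nuisance_regress(ts, cbind(conf, conf[, 1])),
                 "rank-deficient")
  expect_error(nuisance_regress(ts, conf[-1, ]), "confounds have")
})

test_that("scrubbing removes spike volumes plus their configured neighbours", {
  n_t <- 100
  ts <- matrix(rnorm(3 * n_t), 3, n_t)
  motion <- matrix(0, n_t, 6)
  out <- scrub(ts, motion)
  expect_equal(out$retained, 1:n_t)
  expect_equal(out$n_removed, 0)

  motion2 <- motion
  motion2[c(20, 50, 80), 1] <- 2      # 2 mm jumps: FD spikes at 20/21, ...
  out2 <- scrub(ts, motion2, fd_threshold = 0.5, n_back = 1, n_forward = 2)
  spikes <- c(20, 21, 50, 51, 80, 81)  # jump up then back down
  expected_bad <- sort(unique(unlist(lapply(spikes, function(i)
    (i - 1):(i + 2)))))
  expect_equal(setdiff(1:n_t, out2$retained), expected_bad)

  out3 <- scrub(ts, motion2, fd_threshold = Inf)
  expect_equal(out3$retained, 1:n_t)
  expect_warning(scrub(ts, `[<-`(motion, , 1, rep(c(0, 9), n_t / 2))),
                 "retained")
})

test_that("framewise displacement combines translations and scaled rotations", {
  motion <- matrix(0, 5, 6)
  motion[3, 2] <- 1.5        # 1.5 mm translation jump
  motion[5, 5] <- 0.01       # 0.01 rad rotation jump -> 0.5 mm at 50 mm
  fd <- framewise_displacement(motion)
  expect_equal(fd, c(0, 0, 1.5, 1.5, 0.5))
})

test_that("connectivity matrices match the definitional covariance formula", {
  set.seed(2)
  ts <- matrix(rnorm(5 * 100), 5, 100)
  r <- connectivity_matrix(ts)
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- ts[i, ]; xj <- ts[j, ]
    oracle[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
  }
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_true(all(diag(r) == 1))

  anti <- rbind(1:50, 50:1)
  expect_equal(connectivity_matrix(anti)[1, 2], -1)
  expect_error(connectivity_matrix(ts[, 1:2]), "at least 3")
  expect_warning(rz <- connectivity_matrix(rbind(ts, 0)), "zero-variance")
  expect_true(is.na(rz[6, 1]))
})

test_that("Fisher z is atanh off-diagonal with NA diagonal and clamped extremes", {
  r <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3)
  z <- fisher_z(r)
  expect_equal(z[1, 2], 0.5493, tolerance = 1e-4)
  expect_equal(z[1, 3], 0)
  expect_equal(z[2, 3], atanh(-0.3))
  expect_true(all(is.na(diag(z))))
  # monotone
  rs <- seq(-0.9, 0.9, by = 0.1)
  zs <- atanh(rs)
  expect_true(all(diff(zs) > 0))
  rr <- diag(2); rr[1, 2] <- rr[2, 1] <- 1
  expect_warning(zz <- fisher_z(rr), "clamped")
  expect_lt(zz[1, 2], Inf)
})

test_that("edge-wise group tests match a summary-statistics oracle and respect FDR conventions", {
  set.seed(3)
  mk_z <- function(shift = 0) {
    z <- matrix(rnorm(16, 0.3 + shift, 0.1), 4)
    z <- (z + t(z)) / 2; diag(z) <- NA
    dimnames(z) <- list(letters[1:4], letters[1:4])
    z
  }
  za <- replicate(6, mk_z(), simplify = FALSE)
  zb <- replicate(6, mk_z(0.5), simplify = FALSE)
  res <- group_connectivity_tests(za, zb, alpha_between = 0.05)
  expect_equal(nrow(res$between), 6)
  # oracle for one edge
  ea <- sapply(za, function(z) z["a", "b"])
  eb <- sapply(zb, function(z) z["a", "b"])
  expect_equal(res$between$t[res$between$edge == "a-b"], t_oracle(ea, eb),
               tolerance = 1e-12)
  expect_true(all(res$between$p_fdr >= res$between$p - 1e-12))
  expect_true(all(res$between$direction[res$between$t < 0] == "b>a"))

  # all-zero matrices: nothing significant within groups
  z0 <- replicate(4, {
    z <- matrix(0, 3, 3); diag(z) <- NA; z
  }, simplify = FALSE)
  res0 <- group_connectivity_tests(z0, z0)
  expect_false(any(res0$within$significant))
  expect_false(any(res0$between$significant))
})

test_that("the full pipeline recovers the target connectivity ordering", {
  sch <- generate_run_schedule(experiment_design(), 1)
  spec <- cohort_spec(n_per_group = 8, n_runs = 6, voxels_per_roi = c(r = 8),
                      seed = 17)
  tcs <- generate_roi_time_courses(spec, sch)
  groups <- vapply(tcs$subjects, `[[`, "", "group")
  zs <- lapply(tcs$subjects, function(s) {
    connectivity_pipeline(s$ts, s$motion, task = tcs$task, tr = tcs$tr)$z
  })
  # dyscalculia group: PVC-IOC and PVC-FG targets are 0.6 vs background 0.35
  zd <- zs[groups == "dyscalculia"]
  ut <- upper.tri(zd[[1]])
  mean_z <- Reduce(`+`, zd)[ut] / length(zd)
  seeds <- rownames(zd[[1]])
  en <- outer(seeds, seeds, paste, sep = "-")[ut]
  hyper <- en %in% c("FG-PVC", "IOC-PVC", "PVC-FG", "PVC-IOC")
  expect_gt(min(mean_z[hyper]), max(mean_z[!hyper]) - 0.05)
  expect_gt(mean(mean_z[hyper]), mean(mean_z[!hyper]))
})
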