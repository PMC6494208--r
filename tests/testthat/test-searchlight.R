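test_that("sphere stencils enumerate exactly the offsets within the radius", {
  expect_equal(nrow(sphere_offsets(2)), 33)
  expect_equal(nrow(sphere_offsets(1)), 7)
  expect_equal(nrow(sphere_offsets(0)), 1)
  expect_error(sphere_offsets(-1), "non-negative")

  # brute force for radius 0..4, plus origin membership and monotonicity
  counts <- sapply(0:4, function(r) {
    g <- expand.grid(-4:4, -4:4, -4:4)
    sum(rowSums(g^2) <= r^2)
  })
  expect_equal(sapply(0:4, function(r) nrow(sphere_offsets(r))), counts)
  expect_true(all(diff(counts) >= 0))
  st <- sphere_offsets(2)
  expect_true(any(rowSums(abs(st)) == 0))
})

test_that("searchlight peaks inside an informative cluster and stays at chance without one", {
  tv <- generate_toy_volume(c(9, 9, 9),
                            clusters = list(list(center = c(5, 5, 5),
                                                 radius = 2,
                                                 separation = 9)),
                            n_runs = 6, n_conditions = 4, seed = 3)
  sl <- searchlight_map(tv, sphere_offsets(1),
                        cv = cv_spec(n_repeats = 3, seed = 1))
  peak <- which(sl$map == max(sl$map, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lte(sqrt(sum((peak - c(5, 5, 5))^2)), 2)

  # mask that excludes the cluster: no information anywhere
  mask <- array(TRUE, c(9, 9, 9))
  mask[3:7, 3:7, 3:7] <- FALSE
  tv_masked <- tv; tv_masked$mask <- mask
  sl2 <- searchlight_map(tv_masked, sphere_offsets(1),
                         cv = cv_spec(n_repeats = 3, seed = 1))
  expect_lt(mean(sl2$map, na.rm = TRUE), 0.62)
  expect_true(all(is.na(sl2$map[!mask])))
})

test_that("a pure-noise volume yields a chance accuracy field", {
  tv <- generate_toy_volume(c(7, 7, 7), clusters = list(), n_runs = 6,
                            n_conditions = 4, seed = 5)
  sl <- searchlight_map(tv, sphere_offsets(1),
                        cv = cv_spec(n_repeats = 5, seed = 2))
  vals <- sl$map[!is.na(sl$map)]
  # cell values average 6 pairs x 5 repeats x 2 test patterns = 60 decisions
  ci <- 3 * sqrt(0.25 / 60)
  expect_gt(mean(abs(vals - 0.5) <= 2 * ci), 0.7)
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("a stencil covering the whole mask reproduces ROI decoding of those voxels", {
  set.seed(6)
  grid <- c(3, 3, 1)
  data <- array(rnorm(prod(grid) * 6 * 4), c(grid, 6, 4))
  mask <- array(TRUE, grid)
  tv <- list(data = data, mask = mask)
  cv <- cv_spec(n_repeats = 4, seed = 9)
  sl <- searchlight_map(tv, sphere_offsets(3), cv = cv)
  # the center voxel reaches all 9 voxels: equals direct decoding
  pat <- array(NA_real_, c(6, 4, 9), dimnames = list(NULL, paste0("c", 1:4), NULL))
  flat <- matrix(data, 9, 24)
  for (k in 1:4) pat[, k, ] <- t(flat[, (k - 1) * 6 + 1:6])
  m <- pairwise_decoding_matrix(pat, cv)
  expect_equal(sl$map[2, 2, 1], mean(m[upper.tri(m)]))
})

test_that("empty masks and grid mismatches are rejected", {
  tv <- generate_toy_volume(c(5, 5, 5), n_runs = 4, seed = 1)
  tv$mask[] <- FALSE
  expect_error(searchlight_map(tv), "mask is empty")
  tv2 <- generate_toy_volume(c(5, 5, 5), n_runs = 4, seed = 1)
  tv2$mask <- array(TRUE, c(4, 5, 5))
  expect_error(searchlight_map(tv2), "does not match")
})

test_that("smoothing matches a naive mask-renormalized convolution oracle", {
  set.seed(7)
  grid <- c(11, 11, 11)
  m <- array(runif(prod(grid)), grid)
  mask <- array(runif(prod(grid)) > 0.2, grid)
  amap <- list(map = ifelse(mask, m, NA), mask = mask)
  fwhm <- 6; vox <- 2
  out <- smooth_map(amap, fwhm, vox)

  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  K <- max(1, ceiling(3 * sigma))
  w1 <- exp(-(-K:K)^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  coords <- as.matrix(expand.grid(1:11, 1:11, 1:11))
  wt <- function(dx) w1[dx[1] + K + 1] * w1[dx[2] + K + 1] * w1[dx[3] + K + 1]
  # column-normalized smoothing: source voxel j spreads its value over the
  # in-mask voxels it reaches with weights summing to 1
  sj_memo <- new.env()
  sj_of <- function(j) {
    key <- as.character(j)
    if (!is.null(sj_memo[[key]])) return(sj_memo[[key]])
    cj <- coords[j, ]
    sj <- 0
    for (ddx in -K:K) for (ddy in -K:K) for (ddz in -K:K) {
      ct <- cj + c(ddx, ddy, ddz)
      if (any(ct < 1) || any(ct > 11)) next
      if (mask[ct[1], ct[2], ct[3]]) sj <- sj + wt(c(ddx, ddy, ddz))
    }
    sj_memo[[key]] <- sj
    sj
  }
  check <- which(mask)[c(1, 50, 200, 400)]
  for (i in check) {
    ci <- coords[i, ]
    val <- 0
    for (j in which(mask)) {
      cj <- coords[j, ]
      dx <- ci - cj
      if (any(abs(dx) > K)) next
      val <- val + m[cj[1], cj[2], cj[3]] * wt(dx) / sj_of(j)
    }
    expect_equal(out$map[ci[1], ci[2], ci[3]], val, tolerance = 1e-10)
  }
})

test_that("smoothing preserves the in-mask mean and fwhm 0 is the identity", {
  tv <- generate_toy_volume(c(8, 8, 8), n_runs = 4, seed = 8)
  amap <- list(map = array(runif(512), c(8, 8, 8)), mask = tv$mask)
  out <- smooth_map(amap, fwhm_mm = 8, voxel_size_mm = 2)
  expect_lt(abs(mean(out$map, na.rm = TRUE) - mean(amap$map, na.rm = TRUE)),
            1e-10)
  expect_identical(smooth_map(amap, 0), amap)

  # delta image spreads into a kernel summing to 1 inside the mask
  delta <- array(0, c(8, 8, 8)); delta[4, 4, 4] <- 1
  dmap <- smooth_map(list(map = delta, mask = array(TRUE, c(8, 8, 8))), 6, 2)
  expect_equal(sum(dmap$map), 1, tolerance = 1e-10)
  expect_true(dmap$map[4, 4, 4] == max(dmap$map))
})

test_that("max-statistic permutation FWE controls the null and recovers injected deficits", {
  grid <- c(5, 5, 5)
  mk_maps <- function(n, shift_region = NULL, shift = 0, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      m <- array(rnorm(prod(grid), 0.5, 0.05), grid)
      if (!is.null(shift_region)) {
        m[shift_region] <- m[shift_region] + shift
      }
      m
    })
  }
  # null calibration over repeated simulations
  fp <- 0; n_sims <- 60
  for (s in seq_len(n_sims)) {
    res <- group_compare_maps(mk_maps(8, seed = 2 * s), mk_maps(8, seed = 2 * s + 1),
                              alpha = 0.05, n_perm = 200, seed = s)
    fp <- fp + any(res$significant)
  }
  se <- sqrt(0.05 * 0.95 / n_sims)
  expect_lte(fp / n_sims, 0.05 + 3 * se)

  # injected deficit in a known corner is recovered there
  region <- cbind(rep(1:2, each = 2), rep(1:2, 2), 1)
  a <- mk_maps(10, seed = 100)
  b <- mk_maps(10, shift_region = region, shift = -0.4, seed = 101)
  res <- group_compare_maps(a, b, alpha = 0.05, n_perm = 300, seed = 7)
  expect_true(any(res$significant[region]))
  expect_true(res$peak$coord[3] == 1 && all(res$peak$coord[1:2] <= 2))
  expect_error(group_compare_maps(a[1], b, n_perm = 10), "at least 2")
})
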