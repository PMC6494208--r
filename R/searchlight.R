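#' Sphere stencil of voxel offsets
#'
#' All integer offsets with squared Euclidean norm at most `radius^2`, in
#' lexicographic order.  Radius 2 yields 33 offsets (the searchlight volume),
#' radius 1 yields 7, radius 0 the origin alone.
#'
#' @param radius Sphere radius in voxels (>= 0).
#' @return A `sphere_stencil`: integer matrix of offsets (n x 3) with a
#'   `radius` attribute.
#' @examples
#' nrow(sphere_offsets(2))   # 33
#' @export
sphere_offsets <- function(radius = 2) {
  if (radius < 0) stop("radius must be non-negative")
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  g <- g[order(g$dx, g$dy, g$dz), ]
  m <- as.matrix(g)
  rownames(m) <- NULL
  structure(m, radius = radius, class = c("sphere_stencil", class(m)))
}

#' Whole-volume searchlight decoding map
#'
#' Centers the stencil on every in-mask voxel and decodes the conditions from
#' the voxels of the stencil intersected with the mask and grid (so edge
#' centers use fewer voxels).  Each center's value is the mean pairwise
#' decoding accuracy over the requested condition pairs; out-of-mask centers
#' are `NA`.
#'
#' @param volume A `toy_volume` (or list with `data` array `x,y,z,run,cond`
#'   and logical `mask`).
#' @param stencil A [sphere_offsets()] stencil.
#' @param cv,spec Cross-validation and classifier specifications.
#' @param conditions Indices or names of the conditions to decode (e.g. the
#'   four numerosities of one format); default all.
#' @return An `accuracy_map`: list with `map` (3-D array), `mask`,
#'   `smoothing` (`"none"`).
#' @export
searchlight_map <- function(volume, stencil = sphere_offsets(2),
                            cv = cv_spec(n_repeats = 10),
                            spec = classifier_spec(),
                            conditions = NULL) {
  data <- volume$data
  mask <- volume$mask
  stopifnot(length(dim(data)) == 5)
  grid <- dim(data)[1:3]
  if (!all(dim(mask) == grid)) {
    stop(sprintf("mask grid %s does not match data grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(grid, collapse = "x")))
  }
  if (!any(mask)) stop("mask is empty")
  n_cond <- dim(data)[5]
  if (is.null(conditions)) conditions <- seq_len(n_cond)
  cond_names <- paste0("c", conditions)
  n_runs <- dim(data)[4]
  flat <- matrix(data, prod(grid), n_runs * n_cond)  # voxel x (run,cond)
  centers <- which(mask, arr.ind = TRUE)
  lin <- function(co) (co[, 3] - 1) * grid[1] * grid[2] +
    (co[, 2] - 1) * grid[1] + co[, 1]
  mask_lin <- lin(centers)
  in_mask <- logical(prod(grid)); in_mask[mask_lin] <- TRUE
  map <- array(NA_real_, grid)
  for (ii in seq_len(nrow(centers))) {
    co <- sweep(unclass(stencil), 2, centers[ii, ], `+`)
    ok <- co[, 1] >= 1 & co[, 1] <= grid[1] &
      co[, 2] >= 1 & co[, 2] <= grid[2] &
      co[, 3] >= 1 & co[, 3] <= grid[3]
    vox <- lin(co[ok, , drop = FALSE])
    vox <- vox[in_mask[vox]]
    if (length(vox) < 2) next
    # patterns: run x condition x voxel
    pat <- array(NA_real_, c(n_runs, length(conditions), length(vox)),
                 dimnames = list(NULL, cond_names, NULL))
    for (k in seq_along(conditions)) {
      cidx <- (conditions[k] - 1) * n_runs + seq_len(n_runs)
      pat[, k, ] <- t(flat[vox, cidx, drop = FALSE])
    }
    m <- pairwise_decoding_matrix(pat, cv, spec)
    map[centers[ii, 1], centers[ii, 2], centers[ii, 3]] <-
      mean(m[upper.tri(m)])
  }
  structure(list(map = map, mask = mask, smoothing = "none"),
            class = "accuracy_map")
}

# 1-D convolution with zero padding, output same length as input
conv1_same <- function(v, kernel) {
  K <- (length(kernel) - 1) / 2
  full <- stats::convolve(c(rep(0, K), v, rep(0, K)), rev(kernel),
                          type = "open")
  full[(2 * K + 1):(2 * K + length(v))]
}

# separable 3-D convolution of an array with the same 1-D kernel per axis
conv3_sep <- function(a, kernel) {
  d <- dim(a)
  out <- apply(a, c(2, 3), conv1_same, kernel = kernel)
  dim(out) <- d
  out <- aperm(apply(out, c(1, 3), conv1_same, kernel = kernel), c(2, 1, 3))
  aperm(apply(out, c(1, 2), conv1_same, kernel = kernel), c(2, 3, 1))
}

gaussian_kernel_1d <- function(sigma_vox) {
  K <- max(1, ceiling(3 * sigma_vox))
  x <- -K:K
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Mask-aware Gaussian smoothing of an accuracy map
#'
#' Gaussian convolution with `sigma = FWHM / (2 sqrt(2 ln 2))` per axis.
#' Each source voxel's kernel weights are renormalized over the in-mask
#' voxels it reaches, so no accuracy mass leaks outside the mask and the
#' in-mask mean is preserved exactly: a delta image becomes the (in-mask
#' renormalized) kernel itself, summing to 1.
#'
#' @param map An `accuracy_map` (or list with `map` array and `mask`).
#' @param fwhm_mm Full width at half maximum in mm (0 = identity).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return The smoothed `accuracy_map` with `smoothing` recording the FWHM.
#' @export
smooth_map <- function(map, fwhm_mm = 8, voxel_size_mm = 2) {
  stopifnot(fwhm_mm >= 0, voxel_size_mm > 0)
  if (fwhm_mm == 0) return(map)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  kernel <- gaussian_kernel_1d(sigma_vox)
  m <- map$map
  msk <- map$mask & !is.na(m)
  vals <- ifelse(msk, m, 0)
  support <- conv3_sep(array(as.numeric(msk), dim(m)), kernel)
  src <- array(0, dim(m))
  src[msk] <- vals[msk] / support[msk]
  sm <- conv3_sep(src, kernel)
  out <- array(NA_real_, dim(m))
  out[msk] <- sm[msk]
  structure(list(map = out, mask = map$mask,
                 smoothing = sprintf("FWHM %g mm", fwhm_mm)),
            class = "accuracy_map")
}

#' Permutation-based group comparison of accuracy maps
#'
#' Voxel-wise two-sided pooled-variance t-statistics between the two groups'
#' maps, with family-wise error control by max-statistic permutation: group
#' labels are randomly reassigned `n_perm` times, the maximum absolute voxel
#' t recorded each time, and the observed map thresholded at the
#' `1 - alpha` quantile of that null.
#'
#' @param maps_a,maps_b Lists of `accuracy_map`s (or 3-D arrays) per group.
#' @param alpha Family-wise error level.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return List with `t_map` (3-D array), `threshold`, `significant`
#'   (logical array), `peak` (coordinates and t of the maximum |t|),
#'   `null_max` (the permutation null).
#' @export
group_compare_maps <- function(maps_a, maps_b, alpha = 0.05, n_perm = 1000,
                               seed = 1L) {
  get_arr <- function(m) if (is.list(m)) m$map else m
  A <- lapply(maps_a, get_arr); B <- lapply(maps_b, get_arr)
  if (length(A) < 2 || length(B) < 2) {
    stop("need at least 2 subjects per group")
  }
  d <- dim(A[[1]])
  ok <- Reduce(`&`, lapply(c(A, B), function(x) !is.na(x)))
  vox <- which(ok)
  Xa <- sapply(A, function(x) x[vox])    # vox x n1
  Xb <- sapply(B, function(x) x[vox])
  X <- cbind(Xa, Xb)
  n1 <- ncol(Xa); n2 <- ncol(Xb); n <- n1 + n2
  tstat <- function(lab) {                 # lab: logical, TRUE = group A
    ma <- rowMeans(X[, lab, drop = FALSE])
    mb <- rowMeans(X[, !lab, drop = FALSE])
    va <- rowSums((X[, lab, drop = FALSE] - ma)^2)
    vb <- rowSums((X[, !lab, drop = FALSE] - mb)^2)
    sp2 <- (va + vb) / (n - 2)
    se <- sqrt(sp2 * (1 / sum(lab) + 1 / sum(!lab)))
    ifelse(se > 0, (ma - mb) / se, 0)
  }
  lab0 <- c(rep(TRUE, n1), rep(FALSE, n2))
  t_obs <- tstat(lab0)
  set.seed(as.integer(seed))
  null_max <- replicate(n_perm, {
    lab <- sample(lab0)
    max(abs(tstat(lab)))
  })
  thr <- as.numeric(quantile(null_max, 1 - alpha, type = 1))
  t_map <- array(NA_real_, d); t_map[vox] <- t_obs
  signif <- array(FALSE, d); signif[vox] <- abs(t_obs) > thr
  peak_i <- vox[which.max(abs(t_obs))]
  peak <- which(array(seq_len(prod(d)), d) == peak_i, arr.ind = TRUE)
  list(t_map = t_map, threshold = thr, significant = signif,
       peak = list(coord = as.integer(peak[1, ]), t = t_obs[which.max(abs(t_obs))]),
       df = n - 2, null_max = null_max)
}
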