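#' Zero-phase Butterworth band-pass filter for ROI time courses
#'
#' Order-4 Butterworth filter applied forward and backward
#' (`signal::filtfilt`, so zero phase) after removing each series' mean.
#' If the high cut-off reaches the Nyquist frequency of the sampling rate the
#' band cannot be realized on the high side; a warning is raised and a
#' high-pass at the low cut-off is applied instead (the behaviour a nominal
#' 0.01-0.2 Hz band has at TR = 3 s).  A low cut-off at or above Nyquist is
#' an error.
#'
#' @param ts Numeric matrix, regions x time.
#' @param band Length-2 numeric, low and high cut-off in Hz.
#' @param tr Sampling interval in seconds.
#' @param order Butterworth order.
#' @return Filtered matrix, same shape.
#' @export
bandpass <- function(ts, band = c(0.01, 0.2), tr = 3, order = 4) {
  ts <- as.matrix(ts)
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  nyq <- 1 / (2 * tr)
  if (band[1] >= nyq) {
    stop(sprintf("low cut-off %g Hz is at or above Nyquist (%g Hz); band unrealizable",
                 band[1], nyq))
  }
  min_len <- 3 * (order * 2 + 1)
  if (ncol(ts) < min_len) {
    stop(sprintf("series length %d too short for an order-%d zero-phase filter (need >= %d)",
                 ncol(ts), order, min_len))
  }
  if (band[2] >= nyq) {
    warning(sprintf("high cut-off %g Hz is at or above Nyquist (%g Hz); applying high-pass at %g Hz",
                    band[2], nyq, band[1]))
    filt <- signal::butter(order, band[1] / nyq, type = "high")
  } else {
    filt <- signal::butter(order, band / nyq, type = "pass")
  }
  out <- t(apply(ts, 1, function(x) {
    signal::filtfilt(filt, x - mean(x))
  }))
  dimnames(out) <- dimnames(ts)
  out
}

# first temporal derivatives (backward differences, first row 0)
temporal_derivatives <- function(x) {
  x <- as.matrix(x)
  rbind(0, diff(x))
}

#' Regress nuisance signals out of ROI time courses
#'
#' Residualizes each region's series against an intercept, the confound
#' columns and (optionally) their first temporal derivatives, plus an
#' optional task regressor (the HRF-convolved task-versus-baseline time
#' course).  Residuals are orthogonal to every regressor.
#'
#' @param ts Numeric matrix, regions x time.
#' @param confounds Numeric matrix, time x k (e.g. motion parameters and
#'   tissue signals).
#' @param task Optional numeric task regressor (length = time).
#' @param add_derivatives Include first derivatives of the confounds.
#' @return Residual matrix, regions x time.
#' @export
nuisance_regress <- function(ts, confounds = NULL, task = NULL,
                             add_derivatives = TRUE) {
  ts <- as.matrix(ts)
  n_t <- ncol(ts)
  X <- matrix(1, n_t, 1)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_t) {
      stop(sprintf("confounds have %d rows but data has %d time points",
                   nrow(confounds), n_t))
    }
    X <- cbind(X, confounds)
    if (add_derivatives) X <- cbind(X, temporal_derivatives(confounds))
  }
  if (!is.null(task)) {
    stopifnot(length(task) == n_t)
    X <- cbind(X, task)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning(sprintf("confound matrix is rank-deficient (rank %d < %d); using pseudo-inverse",
                    qr_x$rank, ncol(X)))
  }
  res <- t(ts) - X %*% qr.coef(qr_x, t(ts))
  res[is.na(res)] <- 0
  t(res)
}

#' Framewise displacement from motion parameters
#'
#' Sum of absolute backward differences of the three translations (mm) plus
#' the three rotations (radians) converted to arc length on a sphere of
#' `head_radius` mm.  The first volume's displacement is 0.
#'
#' @param motion Numeric matrix, time x 6 (translations mm, rotations rad).
#' @param head_radius Radius in mm for the rotation-to-displacement
#'   conversion.
#' @return Numeric vector of FD per volume.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  d <- abs(temporal_derivatives(motion))
  rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
}

#' Scrub motion-affected volumes
#'
#' Flags volumes whose framewise displacement exceeds `fd_threshold`,
#' extends the flag to `n_back` preceding and `n_forward` following volumes,
#' and removes them from the series.  A subject retaining fewer than half of
#' the volumes is flagged with a warning.
#'
#' @param ts Numeric matrix, regions x time.
#' @param motion Numeric matrix, time x 6, aligned with `ts`.
#' @param fd_threshold FD threshold in mm.
#' @param n_back,n_forward Neighbouring volumes removed around each flagged
#'   volume.
#' @return List with `ts` (scrubbed matrix), `retained` (kept volume
#'   indices), `n_removed`, `fd`, and `low_retention` flag.
#' @export
scrub <- function(ts, motion, fd_threshold = 0.5, n_back = 1, n_forward = 2) {
  ts <- as.matrix(ts)
  motion <- as.matrix(motion)
  if (nrow(motion) != ncol(ts)) {
    stop(sprintf("motion table (%d rows) not aligned with time axis (%d volumes)",
                 nrow(motion), ncol(ts)))
  }
  fd <- framewise_displacement(motion)
  bad <- which(fd > fd_threshold)
  if (length(bad) > 0) {
    ext <- unique(unlist(lapply(bad, function(i) (i - n_back):(i + n_forward))))
    bad <- sort(ext[ext >= 1 & ext <= ncol(ts)])
  }
  retained <- setdiff(seq_len(ncol(ts)), bad)
  low <- length(retained) < ncol(ts) / 2
  if (low) {
    warning(sprintf("only %d of %d volumes retained after scrubbing",
                    length(retained), ncol(ts)))
  }
  list(ts = ts[, retained, drop = FALSE], retained = retained,
       n_removed = length(bad), fd = fd, low_retention = low)
}

#' Seed-by-seed Pearson connectivity matrix
#'
#' @param ts Numeric matrix, regions x time (>= 3 retained volumes).
#' @return Symmetric correlation matrix with unit diagonal; entries involving
#'   a zero-variance region are `NA` (with a warning).
#' @export
connectivity_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 retained volumes")
  sds <- apply(ts, 1, sd)
  r <- suppressWarnings(cor(t(ts)))
  if (any(sds == 0)) {
    warning(sprintf("zero-variance region(s): %s; their correlations are NA",
                    paste(which(sds == 0), collapse = ", ")))
  }
  diag(r) <- 1
  r
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' `z = atanh(r)` elementwise off the diagonal; the diagonal is set to `NA`
#' (it carries no information and is excluded from tests).  Off-diagonal
#' `|r| >= 1` is clamped to `1 - epsilon` with a warning.
#'
#' @param r Correlation matrix.
#' @param epsilon Clamping margin for `|r| = 1`.
#' @return z-score matrix, diagonal `NA`.
#' @export
fisher_z <- function(r, epsilon = 1e-7) {
  r <- as.matrix(r)
  z <- r
  off <- row(r) != col(r)
  clip <- off & !is.na(r) & abs(r) >= 1
  if (any(clip)) {
    warning(sprintf("%d off-diagonal |r| >= 1 clamped to 1 - %g", sum(clip),
                    epsilon))
    z[clip] <- sign(r[clip]) * (1 - epsilon)
  }
  z[off] <- atanh(z[off])
  diag(z) <- NA_real_
  z
}

#' Edge-wise group tests on Fisher z connectivity matrices
#'
#' Within each group, a one-sample t-test of every edge's z-values against 0
#' (random-effects analysis), BH-FDR corrected across edges at
#' `alpha_within`.  Between groups, a two-sided pooled two-sample t-test per
#' edge, BH-FDR corrected across edges at `alpha_between`, with the sign of
#' the difference reported.  Edges undefined (`NA`) in any subject are
#' excluded and counted.
#'
#' @param z_a,z_b Lists of z matrices (one per subject) for the two groups.
#' @param alpha_within,alpha_between FDR levels for the within-group and
#'   between-group families.
#' @return List with `within` (data frame per group x edge), `between`
#'   (data frame per edge), `n_excluded`.
#' @export
group_connectivity_tests <- function(z_a, z_b, alpha_within = 0.001,
                                     alpha_between = 0.05) {
  if (length(z_a) < 2 || length(z_b) < 2) {
    stop("need at least 2 subjects per group")
  }
  p <- nrow(z_a[[1]])
  seeds <- rownames(z_a[[1]]) %||% paste0("seed", seq_len(p))
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  edge_names <- paste(seeds[ut[, 1]], seeds[ut[, 2]], sep = "-")
  extract <- function(zl) t(sapply(zl, function(z) z[ut]))  # subj x edge
  Za <- extract(z_a); Zb <- extract(z_b)
  ok <- !apply(is.na(rbind(Za, Zb)), 2, any)
  n_excluded <- sum(!ok)

  one_sample <- function(Z, group_label) {
    t <- apply(Z[, ok, drop = FALSE], 2, function(v) {
      if (sd(v) == 0) return(if (mean(v) == 0) 0 else NA_real_)
      mean(v) / (sd(v) / sqrt(length(v)))
    })
    df <- nrow(Z) - 1
    pv <- 2 * pt(-abs(t), df)
    data.frame(group = group_label, edge = edge_names[ok], t = t, df = df,
               p = pv, p_fdr = p.adjust(pv, "BH"),
               significant = p.adjust(pv, "BH") < alpha_within,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  within <- rbind(one_sample(Za, "a"), one_sample(Zb, "b"))

  bt <- lapply(which(ok), function(j) two_sample_t(Za[, j], Zb[, j]))
  tval <- vapply(bt, `[[`, numeric(1), "t")
  pval <- vapply(bt, `[[`, numeric(1), "p")
  between <- data.frame(
    edge = edge_names[ok], t = tval,
    df = length(z_a) + length(z_b) - 2, p = pval,
    p_fdr = p.adjust(pval, "BH"),
    direction = ifelse(tval > 0, "a>b", ifelse(tval < 0, "b>a", "none")),
    significant = p.adjust(pval, "BH") < alpha_between,
    stringsAsFactors = FALSE, row.names = NULL)
  list(within = within, between = between, n_excluded = n_excluded)
}

#' Full connectivity preprocessing for one subject
#'
#' Applies the six-step pipeline in order: band-pass filter, regression of
#' motion (+ derivatives), regression of tissue signals (+ derivatives),
#' regression of the task regressor, scrubbing, and (volumetric mode only,
#' not applicable to ROI tables) spatial smoothing.  Returns the Pearson and
#' Fisher z matrices.
#'
#' @param ts Regions x time matrix.
#' @param motion Time x 6 motion parameters.
#' @param tissue Optional time x k tissue (white matter / ventricle) signals.
#' @param task Optional task regressor.
#' @param band,tr Band-pass settings.
#' @param fd_threshold Scrubbing threshold (mm).
#' @return List with `r`, `z`, `n_retained`, `low_retention`.
#' @export
connectivity_pipeline <- function(ts, motion, tissue = NULL, task = NULL,
                                  band = c(0.01, 0.2), tr = 3,
                                  fd_threshold = 0.5) {
  filtered <- suppressWarnings(bandpass(ts, band, tr))
  confounds <- if (is.null(tissue)) motion else cbind(motion, tissue)
  resid <- nuisance_regress(filtered, confounds, task = task)
  sc <- scrub(resid, motion, fd_threshold)
  r <- connectivity_matrix(sc$ts)
  list(r = r, z = fisher_z(r), n_retained = length(sc$retained),
       low_retention = sc$low_retention)
}
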