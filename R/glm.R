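# Fraction of each TR interval occupied by the selected blocks.  Integrating
# occupancy (rather than point-sampling at volume onsets) makes the unconvolved
# regressor sum to (total block seconds) / TR exactly, whatever the block
# lengths are relative to the TR.
block_occupancy <- function(schedule, n_vol, tr, which_blocks) {
  box <- numeric(n_vol)
  sel <- which(which_blocks)
  starts <- (seq_len(n_vol) - 1) * tr
  for (i in sel) {
    on <- schedule$onset_s[i]
    off <- on + schedule$duration_s[i]
    overlap <- pmax(0, pmin(off, starts + tr) - pmax(on, starts))
    box <- box + overlap / tr
  }
  box
}

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar regressor per condition, one for the fixation
#' baseline, the six motion parameters, and an intercept.  Boxcars are
#' occupancy fractions per TR interval (so the unconvolved column for a
#' condition sums to its total presentation time divided by the TR) convolved
#' with the canonical double-gamma HRF sampled at the TR.
#'
#' @param schedule A `run_schedule`.
#' @param motion Numeric matrix, time x 6, of motion parameters; must have
#'   `ceiling(run duration / tr)` rows.
#' @param tr Repetition time in seconds.
#' @return A `design_matrix`: numeric matrix (volumes x regressors) with
#'   column labels, plus attributes `condition_labels` and `boxcars` (the
#'   unconvolved condition boxcars).
#' @export
build_design_matrix <- function(schedule, motion, tr = 3) {
  n_vol <- ceiling(schedule_duration(schedule) / tr)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_vol || ncol(motion) != 6) {
    stop(sprintf("motion table is %d x %d; expected %d x 6 for this schedule",
                 nrow(motion), ncol(motion), n_vol))
  }
  conds <- unique(schedule$condition[schedule$kind == "experimental"])
  conds <- conds[!is.na(conds)]
  h <- canonical_hrf(seq(0, 30, by = tr))
  convolve_tr <- function(box) {
    stats::convolve(box, rev(h), type = "open")[seq_len(n_vol)]
  }
  boxcars <- sapply(conds, function(cc) {
    block_occupancy(schedule, n_vol, tr,
                    schedule$kind == "experimental" &
                      !is.na(schedule$condition) & schedule$condition == cc)
  })
  fix_box <- block_occupancy(schedule, n_vol, tr, schedule$kind == "fixation")
  cols <- list()
  if (length(conds) > 0) {
    boxcars <- matrix(boxcars, nrow = n_vol,
                      dimnames = list(NULL, conds))
    for (cc in conds) cols[[cc]] <- convolve_tr(boxcars[, cc])
  } else {
    boxcars <- matrix(numeric(0), nrow = n_vol, ncol = 0)
  }
  cols[["fixation"]] <- convolve_tr(fix_box)
  for (j in 1:6) cols[[colnames(motion)[j] %||% paste0("motion_", j)]] <- motion[, j]
  cols[["intercept"]] <- rep(1, n_vol)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(X, condition_labels = conds, boxcars = boxcars,
            class = c("design_matrix", class(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a voxel-wise general linear model
#'
#' Ordinary least squares per voxel.  If the design is rank-deficient a
#' warning is raised and the minimum-norm (pseudo-inverse) solution is
#' returned; degrees of freedom are `volumes - rank(design)`.
#'
#' @param timecourses Numeric matrix, voxels x time.
#' @param design Design matrix (time x regressors), e.g. from
#'   [build_design_matrix()].
#' @return A `glm_fit`: list with `betas` (voxels x regressors),
#'   `sigma2` (residual variance per voxel), `df`, `rank`, `xtx_inv`
#'   (generalized inverse of X'X) and `residuals` (voxels x time).
#' @export
fit_glm <- function(timecourses, design) {
  Y <- as.matrix(timecourses)
  X <- unclass(design)
  if (ncol(Y) != nrow(X)) {
    stop(sprintf("time dimension mismatch: data has %d volumes, design has %d rows",
                 ncol(Y), nrow(X)))
  }
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < ncol(X)) {
    warning(sprintf("design matrix is rank-deficient (rank %d < %d columns); using minimum-norm solution",
                    r, ncol(X)))
  }
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  Xp <- sv$v %*% (dinv * t(sv$u))                 # pseudo-inverse, p x n
  betas <- Y %*% t(Xp)                            # voxels x p
  colnames(betas) <- colnames(X)
  fitted <- betas %*% t(X)
  res <- Y - fitted
  df <- nrow(X) - r
  sigma2 <- if (df > 0) rowSums(res^2) / df else rep(NA_real_, nrow(Y))
  # voxels whose residual variance is numerically zero relative to the data
  # scale (e.g. constant or noiseless series) are flagged downstream
  zero_var <- sigma2 <= 1e-12 * pmax(rowMeans(Y^2), .Machine$double.eps)
  xtx_inv <- sv$v %*% (dinv^2 * t(sv$v))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(list(betas = betas, sigma2 = sigma2, df = df, rank = r,
                 xtx_inv = xtx_inv, residuals = res, zero_var = zero_var,
                 design = X),
            class = "glm_fit")
}

#' Condition-versus-baseline t-patterns
#'
#' Computes `t = c'beta / sqrt(sigma2 * c' (X'X)^- c)` per voxel for each
#' requested contrast.  The default contrasts each condition regressor against
#' the fixation regressor.  Voxels with zero residual variance yield `NA`
#' and are reported in the `flagged` attribute rather than silently infinite.
#'
#' @param fit A `glm_fit` from [fit_glm()].
#' @param contrasts Named list of contrast weight vectors (names matching
#'   design columns); `NULL` builds condition-minus-fixation contrasts for
#'   every condition regressor.
#' @return A `t_patterns` object: matrix contrasts x voxels with attributes
#'   `df` and `flagged` (indices of zero-variance voxels).
#' @export
condition_t_patterns <- function(fit, contrasts = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  labels <- colnames(fit$betas)
  if (is.null(contrasts)) {
    conds <- setdiff(labels, c("fixation", "intercept",
                               grep("^(motion_|trans_|rot_)", labels,
                                    value = TRUE)))
    contrasts <- lapply(conds, function(cc) {
      w <- c(1, -1); names(w) <- c(cc, "fixation"); w
    })
    names(contrasts) <- conds
  }
  zero_var <- which(fit$zero_var | !is.finite(fit$sigma2))
  out <- matrix(NA_real_, length(contrasts), nrow(fit$betas),
                dimnames = list(names(contrasts), NULL))
  for (k in seq_along(contrasts)) {
    w <- contrasts[[k]]
    if (!all(names(w) %in% labels)) {
      stop(sprintf("unknown regressor(s) in contrast '%s': %s",
                   names(contrasts)[k],
                   paste(setdiff(names(w), labels), collapse = ", ")))
    }
    cvec <- stats::setNames(numeric(length(labels)), labels)
    cvec[names(w)] <- w
    est <- as.numeric(fit$betas %*% cvec)
    vf <- as.numeric(t(cvec) %*% fit$xtx_inv %*% cvec)
    se <- sqrt(fit$sigma2 * vf)
    t <- ifelse(se > 0, est / se, ifelse(est == 0, 0, NA_real_))
    t[zero_var] <- ifelse(est[zero_var] == 0, 0, NA_real_)
    out[k, ] <- t
  }
  structure(out, df = fit$df, flagged = zero_var, class = "t_patterns")
}
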