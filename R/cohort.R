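#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm sd cor pt qt p.adjust aov t.test quantile runif
#' @importFrom utils head
NULL

#' Deterministic child seed
#'
#' Derives a child seed from a parent seed and a character tag, so every
#' sub-generator has its own reproducible stream while the whole cohort
#' remains a function of one integer.  Result stays below 2^31.
#'
#' @param seed Parent integer seed.
#' @param tag Character tag naming the stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style parameterization: response gamma peaking at 6 s, undershoot
#' peaking at 16 s with 1/6 relative amplitude, unit dispersions.  Scaled to a
#' peak of 1.
#'
#' @param t Time points in seconds (non-negative).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  stopifnot(all(t >= 0))
  a1 <- 6; a2 <- 16; b <- 1; c <- 1 / 6
  h <- stats::dgamma(t, shape = a1, rate = b) -
    c * stats::dgamma(t, shape = a2, rate = b)
  grid <- seq(0, 32, by = 0.1)
  peak <- max(stats::dgamma(grid, a1, b) - c * stats::dgamma(grid, a2, b))
  h / peak
}

# multivariate normal draws via Cholesky (upper) factor of sigma
rmvn <- function(n, sigma) {
  p <- nrow(sigma)
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
    stop("covariance matrix is not positive semi-definite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  matrix(rnorm(n * p), n, p) %*% t(L)
}

#' Specification of a synthetic two-group cohort
#'
#' Encodes the statistical structure the downstream analyses assume: two
#' groups of equal size, several runs per subject, per-region voxel counts,
#' a pattern-separation parameter per (group, format, region), i.i.d. voxel
#' noise, and a per-group target correlation structure between seed regions.
#'
#' The defaults emulate the study conditions this package targets: 24
#' subjects per group, 10 runs, symbolic numerosity patterns weakly and
#' equally separable in both groups, non-symbolic patterns markedly less
#' separable in the dyscalculia group, and hyper-connectivity of the primary
#' visual cortex with the inferior occipital cortex and fusiform gyrus in the
#' dyscalculia group.
#'
#' @param n_per_group Subjects per group.
#' @param n_runs Runs per subject (the study acquired 8-12).
#' @param voxels_per_roi Named integer vector: voxels in each region.
#' @param separation Data frame with columns `group`, `region`, `format`,
#'   `separation` (non-negative pairwise prototype distance). `NULL` uses the
#'   defaults described above.
#' @param noise_sd Standard deviation of i.i.d. voxel noise added per run.
#' @param connectivity_target Named list (one entry per group) of symmetric
#'   unit-diagonal positive semi-definite seed-by-seed correlation matrices.
#'   `NULL` uses the defaults described above.
#' @param groups Group labels; first label is the reference (control) group.
#' @param design An [experiment_design()].
#' @param seed Master integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 24,
                        n_runs = 10,
                        voxels_per_roi = c(all_regions = 60),
                        separation = NULL,
                        noise_sd = 1,
                        connectivity_target = NULL,
                        groups = c("control", "dyscalculia"),
                        design = experiment_design(),
                        seed = 1L) {
  stopifnot(n_per_group >= 1, n_runs >= 1, length(groups) == 2,
            noise_sd > 0, all(voxels_per_roi >= 1))
  regions <- names(voxels_per_roi)
  if (is.null(regions)) stop("voxels_per_roi must be named by region")
  formats <- unique(design$conditions$format)
  if (is.null(separation)) {
    separation <- expand.grid(group = groups, region = regions,
                              format = formats, stringsAsFactors = FALSE)
    separation$separation <- ifelse(
      separation$format == "symbolic", 0.8,
      ifelse(separation$group == groups[1], 2.0, 1.0))
  }
  stopifnot(all(c("group", "region", "format", "separation") %in%
                  names(separation)),
            all(separation$separation >= 0))
  if (is.null(connectivity_target)) {
    connectivity_target <- default_connectivity_targets(groups)
  }
  for (g in names(connectivity_target)) {
    m <- connectivity_target[[g]]
    if (!isSymmetric(unname(m)) || any(abs(diag(m) - 1) > 1e-12)) {
      stop(sprintf("connectivity target for group '%s' must be symmetric with unit diagonal", g))
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(sprintf("connectivity target for group '%s' is not positive semi-definite", g))
    }
  }
  structure(list(n_per_group = n_per_group, n_runs = n_runs,
                 voxels_per_roi = voxels_per_roi, separation = separation,
                 noise_sd = noise_sd,
                 connectivity_target = connectivity_target,
                 groups = groups, design = design, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default seed-region correlation targets
#'
#' Eight level-III seed regions with a common background correlation of 0.35;
#' in the second (dyscalculia) group the PVC-IOC and PVC-FG edges are raised
#' to 0.6, the direction of the hyper-connectivity reported for that group.
#'
#' @param groups Two group labels.
#' @param seeds Seed region names.
#' @return Named list of correlation matrices.
#' @export
default_connectivity_targets <- function(groups = c("control", "dyscalculia"),
                                         seeds = c("FG", "IFG", "SFG", "IOC",
                                                   "PVC", "IPL", "SPL", "IPS")) {
  base <- matrix(0.35, length(seeds), length(seeds),
                 dimnames = list(seeds, seeds))
  diag(base) <- 1
  hyper <- base
  if (all(c("PVC", "IOC", "FG") %in% seeds)) {
    hyper["PVC", "IOC"] <- hyper["IOC", "PVC"] <- 0.6
    hyper["PVC", "FG"] <- hyper["FG", "PVC"] <- 0.6
  }
  out <- list(base, hyper)
  names(out) <- groups
  out
}

sep_lookup <- function(sep, group, region, format) {
  v <- sep$separation[sep$group == group & sep$region == region &
                        sep$format == format]
  if (length(v) != 1) {
    stop(sprintf("no separation entry for (%s, %s, %s)", group, region, format))
  }
  v
}

#' Generate per-subject condition voxel patterns
#'
#' For each subject and region, condition prototypes are placed at the
#' vertices of a regular simplex spanned by random orthonormal directions in
#' voxel space, scaled so the pairwise prototype distance equals the
#' separation parameter for that (group, format, region).  Each run's
#' observed pattern is the prototype plus i.i.d. Gaussian noise, mimicking
#' the per-run condition t-patterns the first-level model produces.
#'
#' @param spec A [cohort_spec()].
#' @return A `pattern_dataset`: list with `subjects` (each holding `id`,
#'   `group` and `patterns`, a per-region array `run x condition x voxel`),
#'   `regions`, `conditions` (the design's condition table) and `groups`.
#' @export
generate_condition_patterns <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$voxels_per_roi < 2)) {
    stop("every region needs at least 2 voxels (patterns cannot be standardized)")
  }
  cond <- spec$design$conditions
  n_cond <- nrow(cond)
  subjects <- list()
  sid <- 0L
  for (g in spec$groups) {
    for (s in seq_len(spec$n_per_group)) {
      sid <- sid + 1L
      set.seed(derive_seed(spec$seed, paste0("patterns/", g, "/", s)))
      pats <- list()
      for (r in names(spec$voxels_per_roi)) {
        nv <- spec$voxels_per_roi[[r]]
        if (nv < n_cond) {
          # orthonormal directions need nv >= n_cond; enforce enough room
          stop(sprintf("region '%s' has %d voxels; need >= %d (one simplex direction per condition)",
                       r, nv, n_cond))
        }
        # random orthonormal basis, one direction per condition
        Q <- qr.Q(qr(matrix(rnorm(nv * n_cond), nv, n_cond)))
        proto <- matrix(0, n_cond, nv)
        for (ci in seq_len(n_cond)) {
          d <- sep_lookup(spec$separation, g, r, cond$format[ci])
          # prototypes d/sqrt(2) * e_ci have pairwise distance d within format
          proto[ci, ] <- (d / sqrt(2)) * Q[, ci]
        }
        arr <- array(NA_real_, dim = c(spec$n_runs, n_cond, nv),
                     dimnames = list(NULL, cond$condition, NULL))
        for (run in seq_len(spec$n_runs)) {
          arr[run, , ] <- proto +
            matrix(rnorm(n_cond * nv, sd = spec$noise_sd), n_cond, nv)
        }
        pats[[r]] <- arr
      }
      subjects[[sid]] <- list(id = sprintf("%s_%02d", g, s), group = g,
                              patterns = pats)
    }
  }
  structure(list(subjects = subjects, regions = names(spec$voxels_per_roi),
                 conditions = cond, groups = spec$groups),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("pattern_dataset: %d subjects (%s), %d conditions, regions: %s\n",
              length(x$subjects),
              paste(table(vapply(x$subjects, `[[`, "", "group")), collapse = "+"),
              nrow(x$conditions), paste(x$regions, collapse = ", ")))
  invisible(x)
}

#' Generate seed-region BOLD-like time courses
#'
#' Draws multivariate Gaussian noise with the group's target correlation
#' structure, adds a shared task component (schedule boxcar convolved with the
#' canonical HRF) to every seed, and synthesizes slow-drift motion parameters.
#' Sampled at the design's TR; runs are concatenated.
#'
#' @param spec A [cohort_spec()].
#' @param schedule A `run_schedule` providing the task timing of one run.
#' @param task_amplitude Amplitude of the shared task component (in noise SD
#'   units).
#' @param n_runs Number of concatenated runs; defaults to `spec$n_runs`.
#' @return A `timecourse_set`: list with per-subject entries holding `ts`
#'   (seed x time matrix), `motion` (time x 6), `group`; plus `seeds`, `tr`
#'   and the schedule.
#' @export
generate_roi_time_courses <- function(spec, schedule, task_amplitude = 0.5,
                                      n_runs = spec$n_runs) {
  stopifnot(inherits(spec, "cohort_spec"))
  tr <- spec$design$tr
  n_vol_run <- ceiling(schedule_duration(schedule) / tr)
  n_vol <- n_vol_run * n_runs
  task <- task_regressor(schedule, tr, n_runs)

  subjects <- list()
  sid <- 0L
  for (g in spec$groups) {
    target <- spec$connectivity_target[[g]]
    if (is.null(target)) {
      stop(sprintf("no connectivity target defined for group '%s'", g))
    }
    seeds <- rownames(target)
    for (s in seq_len(spec$n_per_group)) {
      sid <- sid + 1L
      set.seed(derive_seed(spec$seed, paste0("timecourses/", g, "/", s)))
      noise <- t(rmvn(n_vol, target))                  # seeds x time
      ts <- noise + matrix(task_amplitude * task, nrow(target), n_vol,
                           byrow = TRUE)
      rownames(ts) <- seeds
      motion <- generate_motion(n_vol)
      subjects[[sid]] <- list(id = sprintf("%s_%02d", g, s), group = g,
                              ts = ts, motion = motion)
    }
  }
  structure(list(subjects = subjects,
                 seeds = rownames(spec$connectivity_target[[spec$groups[1]]]),
                 tr = tr, schedule = schedule, task = task),
            class = "timecourse_set")
}

#' HRF-convolved task-versus-baseline regressor
#'
#' Occupancy boxcar of all experimental blocks, convolved with the canonical
#' HRF at the TR, concatenated over runs; used both by the time-course
#' generator (as the shared task component) and by the connectivity
#' preprocessing (as the task regressor to remove).
#'
#' @param schedule A `run_schedule`.
#' @param tr Repetition time in seconds.
#' @param n_runs Number of concatenated runs.
#' @return Numeric vector of length `ceiling(duration / tr) * n_runs`.
#' @export
task_regressor <- function(schedule, tr = 3, n_runs = 1) {
  n_vol_run <- ceiling(schedule_duration(schedule) / tr)
  box <- block_occupancy(schedule, n_vol_run, tr,
                         schedule$kind == "experimental")
  h <- canonical_hrf(seq(0, 30, by = tr))
  run <- stats::convolve(box, rev(h), type = "open")[seq_len(n_vol_run)]
  rep(run, n_runs)
}

# slow random-walk motion: 3 translations (mm), 3 rotations (rad)
generate_motion <- function(n_vol, walk_sd = 0.02) {
  m <- apply(matrix(rnorm(n_vol * 6, sd = walk_sd), n_vol, 6), 2, cumsum)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m[, 4:6] <- m[, 4:6] / 50          # rotations an order smaller, in radians
  m
}

#' Generate a toy volumetric pattern set for searchlight tests
#'
#' A small 3-D grid holding per-run, per-condition voxel values: pure
#' Gaussian noise everywhere except inside the specified spherical clusters,
#' where condition prototypes separated by `separation` are added.  A brain
#' mask (all `TRUE` by default) is emitted alongside.
#'
#' @param grid_shape Integer length-3 grid dimensions (kept small, <= 30^3).
#' @param clusters List of clusters, each a list with `center` (length-3
#'   integer), `radius` (voxels) and `separation` (prototype distance).
#' @param n_runs,n_conditions Runs and conditions to simulate.
#' @param noise_sd Noise standard deviation.
#' @param mask Optional logical array of `grid_shape`; default all `TRUE`.
#' @param seed Integer seed.
#' @return A `toy_volume`: list with `data` (array `x,y,z,run,condition`),
#'   `mask`, `clusters`, and condition labels.
#' @export
generate_toy_volume <- function(grid_shape = c(12, 12, 12), clusters = list(),
                                n_runs = 6, n_conditions = 4, noise_sd = 1,
                                mask = NULL, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            prod(grid_shape) <= 30^3)
  set.seed(derive_seed(seed, "toy_volume"))
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  stopifnot(all(dim(mask) == grid_shape))
  conds <- paste0("cond_", seq_len(n_conditions))
  data <- array(rnorm(prod(grid_shape) * n_runs * n_conditions, sd = noise_sd),
                dim = c(grid_shape, n_runs, n_conditions))
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  for (cl in clusters) {
    stopifnot(length(cl$center) == 3)
    if (any(cl$center < 1) || any(cl$center > grid_shape)) {
      stop(sprintf("cluster center (%s) lies outside the grid",
                   paste(cl$center, collapse = ",")))
    }
    d2 <- rowSums(sweep(coords, 2, cl$center)^2)
    inside <- which(d2 <= cl$radius^2)
    nv <- length(inside)
    if (nv < n_conditions) {
      stop(sprintf("cluster at (%s) covers %d voxels; need >= %d conditions",
                   paste(cl$center, collapse = ","), nv, n_conditions))
    }
    Q <- qr.Q(qr(matrix(rnorm(nv * n_conditions), nv, n_conditions)))
    proto <- t(Q) * (cl$separation / sqrt(2))   # n_conditions x nv
    for (run in seq_len(n_runs)) {
      for (ci in seq_len(n_conditions)) {
        idx <- cbind(coords[inside, , drop = FALSE], run, ci)
        data[idx] <- data[idx] + proto[ci, ]
      }
    }
  }
  structure(list(data = data, mask = mask, clusters = clusters,
                 conditions = conds), class = "toy_volume")
}

#' Generate a synthetic diffusion tract-metric table
#'
#' Per subject and tract, draws FA / MD / AD / RD values around plausible
#' white-matter means, optionally shifting a metric in one group for selected
#' tracts (to exercise the group tests).
#'
#' @param n_per_group Subjects per group.
#' @param tracts Tract names.
#' @param effect Optional list with `tract`, `metric`, `shift` (added to the
#'   second group's values for that tract/metric).
#' @param groups Group labels.
#' @param seed Integer seed.
#' @return Data frame: `subject`, `group`, `tract`, `FA`, `MD`, `AD`, `RD`.
#' @export
generate_tract_table <- function(n_per_group = 22,
                                 tracts = c("CC_genu", "CC_splenium",
                                            "IFOF_L", "IFOF_R", "ILF_L",
                                            "ILF_R", "AF_FTP_L", "AF_FTP_R",
                                            "AF_TP_L", "AF_TP_R"),
                                 effect = NULL,
                                 groups = c("control", "dyscalculia"),
                                 seed = 1L) {
  set.seed(derive_seed(seed, "dti"))
  rows <- list()
  for (g in groups) {
    for (s in seq_len(n_per_group)) {
      fa <- pmin(pmax(rnorm(length(tracts), 0.45, 0.04), 0.05), 0.95)
      md <- rnorm(length(tracts), 0.80, 0.05) * 1e-3
      ad <- md * (1 + 2 * fa / 3)
      rd <- pmax(md * (1 - fa / 3), 1e-5)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("%s_%02d", g, s), group = g, tract = tracts,
        FA = fa, MD = md, AD = ad, RD = rd, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(effect)) {
    sel <- tab$group == groups[2] & tab$tract == effect$tract
    tab[sel, effect$metric] <- tab[sel, effect$metric] + effect$shift
  }
  rownames(tab) <- NULL
  tab
}
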