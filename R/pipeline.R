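#' Configuration for an end-to-end synthetic-cohort run
#'
#' @param spec A [cohort_spec()] describing the cohort to simulate.
#' @param stages Character vector of stages to run, from
#'   `c("simulate", "decode", "classify", "connectivity", "summary")`.
#' @param cv_repeats Decoding cross-validation repeats per subject.
#' @param classify_repeats LPOCV repeats for subject classification.
#' @param n_permutations Permutations for the subject-classification test.
#' @param lpocv_repeats LPOCV repeats inside each permutation.
#' @param alpha Significance level for the gated hierarchy.
#' @param region Region used for decoding and classification.
#' @param seed Global seed (propagated to every stochastic stage).
#' @param out_dir Optional output directory; results and a config snapshot
#'   are written there as TSV/JSON.
#' @return A `run_config`.
#' @export
run_config <- function(spec = cohort_spec(),
                       stages = c("simulate", "decode", "classify",
                                  "connectivity", "summary"),
                       cv_repeats = 20, classify_repeats = 50,
                       n_permutations = 200, lpocv_repeats = 5,
                       alpha = 0.05, region = NULL, seed = 1L,
                       out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(region)) region <- names(spec$voxels_per_roi)[1]
  structure(list(spec = spec, stages = stages, cv_repeats = cv_repeats,
                 classify_repeats = classify_repeats,
                 n_permutations = n_permutations,
                 lpocv_repeats = lpocv_repeats, alpha = alpha,
                 region = region, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate the cohort
#' (schedules, patterns, time courses), ROI decoding with a root-level gated
#' group test per format, subject classification with a permutation test,
#' the seed connectivity pipeline with edge-wise group tests, and a summary.
#' Rerunning with the same config and seed reproduces every number; if
#' `out_dir` is set, tables are written as TSV plus a JSON config snapshot
#' stamped with the seed and package version.
#'
#' @param config A [run_config()].
#' @return A named list of stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  spec$seed <- derive_seed(config$seed, "cohort")
  res <- list(seed = config$seed,
              version = as.character(utils::packageVersion("numdecode")))

  schedule <- generate_run_schedule(spec$design,
                                    seed = derive_seed(config$seed, "schedule"))
  res$schedule <- schedule
  if ("simulate" %in% config$stages) {
    res$patterns <- generate_condition_patterns(spec)
    res$timecourses <- generate_roi_time_courses(spec, schedule)
  }

  if ("decode" %in% config$stages) {
    if (is.null(res$patterns)) stop("stage 'decode' needs stage 'simulate'")
    acc <- cohort_within_format_accuracy(
      res$patterns, config$region,
      cv = cv_spec(n_repeats = config$cv_repeats,
                   seed = derive_seed(config$seed, "decode")))
    res$decoding <- acc
    root <- roi_hierarchy(data.frame(name = config$region, level = 1L,
                                     parent = NA_character_))
    res$decoding_tests <- do.call(rbind, lapply(
      unique(acc$format), function(f) {
        af <- acc[acc$format == f, ]
        vals <- matrix(af$accuracy, nrow = 1,
                       dimnames = list(config$region, af$subject))
        out <- gated_level_test(root, vals, af$group, alpha = config$alpha)
        out$format <- f
        out
      }))
  }

  if ("classify" %in% config$stages) {
    if (is.null(res$patterns)) stop("stage 'classify' needs stage 'simulate'")
    # subject features: mean pattern across conditions of each format
    conds <- res$patterns$conditions
    res$classification <- lapply(unique(conds$format), function(f) {
      sel <- which(conds$format == f)
      feats <- t(sapply(res$patterns$subjects, function(s) {
        apply(s$patterns[[config$region]][, sel, , drop = FALSE], 3, mean)
      }))
      groups <- vapply(res$patterns$subjects, `[[`, "", "group")
      permutation_test(feats, groups,
                       n_permutations = config$n_permutations,
                       lpocv_repeats = config$lpocv_repeats,
                       seed = derive_seed(config$seed, paste0("classify/", f)))[
                         c("observed", "p")]
    })
    names(res$classification) <- unique(conds$format)
  }

  if ("connectivity" %in% config$stages) {
    if (is.null(res$timecourses)) stop("stage 'connectivity' needs stage 'simulate'")
    tcs <- res$timecourses
    zs <- lapply(tcs$subjects, function(s) {
      connectivity_pipeline(s$ts, s$motion, task = tcs$task, tr = tcs$tr)$z
    })
    groups <- vapply(tcs$subjects, `[[`, "", "group")
    res$connectivity <- group_connectivity_tests(
      zs[groups == spec$groups[1]], zs[groups == spec$groups[2]])
  }

  if ("summary" %in% config$stages) {
    res$summary <- list(
      n_subjects = 2 * spec$n_per_group,
      run_duration_s = schedule_duration(schedule),
      stages = config$stages)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_schedule_tsv(schedule, file.path(config$out_dir, "schedule.tsv"))
    if (!is.null(res$decoding)) {
      utils::write.table(res$decoding,
                         file.path(config$out_dir, "decoding_accuracy.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$decoding_tests,
                         file.path(config$out_dir, "decoding_group_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$connectivity)) {
      utils::write.table(res$connectivity$between,
                         file.path(config$out_dir, "connectivity_between.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    snap <- list(seed = config$seed, version = res$version,
                 stages = config$stages,
                 n_per_group = spec$n_per_group, n_runs = spec$n_runs,
                 cv_repeats = config$cv_repeats, alpha = config$alpha)
    jsonlite::write_json(snap, file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(res$classification)) {
      jsonlite::write_json(res$classification,
                           file.path(config$out_dir, "classification.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  res
}
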