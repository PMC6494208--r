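#' Experiment design for a numerosity comparison block run
#'
#' Describes the short-block design of the scanning experiment: 4 numerosities
#' (2, 4, 6, 8) crossed with 2 presentation formats (symbolic digits,
#' non-symbolic dot arrays) give 8 conditions, each shown in 6 short blocks of
#' 4, 5 or 6 s per run.  Runs open and close with an 8-s fixation block and an
#' additional fixation block follows every 8th experimental block.
#'
#' Block durations are balanced so that each condition's blocks sum to
#' `blocks_per_condition * mean(block_durations)` seconds and the interleaved
#' fixation blocks sum to `interleaved_total` seconds, which pins the total run
#' length (280 s under the defaults: 2 x 8 + 48 x 5 + 24).
#'
#' @param numerosities Integer vector of magnitudes shown.
#' @param formats Character vector of presentation formats.
#' @param blocks_per_condition Number of blocks per condition per run.
#' @param block_durations Allowed experimental block durations in seconds.
#' @param trial_duration Duration of one trial in seconds.
#' @param stim_on Stimulus-on time within a trial in seconds.
#' @param boundary_fixation Duration of the opening/closing fixation blocks (s).
#' @param n_interleaved_fixation Number of fixation blocks interleaved between
#'   experimental blocks.
#' @param interleaved_total Total seconds allotted to interleaved fixation.
#' @param tr Repetition time of the acquisition in seconds.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design()
#' d$n_conditions       # 8
#' run_length(d)        # 280
#' @export
experiment_design <- function(numerosities = c(2, 4, 6, 8),
                              formats = c("symbolic", "nonsymbolic"),
                              blocks_per_condition = 6,
                              block_durations = c(4, 5, 6),
                              trial_duration = 1,
                              stim_on = 0.2,
                              boundary_fixation = 8,
                              n_interleaved_fixation = 5,
                              interleaved_total = 24,
                              tr = 3) {
  stopifnot(length(numerosities) >= 1, length(formats) >= 1,
            blocks_per_condition >= 0, all(block_durations > 0),
            trial_duration > 0, stim_on > 0, stim_on <= trial_duration,
            boundary_fixation > 0, n_interleaved_fixation >= 0,
            interleaved_total >= 0, tr > 0)
  if (any(block_durations %% trial_duration != 0)) {
    stop("every block duration must be an integer number of trials")
  }
  conditions <- expand.grid(numerosity = numerosities, format = formats,
                            stringsAsFactors = FALSE)
  conditions$condition <- paste(substr(conditions$format, 1, 3),
                                conditions$numerosity, sep = "_")
  conditions <- conditions[, c("condition", "format", "numerosity")]
  structure(list(
    conditions = conditions,
    n_conditions = nrow(conditions),
    blocks_per_condition = blocks_per_condition,
    block_durations = sort(block_durations),
    trial_duration = trial_duration,
    stim_on = stim_on,
    boundary_fixation = boundary_fixation,
    n_interleaved_fixation = n_interleaved_fixation,
    interleaved_total = interleaved_total,
    tr = tr
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Block-design numerosity experiment\n")
  cat(sprintf("  %d conditions (%d numerosities x %d formats), %d blocks each\n",
              x$n_conditions, length(unique(x$conditions$numerosity)),
              length(unique(x$conditions$format)), x$blocks_per_condition))
  cat(sprintf("  block durations {%s} s, TR %g s, run length %g s\n",
              paste(x$block_durations, collapse = ","), x$tr, run_length(x)))
  invisible(x)
}

#' Target run length implied by a design
#'
#' @param design An [experiment_design()].
#' @return Run length in seconds.
#' @export
run_length <- function(design) {
  n_exp <- design$n_conditions * design$blocks_per_condition
  exp_total <- design$blocks_per_condition * mean(design$block_durations) *
    design$n_conditions
  inter <- if (n_exp > 0) design$interleaved_total else 0
  2 * design$boundary_fixation + exp_total + inter
}

# Find a multiset of `n` values from `choices` summing to `target`.
# Exhaustive depth-first search over non-decreasing sequences; n is small
# (<= blocks per condition) so this is instantaneous.
balanced_multiset <- function(n, choices, target) {
  choices <- sort(unique(choices))
  if (n == 0) {
    if (target == 0) return(numeric(0)) else return(NULL)
  }
  recurse <- function(n, target, lo) {
    if (n == 0) return(if (target == 0) numeric(0) else NULL)
    for (c in choices[choices >= lo]) {
      rem <- target - c
      if (rem < (n - 1) * choices[1] || rem > (n - 1) * choices[length(choices)])
        next
      sol <- recurse(n - 1, rem, c)
      if (!is.null(sol)) return(c(c, sol))
    }
    NULL
  }
  recurse(n, target, choices[1])
}

#' Generate one run schedule
#'
#' Lays out a single experimental run: an 8-s fixation block at the start and
#' end, `blocks_per_condition` blocks of every condition in seeded random
#' order, and one interleaved fixation block after every 8th experimental
#' block.  Experimental block durations are balanced per condition (each
#' condition's blocks sum to the same total) and interleaved fixation
#' durations are balanced so the run hits the design's target length exactly.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return A `run_schedule`: a data frame with columns `kind`
#'   (`"experimental"`/`"fixation"`), `condition` (`NA` for fixation),
#'   `onset_s` and `duration_s`, with the design attached as an attribute.
#' @examples
#' sch <- generate_run_schedule(experiment_design(), seed = 1)
#' sum(sch$duration_s)                       # 280
#' table(sch$kind)                           # 48 experimental, 7 fixation
#' @export
generate_run_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(as.integer(seed))

  b <- design$blocks_per_condition
  per_cond_total <- b * mean(design$block_durations)
  if (per_cond_total != round(per_cond_total)) {
    stop("blocks_per_condition x mean block duration is not an integer; ",
         "durations cannot be balanced")
  }
  base_ms <- balanced_multiset(b, design$block_durations, per_cond_total)
  if (is.null(base_ms)) {
    stop(sprintf(
      "cannot balance %d blocks from durations {%s} to a per-condition total of %g s",
      b, paste(design$block_durations, collapse = ","), per_cond_total))
  }

  n_exp <- design$n_conditions * b
  blocks <- data.frame(kind = character(0), condition = character(0),
                       duration_s = numeric(0), stringsAsFactors = FALSE)

  if (n_exp > 0) {
    # per-condition balanced durations, shuffled within condition
    durs <- lapply(seq_len(design$n_conditions),
                   function(i) sample(base_ms, length(base_ms)))
    cond_labels <- design$conditions$condition
    # order of the 48 experimental blocks: seeded permutation of the
    # condition sequence (6 copies of each condition)
    order_idx <- sample(rep(seq_len(design$n_conditions), each = b))
    taken <- integer(design$n_conditions)
    exp_blocks <- data.frame(
      kind = "experimental",
      condition = cond_labels[order_idx],
      duration_s = vapply(order_idx, function(ci) {
        taken[ci] <<- taken[ci] + 1L
        durs[[ci]][taken[ci]]
      }, numeric(1)),
      stringsAsFactors = FALSE)

    inter_ms <- balanced_multiset(design$n_interleaved_fixation,
                                  design$block_durations,
                                  design$interleaved_total)
    if (is.null(inter_ms)) {
      stop(sprintf(
        "cannot balance %d interleaved fixation blocks from {%s} to %g s",
        design$n_interleaved_fixation,
        paste(design$block_durations, collapse = ","),
        design$interleaved_total))
    }
    inter_ms <- sample(inter_ms, length(inter_ms))

    # insert an interleaved fixation after every 8th experimental block
    # (never after the final one, which is followed by the closing fixation)
    rows <- list()
    k <- 0L
    for (i in seq_len(n_exp)) {
      rows[[length(rows) + 1L]] <- exp_blocks[i, ]
      if (i %% 8 == 0 && i < n_exp && k < length(inter_ms)) {
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "fixation", condition = NA_character_,
          duration_s = inter_ms[k], stringsAsFactors = FALSE)
      }
    }
    blocks <- do.call(rbind, rows)
  }

  boundary <- data.frame(kind = "fixation", condition = NA_character_,
                         duration_s = design$boundary_fixation,
                         stringsAsFactors = FALSE)
  blocks <- rbind(boundary, blocks, boundary)
  blocks$onset_s <- cumsum(c(0, blocks$duration_s[-nrow(blocks)]))
  blocks <- blocks[, c("kind", "condition", "onset_s", "duration_s")]
  rownames(blocks) <- NULL
  attr(blocks, "design") <- design
  class(blocks) <- c("run_schedule", "data.frame")
  blocks
}

#' Total duration of a schedule
#' @param schedule A `run_schedule`.
#' @return Sum of all block durations in seconds.
#' @export
schedule_duration <- function(schedule) sum(schedule$duration_s)

#' Write / read a run schedule as TSV
#'
#' Columns: `kind`, `condition`, `onset_s`, `duration_s`.
#'
#' @param schedule A `run_schedule`.
#' @param path File path.
#' @return `read_schedule_tsv` returns a `run_schedule` (without the design
#'   attribute); `write_schedule_tsv` returns `path` invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  df$condition <- as.character(df$condition)
  class(df) <- c("run_schedule", "data.frame")
  df
}
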