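#' Define a subject-level ROI from an anatomical mask and a localizer map
#'
#' Intersects the anatomical mask with the voxels whose localizer t-statistic
#' exceeds the one-sided uncorrected threshold (`p < 0.001` by default,
#' against a t distribution with `df` degrees of freedom).  An empty result is
#' allowed: the ROI is then undefinable in that subject.
#'
#' @param anatomical_mask Logical array (or vector) of voxels in the mask.
#' @param localizer_map Numeric array of the same shape: localizer
#'   task-minus-fixation t-statistics.
#' @param p_threshold One-sided uncorrected p threshold.
#' @param df Degrees of freedom of the localizer statistic.
#' @return Sorted integer indices (into the flattened grid) of the ROI
#'   voxels, with attribute `definable` (`TRUE` if non-empty).
#' @export
define_roi <- function(anatomical_mask, localizer_map, p_threshold = 0.001,
                       df = 100) {
  if (!all(dim2(anatomical_mask) == dim2(localizer_map))) {
    stop(sprintf("grid mismatch: mask is %s, localizer map is %s",
                 paste(dim2(anatomical_mask), collapse = "x"),
                 paste(dim2(localizer_map), collapse = "x")))
  }
  thr <- qt(1 - p_threshold, df)
  idx <- sort(which(as.logical(anatomical_mask) &
                      as.numeric(localizer_map) > thr))
  attr(idx, "definable") <- length(idx) > 0
  idx
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Construct an ROI hierarchy
#'
#' A tree of named regions over (up to) four spatial scales: the whole
#' cortex root, lobes, regions, and intraparietal-sulcus subparts.  Each
#' non-root node names its parent; validation enforces a single root and
#' existing parents with strictly smaller levels.
#'
#' @param nodes Data frame with columns `name`, `level` (integer, 1 = root)
#'   and `parent` (`NA` for the root).
#' @param voxels Optional nested list `voxels[[node]][[subject]]` of voxel
#'   index vectors.
#' @return An object of class `roi_hierarchy` with empty `excluded` table.
#' @export
roi_hierarchy <- function(nodes, voxels = NULL) {
  stopifnot(all(c("name", "level", "parent") %in% names(nodes)))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$name)) stop("node names must be unique")
  roots <- nodes$name[is.na(nodes$parent)]
  if (length(roots) != 1) {
    stop(sprintf("hierarchy must have exactly one root; found %d", length(roots)))
  }
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (is.na(p)) next
    j <- match(p, nodes$name)
    if (is.na(j)) stop(sprintf("parent '%s' of '%s' not in hierarchy",
                               p, nodes$name[i]))
    if (nodes$level[j] >= nodes$level[i]) {
      stop(sprintf("node '%s' (level %d) must have a parent at a lower level",
                   nodes$name[i], nodes$level[i]))
    }
  }
  if (!is.null(voxels)) {
    # nesting: child voxels must lie inside the parent's, per subject
    for (i in seq_len(nrow(nodes))) {
      p <- nodes$parent[i]
      if (is.na(p) || is.null(voxels[[nodes$name[i]]])) next
      for (s in seq_along(voxels[[nodes$name[i]]])) {
        child <- voxels[[nodes$name[i]]][[s]]
        par <- voxels[[p]][[s]]
        if (!all(child %in% par)) {
          stop(sprintf("voxels of '%s' are not nested in parent '%s' (subject %d)",
                       nodes$name[i], p, s))
        }
      }
    }
  }
  structure(list(nodes = nodes, voxels = voxels,
                 excluded = data.frame(name = character(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)),
            class = "roi_hierarchy")
}

#' The study's four-level ROI hierarchy
#'
#' Root "all_regions"; four lobes; eleven level-III regions (fusiform gyrus,
#' inferior/superior frontal gyri, inferior occipital cortex, superior
#' occipital gyrus, primary visual cortex, supramarginal gyrus, angular
#' gyrus, inferior/superior parietal lobules, IPS); and four IPS subparts
#' (left/right anterior/posterior).
#'
#' @return An `roi_hierarchy`.
#' @export
default_roi_hierarchy <- function() {
  nodes <- rbind(
    data.frame(name = "all_regions", level = 1L, parent = NA_character_),
    data.frame(name = c("frontal", "parietal", "temporal", "occipital"),
               level = 2L, parent = "all_regions"),
    data.frame(name = c("IFG", "SFG"), level = 3L, parent = "frontal"),
    data.frame(name = c("SMG", "AG", "IPL", "SPL", "IPS"),
               level = 3L, parent = "parietal"),
    data.frame(name = "FG", level = 3L, parent = "temporal"),
    data.frame(name = c("IOC", "SOG", "PVC"), level = 3L, parent = "occipital"),
    data.frame(name = c("IPS_LA", "IPS_RA", "IPS_LP", "IPS_RP"),
               level = 4L, parent = "IPS")
  )
  roi_hierarchy(nodes)
}

#' @export
print.roi_hierarchy <- function(x, ...) {
  cat(sprintf("roi_hierarchy: %d nodes over levels %s; %d excluded\n",
              nrow(x$nodes),
              paste(range(x$nodes$level), collapse = "-"),
              nrow(x$excluded)))
  invisible(x)
}

#' Exclude ROIs undefinable in too many subjects
#'
#' A node that could not be defined (empty voxel set) in at least
#' `min_undefined` subjects is moved to the hierarchy's excluded list and
#' never tested.  Subjects lacking a retained ROI are skipped for that ROI
#' only, downstream.
#'
#' @param hierarchy An `roi_hierarchy`.
#' @param definable Logical matrix, nodes x subjects (rownames = node names):
#'   `TRUE` where the ROI is definable in that subject.
#' @param min_undefined Exclusion threshold (subjects).
#' @return The hierarchy with its `excluded` table filled in.
#' @export
exclude_undefinable <- function(hierarchy, definable, min_undefined = 5) {
  stopifnot(inherits(hierarchy, "roi_hierarchy"), is.matrix(definable))
  missing_rows <- setdiff(rownames(definable), hierarchy$nodes$name)
  if (length(missing_rows) > 0) {
    stop("definable matrix has unknown nodes: ",
         paste(missing_rows, collapse = ", "))
  }
  n_undef <- rowSums(!definable)
  out <- names(n_undef)[n_undef >= min_undefined]
  if (length(out) > 0) {
    hierarchy$excluded <- rbind(
      hierarchy$excluded,
      data.frame(name = out,
                 reason = sprintf("undefinable in %d subjects (threshold %d)",
                                  n_undef[out], min_undefined),
                 stringsAsFactors = FALSE))
  }
  hierarchy
}

#' Retained seed regions at one hierarchy level
#'
#' @param hierarchy An `roi_hierarchy` (after [exclude_undefinable()]).
#' @param level Hierarchy level.
#' @return Character vector of retained node names at that level.
#' @export
seeds_at_level <- function(hierarchy, level = 3) {
  setdiff(hierarchy$nodes$name[hierarchy$nodes$level == level],
          hierarchy$excluded$name)
}

#' Mean contrast value within an ROI
#'
#' @param contrast_map Numeric array/vector of per-voxel contrast values for
#'   one subject.
#' @param roi Integer voxel indices (e.g. from [define_roi()]).
#' @return Mean over the ROI voxels, or `NA` with status "skipped" attribute
#'   if the ROI is empty.
#' @export
univariate_roi_stat <- function(contrast_map, roi) {
  if (length(roi) == 0) {
    return(structure(NA_real_, status = "skipped"))
  }
  mean(as.numeric(contrast_map)[roi])
}

#' Gated level-wise FDR group test over an ROI hierarchy
#'
#' Tests the root with a two-sided two-sample t-test; descends a level only
#' below nodes whose FDR-adjusted p falls under `alpha`, applying
#' Benjamini-Hochberg correction across the nodes actually tested at each
#' level.  Children of non-significant (or untested) parents are reported as
#' "not tested"; excluded nodes are never tested.
#'
#' @param hierarchy An `roi_hierarchy`.
#' @param values Numeric matrix nodes x subjects (rownames = node names);
#'   `NA` marks a subject lacking that ROI.
#' @param groups Factor/character of group labels (length = subjects, two
#'   levels).
#' @param alpha Significance level applied to adjusted p-values.
#' @return A data frame `node, level, parent, t, df, p, p_fdr, status` with
#'   status in `significant`, `not significant`, `not tested`, `excluded`,
#'   `skipped`.
#' @export
gated_level_test <- function(hierarchy, values, groups, alpha = 0.05) {
  stopifnot(inherits(hierarchy, "roi_hierarchy"), is.matrix(values))
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, ncol(values) == length(groups))
  nodes <- hierarchy$nodes
  res <- data.frame(node = nodes$name, level = nodes$level,
                    parent = nodes$parent, t = NA_real_, df = NA_real_,
                    p = NA_real_, p_fdr = NA_real_,
                    status = "not tested", stringsAsFactors = FALSE)
  res$status[res$node %in% hierarchy$excluded$name] <- "excluded"

  sig <- character(0)
  for (lev in sort(unique(nodes$level))) {
    at <- which(res$level == lev & res$status != "excluded")
    testable <- at[vapply(at, function(i) {
      is.na(res$parent[i]) || res$parent[i] %in% sig
    }, logical(1))]
    if (length(testable) == 0) next
    for (i in testable) {
      v <- values[res$node[i], ]
      ok <- !is.na(v)
      a <- v[ok & groups == levels(groups)[1]]
      b <- v[ok & groups == levels(groups)[2]]
      if (length(a) < 2 || length(b) < 2) {
        res$status[i] <- "skipped"
        next
      }
      tt <- two_sample_t(a, b)
      res$t[i] <- tt$t; res$df[i] <- tt$df; res$p[i] <- tt$p
      res$status[i] <- "tested"
    }
    tested <- which(res$level == lev & res$status == "tested")
    if (length(tested) > 0) {
      res$p_fdr[tested] <- p.adjust(res$p[tested], method = "BH")
      is_sig <- res$p_fdr[tested] < alpha
      res$status[tested] <- ifelse(is_sig, "significant", "not significant")
      sig <- c(sig, res$node[tested][is_sig])
    }
  }
  res
}

# pooled-variance two-sided two-sample t-test on raw samples
two_sample_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  if (se == 0) {
    t <- if (mean(a) == mean(b)) 0 else NA_real_
    p <- if (mean(a) == mean(b)) 1 else NA_real_
    return(list(t = t, df = df, p = p))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
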