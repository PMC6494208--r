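#' Group summary statistics
#'
#' @param mean,sd,n Sample mean, standard deviation (> 0) and size (>= 2).
#' @return A `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(sd > 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = n), class = "group_summary")
}

#' Two-sided two-sample t-test from summary statistics
#'
#' Pooled-variance t with `df = n1 + n2 - 2`, as used for all group
#' comparisons (behavioral measures, accuracies, connectivity, DTI metrics).
#'
#' @param a,b [group_summary()] objects.
#' @return List with `t`, `df`, `p`.
#' @examples
#' two_sample_t_summary(group_summary(35.00, 7.97, 24),
#'                      group_summary(54.50, 15.86, 24))  # |t| = 5.38
#' @export
two_sample_t_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- (a$mean - b$mean) / se
  df <- a$n + b$n - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohen's d from summary statistics
#'
#' `d = (mean_a - mean_b) / s_pooled`; for equal group sizes the pooled SD
#' reduces to `sqrt((sd_a^2 + sd_b^2) / 2)`.
#'
#' @param a,b [group_summary()] objects.
#' @return Cohen's d.
#' @export
cohens_d_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  if (sp == 0) stop("zero pooled SD")
  (a$mean - b$mean) / sp
}

#' Two-way between-observations ANOVA (group x format)
#'
#' The behavioral analysis treats each subject's score in each format as an
#' independent observation, giving the (1, 92) degrees-of-freedom layout for
#' 48 subjects x 2 formats.  Fitted with `stats::aov` on
#' `score ~ group * format`.
#'
#' @param data Data frame with columns `group`, `format`, `score` (>= 2
#'   observations per cell).
#' @return Data frame with rows `group`, `format`, `group:format` and
#'   columns `F`, `df1`, `df2`, `p`.
#' @export
anova_2x2 <- function(data) {
  stopifnot(all(c("group", "format", "score") %in% names(data)))
  data$group <- factor(data$group)
  data$format <- factor(data$format)
  cells <- table(data$group, data$format)
  if (any(cells < 2)) stop("every group x format cell needs >= 2 observations")
  fit <- aov(score ~ group * format, data = data)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  df2 <- s[terms == "Residuals", "Df"]
  out <- data.frame(term = terms[keep], F = s[keep, "F value"],
                    df1 = s[keep, "Df"], df2 = df2,
                    p = s[keep, "Pr(>F)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  # degenerate data with no variance at all: every F ratio is 0/0; report 0
  tot_ss <- sum(s[, "Sum Sq"])
  if (is.nan(tot_ss) || tot_ss <= 1e-20 * max(1, sum(data$score^2)) ||
      anyNA(out$F)) {
    degenerate <- is.na(out$F) | tot_ss <= 1e-20 * max(1, sum(data$score^2))
    out$F[degenerate] <- 0
    out$p[degenerate] <- 1
  }
  out
}

#' Group comparison of diffusion tract metrics
#'
#' Two-sided pooled two-sample t-tests per tract for each metric (FA, MD,
#' AD, RD), with BH-FDR correction applied across tracts within each metric
#' (one correction family per metric; set `family = "all"` to correct across
#' all tract x metric cells instead).  Subjects missing a tract are excluded
#' from that tract's tests, with a count.
#'
#' @param table Data frame with columns `subject`, `group`, `tract` and the
#'   metric columns.
#' @param metrics Metric column names.
#' @param family `"tracts"` (default: FDR across tracts within metric) or
#'   `"all"`.
#' @return Data frame `tract, metric, n_a, n_b, n_missing, t, df, p, p_fdr`.
#' @export
dti_group_compare <- function(table, metrics = c("FA", "MD", "AD", "RD"),
                              family = c("tracts", "all")) {
  family <- match.arg(family)
  stopifnot(all(c("subject", "group", "tract") %in% names(table)),
            all(metrics %in% names(table)))
  groups <- unique(table$group)
  if (length(groups) != 2) stop("table must contain exactly two groups")
  tracts <- unique(table$tract)
  rows <- list()
  for (m in metrics) {
    for (tr in tracts) {
      sub <- table[table$tract == tr, c("group", m)]
      ok <- !is.na(sub[[m]])
      a <- sub[[m]][ok & sub$group == groups[1]]
      b <- sub[[m]][ok & sub$group == groups[2]]
      if (length(a) < 2 || length(b) < 2) {
        stop(sprintf("tract '%s' lacks both groups for metric %s", tr, m))
      }
      tt <- two_sample_t(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        tract = tr, metric = m, n_a = length(a), n_b = length(b),
        n_missing = sum(!ok), t = tt$t, df = tt$df, p = tt$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (family == "tracts") {
    out$p_fdr <- NA_real_
    for (m in metrics) {
      sel <- out$metric == m
      out$p_fdr[sel] <- p.adjust(out$p[sel], "BH")
    }
  } else {
    out$p_fdr <- p.adjust(out$p, "BH")
  }
  rownames(out) <- NULL
  out
}
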