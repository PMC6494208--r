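# Small fixtures shared across test files.  Everything is generated in code;
# sizes are kept at desk scale.

tiny_cohort <- function(seed = 1, n_per_group = 2, n_runs = 6, voxels = 16,
                        separation = NULL) {
  cohort_spec(n_per_group = n_per_group, n_runs = n_runs,
              voxels_per_roi = c(all_regions = voxels),
              separation = separation, seed = seed)
}

# a separation table with one knob per (group, format)
sep_table <- function(sym_a, sym_b, non_a, non_b, region = "all_regions",
                      groups = c("control", "dyscalculia")) {
  df <- expand.grid(group = groups, region = region,
                    format = c("symbolic", "nonsymbolic"),
                    stringsAsFactors = FALSE)
  df$separation <- ifelse(df$format == "symbolic",
                          ifelse(df$group == groups[1], sym_a, sym_b),
                          ifelse(df$group == groups[1], non_a, non_b))
  df
}

# exhaustive Benjamini-Hochberg step-up oracle: find the largest k with
# p_(k) <= k/m * q by direct enumeration, then report adjusted p-values via
# the definitional min over thresholds
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- rank(p, ties.method = "first")[i]
    cand <- vapply(seq(k, m), function(j) m * sort(p)[j] / j, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# pooled two-sample t from raw data, written out longhand
t_oracle <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
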