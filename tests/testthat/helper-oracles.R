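# Independent oracles used across the suite. These deliberately use
# different algorithms from the package code paths they check.

# AUC as the tie-corrected rank statistic (Mann-Whitney form).
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Upper-hull membership by exhaustive chord checking: a point is off the
# hull iff it lies strictly below the segment joining some pair of other
# points (corners (0,0) and (1,1) included). O(n^3), small sets only.
hull_oracle <- function(points) {
  p <- unique(rbind(data.frame(fpr = c(0, 1), tpr = c(0, 1)), points))
  p <- p[order(p$fpr, p$tpr), ]
  n <- nrow(p)
  on_hull <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == i || b == i || p$fpr[a] >= p$fpr[b]) next
        if (p$fpr[i] >= p$fpr[a] && p$fpr[i] <= p$fpr[b]) {
          chord <- p$tpr[a] + (p$tpr[b] - p$tpr[a]) *
            (p$fpr[i] - p$fpr[a]) / (p$fpr[b] - p$fpr[a])
          if (p$tpr[i] < chord - 1e-12) on_hull[i] <- FALSE
        }
      }
    }
  }
  p[on_hull, ]
}

# Powerset filter used to cross-check enumerate_subsets().
powerset_subsets <- function(features, min_size, diagnostic,
                             require_diagnostic) {
  n <- length(features)
  out <- list()
  for (mask in seq_len(2^n) - 1L) {
    s <- features[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(s) < min_size) next
    if (require_diagnostic && !any(s %in% diagnostic)) next
    out[[length(out) + 1L]] <- s
  }
  out
}

# Canonical string form for set-of-subsets comparison.
subset_keys <- function(subsets) {
  sort(vapply(subsets, function(s) paste(sort(s), collapse = "|"),
              character(1)))
}

# Small two-cluster cohort: controls near low faq/high mmse, MCI opposite.
two_cluster_cohort <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    subject_id = sprintf("S%03d", seq_len(2 * n_per)),
    age = round(runif(2 * n_per, 60, 90), 1),
    yoe = sample(8:18, 2 * n_per, TRUE),
    mmse = c(sample(28:30, n_per, TRUE), sample(24:26, n_per, TRUE)),
    faq = c(sample(0:1, n_per, TRUE), sample(8:12, n_per, TRUE)),
    gds = sample(0:3, 2 * n_per, TRUE),
    label = rep(c(0L, 1L), each = n_per)
  )
  cohort(df, provenance = "synthetic")
}

write_toy_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
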