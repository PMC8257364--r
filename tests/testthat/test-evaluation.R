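test_that("confusion-matrix rates match hand-computed values", {
  cm <- confusion_matrix(tp = 27, fn = 3, tn = 39, fp = 7)
  expect_equal(100 * accuracy(cm), 86.84, tolerance = 5e-3)
  expect_equal(sensitivity(cm), 0.9)
  expect_equal(specificity(cm), 39 / 46)
  expect_equal(ppv(cm), 27 / 34)
  expect_equal(npv(cm), 39 / 42)

  ger <- confusion_matrix(tp = 17, fn = 13, tn = 43, fp = 3)
  expect_equal(100 * accuracy(ger), 78.95, tolerance = 5e-3)

  perfect <- confusion_matrix(10, 0, 10, 0)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)
  expect_equal(accuracy(perfect), 1)

  none <- confusion_matrix(0, 0, 5, 5)
  expect_error(sensitivity(none), "sensitivity")
  expect_error(npv(confusion_matrix(5, 0, 0, 5)), "npv")
})

test_that("confusion_from_rates agrees with a brute-force search", {
  # oracle: enumerate all integer count pairs consistent with the printed
  # 2-decimal percentages
  brute <- function(sen_pct, spc_pct, n_pos, n_neg) {
    tp <- which(vapply(0:n_pos, function(t) {
      sprintf("%.2f", 100 * t / n_pos) == sprintf("%.2f", sen_pct)
    }, logical(1))) - 1L
    tn <- which(vapply(0:n_neg, function(t) {
      sprintf("%.2f", 100 * t / n_neg) == sprintf("%.2f", spc_pct)
    }, logical(1))) - 1L
    c(tp = tp[1], tn = tn[1])
  }
  cases <- list(c(90.00, 84.78), c(23.33, 100.00), c(86.67, 71.74),
                c(83.33, 89.13), c(56.67, 93.48))
  for (cs in cases) {
    cm <- confusion_from_rates(cs[1] / 100, cs[2] / 100, 30, 46)
    expected <- brute(cs[1], cs[2], 30, 46)
    expect_equal(cm$tp, unname(expected["tp"]))
    expect_equal(cm$tn, unname(expected["tn"]))
  }
  expect_equal(unclass(confusion_from_rates(0.9, 0.8478, 30, 46))[c("tp", "fn", "tn", "fp")],
               list(tp = 27L, fn = 3L, tn = 39L, fp = 7L))
  expect_equal(confusion_from_rates(1, 1, 10, 10)$fp, 0L)
  expect_error(confusion_from_rates(0.8512, 0.5, 30, 46), "inconsistent")
})

test_that("rate -> count reconstruction is the identity on real matrices", {
  set.seed(42)
  for (i in 1:200) {
    n_pos <- sample(5:60, 1)
    n_neg <- sample(5:60, 1)
    tp <- sample(0:n_pos, 1)
    tn <- sample(0:n_neg, 1)
    cm <- confusion_matrix(tp, n_pos - tp, tn, n_neg - tn)
    back <- confusion_from_rates(sensitivity(cm), specificity(cm),
                                 n_pos, n_neg, digits = 12)
    expect_identical(unclass(back), unclass(cm))
  }
})

test_that("clinical utility indices and grades reproduce published rows", {
  best <- cui(confusion_matrix(27, 3, 39, 7))
  expect_equal(best$cui_plus, 0.7147, tolerance = 5e-5)
  expect_equal(best$cui_minus, 0.7873, tolerance = 5e-5)
  expect_equal(best$grade_plus, "good")
  expect_equal(best$grade_minus, "good")

  # 100% specificity rater: PPV convention makes CUI+ = sensitivity
  pcp1 <- cui(confusion_matrix(7, 23, 46, 0))
  expect_equal(pcp1$cui_plus, 7 / 30)

  perfect <- cui(confusion_matrix(10, 0, 10, 0))
  expect_equal(perfect$cui_plus, 1)
  expect_equal(perfect$cui_minus, 1)
  expect_equal(perfect$grade_plus, "excellent")

  expect_error(cui(confusion_matrix(0, 10, 10, 0)), "no predicted positives")
})

test_that("CUI grade boundaries sit at 0.81 / 0.64 / 0.49", {
  grade_of <- function(cp) {
    # build a matrix with sensitivity ~ sqrt(cp) on a large balanced sample
    cui(confusion_from_rates(cp, 1, 10000, 10,
                             digits = 12))$grade_plus
  }
  expect_equal(grade_of(0.81), "excellent")
  expect_equal(grade_of(0.8099), "good")
  expect_equal(grade_of(0.64), "good")
  expect_equal(grade_of(0.6399), "satisfactory")
  expect_equal(grade_of(0.49), "satisfactory")
  expect_equal(grade_of(0.4899), "poor")
})

test_that("cui_plus/minus never exceed their component rates", {
  set.seed(7)
  for (i in 1:100) {
    cm <- confusion_matrix(sample(1:30, 1), sample(0:20, 1),
                           sample(1:40, 1), sample(0:20, 1))
    ci <- cui(cm)
    p <- if (cm$fp == 0) 1 else ppv(cm)
    n <- if (cm$fn == 0) 1 else npv(cm)
    expect_lte(ci$cui_plus, min(sensitivity(cm), p) + 1e-12)
    expect_lte(ci$cui_minus, min(specificity(cm), n) + 1e-12)
  }
})

test_that("roc sweep enumerates the hand-checkable 4-record toy", {
  scores <- c(0.1, 0.4, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  curve <- roc_from_scores(scores, labels)
  expect_equal(curve$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(curve$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(auc(curve), 1)
  # balanced threshold: sen = spc = 1 at threshold 0.4
  expect_equal(balanced_threshold(curve), 0.4)
})

test_that("degenerate score distributions give chance/perfect curves", {
  all_equal <- roc_from_scores(rep(0.5, 8), rep(c(0, 1), 4))
  expect_equal(nrow(all_equal), 2L)
  expect_equal(auc(all_equal), 0.5)

  sep <- roc_from_scores(c(1, 2, 3, 11, 12, 13), rep(c(0, 1), each = 3))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  expect_equal(auc(sep), 1)
  expect_error(roc_from_scores(1:4, rep(1, 4)), "both classes")
})

test_that("convex hull drops dominated points and matches the chord oracle", {
  pts <- data.frame(fpr = c(0, 0.2, 0.4, 1), tpr = c(0, 0.4, 0.3, 1))
  hull <- convex_hull(pts)
  expect_false(any(hull$fpr == 0.4 & hull$tpr == 0.3))
  oracle <- hull_oracle(pts)
  expect_equal(hull$fpr, oracle$fpr)
  expect_equal(hull$tpr, oracle$tpr)
  expect_gte(auc(hull), auc(pts))

  expect_equal(auc(data.frame(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  expect_equal(auc(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1)
})

test_that("hull agrees with the chord oracle on random curves", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    curve <- roc_from_scores(round(runif(n), 2),
                             c(0, 1, sample(0:1, n - 2, TRUE)))
    hull <- convex_hull(curve)
    oracle <- hull_oracle(roc_points(curve))
    # same enclosed area (collinear points do not change it) ...
    oracle_area <- auc(rbind(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                             oracle[, c("fpr", "tpr")]))
    expect_equal(auc(hull), oracle_area, info = paste("curve", i))
    # ... and every hull vertex is chord-maximal (or the (0,0) corner)
    keys <- c("0/0", paste(oracle$fpr, oracle$tpr, sep = "/"))
    expect_true(all(paste(hull$fpr, hull$tpr, sep = "/") %in% keys),
                info = paste("curve", i))
    expect_gte(auc(hull), auc(curve))
  }
})

test_that("balanced threshold equalizes sensitivity and specificity", {
  # symmetric score distribution: the midpoint threshold balances rates
  scores <- c(1, 2, 3, 4, 6, 7, 8, 9)
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  th <- balanced_threshold(roc_from_scores(scores, labels))
  expect_gte(th, 4)
  expect_lt(th, 6)
  pred <- as.integer(scores > th)
  cm <- confusion_from_predictions(labels, pred)
  expect_equal(sensitivity(cm), specificity(cm))
})

test_that("single-scale cut-off search matches brute force", {
  # toy: all cases faq >= 1, all controls faq = 0 -> cut-off 0/1, perfect
  df <- data.frame(subject_id = sprintf("s%d", 1:12), age = 70, yoe = 12,
                   mmse = c(26:30, 24, 25, 27, 28, 29, 30, 26),
                   faq = c(rep(0, 6), c(1, 2, 3, 2, 5, 4)),
                   gds = rep(0:1, 6), label = rep(c(0L, 1L), each = 6))
  toy <- cohort(df)
  res <- best_scale_cutoff(toy, "faq")
  expect_equal(res$label, "0/1")
  expect_equal(accuracy(res$cm), 1)

  # orientation flip turns the perfect separator into its complement
  flipped <- best_scale_cutoff(toy, "faq", orientation = "lower-is-impaired")
  expect_lt(accuracy(flipped$cm), 0.6)

  # seeded synthetic cohort vs exhaustive brute force on accuracy
  coh <- generate_cohort(adni_like_spec(seed = 31))
  for (scale in c("faq", "mmse", "gds")) {
    hi <- scale != "mmse"
    v <- coh[[scale]]
    accs <- vapply(seq(min(v), max(v) - 1), function(cc) {
      pred <- if (hi) as.integer(v > cc) else as.integer(v <= cc)
      mean(pred == coh$label)
    }, numeric(1))
    res <- best_scale_cutoff(coh, scale)
    expect_equal(accuracy(res$cm), max(accs), info = scale)
  }
  expect_error(best_scale_cutoff(coh, "age"), "integer-valued")
  const <- toy
  expect_error(best_scale_cutoff(const, "age"), "constant scale")
})

test_that("pooled means reproduce the headline physician rates", {
  expect_equal(round(pooled_mean(c(86.67, 56.67, 23.33, 20.00)), 2), 46.67)
  expect_equal(round(pooled_mean(c(71.74, 93.48, 100.00, 100.00)), 2), 91.31)
  expect_equal(pooled_mean(5), 5)
  expect_error(pooled_mean(numeric(0)), "no values")
})
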