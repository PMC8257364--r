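#' Confusion matrix
#'
#' @param tp,fn,tn,fp Non-negative integer counts (true positives, false
#'   negatives, true negatives, false positives), with MCI as the positive
#'   class.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion matrix from observed and predicted labels
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return A [confusion_matrix()].
#' @export
confusion_from_predictions <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_matrix(tp = sum(truth == 1 & predicted == 1),
                   fn = sum(truth == 1 & predicted == 0),
                   tn = sum(truth == 0 & predicted == 0),
                   fp = sum(truth == 0 & predicted == 1))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fn=%d tn=%d fp=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

rate_or_stop <- function(num, den, metric) {
  if (den == 0) stop("undefined rate: ", metric, " has zero denominator",
                     call. = FALSE)
  num / den
}

#' Diagnostic rates from a confusion matrix
#'
#' Sensitivity (true positive rate), specificity (true negative rate),
#' accuracy, positive and negative predictive value. All are proportions in
#' `[0, 1]`; a zero denominator raises an error naming the metric.
#'
#' @param cm A [confusion_matrix()].
#' @return A proportion in `[0, 1]`.
#' @export
sensitivity <- function(cm) rate_or_stop(cm$tp, cm$tp + cm$fn, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(cm) rate_or_stop(cm$tn, cm$tn + cm$fp, "specificity")

#' @rdname sensitivity
#' @export
accuracy <- function(cm) {
  rate_or_stop(cm$tp + cm$tn, cm$tp + cm$fn + cm$tn + cm$fp, "accuracy")
}

#' @rdname sensitivity
#' @export
ppv <- function(cm) rate_or_stop(cm$tp, cm$tp + cm$fp, "ppv")

#' @rdname sensitivity
#' @export
npv <- function(cm) rate_or_stop(cm$tn, cm$tn + cm$fn, "npv")

#' Reconstruct a confusion matrix from printed rates
#'
#' Given a sensitivity and specificity printed at finite precision, and the
#' class sizes, recovers the integer confusion matrix: `tp = round(sen *
#' n_pos)`, `tn = round(spc * n_neg)`. The reconstruction is verified by
#' re-deriving the rates; inputs that no integer counts can produce raise
#' an error reporting the nearest consistent counts.
#'
#' @param sen,spc Rates as proportions in `[0, 1]`.
#' @param n_pos,n_neg Number of true positives/negatives in the sample.
#' @param digits Decimal digits at which the proportions were printed
#'   (4 corresponds to percentages at 2 decimals); the check tolerance is
#'   half a unit of that last digit.
#' @return A [confusion_matrix()].
#' @export
confusion_from_rates <- function(sen, spc, n_pos, n_neg, digits = 4) {
  stopifnot(sen >= 0, sen <= 1, spc >= 0, spc <= 1, n_pos >= 1, n_neg >= 1)
  tp <- round(sen * n_pos)
  tn <- round(spc * n_neg)
  tol <- 0.5 * 10^-digits
  if (abs(tp / n_pos - sen) > tol || abs(tn / n_neg - spc) > tol) {
    stop(sprintf(
      paste0("rates inconsistent with integer counts at %d digits; ",
             "nearest counts tp=%d/%d (%.6f), tn=%d/%d (%.6f)"),
      digits, tp, n_pos, tp / n_pos, tn, n_neg, tn / n_neg), call. = FALSE)
  }
  confusion_matrix(tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

cui_grade <- function(x) {
  if (x >= 0.81) "excellent" else if (x >= 0.64) "good"
  else if (x >= 0.49) "satisfactory" else "poor"
}

#' Clinical utility indices
#'
#' `CUI+ = sensitivity x PPV` grades rule-in accuracy and
#' `CUI- = specificity x NPV` grades rule-out accuracy, each mapped to a
#' qualitative grade: excellent >= 0.81, good >= 0.64, satisfactory >= 0.49,
#' poor below. When a classifier makes no false-positive calls but some true
#' positives, PPV is taken as 1 (and symmetrically NPV when fn = 0, tn > 0),
#' so a 100%-specificity rater still has a defined CUI+.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `cui_report` with elements `cui_plus`,
#'   `cui_minus`, `grade_plus`, `grade_minus`.
#' @export
cui <- function(cm) {
  sen <- sensitivity(cm)
  spc <- specificity(cm)
  if (cm$tp + cm$fp == 0) {
    stop("undefined cui_plus: no predicted positives", call. = FALSE)
  }
  if (cm$tn + cm$fn == 0) {
    stop("undefined cui_minus: no predicted negatives", call. = FALSE)
  }
  p <- if (cm$fp == 0 && cm$tp > 0) 1 else ppv(cm)
  n <- if (cm$fn == 0 && cm$tn > 0) 1 else npv(cm)
  cp <- sen * p
  cn <- spc * n
  structure(list(cui_plus = cp, cui_minus = cn,
                 grade_plus = cui_grade(cp), grade_minus = cui_grade(cn)),
            class = "cui_report")
}

#' @export
print.cui_report <- function(x, ...) {
  cat(sprintf("<cui_report> CUI+ %.4f (%s), CUI- %.4f (%s)\n",
              x$cui_plus, x$grade_plus, x$cui_minus, x$grade_minus))
  invisible(x)
}

new_roc_curve <- function(points, n_pos, n_neg) {
  structure(points, class = c("roc_curve", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

#' ROC curve from scores and labels
#'
#' Sweeps the decision threshold over every distinct score plus a sentinel
#' below the minimum (a record is called positive when its score is
#' strictly greater than the threshold), producing one
#' (1 - specificity, sensitivity) point per threshold. The resulting curve
#' always contains (0, 0) and (1, 1).
#'
#' @param scores Numeric scores (higher = more MCI-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return An object of class `roc_curve`: a data frame with columns
#'   `threshold`, `fpr`, `tpr`, ordered by decreasing threshold.
#' @export
roc_from_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes required for a ROC sweep", call. = FALSE)
  }
  thr <- c(sort(unique(scores), decreasing = TRUE), min(scores) - 1)
  pts <- vapply(thr, function(th) {
    pred <- scores > th
    c(fpr = sum(pred & labels == 0) / n_neg,
      tpr = sum(pred & labels == 1) / n_pos)
  }, numeric(2))
  new_roc_curve(data.frame(threshold = thr, fpr = pts["fpr", ],
                           tpr = pts["tpr", ]),
                n_pos = n_pos, n_neg = n_neg)
}

#' ROC sweep over the Grossberg threshold of a model
#'
#' @param model A `cpn_model`.
#' @param test Test [cohort()] with both classes.
#' @return A `roc_curve` (see [roc_from_scores()]).
#' @export
roc_sweep <- function(model, test) {
  roc_from_scores(cpn_score(model, test), test$label)
}

roc_points <- function(curve) {
  if (inherits(curve, "data.frame")) {
    data.frame(fpr = curve$fpr, tpr = curve$tpr)
  } else {
    stop("expected a roc_curve or data.frame with fpr/tpr", call. = FALSE)
  }
}

#' Area under a ROC curve
#'
#' Trapezoid rule over the curve's points sorted by false positive rate.
#'
#' @param curve A `roc_curve` (or data frame with `fpr`, `tpr` columns).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  p <- roc_points(curve)
  p <- p[order(p$fpr, p$tpr), , drop = FALSE]
  n <- nrow(p)
  if (n < 2L) return(0)
  sum(diff(p$fpr) * (p$tpr[-1] + p$tpr[-n]) / 2)
}

#' Upper convex hull of a ROC curve
#'
#' The hull over the curve's points together with (0, 0) and (1, 1). Hull
#' operating points are achievable by threshold randomization, and the hull
#' AUC always dominates the raw-curve AUC; it is the statistic feature
#' subsets are ranked by.
#'
#' @param curve A `roc_curve` or data frame with `fpr`, `tpr`.
#' @return A `roc_curve` containing only the hull vertices (thresholds are
#'   carried over where a vertex came from the sweep, `NA` for the
#'   injected corners).
#' @export
convex_hull <- function(curve) {
  p <- roc_points(curve)
  thr <- if (!is.null(curve$threshold)) curve$threshold else rep(NA_real_, nrow(p))
  p <- rbind(data.frame(fpr = c(0, 1), tpr = c(0, 1)), p)
  thr <- c(NA_real_, NA_real_, thr)
  keep <- !duplicated(p[, c("fpr", "tpr")])
  p <- p[keep, , drop = FALSE]
  thr <- thr[keep]
  ord <- order(p$fpr, p$tpr)
  p <- p[ord, , drop = FALSE]
  thr <- thr[ord]
  cross <- function(o, a, b) {
    (p$fpr[a] - p$fpr[o]) * (p$tpr[b] - p$tpr[o]) -
      (p$tpr[a] - p$tpr[o]) * (p$fpr[b] - p$fpr[o])
  }
  hull <- integer(0)
  for (i in seq_len(nrow(p))) {
    while (length(hull) >= 2L &&
           cross(hull[length(hull) - 1L], hull[length(hull)], i) >= 0) {
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, i)
  }
  new_roc_curve(data.frame(threshold = thr[hull], fpr = p$fpr[hull],
                           tpr = p$tpr[hull]),
                n_pos = attr(curve, "n_pos"), n_neg = attr(curve, "n_neg"))
}

#' Balanced operating threshold
#'
#' Chooses, among the sweep thresholds, the one making sensitivity and
#' specificity as similar as possible (minimum `|sen - spc|`); ties are
#' broken toward higher sensitivity.
#'
#' @param curve A `roc_curve` from [roc_sweep()]/[roc_from_scores()].
#' @return The selected threshold.
#' @export
balanced_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  d <- abs(curve$tpr - (1 - curve$fpr))
  best <- which(d == min(d))
  best <- best[which.max(curve$tpr[best])]
  curve$threshold[best]
}

#' Optimum cut-off for a single screening scale
#'
#' Evaluates every integer boundary of the scale as a univariate
#' classifier. For FAQ and GDS (higher is impaired) a subject scoring above
#' the cut-off is called MCI; for MMSE (lower is impaired) a subject
#' scoring at or below it. The cut-off maximizing accuracy is returned
#' (ties broken toward higher sensitivity, then the lower boundary), with
#' its confusion matrix and the full univariate ROC.
#'
#' @param test A [cohort()] with both classes.
#' @param scale One of `"mmse"`, `"faq"`, `"gds"` (any integer-valued
#'   feature is accepted).
#' @param orientation `"higher-is-impaired"` (FAQ/GDS) or
#'   `"lower-is-impaired"` (MMSE). Defaults to the clinical convention for
#'   the named scale.
#' @return A list of class `scale_cutoff` with elements `cutoff` (c(lo, hi)
#'   boundary), `label` (e.g. `"0/1"`), `cm`, `curve`, `accuracy`.
#' @export
best_scale_cutoff <- function(test, scale,
                              orientation = c("higher-is-impaired",
                                              "lower-is-impaired")) {
  stopifnot(inherits(test, "cohort"))
  if (missing(orientation)) {
    orientation <- if (scale == "mmse") "lower-is-impaired"
                   else "higher-is-impaired"
  }
  orientation <- match.arg(orientation)
  v <- test[[scale]]
  if (is.null(v)) stop("unknown scale: ", scale, call. = FALSE)
  if (any(v != round(v))) stop("scale must be integer-valued on the test set",
                               call. = FALSE)
  if (min(v) == max(v)) stop("constant scale: ", scale, call. = FALSE)
  labels <- test$label
  cuts <- seq(min(v), max(v) - 1L)
  evals <- lapply(cuts, function(cc) {
    pred <- if (orientation == "higher-is-impaired") as.integer(v > cc)
            else as.integer(v <= cc)
    cm <- confusion_from_predictions(labels, pred)
    list(cut = cc, cm = cm, acc = accuracy(cm), sen = sensitivity(cm))
  })
  accs <- vapply(evals, `[[`, numeric(1), "acc")
  sens <- vapply(evals, `[[`, numeric(1), "sen")
  best <- which(accs == max(accs))
  best <- best[sens[best] == max(sens[best])][1L]
  chosen <- evals[[best]]
  scores <- if (orientation == "higher-is-impaired") v else -v
  structure(list(cutoff = c(chosen$cut, chosen$cut + 1L),
                 label = sprintf("%d/%d", chosen$cut, chosen$cut + 1L),
                 cm = chosen$cm,
                 curve = roc_from_scores(scores, labels),
                 accuracy = chosen$acc),
            class = "scale_cutoff")
}

#' Pooled mean of rates
#'
#' Arithmetic mean, used to pool e.g. the four physicians' sensitivities
#' into a single headline rate.
#'
#' @param values Non-empty numeric vector of rates.
#' @return The mean.
#' @export
pooled_mean <- function(values) {
  if (length(values) == 0L) stop("no values to pool", call. = FALSE)
  mean(values)
}

#' Recompute accuracy and clinical utility from printed rates
#'
#' Helper for comparing against published tables: reconstructs the
#' confusion matrix from a printed sensitivity/specificity pair (given as
#' percentages) and the test composition, then recomputes accuracy and
#' CUIs.
#'
#' @param sen_pct,spc_pct Printed percentages (2 decimals).
#' @param n_pos,n_neg Class sizes of the test sample.
#' @param digits Printed precision passed to [confusion_from_rates()]
#'   (proportion digits; 4 matches 2-decimal percentages).
#' @return A one-row data frame with `acc_pct`, `sen_pct`, `spc_pct`,
#'   `cui_plus`, `cui_minus` and the reconstructed counts.
#' @export
metrics_from_printed <- function(sen_pct, spc_pct, n_pos, n_neg, digits = 4) {
  cm <- confusion_from_rates(sen_pct / 100, spc_pct / 100, n_pos, n_neg,
                             digits = digits)
  ci <- cui(cm)
  data.frame(tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
             acc_pct = 100 * accuracy(cm),
             sen_pct = 100 * sensitivity(cm),
             spc_pct = 100 * specificity(cm),
             cui_plus = ci$cui_plus, cui_minus = ci$cui_minus)
}
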