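#' Enumerate admissible feature subsets
#'
#' All subsets of the candidate features of at least `min_size` members,
#' optionally constrained to contain at least one diagnostic instrument
#' (MMSE/FAQ/GDS). With the five standard features, `min_size = 2` and the
#' constraint on, 25 subsets are admissible; with the constraint off, 26
#' (only `{age, yoe}` differs). Order is deterministic: by size, then
#' lexicographically in the order of `features`.
#'
#' @param features Candidate feature names.
#' @param min_size Minimum subset size.
#' @param diagnostic Names counted as diagnostic instruments.
#' @param require_diagnostic Enforce the at-least-one-instrument constraint.
#' @return List of character vectors.
#' @export
enumerate_subsets <- function(features = cpn_features(), min_size = 2L,
                              diagnostic = diagnostic_features(),
                              require_diagnostic = TRUE) {
  stopifnot(min_size >= 1L)
  diagnostic <- intersect(diagnostic, features)
  if (require_diagnostic && length(diagnostic) == 0L) {
    stop("no diagnostic feature among the candidates", call. = FALSE)
  }
  out <- list()
  for (sz in seq(min_size, length(features))) {
    for (cols in combn(seq_along(features), sz, simplify = FALSE)) {
      s <- features[cols]
      if (!require_diagnostic || any(s %in% diagnostic)) {
        out[[length(out) + 1L]] <- s
      }
    }
  }
  out
}

#' Fitness configuration for the wrapper search
#'
#' Defines the grid of CPN variants trained per candidate subset: lattice
#' geometries (default: square and hexagonal, each planar and toroidal, all
#' 8x8), the training schedule, and how many random restarts per geometry.
#' The best variant by convex-hull AUC on the held-out split represents the
#' subset.
#'
#' @param geometries List of [lattice_geometry()] objects.
#' @param schedule A [training_schedule()].
#' @param seeds_per_subset Random restarts per geometry.
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(geometries = default_geometries(),
                           schedule = training_schedule(),
                           seeds_per_subset = 1L) {
  stopifnot(length(geometries) >= 1L, seeds_per_subset >= 1L)
  structure(list(geometries = geometries, schedule = schedule,
                 seeds_per_subset = as.integer(seeds_per_subset)),
            class = "fitness_config")
}

#' @rdname fitness_config
#' @param rows,cols Map dimensions shared by the four default geometries.
#' @export
default_geometries <- function(rows = 8L, cols = 8L) {
  list(lattice_geometry("square", "planar", rows, cols),
       lattice_geometry("square", "toroidal", rows, cols),
       lattice_geometry("hexagonal", "planar", rows, cols),
       lattice_geometry("hexagonal", "toroidal", rows, cols))
}

# Train the configured CPN variants on one subset, keep the best by hull
# AUC on the test split, and evaluate it at its balanced threshold.
evaluate_subset <- function(train, test, subset, config = fitness_config(),
                            seed = 1L) {
  best <- NULL
  counter <- 0L
  for (geometry in config$geometries) {
    for (rep in seq_len(config$seeds_per_subset)) {
      counter <- counter + 1L
      model <- train_cpn(train, subset, geometry, config$schedule,
                         seed = derive_seed(seed, counter))
      curve <- roc_sweep(model, test)
      hull <- convex_hull(curve)
      a <- auc(hull)
      if (is.null(best) || a > best$auc_hull) {
        best <- list(model = model, curve = curve, hull = hull, auc_hull = a)
      }
    }
  }
  # scores live in [0,1]; the below-minimum sentinel can be negative, so
  # clip to keep the stored threshold a valid Grossberg threshold
  model <- set_threshold(best$model,
                         min(1, max(0, balanced_threshold(best$curve))))
  cm <- confusion_from_predictions(test$label, cpn_classify(model, test))
  ci <- cui(cm)
  structure(list(subset = subset,
                 label = subset_label(subset),
                 model = model,
                 curve = best$curve,
                 hull = best$hull,
                 metrics = list(auc_hull = best$auc_hull,
                                auc_raw = auc(best$curve),
                                accuracy = accuracy(cm),
                                sensitivity = sensitivity(cm),
                                specificity = specificity(cm),
                                cui_plus = ci$cui_plus,
                                cui_minus = ci$cui_minus,
                                threshold = model$threshold),
                 cm = cm),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<subset_result> %s | hull AUC %.4f | acc %.4f | sen %.4f | spc %.4f\n",
    x$label, m$auc_hull, m$accuracy, m$sensitivity, m$specificity))
  invisible(x)
}

#' Evaluate and rank feature subsets
#'
#' Wrapper feature selection: each subset is represented by its best CPN
#' variant (geometry grid x restarts, see [fitness_config()]) and subsets
#' are ranked by convex-hull AUC on the held-out test split, descending.
#'
#' @param train,test Disjoint [cohort()] splits.
#' @param subsets List of feature subsets, e.g. from [enumerate_subsets()].
#' @param config A [fitness_config()].
#' @param seed Master seed; per-model seeds are derived deterministically.
#' @return An object of class `subset_ranking`: a list of `subset_result`s
#'   in rank order. `as.data.frame()` yields a table with one row per
#'   subset (AUC/accuracy/sensitivity/specificity as percentages, CUIs).
#' @export
evaluate_all_subsets <- function(train, test, subsets = enumerate_subsets(),
                                 config = fitness_config(), seed = 1L) {
  results <- lapply(seq_along(subsets), function(i) {
    evaluate_subset(train, test, subsets[[i]], config,
                    seed = derive_seed(seed, i * 1000L))
  })
  aucs <- vapply(results, function(r) r$metrics$auc_hull, numeric(1))
  structure(results[order(-aucs)], class = "subset_ranking")
}

#' @export
as.data.frame.subset_ranking <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    m <- r$metrics
    data.frame(subset = r$label,
               auc_pct = 100 * m$auc_hull,
               acc_pct = 100 * m$accuracy,
               sen_pct = 100 * m$sensitivity,
               spc_pct = 100 * m$specificity,
               cui_plus = m$cui_plus,
               cui_minus = m$cui_minus,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.subset_ranking <- function(x, ...) {
  df <- as.data.frame(x)
  df[, -1] <- round(df[, -1], 4)
  print.data.frame(df)
  invisible(x)
}

#' Backward elimination over the feature set
#'
#' Starts from the full feature set and iteratively removes the single
#' feature whose removal maximizes the convex-hull AUC of the best CPN on
#' the test split, subject to the admissibility constraints (minimum size,
#' at least one diagnostic instrument). Fitness ties keep the earliest
#' candidate in feature order. Stops when no admissible removal remains.
#'
#' @inheritParams evaluate_all_subsets
#' @param start Starting subset (the full feature set).
#' @param min_size Minimum admissible subset size.
#' @param diagnostic,require_diagnostic Diagnostic-instrument constraint.
#' @return An object of class `elimination_trace`: every evaluated
#'   `subset_result` in evaluation order, each carrying `step` and `chosen`
#'   fields (`chosen` marks the path the elimination followed).
#' @export
backward_eliminate <- function(train, test, start = cpn_features(),
                               config = fitness_config(), seed = 1L,
                               min_size = 2L,
                               diagnostic = diagnostic_features(),
                               require_diagnostic = TRUE) {
  admissible <- function(s) {
    length(s) >= min_size && (!require_diagnostic || any(s %in% diagnostic))
  }
  if (!admissible(start)) stop("start subset is not admissible", call. = FALSE)
  counter <- 0L
  eval_one <- function(s, step, chosen) {
    counter <<- counter + 1L
    r <- evaluate_subset(train, test, s, config,
                         seed = derive_seed(seed, counter * 1000L))
    r$step <- step
    r$chosen <- chosen
    r
  }
  current <- eval_one(start, 0L, TRUE)
  trace <- list(current)
  step <- 0L
  repeat {
    step <- step + 1L
    cand_sets <- Filter(admissible, lapply(current$subset, function(f) {
      setdiff(current$subset, f)
    }))
    if (length(cand_sets) == 0L) break
    cands <- lapply(cand_sets, eval_one, step = step, chosen = FALSE)
    aucs <- vapply(cands, function(r) r$metrics$auc_hull, numeric(1))
    pick <- which.max(aucs)  # strict max keeps the earliest candidate on ties
    cands[[pick]]$chosen <- TRUE
    trace <- c(trace, cands)
    current <- cands[[pick]]
  }
  structure(trace, class = "elimination_trace")
}

#' @export
as.data.frame.elimination_trace <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(step = r$step, subset = r$label, chosen = r$chosen,
               auc_pct = 100 * r$metrics$auc_hull,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.elimination_trace <- function(x, ...) {
  df <- as.data.frame(x)
  df$auc_pct <- round(df$auc_pct, 2)
  print.data.frame(df)
  invisible(x)
}
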