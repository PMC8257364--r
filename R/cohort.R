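#' Candidate clinical features
#'
#' The five candidate input variables of the screening system, in canonical
#' order: age (years), years of education (`yoe`), MMSE (0--30, lower is
#' more impaired), FAQ (higher is more impaired) and GDS (higher means more
#' depressive symptoms).
#'
#' @return Character vector of the five feature names.
#' @export
cpn_features <- function() c("age", "yoe", "mmse", "faq", "gds")

#' Diagnostic-criterion features
#'
#' The subset of features that are direct diagnostic instruments (MMSE, FAQ,
#' GDS) as opposed to demographic modifiers (age, years of education). The
#' feature-subset search can be constrained to keep at least one of these.
#'
#' @return Character vector of the three instrument names.
#' @export
diagnostic_features <- function() c("mmse", "faq", "gds")

#' Pretty display label for a feature subset
#'
#' @param subset Character vector of feature names.
#' @return A single string such as `"Age + MMSE + FAQ"`.
#' @export
subset_label <- function(subset) {
  pretty <- c(age = "Age", yoe = "YOE", mmse = "MMSE", faq = "FAQ", gds = "GDS")
  unknown <- setdiff(subset, names(pretty))
  lab <- ifelse(subset %in% names(pretty), pretty[subset], subset)
  paste(lab, collapse = " + ")
}

cohort_columns <- function() c("subject_id", cpn_features(), "label")

validate_cohort_df <- function(df) {
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty cohort", call. = FALSE)
  num_cols <- c(cpn_features(), "label")
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vv <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vv) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1L]),
             call. = FALSE)
      }
      df[[col]] <- vv
    }
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("missing or non-finite value in column '%s' at row %d",
                   col, bad[1L]), call. = FALSE)
    }
  }
  checks <- list(
    age  = function(v) v > 0,
    yoe  = function(v) v >= 0,
    mmse = function(v) v >= 0 & v <= 30,
    faq  = function(v) v >= 0,
    gds  = function(v) v >= 0,
    label = function(v) v %in% c(0, 1)
  )
  for (col in names(checks)) {
    bad <- which(!checks[[col]](df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("invalid %s value (%s) at row %d", col,
                   format(df[[col]][bad[1L]]), bad[1L]), call. = FALSE)
    }
  }
  df$subject_id <- as.character(df$subject_id)
  df$label <- as.integer(df$label)
  for (col in cpn_features()) df[[col]] <- as.numeric(df[[col]])
  df[, cohort_columns(), drop = FALSE]
}

#' Construct a cohort
#'
#' A cohort is a data frame with one row per subject and columns
#' `subject_id`, `age`, `yoe`, `mmse`, `faq`, `gds`, `label`
#' (label: 0 = control, 1 = MCI). Values are validated against the
#' instrument ranges (MMSE in 0--30, FAQ/GDS non-negative, binary label).
#'
#' @param df Data frame with the columns above.
#' @param provenance Free-text origin tag, e.g. `"synthetic"`.
#' @return An object of class `cohort` (a validated data frame).
#' @export
cohort <- function(df, provenance = "user-supplied") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df <- validate_cohort_df(df)
  rownames(df) <- NULL
  structure(df, class = c("cohort", "data.frame"), provenance = provenance)
}

#' @export
print.cohort <- function(x, ...) {
  n_pos <- sum(x$label == 1L)
  cat(sprintf("<cohort> %d subjects (%d controls, %d MCI), provenance: %s\n",
              nrow(x), nrow(x) - n_pos, n_pos,
              attr(x, "provenance") %||% "unknown"))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset rows of a cohort while keeping class and provenance.
subset_cohort <- function(x, idx) {
  cohort(as.data.frame(x)[idx, , drop = FALSE],
         provenance = attr(x, "provenance") %||% "user-supplied")
}

#' Read a cohort from CSV
#'
#' Comma-separated, UTF-8, header required. The canonical header is
#' `subject_id,age,yoe,mmse,faq,gds,label` with label coded 0 (control) /
#' 1 (MCI); deviating column names can be remapped through `columns`.
#'
#' @param path Path to a CSV file.
#' @param columns Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(mmse = "MMSE_total")`.
#' @param provenance Origin tag stored on the cohort.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, columns = NULL, provenance = "user-supplied") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      if (!columns[[canon]] %in% names(df)) {
        stop("mapped column not in file: ", columns[[canon]], call. = FALSE)
      }
      names(df)[names(df) == columns[[canon]]] <- canon
    }
  }
  cohort(df, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Emits the same dialect [read_cohort()] expects (comma-separated, header,
#' label 0/1).
#'
#' @param x A [cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits a cohort into disjoint train and test sets preserving the
#' control/MCI ratio. The control (majority) stratum receives
#' `floor(test_count * n_controls / n)` test subjects and the MCI stratum
#' the remainder; for the 331-subject cohort (128 MCI) and a 76-subject
#' test set this yields the reference 30 MCI / 46 control composition.
#'
#' @param x A [cohort()].
#' @param test_count Number of subjects in the test set.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A list with elements `train` and `test`, both cohorts.
#' @export
stratified_split <- function(x, test_count, seed) {
  stopifnot(inherits(x, "cohort"))
  n <- nrow(x)
  if (!is.numeric(test_count) || test_count != round(test_count) ||
      test_count <= 0 || test_count >= n) {
    stop("test_count must be an integer in (0, cohort size)", call. = FALSE)
  }
  pos <- which(x$label == 1L)
  neg <- which(x$label == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("cohort must contain both classes", call. = FALSE)
  }
  n_test_neg <- floor(test_count * length(neg) / n)
  n_test_pos <- test_count - n_test_neg
  if (n_test_pos < 1L || n_test_neg < 1L) {
    stop("a stratum would receive 0 test subjects", call. = FALSE)
  }
  if (n_test_pos >= length(pos) || n_test_neg >= length(neg)) {
    stop("a stratum would be exhausted by the test set", call. = FALSE)
  }
  set.seed(seed)
  test_idx <- sort(c(sample(pos, n_test_pos), sample(neg, n_test_neg)))
  list(train = subset_cohort(x, setdiff(seq_len(n), test_idx)),
       test = subset_cohort(x, test_idx))
}

#' Learn per-feature min--max scaling from a training cohort
#'
#' Each selected feature is mapped linearly so the training minimum becomes
#' 0 and the training maximum 1; this keeps SOM inputs in the unit
#' hypercube. [apply_scaling()] clips values outside the training range.
#'
#' @param train Training [cohort()].
#' @param subset Character vector of feature names to scale.
#' @return An object of class `scaling_spec`.
#' @export
fit_scaling <- function(train, subset) {
  stopifnot(inherits(train, "cohort"), length(subset) >= 1L)
  bad <- setdiff(subset, cpn_features())
  if (length(bad) > 0L) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  spec <- lapply(subset, function(f) {
    v <- train[[f]]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) stop("constant feature on training data: ", f, call. = FALSE)
    c(min = lo, max = hi)
  })
  names(spec) <- subset
  structure(list(ranges = spec, features = subset), class = "scaling_spec")
}

#' Apply a learned scaling
#'
#' @param spec A `scaling_spec` from [fit_scaling()].
#' @param data A [cohort()], data frame, or named numeric vector holding the
#'   scaled features.
#' @return Numeric matrix in `[0,1]^k`, one row per record, columns in the
#'   order of `spec$features`. Values outside the training range are clipped.
#' @export
apply_scaling <- function(spec, data) {
  stopifnot(inherits(spec, "scaling_spec"))
  if (is.numeric(data) && !is.null(names(data))) {
    data <- as.data.frame(as.list(data))
  }
  missing <- setdiff(spec$features, names(data))
  if (length(missing) > 0L) {
    stop("data lacks feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(spec$features, function(f) {
    r <- spec$ranges[[f]]
    pmin(1, pmax(0, (data[[f]] - r[["min"]]) / (r[["max"]] - r[["min"]])))
  }, numeric(nrow(as.data.frame(data))))
  out <- matrix(out, ncol = length(spec$features),
                dimnames = list(NULL, spec$features))
  out
}
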