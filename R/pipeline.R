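#' Configuration for an end-to-end run
#'
#' @param seed Master seed; every downstream seed (cohort generation,
#'   split, per-model training) is derived from it deterministically.
#' @param cohort_path Optional CSV of an existing cohort; when `NULL` a
#'   synthetic cohort is generated from [adni_like_spec()].
#' @param scale_n Size multiplier for the synthetic cohort.
#' @param test_count Test-set size for the stratified split (default 76,
#'   with the resulting 30 MCI / 46 control composition).
#' @param search_mode `"exhaustive"` (rank all admissible subsets) or
#'   `"backward"` (backward elimination).
#' @param config A [fitness_config()].
#' @param out_dir Output directory for reports, models and the log.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort_path = NULL, scale_n = 1,
                       test_count = 76L,
                       search_mode = c("exhaustive", "backward"),
                       config = fitness_config(), out_dir = "cpnmci-run") {
  search_mode <- match.arg(search_mode)
  structure(list(seed = as.integer(seed), cohort_path = cohort_path,
                 scale_n = scale_n, test_count = as.integer(test_count),
                 search_mode = search_mode, config = config,
                 out_dir = out_dir),
            class = "run_config")
}

fmt2 <- function(x) sprintf("%.2f", x)
fmt4 <- function(x) sprintf("%.4f", x)

# Re-derive every report row's CUI cells from its printed rates; a mismatch
# means the report is internally inconsistent and aborts the run.
check_report_consistency <- function(df, n_pos, n_neg) {
  for (i in seq_len(nrow(df))) {
    cm <- confusion_from_rates(as.numeric(df$sen_pct[i]) / 100,
                               as.numeric(df$spc_pct[i]) / 100,
                               n_pos, n_neg)
    ci <- cui(cm)
    ok <- identical(fmt4(ci$cui_plus), df$cui_plus[i]) &&
      identical(fmt4(ci$cui_minus), df$cui_minus[i]) &&
      identical(fmt2(100 * accuracy(cm)), df$acc_pct[i])
    if (!ok) {
      stop("report row ", i, " failed the rate/CUI consistency re-check",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run the full screening pipeline
#'
#' Generates (or reads) a cohort, performs the stratified split, runs the
#' wrapper feature search, evaluates the best model against the single-test
#' cut-offs, and writes `table2.csv` (ranked subsets), `table3.csv` (best
#' system vs. FAQ/MMSE/GDS cut-offs), `models/best_model.json` and
#' `run.log` into the output directory. Report CSVs are byte-identical
#' across reruns with the same master seed; every report row's CUI cells
#' are re-verified from its own printed rates before writing.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the output paths, the ranking (or trace)
#'   and the best `subset_result`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$out_dir, "models"), showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(fmt, ...) {
    writeLines(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"),
                       ...), log_con)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logf("stage %-10s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  logf("config: seed=%d source=%s scale_n=%s test_count=%d mode=%s",
       cfg$seed, cfg$cohort_path %||% "synthetic", format(cfg$scale_n),
       cfg$test_count, cfg$search_mode)

  coh <- stage("cohort", {
    if (is.null(cfg$cohort_path)) {
      generate_cohort(adni_like_spec(seed = derive_seed(cfg$seed, 1L),
                                     scale_n = cfg$scale_n))
    } else {
      read_cohort(cfg$cohort_path)
    }
  })
  if (cfg$test_count >= nrow(coh)) {
    stop("test_count (", cfg$test_count, ") must be smaller than the cohort (",
         nrow(coh), ")", call. = FALSE)
  }
  split <- stage("split", stratified_split(coh, cfg$test_count,
                                           seed = derive_seed(cfg$seed, 2L)))

  search <- stage("search", {
    if (cfg$search_mode == "exhaustive") {
      evaluate_all_subsets(split$train, split$test,
                           config = cfg$config,
                           seed = derive_seed(cfg$seed, 3L))
    } else {
      backward_eliminate(split$train, split$test, config = cfg$config,
                         seed = derive_seed(cfg$seed, 3L))
    }
  })
  results <- if (inherits(search, "subset_ranking")) search else {
    aucs <- vapply(search, function(r) r$metrics$auc_hull, numeric(1))
    structure(search[order(-aucs)], class = "subset_ranking")
  }
  best <- results[[1L]]

  table2 <- stage("report", {
    df <- as.data.frame(results)
    out <- data.frame(subset = df$subset,
                      auc_pct = fmt2(df$auc_pct), acc_pct = fmt2(df$acc_pct),
                      sen_pct = fmt2(df$sen_pct), spc_pct = fmt2(df$spc_pct),
                      cui_plus = fmt4(df$cui_plus),
                      cui_minus = fmt4(df$cui_minus),
                      stringsAsFactors = FALSE)
    n_pos <- sum(split$test$label == 1L)
    n_neg <- sum(split$test$label == 0L)
    check_report_consistency(out, n_pos, n_neg)

    rows <- list(c(system = sprintf("CPN (%s)", best$label),
                   auc_pct = fmt2(100 * best$metrics$auc_hull),
                   cutoff = "-",
                   acc_pct = fmt2(100 * best$metrics$accuracy),
                   sen_pct = fmt2(100 * best$metrics$sensitivity),
                   spc_pct = fmt2(100 * best$metrics$specificity),
                   cui_plus = fmt4(best$metrics$cui_plus),
                   cui_minus = fmt4(best$metrics$cui_minus)))
    for (scale in c("faq", "mmse", "gds")) {
      sc <- best_scale_cutoff(split$test, scale)
      ci <- cui(sc$cm)
      rows[[length(rows) + 1L]] <-
        c(system = sprintf("%s cut-off", toupper(scale)),
          auc_pct = fmt2(100 * auc(sc$curve)),
          cutoff = sc$label,
          acc_pct = fmt2(100 * accuracy(sc$cm)),
          sen_pct = fmt2(100 * sensitivity(sc$cm)),
          spc_pct = fmt2(100 * specificity(sc$cm)),
          cui_plus = fmt4(ci$cui_plus),
          cui_minus = fmt4(ci$cui_minus))
    }
    table3 <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    check_report_consistency(table3, n_pos, n_neg)

    write.csv(out, file.path(cfg$out_dir, "table2.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(table3, file.path(cfg$out_dir, "table3.csv"),
              row.names = FALSE, quote = FALSE)
    write_cpn_model(best$model,
                    file.path(cfg$out_dir, "models", "best_model.json"))
    out
  })
  logf("best subset: %s (hull AUC %s)", best$label,
       fmt2(100 * best$metrics$auc_hull))

  invisible(list(out_dir = cfg$out_dir,
                 table2 = file.path(cfg$out_dir, "table2.csv"),
                 table3 = file.path(cfg$out_dir, "table3.csv"),
                 model = file.path(cfg$out_dir, "models", "best_model.json"),
                 ranking = results, best = best))
}

#' Recompute physician metrics from printed rates
#'
#' Reads a table of printed sensitivity/specificity percentages (one row
#' per rater or system) and recomputes accuracy and clinical utility
#' indices from the reconstructed confusion matrices.
#'
#' @param ratings Data frame (or CSV path) with columns `system`,
#'   `sen_pct`, `spc_pct`.
#' @param n_pos,n_neg Test composition the rates refer to (default the
#'   reference 30 MCI / 46 controls).
#' @return Data frame with reconstructed counts, accuracy and CUIs per row,
#'   plus pooled mean sensitivity/specificity in the attribute `pooled`.
#' @export
physicians_report <- function(ratings, n_pos = 30L, n_neg = 46L) {
  if (is.character(ratings)) ratings <- read.csv(ratings,
                                                 stringsAsFactors = FALSE)
  stopifnot(all(c("system", "sen_pct", "spc_pct") %in% names(ratings)))
  rows <- do.call(rbind, lapply(seq_len(nrow(ratings)), function(i) {
    metrics_from_printed(ratings$sen_pct[i], ratings$spc_pct[i], n_pos, n_neg)
  }))
  out <- cbind(system = ratings$system, rows, stringsAsFactors = FALSE)
  attr(out, "pooled") <- c(sen_pct = pooled_mean(ratings$sen_pct),
                           spc_pct = pooled_mean(ratings$spc_pct))
  out
}
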