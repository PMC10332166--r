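# Repeated-holdout experimental protocol: hidden-node sweep x seeded runs,
# per-run metric collection on the percent scale, and aggregation by mean,
# RMSE against the 100% optimum, and population standard deviation.

#' Experiment configuration for the hidden-node sweep
#'
#' Defaults follow the diagnostic protocol: hidden nodes 25 to 200 in steps
#' of 25, 50 runs per hidden-node count, a fresh stratified 70/30 split per
#' run, and statistics computed on the percent scale against an optimum of
#' 100.
#'
#' @param hidden_counts Positive integers to sweep.
#' @param runs Runs per hidden-node count.
#' @param test_fraction Held-out fraction per run.
#' @param base_seed Integer; every run seed is derived from it.
#' @param reshuffle_per_run If `TRUE` (default) each run re-splits with seed
#'   `base_seed + run`; if `FALSE` one fixed split (seed `base_seed`) is
#'   reused for all runs.
#' @param optimum The optimal value `o` (percent scale) that RMSE measures
#'   concentration around.
#' @param activation,pinv_cutoff,scale_features Passed through to
#'   [fln_config()] for every fit.
#' @return An object of class `"fln_experiment_config"`.
#' @export
experiment_config <- function(hidden_counts = seq(25L, 200L, by = 25L),
                              runs = 50L, test_fraction = 0.30,
                              base_seed = 1L, reshuffle_per_run = TRUE,
                              optimum = 100, activation = "logistic",
                              pinv_cutoff = 1e-12, scale_features = TRUE) {
  runs <- as.integer(runs)
  hidden_counts <- as.integer(hidden_counts)
  if (runs < 1L) stop("invalid configuration: runs must be >= 1")
  if (!length(hidden_counts) || any(hidden_counts < 1L))
    stop("invalid configuration: hidden_counts must be positive integers")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("invalid configuration: test_fraction must lie in (0, 1)")
  structure(list(hidden_counts = hidden_counts, runs = runs,
                 test_fraction = test_fraction,
                 base_seed = as.integer(base_seed),
                 reshuffle_per_run = isTRUE(reshuffle_per_run),
                 optimum = optimum, activation = activation,
                 pinv_cutoff = pinv_cutoff,
                 scale_features = isTRUE(scale_features)),
            class = "fln_experiment_config")
}

# seeds for one (hidden-count index, run) cell; both derived from base_seed
run_seeds <- function(config, hc_idx, run) {
  list(split = if (config$reshuffle_per_run)
         config$base_seed + run else config$base_seed,
       weights = config$base_seed + 10000L * hc_idx + run)
}

# one fit/evaluate cycle; returns the full evaluation context
run_once <- function(data, hidden_count, hc_idx, run, config) {
  seeds <- run_seeds(config, hc_idx, run)
  t0 <- proc.time()[["elapsed"]]
  split <- stratified_split(data, config$test_fraction, seed = seeds$split)
  model <- fln_fit(split$train,
                   fln_config(hidden_count = hidden_count,
                              seed = seeds$weights,
                              activation = config$activation,
                              pinv_cutoff = config$pinv_cutoff,
                              scale_features = config$scale_features))
  scores <- fln_scores(model, split$test$features)
  pred <- max.col(scores, ties.method = "first")
  cm <- confusion_matrix(split$test$labels, pred, positive_label = 1L)
  list(report = compute_metrics(cm), cm = cm, scores = scores,
       split = split, model = model,
       elapsed = proc.time()[["elapsed"]] - t0, seeds = seeds)
}

#' Run the repeated-holdout experiment
#'
#' For every hidden-node count and run index: derive the run seeds from
#' `base_seed`, split the data (fresh split per run unless
#' `reshuffle_per_run = FALSE`), fit an FLN, predict on the held-out
#' partition, and record the confusion-matrix counts and all metrics on the
#' percent scale. Fully reproducible from the configuration.
#'
#' @param data An [fln_dataset()] containing both classes.
#' @param config An [experiment_config()].
#' @return A data frame with one row per (hidden_count, run): seed columns,
#'   `tp`, `fn`, `fp`, `tn`, the eight metrics (percent scale) and
#'   `elapsed` seconds.
#' @examples
#' d <- synth_dataset("wbcd_like", 40, 60, separation = 3, seed = 1)
#' runs <- run_experiment(d, experiment_config(hidden_counts = 10,
#'                                             runs = 3, base_seed = 7))
#' runs[, c("hidden_count", "run", "accuracy", "mcc")]
#' @export
run_experiment <- function(data, config = experiment_config()) {
  data <- as_fln_dataset(data)
  stopifnot(inherits(config, "fln_experiment_config"))
  if (length(unique(data$labels)) < 2L)
    stop("invalid dataset: both classes must be present")
  rows <- vector("list", length(config$hidden_counts) * config$runs)
  i <- 0L
  for (hc_idx in seq_along(config$hidden_counts)) {
    hc <- config$hidden_counts[hc_idx]
    for (run in seq_len(config$runs)) {
      res <- tryCatch(
        run_once(data, hc, hc_idx, run, config),
        error = function(e) stop("run failed at hidden_count=", hc,
                                 ", run=", run, ": ", conditionMessage(e)))
      rep <- res$report
      i <- i + 1L
      rows[[i]] <- data.frame(
        hidden_count = hc, run = run,
        split_seed = res$seeds$split, weight_seed = res$seeds$weights,
        tp = res$cm$tp, fn = res$cm$fn, fp = res$cm$fp, tn = res$cm$tn,
        accuracy = 100 * rep$accuracy, precision = 100 * rep$precision,
        recall = 100 * rep$recall, specificity = 100 * rep$specificity,
        f_measure = 100 * rep$f_measure, g_mean = 100 * rep$g_mean,
        mcc = 100 * rep$mcc, balanced_auroc = 100 * rep$balanced_auroc,
        elapsed = res$elapsed)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate repeated-run metrics by mean, RMSE and STD
#'
#' For each hidden-node count and metric computes, over the `N` runs on the
#' percent scale: the mean `mu = sum(X_i)/N`, the root-mean-square error
#' against the optimum `o`, `rmse = sqrt(sum((X_i - o)^2)/N)`, and the
#' population standard deviation `std = sqrt(sum((X_i - mu)^2)/N)`
#' (divide-by-N, not N-1). These satisfy the exact identity
#' `rmse^2 = (o - mu)^2 + std^2`.
#'
#' @param runs Data frame from [run_experiment()] (any subset of its rows).
#' @param optimum The optimum `o`, default 100 (percent scale).
#' @param metrics Which metric columns to aggregate.
#' @return Data frame with columns `hidden_count`, `metric`, `mean`,
#'   `rmse`, `std`, `n_runs`.
#' @examples
#' aggregate_runs(data.frame(hidden_count = 25, run = 1:2,
#'                           accuracy = c(90, 110)),
#'                metrics = "accuracy")
#' @export
aggregate_runs <- function(runs, optimum = 100, metrics = metric_names()) {
  if (!is.data.frame(runs) || nrow(runs) == 0L)
    stop("invalid input: no run results to aggregate")
  metrics <- intersect(metrics, names(runs))
  out <- list()
  for (hc in unique(runs$hidden_count)) {
    sub <- runs[runs$hidden_count == hc, , drop = FALSE]
    N <- nrow(sub)
    for (met in metrics) {
      x <- sub[[met]]
      mu <- sum(x) / N
      out[[length(out) + 1L]] <- data.frame(
        hidden_count = hc, metric = met, mean = mu,
        rmse = sqrt(sum((x - optimum)^2) / N),
        std = sqrt(sum((x - mu)^2) / N), n_runs = N)
    }
  }
  do.call(rbind, out)
}

# best run: maximal accuracy, ties to higher mcc, then lowest run index
best_run_row <- function(runs) {
  ord <- order(-runs$accuracy, -runs$mcc, runs$hidden_count, runs$run)
  runs[ord[1L], , drop = FALSE]
}

#' Full sweep report
#'
#' Summarizes a finished experiment: the per-hidden-count statistics table
#' (mean/RMSE/STD for every metric), the best run (maximal accuracy, ties
#' broken by higher MCC then lowest run index) with its confusion matrix,
#' metric report and ROC points (re-derived deterministically from the
#' stored seeds), per-hidden-count total elapsed time, and the raw per-run
#' records for boxplots.
#'
#' @param runs Data frame from [run_experiment()].
#' @param data The dataset the experiment was run on (needed to rebuild the
#'   best run's ROC curve).
#' @param config The [experiment_config()] used.
#' @return A list of class `"fln_sweep_report"`: `stats`, `best_run`
#'   (list with `hidden_count`, `run`, `report`, `confusion`, `roc`),
#'   `timing`, `runs`.
#' @export
sweep_report <- function(runs, data, config) {
  stats <- aggregate_runs(runs, optimum = config$optimum)
  best <- best_run_row(runs)
  hc_idx <- match(best$hidden_count, config$hidden_counts)
  redo <- run_once(as_fln_dataset(data), best$hidden_count, hc_idx,
                   best$run, config)
  roc <- roc_curve(redo$scores[, 1L], redo$split$test$labels,
                   positive_label = 1L)
  timing <- stats::aggregate(elapsed ~ hidden_count, data = runs, FUN = sum)
  names(timing)[2L] <- "total_elapsed"
  structure(list(stats = stats,
                 best_run = list(hidden_count = best$hidden_count,
                                 run = best$run, report = redo$report,
                                 confusion = redo$cm, roc = roc),
                 timing = timing, runs = runs),
            class = "fln_sweep_report")
}

#' @export
print.fln_sweep_report <- function(x, ...) {
  acc <- x$stats[x$stats$metric == "accuracy", ]
  cat("FLN hidden-node sweep (", max(x$runs$run), " runs each)\n", sep = "")
  print(acc[, c("hidden_count", "mean", "rmse", "std")], row.names = FALSE)
  br <- x$best_run
  cat(sprintf("best run: hidden_count=%d run=%d accuracy=%.2f%% AROC=%.5f\n",
              br$hidden_count, br$run, 100 * br$report$accuracy,
              br$report$balanced_auroc))
  invisible(x)
}

#' Write sweep outputs to a directory
#'
#' Emits `stats.csv` (the statistics table), `runs.csv` (per-run records),
#' `best_run.json` (confusion matrix + metric report of the best run) and
#' `roc.tsv` (the best run's ROC points).
#'
#' @param report An `"fln_sweep_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_report <- function(report, dir) {
  stopifnot(inherits(report, "fln_sweep_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$stats, file.path(dir, "stats.csv"),
                   row.names = FALSE)
  utils::write.csv(report$runs, file.path(dir, "runs.csv"),
                   row.names = FALSE)
  br <- report$best_run
  jsonlite::write_json(
    list(hidden_count = br$hidden_count, run = br$run,
         confusion = br$confusion[c("tp", "fn", "fp", "tn")],
         metrics = br$report[metric_names()]),
    file.path(dir, "best_run.json"), auto_unbox = TRUE, digits = I(10))
  utils::write.table(br$roc$points, file.path(dir, "roc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
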