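# Labelled tabular dataset container plus readers/writers for the two UCI
# Wisconsin breast-cancer dialects, min-max scaling, and stratified splits.

WBCD_FEATURES <- c("clump_thickness", "uniformity_cell_size",
                   "uniformity_cell_shape", "marginal_adhesion",
                   "single_epithelial_cell_size", "bare_nuclei",
                   "bland_chromatin", "normal_nucleoli", "mitoses")

WDBC_CHARACTERISTICS <- c("radius", "texture", "perimeter", "area",
                          "smoothness", "compactness", "concavity",
                          "concave_points", "symmetry", "fractal_dimension")

# Per-characteristic observed ranges of the WDBC features, one row per
# characteristic: mean, standard-error and maximum ("worst") measurement.
WDBC_RANGES <- local({
  m <- rbind(
    c(6.98, 28.11,    0.112, 2.873,   7.93, 36.04),
    c(9.71, 39.28,    0.36,  4.89,    12.02, 49.54),
    c(43.79, 188.50,  0.76,  21.98,   50.41, 251.20),
    c(143.50, 2501.0, 6.80,  542.20,  185.20, 4254.00),
    c(0.053, 0.163,   0.002, 0.031,   0.071, 0.223),
    c(0.019, 0.345,   0.002, 0.135,   0.027, 1.058),
    c(0.000, 0.427,   0.000, 0.396,   0.000, 1.252),
    c(0.000, 0.201,   0.000, 0.053,   0.000, 0.291),
    c(0.106, 0.304,   0.008, 0.079,   0.157, 0.664),
    c(0.050, 0.097,   0.001, 0.030,   0.055, 0.208))
  dimnames(m) <- list(WDBC_CHARACTERISTICS,
                      c("mean_lo", "mean_hi", "se_lo", "se_hi",
                        "max_lo", "max_hi"))
  m
})

wdbc_feature_names <- function() {
  as.vector(vapply(c("mean", "se", "max"), function(s)
    paste(WDBC_CHARACTERISTICS, s, sep = "_"), character(10)))
}

# lo/hi bounds in file column order (10 means, 10 SEs, 10 maxima)
wdbc_feature_bounds <- function() {
  lo <- c(WDBC_RANGES[, "mean_lo"], WDBC_RANGES[, "se_lo"],
          WDBC_RANGES[, "max_lo"])
  hi <- c(WDBC_RANGES[, "mean_hi"], WDBC_RANGES[, "se_hi"],
          WDBC_RANGES[, "max_hi"])
  list(lo = unname(lo), hi = unname(hi))
}

#' Labelled feature dataset
#'
#' The package's common container: a numeric feature matrix (samples as
#' rows), integer class labels in `1..l`, and naming metadata. Label 1 is
#' conventionally the malignant (positive) class in the breast-cancer
#' schemas.
#'
#' @param features Numeric matrix or data frame, `N x n`, no missing values.
#' @param labels Integer vector of length `N` with values in
#'   `1..length(class_names)`.
#' @param class_names Character vector of class names (length `l`).
#' @param feature_names Optional feature names (defaults to matrix column
#'   names or `f1..fn`).
#' @param provenance Free-text note on where the data came from.
#' @return An object of class `"fln_dataset"`.
#' @export
fln_dataset <- function(features, labels,
                        class_names = c("malignant", "benign"),
                        feature_names = NULL, provenance = "") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  l <- length(class_names)
  if (nrow(features) != length(labels))
    stop("invalid dataset: nrow(features) != length(labels)")
  if (anyNA(features))
    stop("invalid dataset: features contain missing values")
  if (length(labels) && (anyNA(labels) || any(labels < 1L) || any(labels > l)))
    stop("invalid label: labels must lie in 1..", l)
  if (is.null(feature_names))
    feature_names <- colnames(features)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 class_names = as.character(class_names),
                 feature_names = as.character(feature_names),
                 provenance = provenance),
            class = "fln_dataset")
}

#' Coerce to an fln_dataset
#' @param x An `"fln_dataset"` or a list with `features` and `labels`.
#' @return An `"fln_dataset"`.
#' @export
as_fln_dataset <- function(x) {
  if (inherits(x, "fln_dataset")) return(x)
  if (is.list(x) && !is.null(x$features) && !is.null(x$labels))
    return(fln_dataset(x$features, x$labels,
                       class_names = x$class_names %||% c("malignant", "benign"),
                       feature_names = x$feature_names,
                       provenance = x$provenance %||% ""))
  stop("cannot coerce to fln_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fln_dataset <- function(x, ...) {
  cat(sprintf("fln_dataset: %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names),
                      labels = x$class_names))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

dataset_subset <- function(data, idx) {
  fln_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
              class_names = data$class_names,
              feature_names = data$feature_names,
              provenance = data$provenance)
}

#' Read a WBCD-dialect file
#'
#' Parses the original Wisconsin Breast Cancer Database comma-separated
#' layout: 11 fields per row (sample id, nine integer cytology features in
#' 1..10, class code 2 = benign / 4 = malignant), no header, `?` for a
#' missing value. Rows containing any missing feature are dropped entirely.
#' Class codes are mapped to label 1 = malignant, 2 = benign.
#'
#' @param path Path to the file.
#' @return An [fln_dataset()] with the nine named cytology features.
#' @export
read_wbcd <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != 11L))
    stop("parse error: line ", which(widths != 11L)[1],
         " has ", widths[widths != 11L][1], " fields, expected 11")
  raw <- do.call(rbind, parts)
  keep <- !apply(raw[, 2:10, drop = FALSE] == "?", 1L, any)
  raw <- raw[keep, , drop = FALSE]
  feats <- suppressWarnings(
    matrix(as.numeric(raw[, 2:10, drop = FALSE]), ncol = 9L))
  if (anyNA(feats))
    stop("parse error: non-numeric feature value")
  if (any(feats != round(feats)) || any(feats < 1) || any(feats > 10))
    stop("parse error: WBCD features must be integers in 1..10")
  cls <- raw[, 11L]
  if (!all(cls %in% c("2", "4")))
    stop("invalid label: WBCD class code must be 2 (benign) or 4 (malignant)")
  labels <- ifelse(cls == "4", 1L, 2L)
  colnames(feats) <- WBCD_FEATURES
  d <- fln_dataset(feats, labels, provenance = paste0("wbcd:", path))
  d$ids <- raw[, 1L]
  d
}

#' Read a WDBC-dialect file
#'
#' Parses the Wisconsin Diagnostic Breast Cancer comma-separated layout:
#' 32 fields per row (sample id, diagnosis `M`/`B`, thirty real-valued
#' features: the mean, standard error and maximum of ten cell-nucleus
#' characteristics). `M` maps to label 1 = malignant, `B` to 2 = benign.
#'
#' @param path Path to the file.
#' @return An [fln_dataset()] with the thirty named features.
#' @export
read_wdbc <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != 32L))
    stop("parse error: line ", which(widths != 32L)[1],
         " has ", widths[widths != 32L][1], " fields, expected 32")
  raw <- do.call(rbind, parts)
  diag <- raw[, 2L]
  if (!all(diag %in% c("M", "B")))
    stop("invalid label: WDBC diagnosis must be M or B")
  feats <- suppressWarnings(
    matrix(as.numeric(raw[, 3:32, drop = FALSE]), ncol = 30L))
  if (anyNA(feats))
    stop("parse error: non-numeric feature value")
  labels <- ifelse(diag == "M", 1L, 2L)
  colnames(feats) <- wdbc_feature_names()
  d <- fln_dataset(feats, labels, provenance = paste0("wdbc:", path))
  d$ids <- raw[, 1L]
  d
}

#' Write a dataset to disk
#'
#' `format = "csv"` writes the canonical header layout
#' `id, class_name, label, <features...>`. `"wbcd"` and `"wdbc"` emit the
#' corresponding native UCI dialect (headerless), so a dataset read from
#' one of those dialects round-trips exactly.
#'
#' @param data An [fln_dataset()].
#' @param path Output path.
#' @param format One of `"csv"`, `"wbcd"`, `"wdbc"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("csv", "wbcd", "wdbc")) {
  format <- match.arg(format)
  data <- as_fln_dataset(data)
  ids <- data$ids %||% as.character(seq_len(nrow(data$features)))
  if (format == "csv") {
    df <- data.frame(id = ids,
                     class_name = data$class_names[data$labels],
                     label = data$labels,
                     data$features, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "wbcd") {
    if (ncol(data$features) != 9L)
      stop("wbcd dialect requires 9 features")
    code <- ifelse(data$labels == 1L, 4L, 2L)
    lines <- paste(ids, apply(data$features, 1L, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE), collapse = ",")),
      code, sep = ",")
    writeLines(lines, path)
  } else {
    if (ncol(data$features) != 30L)
      stop("wdbc dialect requires 30 features")
    diag <- ifelse(data$labels == 1L, "M", "B")
    lines <- paste(ids, diag, apply(data$features, 1L, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
            collapse = ",")), sep = ",")
    writeLines(lines, path)
  }
  invisible(path)
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Splits each class independently: a seeded shuffle of the class's sample
#' indices, then `round_half_up(test_fraction * n_class)` samples go to the
#' test partition. At `test_fraction = 0.30` this reproduces the published
#' WBCD (72/133 test) and WDBC (64/107 test) per-class counts.
#'
#' @param data An [fln_dataset()].
#' @param test_fraction Fraction of each class assigned to test, in `[0, 1)`.
#' @param seed Integer seed for the shuffle.
#' @return A list of class `"fln_split"` with `train`, `test` (both
#'   [fln_dataset()]s) and `per_class_counts` (data frame of class,
#'   n_total, n_train, n_test).
#' @examples
#' d <- synth_dataset("wbcd_like", 40, 60, seed = 1)
#' s <- stratified_split(d, 0.3, seed = 5)
#' s$per_class_counts
#' @export
stratified_split <- function(data, test_fraction = 0.30, seed = 1L) {
  data <- as_fln_dataset(data)
  if (!is.numeric(test_fraction) || test_fraction < 0 || test_fraction >= 1)
    stop("invalid split: test_fraction must lie in [0, 1)")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  l <- length(data$class_names)
  test_idx <- integer(0)
  counts <- data.frame(class = data$class_names,
                       n_total = 0L, n_train = 0L, n_test = 0L)
  for (k in seq_len(l)) {
    idx <- which(data$labels == k)
    n_k <- length(idx)
    n_test <- as.integer(round_half_up(test_fraction * n_k))
    if (n_k > 0L && n_k - n_test < 1L && test_fraction > 0)
      stop("invalid split: class '", data$class_names[k],
           "' left without training samples")
    pick <- if (n_k) sample(idx)[seq_len(n_test)] else integer(0)
    test_idx <- c(test_idx, pick)
    counts$n_total[k] <- n_k
    counts$n_test[k] <- n_test
    counts$n_train[k] <- n_k - n_test
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(data$features)), test_idx)
  structure(list(train = dataset_subset(data, train_idx),
                 test = dataset_subset(data, test_idx),
                 per_class_counts = counts),
            class = "fln_split")
}

#' Fit a per-feature min-max scaler
#'
#' @param x Numeric training feature matrix (samples as rows).
#' @return An `"fln_scaler"` holding per-feature minima and maxima.
#' @export
minmax_fit <- function(x) {
  x <- as.matrix(x)
  structure(list(min = unname(apply(x, 2L, min)),
                 max = unname(apply(x, 2L, max))),
            class = "fln_scaler")
}

#' Apply a min-max scaler
#'
#' Maps each feature to `(x - min) / (max - min)` using the training range.
#' Constant features (min == max) map to 0. With `clip = TRUE` values
#' outside the training range are clipped into `[0, 1]` — the rule applied
#' to test data.
#'
#' @param scaler An `"fln_scaler"` from [minmax_fit()].
#' @param x Feature matrix to scale.
#' @param clip Clip scaled values into `[0, 1]`?
#' @return Scaled matrix with the same shape as `x`.
#' @export
minmax_apply <- function(scaler, x, clip = TRUE) {
  stopifnot(inherits(scaler, "fln_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$min))
    stop("shape error: scaler fitted on ", length(scaler$min),
         " features, got ", ncol(x))
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2L, scaler$min, "-")
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 2L, rng, "/")
  out[, const] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Fit a scaler on training features and apply it to both partitions
#'
#' @param train_features Training matrix the scaler is learned from.
#' @param other_features Optional matrix scaled with the training range and
#'   clipped to `[0, 1]`.
#' @return List with `train`, `other` (or `NULL`) and `scaler`.
#' @export
minmax_fit_apply <- function(train_features, other_features = NULL) {
  scaler <- minmax_fit(train_features)
  list(train = minmax_apply(scaler, train_features, clip = FALSE),
       other = if (is.null(other_features)) NULL else
         minmax_apply(scaler, other_features, clip = TRUE),
       scaler = scaler)
}
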