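# Schema-faithful synthetic tumor-feature generator: truncated-normal
# features within each schema's observed ranges, with a controllable
# class-separation parameter, so the classifier and harness are testable
# without downloading the real cytology data.

# inverse-CDF truncated normal on [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(a + stats::runif(n) * (b - a))
}

#' Generate a synthetic breast-tumor feature dataset
#'
#' Emulates one of the two Wisconsin schemas: `"wbcd_like"` (nine integer
#' cytology features in 1..10) or `"wdbc_like"` (thirty real cell-nucleus
#' features, each confined to its observed range). Each feature is drawn
#' from a truncated normal whose standard deviation is one tenth of the
#' schema range; the two class means are offset along every feature by
#' `separation` pooled standard deviations, benign low and malignant high
#' (mirroring the real datasets' direction). Class 1 is malignant.
#'
#' @param schema `"wbcd_like"` or `"wdbc_like"`.
#' @param n_malignant,n_benign Samples per class (defaults keep the real
#'   datasets' roughly 35% malignant mix).
#' @param separation Nonnegative distance between the class means in pooled
#'   standard-deviation units; 0 makes the classes indistinguishable.
#' @param seed Integer seed; output is deterministic in it.
#' @return An [fln_dataset()] (malignant samples first).
#' @examples
#' d <- synth_dataset("wbcd_like", n_malignant = 30, n_benign = 50,
#'                    separation = 3, seed = 1)
#' range(d$features)  # within [1, 10]
#' @export
synth_dataset <- function(schema = c("wbcd_like", "wdbc_like"),
                          n_malignant = 70L, n_benign = 130L,
                          separation = 3, seed = 1L) {
  schema <- match.arg(schema)
  if (!is.numeric(separation) || separation < 0)
    stop("configuration error: separation must be nonnegative")
  n_malignant <- as.integer(n_malignant)
  n_benign <- as.integer(n_benign)
  if (n_malignant < 0L || n_benign < 0L)
    stop("configuration error: class sizes must be nonnegative")
  if (schema == "wbcd_like") {
    lo <- rep(1, 9)
    hi <- rep(10, 9)
    feature_names <- WBCD_FEATURES
  } else {
    bounds <- wdbc_feature_bounds()
    lo <- bounds$lo
    hi <- bounds$hi
    feature_names <- wdbc_feature_names()
  }
  sd_f <- (hi - lo) / 10
  mid <- (lo + hi) / 2
  mu_mal <- pmin(mid + separation * sd_f / 2, hi)
  mu_ben <- pmax(mid - separation * sd_f / 2, lo)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  draw_class <- function(n, mu) {
    out <- matrix(0, nrow = n, ncol = length(lo))
    for (j in seq_along(lo))
      out[, j] <- rtruncnorm(n, mu[j], sd_f[j], lo[j], hi[j])
    out
  }
  feats <- rbind(draw_class(n_malignant, mu_mal),
                 draw_class(n_benign, mu_ben))
  if (schema == "wbcd_like" && nrow(feats))
    feats <- pmin(pmax(round(feats), 1), 10)
  if (!nrow(feats)) feats <- matrix(0, 0, length(lo))
  colnames(feats) <- feature_names
  fln_dataset(feats,
              labels = c(rep(1L, n_malignant), rep(2L, n_benign)),
              provenance = sprintf(
                "synthetic %s (sep=%g, seed=%d)", schema, separation,
                as.integer(seed)))
}

#' Linear regression probe fixture
#'
#' A small continuous-target fixture: features uniform on `[0, 1]` and
#' targets an exact linear map `y = x A'` of the features. Because the FLN
#' output layer contains a direct linear input-to-output block, the
#' closed-form solve must fit this probe with (numerically) zero residual.
#'
#' @param n Number of samples (at least `n_features + 1`).
#' @param n_features Number of features.
#' @param n_targets Number of target columns.
#' @param seed Integer seed.
#' @return List with `features` (`n x n_features`), `targets`
#'   (`n x n_targets`) and the coefficient matrix `A` (`n_targets x
#'   n_features`).
#' @export
generate_linear_probe <- function(n, n_features, n_targets = 2L, seed = 1L) {
  if (n < n_features + 1L)
    stop("configuration error: need n >= n_features + 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  x <- matrix(stats::runif(n * n_features), nrow = n)
  A <- matrix(stats::runif(n_targets * n_features, -2, 2), nrow = n_targets)
  list(features = x, targets = x %*% t(A), A = A)
}

#' Validate feature values against a schema's ranges
#'
#' The range validators used on ingestion: wbcd-like features must be
#' integers in 1..10; wdbc-like features must lie inside each feature's
#' observed range.
#'
#' @param features Feature matrix.
#' @param schema `"wbcd_like"` or `"wdbc_like"`.
#' @return `TRUE` if every value conforms, else `FALSE`.
#' @export
validate_schema <- function(features, schema = c("wbcd_like", "wdbc_like")) {
  schema <- match.arg(schema)
  features <- as.matrix(features)
  if (schema == "wbcd_like") {
    ncol(features) == 9L && all(features == round(features)) &&
      all(features >= 1) && all(features <= 10)
  } else {
    if (ncol(features) != 30L) return(FALSE)
    bounds <- wdbc_feature_bounds()
    all(sweep(features, 2L, bounds$lo, ">=")) &&
      all(sweep(features, 2L, bounds$hi, "<="))
  }
}
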