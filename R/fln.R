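# Fast learning network: random input weights + biases, closed-form
# least-squares output weights over the stacked matrix H = [X; G].

#' FLN training configuration
#'
#' Bundles the tunable knobs of a fast learning network fit. The only
#' structural parameter is `hidden_count` (the number of hidden nodes, `m`);
#' everything else controls reproducibility and numerics.
#'
#' @param hidden_count Positive integer, number of hidden nodes.
#' @param seed Integer seed for the random input weights and biases. A fit is
#'   fully determined by the config and the training data.
#' @param activation Name of the hidden activation `g(.)`: `"logistic"`
#'   (default), `"tanh"` or `"relu"`.
#' @param pinv_cutoff Nonnegative relative singular-value cutoff for the
#'   Moore-Penrose pseudoinverse: singular values below
#'   `pinv_cutoff * max(singular values)` are treated as zero.
#' @param ridge Nonnegative ridge term added to `H H'` instead of using the
#'   pseudoinverse; `0` (default) selects the pseudoinverse route.
#' @param scale_features Logical; if `TRUE` (default) the fit learns a
#'   per-feature min-max scaler on the training data and stores it in the
#'   model (prediction clips new data to the training range).
#'
#' @return An object of class `"fln_config"`.
#' @examples
#' fln_config(hidden_count = 25, seed = 1)
#' @export
fln_config <- function(hidden_count = 25L, seed = 1L,
                       activation = c("logistic", "tanh", "relu"),
                       pinv_cutoff = 1e-12, ridge = 0,
                       scale_features = TRUE) {
  activation <- match.arg(activation)
  hidden_count <- as.integer(hidden_count)
  if (length(hidden_count) != 1L || is.na(hidden_count) || hidden_count < 1L)
    stop("invalid configuration: 'hidden_count' must be a positive integer")
  if (!is.numeric(pinv_cutoff) || length(pinv_cutoff) != 1L || pinv_cutoff < 0)
    stop("invalid configuration: 'pinv_cutoff' must be a nonnegative real")
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0)
    stop("invalid configuration: 'ridge' must be a nonnegative real")
  structure(list(hidden_count = hidden_count, seed = as.integer(seed),
                 activation = activation,
                 pinv_cutoff = as.numeric(pinv_cutoff),
                 ridge = as.numeric(ridge),
                 scale_features = isTRUE(scale_features)),
            class = "fln_config")
}

activation_fun <- function(name) {
  switch(name,
         logistic = function(z) 1 / (1 + exp(-z)),
         tanh     = base::tanh,
         relu     = function(z) pmax(z, 0),
         stop("unknown activation: ", name))
}

#' Draw the random input weights and hidden biases
#'
#' Step 1 of FLN learning: input-to-hidden weights uniform on `[-1, 1]`,
#' hidden biases uniform on `[0, 1]`, fully determined by `config$seed`.
#' The weight matrix is drawn before the bias vector, in row-major order.
#'
#' @param config An [fln_config()].
#' @param n_features Positive integer, number of input features `n`.
#' @return A list with `W_in` (`m x n` matrix) and `b` (length-`m` vector).
#' @examples
#' w <- fln_init_weights(fln_config(hidden_count = 2, seed = 7), n_features = 3)
#' range(w$W_in)  # within [-1, 1]
#' @export
fln_init_weights <- function(config, n_features) {
  stopifnot(inherits(config, "fln_config"))
  n_features <- as.integer(n_features)
  if (length(n_features) != 1L || is.na(n_features) || n_features < 1L)
    stop("invalid configuration: 'n_features' must be a positive integer")
  m <- config$hidden_count
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  W_in <- matrix(stats::runif(m * n_features, -1, 1), nrow = m,
                 ncol = n_features, byrow = TRUE)
  b <- stats::runif(m, 0, 1)
  list(W_in = W_in, b = b)
}

#' Hidden-layer output matrix
#'
#' Computes `G[k, j] = g(W_in[k, ] . X[, j] + b[k])` for the `m x N`
#' hidden-output matrix. Samples are columns of `X` here (the internal
#' orientation); with the logistic activation every entry lies in (0, 1).
#'
#' @param W_in `m x n` input weight matrix.
#' @param b Length-`m` bias vector.
#' @param X `n x N` input matrix, samples as columns.
#' @param activation Hidden activation name (see [fln_config()]).
#' @return The `m x N` matrix `G`.
#' @export
fln_hidden_output <- function(W_in, b, X, activation = "logistic") {
  W_in <- as.matrix(W_in)
  X <- as.matrix(X)
  if (ncol(W_in) != nrow(X))
    stop("shape error: W_in has ", ncol(W_in), " columns but X has ",
         nrow(X), " rows")
  if (length(b) != nrow(W_in))
    stop("shape error: length(b) != nrow(W_in)")
  g <- activation_fun(activation)
  g(W_in %*% X + b)   # b recycles down columns: row k gets b[k]
}

#' One-hot target matrix
#'
#' Encodes integer class labels `1..l` as an `l x N` matrix with a single 1
#' per column.
#'
#' @param labels Integer vector of class labels in `1..l`.
#' @param l Number of classes.
#' @return `l x N` 0/1 matrix; every column sums to 1.
#' @examples
#' encode_targets(c(1, 2, 2), 2)
#' @export
encode_targets <- function(labels, l) {
  labels <- as.integer(labels)
  l <- as.integer(l)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > l))
    stop("invalid label: labels must lie in 1..", l)
  Y <- matrix(0, nrow = l, ncol = length(labels))
  Y[cbind(labels, seq_along(labels))] <- 1
  Y
}

# Moore-Penrose pseudoinverse by SVD with a relative singular-value cutoff.
# Kept internal: the closed-form solve below is the package's core.
mp_pinv <- function(A, rel_cutoff = 1e-12) {
  s <- svd(A)
  if (length(s$d) == 0L || max(s$d) == 0)
    return(matrix(0, ncol(A), nrow(A)))
  keep <- s$d > rel_cutoff * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Closed-form FLN solve for arbitrary real targets
#'
#' The regression core of the package: given training features (samples as
#' rows) and a real target matrix (samples as rows, one column per output),
#' draws the random hidden layer and solves
#' `W_hat = Y H^+` with `H = [X; G]` stacked, so the direct input-to-output
#' block `W_oi` and hidden-to-output block `W_oh` are the joint least-squares
#' optimum. No feature scaling or label encoding is applied.
#'
#' @param x Numeric matrix of features, `N x n`.
#' @param y Numeric matrix of targets, `N x l` (a vector is treated as one
#'   column).
#' @param config An [fln_config()].
#' @return List with `W_in`, `b`, `W_oi` (`l x n`), `W_oh` (`l x m`),
#'   `residual` (max absolute training residual of `W_hat H - Y`).
#' @export
fln_solve <- function(x, y, config = fln_config()) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y))
    stop("shape error: x and y must have the same number of rows")
  w <- fln_init_weights(config, ncol(x))
  X <- t(x)                                             # n x N
  G <- fln_hidden_output(w$W_in, w$b, X, config$activation)
  H <- rbind(X, G)                                      # (n+m) x N
  Y <- t(y)                                             # l x N
  W_hat <- if (config$ridge > 0) {
    Y %*% t(H) %*% solve(tcrossprod(H) + diag(config$ridge, nrow(H)))
  } else {
    Y %*% mp_pinv(H, config$pinv_cutoff)
  }
  n <- ncol(x)
  list(W_in = w$W_in, b = w$b,
       W_oi = W_hat[, seq_len(n), drop = FALSE],
       W_oh = W_hat[, n + seq_len(config$hidden_count), drop = FALSE],
       residual = max(abs(W_hat %*% H - Y)))
}

#' Fit a fast learning network classifier
#'
#' Trains an FLN on a labelled dataset: min-max scales the features (unless
#' disabled in the config), draws the random input weights and biases, builds
#' the hidden-output matrix `G` and the stacked matrix `H = [X; G]`, one-hot
#' encodes the labels, and solves the combined output-weight matrix
#' `W_hat = Y H^+` by singular-value pseudoinverse. The first `n` columns of
#' `W_hat` are the direct input-to-output weights `W_oi`, the remaining `m`
#' the hidden-to-output weights `W_oh`; output biases are identically zero.
#'
#' @param data An [fln_dataset()] (or anything [as_fln_dataset()] accepts)
#'   containing at least two classes.
#' @param config An [fln_config()].
#' @return An object of class `"fln"` with components `W_in`, `b`, `W_oi`,
#'   `W_oh`, `c` (zero output biases), `scaler` (per-feature min/max, or
#'   `NULL`), `class_names`, `feature_names` and `config`.
#' @examples
#' d <- synth_dataset("wbcd_like", n_malignant = 30, n_benign = 50,
#'                    separation = 4, seed = 2)
#' model <- fln_fit(d, fln_config(hidden_count = 10, seed = 1))
#' table(truth = d$labels, pred = predict(model, d$features))
#' @seealso [predict.fln()], [write_fln()]
#' @export
fln_fit <- function(data, config = fln_config()) {
  data <- as_fln_dataset(data)
  stopifnot(inherits(config, "fln_config"))
  l <- length(data$class_names)
  if (length(unique(data$labels)) < 2L)
    stop("invalid dataset: training data must contain at least two classes")
  x <- data$features
  scaler <- NULL
  if (config$scale_features) {
    scaler <- minmax_fit(x)
    x <- minmax_apply(scaler, x, clip = FALSE)  # training data defines range
  }
  sol <- fln_solve(x, t(encode_targets(data$labels, l)), config)
  structure(list(W_in = sol$W_in, b = sol$b, W_oi = sol$W_oi,
                 W_oh = sol$W_oh, c = rep(0, l), scaler = scaler,
                 class_names = data$class_names,
                 feature_names = data$feature_names, config = config),
            class = "fln")
}

#' Raw class scores of a fitted FLN
#'
#' For each row `x` of `newdata` (after applying the model's stored min-max
#' scaler, clipping to the training range) returns
#' `W_oi x + W_oh g(W_in x + b)`; the output activation is the identity and
#' the output biases are zero, so the scores approximate the one-hot targets.
#'
#' @param model A fitted `"fln"` object.
#' @param newdata Numeric matrix with one row per sample and the training
#'   feature count of columns.
#' @return Numeric matrix, samples x classes, column names the class names.
#' @export
fln_scores <- function(model, newdata) {
  stopifnot(inherits(model, "fln"))
  newdata <- as.matrix(newdata)
  n <- ncol(model$W_in)
  if (ncol(newdata) != n)
    stop("shape error: model expects ", n, " features, got ", ncol(newdata))
  if (!is.null(model$scaler))
    newdata <- minmax_apply(model$scaler, newdata, clip = TRUE)
  X <- t(newdata)
  G <- fln_hidden_output(model$W_in, model$b, X, model$config$activation)
  scores <- t(model$W_oi %*% X + model$W_oh %*% G + model$c)
  colnames(scores) <- model$class_names
  scores
}

#' Predict classes or scores from a fitted FLN
#'
#' @param object A fitted `"fln"` object.
#' @param newdata Feature matrix, samples as rows.
#' @param type `"class"` (default) for integer class labels — the index of
#'   the maximal score, ties broken toward the smallest class index — or
#'   `"score"` for the raw score matrix.
#' @param ... Unused.
#' @return Integer label vector or score matrix.
#' @export
predict.fln <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  scores <- fln_scores(object, newdata)
  if (type == "score") return(scores)
  max.col(scores, ties.method = "first")
}

#' @export
print.fln <- function(x, ...) {
  cat("Fast learning network classifier\n")
  cat(sprintf("  features: %d   hidden nodes: %d   classes: %s\n",
              ncol(x$W_in), nrow(x$W_in),
              paste(x$class_names, collapse = ", ")))
  cat(sprintf("  activation: %s   scaled inputs: %s   seed: %d\n",
              x$config$activation, !is.null(x$scaler), x$config$seed))
  invisible(x)
}

#' Serialize a fitted FLN to JSON
#'
#' Writes every model component (weights, biases, scaler, class names,
#' config) with 17 significant digits so that [read_fln()] reproduces the
#' model bit-exactly.
#'
#' @param model A fitted `"fln"` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_fln <- function(model, path) {
  stopifnot(inherits(model, "fln"))
  payload <- list(
    W_in = model$W_in, b = model$b, W_oi = model$W_oi, W_oh = model$W_oh,
    c = model$c,
    scaler = if (is.null(model$scaler)) NULL else
      list(min = model$scaler$min, max = model$scaler$max),
    class_names = model$class_names, feature_names = model$feature_names,
    config = unclass(model$config))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a serialized FLN model
#'
#' @param path File written by [write_fln()].
#' @return An object of class `"fln"`.
#' @export
read_fln <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- fln_config(hidden_count = p$config$hidden_count,
                    seed = p$config$seed, activation = p$config$activation,
                    pinv_cutoff = p$config$pinv_cutoff,
                    ridge = p$config$ridge,
                    scale_features = p$config$scale_features)
  scaler <- if (is.null(p$scaler)) NULL else
    structure(list(min = p$scaler$min, max = p$scaler$max),
              class = "fln_scaler")
  structure(list(W_in = as.matrix(p$W_in), b = as.numeric(p$b),
                 W_oi = as.matrix(p$W_oi), W_oh = as.matrix(p$W_oh),
                 c = as.numeric(p$c), scaler = scaler,
                 class_names = as.character(p$class_names),
                 feature_names = as.character(p$feature_names),
                 config = cfg),
            class = "fln")
}
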