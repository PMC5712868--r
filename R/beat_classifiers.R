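# Beat-level classifiers: a rule-based ventricular-premature-complex (VPC)
# detector driven by QRS width and prematurity, and a single-hidden-layer
# perceptron for atrial premature complexes (APC), trained by
# backpropagation with a 60/20/20 stratified split and validation early
# stopping. V labels always take precedence over MLP output.

#' Classify ventricular premature complexes
#'
#' A beat is labeled `V` when it is both wide and premature:
#' `qrs_duration > width_factor * running-median QRS width` and
#' `rr_prev < prematurity_factor * rr_mean_20`. The running median is taken
#' over the QRS durations of up to `median_window` preceding and following
#' beats (the beat itself excluded). Beats with any undefined feature are
#' never labeled V; they keep their prior label, or `N` when unlabeled.
#'
#' @param features Data frame from [extract_beat_features()].
#' @param beats The matching [beat_series()].
#' @param width_factor Width multiplier on the running-median QRS duration
#'   (default 1.5).
#' @param prematurity_factor RR-prematurity multiplier on the local mean RR
#'   (default 0.85).
#' @param median_window Number of neighboring beats pooled for the running
#'   median QRS width (default 50).
#' @return A [beat_series()] with updated labels.
#' @export
classify_vpc <- function(features, beats, width_factor = 1.5,
                         prematurity_factor = 0.85, median_window = 50L) {
  n <- length(beats$beat_samples)
  if (nrow(features) != n)
    stop("`features` and `beats` are not aligned")
  labels <- ifelse(beats$labels == "unknown", "N", beats$labels)
  qd <- features$qrs_duration
  for (i in seq_len(n)) {
    if (is.na(qd[i]) || is.na(features$rr_prev[i]) ||
        is.na(features$rr_mean_20[i])) next
    nb <- setdiff(max(1L, i - median_window):min(n, i + median_window), i)
    ref_width <- stats::median(qd[nb], na.rm = TRUE)
    if (is.na(ref_width)) next
    if (qd[i] > width_factor * ref_width &&
        features$rr_prev[i] < prematurity_factor * features$rr_mean_20[i])
      labels[i] <- "V"
  }
  beat_series(beats$beat_samples, fs = beats$fs, labels = labels)
}

#' Default APC-MLP training configuration
#'
#' @return Named list: `n_hidden` (hidden units, 10), `lr` (learning rate,
#'   0.5), `momentum` (0.9), `max_epochs` (500), `patience` (early-stopping
#'   patience on validation loss, 20), `split` (train/validation/test
#'   fractions, 60/20/20).
#' @export
mlp_config <- function() {
  list(n_hidden = 10L, lr = 0.5, momentum = 0.9, max_epochs = 500L,
       patience = 20L, split = c(train = 0.6, validation = 0.2, test = 0.2))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the APC perceptron
#'
#' Applies the model's stored imputation and z-scoring, then the
#' sigmoid-activated hidden and output layers. Returns the probability that
#' the beat is an atrial premature complex (class S); the decision rule is
#' S iff probability >= 0.5 (ties sensitivity-favoring).
#'
#' @param model An `mlp_model` from [train_apc_mlp()] (or [mlp_model()] for a
#'   raw, unnormalized model).
#' @param x Numeric feature vector of length `n_in`, or a matrix with
#'   `n_in` columns.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
mlp_forward <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != model$n_in)
    stop(sprintf("expected %d features, got %d", model$n_in, ncol(X)))
  X <- .mlp_normalize(model, X)
  p <- .mlp_fwd_raw(model, X)$p
  if (is.matrix(x)) p else p[1L]
}

.mlp_normalize <- function(model, X) {
  if (is.null(model$center)) return(X)
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- model$impute[j]
    X[, j] <- (xj - model$center[j]) / model$scale[j]
  }
  X
}

.mlp_fwd_raw <- function(model, X) {
  A <- .sigmoid(sweep(X %*% model$W1, 2L, model$b1, "+"))
  p <- as.numeric(.sigmoid(A %*% model$W2 + model$b2))
  list(A = A, p = p)
}

#' Construct a raw MLP model
#'
#' Mostly useful for testing; [train_apc_mlp()] builds models with stored
#' normalization constants.
#'
#' @param W1,b1 Input-to-hidden weights (`n_in x n_hidden`) and biases.
#' @param W2,b2 Hidden-to-output weights (`n_hidden x 1`) and bias.
#' @param center,scale,impute Optional per-feature normalization constants.
#' @return Object of class `mlp_model`.
#' @export
mlp_model <- function(W1, b1, W2, b2, center = NULL, scale = NULL,
                      impute = NULL) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  stopifnot(ncol(W1) == length(b1), nrow(W2) == ncol(W1), ncol(W2) == 1L,
            length(b2) == 1L)
  if (any(!is.finite(W1)) || any(!is.finite(W2)))
    stop("weights must be finite")
  structure(list(n_in = nrow(W1), n_hidden = ncol(W1),
                 W1 = W1, b1 = as.numeric(b1), W2 = W2,
                 b2 = as.numeric(b2),
                 center = center, scale = scale, impute = impute,
                 classes = c("N", "S")),
            class = "mlp_model")
}

# weighted cross-entropy loss and analytic gradients, on already-normalized X
.mlp_loss_grad <- function(model, X, y, w) {
  fwd <- .mlp_fwd_raw(model, X)
  p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
  loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
  dz2 <- w * (fwd$p - y) / sum(w)               # d loss / d (output pre-act)
  gW2 <- t(fwd$A) %*% dz2
  gb2 <- sum(dz2)
  dA <- matrix(dz2, ncol = 1L) %*% t(model$W2)
  dz1 <- dA * fwd$A * (1 - fwd$A)
  gW1 <- t(X) %*% dz1
  gb1 <- colSums(dz1)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Loss and analytic gradients of the perceptron
#'
#' Weighted binary cross-entropy of the model on `(X, y)` together with the
#' backpropagated gradients for every weight and bias. Exposed so the
#' analytic gradients can be checked against finite differences.
#'
#' @param model An `mlp_model`; normalization constants are ignored here
#'   (`X` is taken as-is).
#' @param X Numeric matrix, one row per instance.
#' @param y 0/1 target vector (1 = class S).
#' @param weights Optional per-instance loss weights.
#' @return List with `loss`, `gW1`, `gb1`, `gW2`, `gb2`.
#' @export
mlp_gradients <- function(model, X, y, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  .mlp_loss_grad(model, X, y, weights)
}

#' Train the APC perceptron
#'
#' Imputes missing feature values with training-set medians, z-scores with
#' training-set statistics (both stored in the model), splits the beats into
#' stratified 60/20/20 train/validation/test subsets, and fits the network by
#' full-batch gradient descent with momentum on an
#' inverse-class-frequency-weighted cross-entropy. Training stops early when
#' the validation loss has not improved for `patience` epochs, and the
#' weights of the best validation epoch are kept. Deterministic given `seed`.
#'
#' @param features Data frame or matrix of per-beat features (rows = beats).
#' @param ref_labels Per-beat reference labels; `"S"` marks the positive
#'   class, anything else is negative.
#' @param config See [mlp_config()].
#' @param seed Integer RNG seed controlling initialization and the split.
#' @return List with `model` (class `mlp_model`) and `report` (class
#'   `mlp_train_report`: split fractions, epochs run, per-split accuracy,
#'   seed).
#' @export
train_apc_mlp <- function(features, ref_labels, config = mlp_config(),
                          seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.integer(ref_labels == "S")
  if (length(unique(y)) < 2L)
    stop("training refused: only one class present in `ref_labels`")
  if (min(table(y)) < 10L)
    stop("training refused: need at least 10 beats per class")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # stratified 60/20/20 split
  split_of <- integer(length(y))
  for (cls in unique(y)) {
    ids <- sample(which(y == cls))
    n <- length(ids)
    n_tr <- floor(config$split[["train"]] * n)
    n_va <- floor(config$split[["validation"]] * n)
    split_of[ids[seq_len(n_tr)]] <- 1L
    split_of[ids[n_tr + seq_len(n_va)]] <- 2L
    split_of[ids[(n_tr + n_va + 1L):n]] <- 3L
  }

  tr <- split_of == 1L
  impute <- apply(X[tr, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  impute[is.na(impute)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- impute[j]
  center <- colMeans(X[tr, , drop = FALSE])
  scale <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xn <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  n_in <- ncol(X); nh <- config$n_hidden
  lim <- 1 / sqrt(n_in)
  W1 <- matrix(stats::runif(n_in * nh, -lim, lim), n_in, nh)
  b1 <- numeric(nh)
  W2 <- matrix(stats::runif(nh, -1 / sqrt(nh), 1 / sqrt(nh)), nh, 1L)
  b2 <- 0
  model <- mlp_model(W1, b1, W2, b2)

  # inverse-frequency class weights on the training split
  freq <- table(factor(y[tr], levels = c(0L, 1L)))
  cw <- as.numeric(sum(freq) / (2 * freq))
  w_tr <- cw[y[tr] + 1L]

  Xtr <- Xn[tr, , drop = FALSE]; ytr <- y[tr]
  va <- split_of == 2L
  Xva <- Xn[va, , drop = FALSE]; yva <- y[va]
  w_va <- cw[yva + 1L]

  vel <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = 0)
  best <- list(loss = Inf, model = model, epoch = 0L)
  stale <- 0L
  epochs_run <- 0L
  loss_hist <- numeric()
  for (ep in seq_len(config$max_epochs)) {
    g <- .mlp_loss_grad(model, Xtr, ytr, w_tr)
    loss_hist <- c(loss_hist, g$loss)
    vel$W1 <- config$momentum * vel$W1 - config$lr * g$gW1
    vel$b1 <- config$momentum * vel$b1 - config$lr * g$gb1
    vel$W2 <- config$momentum * vel$W2 - config$lr * g$gW2
    vel$b2 <- config$momentum * vel$b2 - config$lr * g$gb2
    model$W1 <- model$W1 + vel$W1
    model$b1 <- model$b1 + vel$b1
    model$W2 <- model$W2 + vel$W2
    model$b2 <- model$b2 + vel$b2
    epochs_run <- ep
    vloss <- .mlp_loss_grad(model, Xva, yva, w_va)$loss
    if (vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, model = model, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model <- best$model
  model$center <- center; model$scale <- scale; model$impute <- impute

  acc <- function(mask) {
    if (!any(mask)) return(NA_real_)
    p <- .mlp_fwd_raw(model, Xn[mask, , drop = FALSE])$p
    mean((p >= 0.5) == (y[mask] == 1L))
  }
  report <- structure(
    list(split = config$split, epochs_run = epochs_run,
         best_epoch = best$epoch,
         train_accuracy = acc(tr), val_accuracy = acc(va),
         test_accuracy = acc(split_of == 3L), seed = seed,
         loss_history = loss_hist),
    class = "mlp_train_report")
  list(model = model, report = report)
}

#' @export
print.mlp_train_report <- function(x, ...) {
  cat(sprintf(paste0("<mlp_train_report> %d epochs (best %d), accuracy ",
                     "train %.1f%% / val %.1f%% / test %.1f%% (seed %d)\n"),
              x$epochs_run, x$best_epoch, 100 * x$train_accuracy,
              100 * x$val_accuracy, 100 * x$test_accuracy, x$seed))
  invisible(x)
}

#' Classify atrial premature complexes
#'
#' Applies the trained perceptron to every beat not already labeled `V`
#' (ventricular labels from the upstream rule take precedence and are never
#' overwritten). A beat becomes `S` when the forward probability is >= 0.5.
#'
#' @param model Trained `mlp_model`.
#' @param features Per-beat feature data frame aligned with `beats`.
#' @param beats A [beat_series()].
#' @return A [beat_series()] with updated labels.
#' @export
classify_apc <- function(model, features, beats) {
  n <- length(beats$beat_samples)
  if (nrow(features) != n) stop("`features` and `beats` are not aligned")
  labels <- ifelse(beats$labels == "unknown", "N", beats$labels)
  if (n) {
    p <- mlp_forward(model, as.matrix(features))
    sel <- labels != "V" & p >= 0.5
    labels[sel] <- "S"
  }
  beat_series(beats$beat_samples, fs = beats$fs, labels = labels)
}

#' Persist / restore an MLP model as JSON
#'
#' Shapes, weights and normalization constants are stored at full printed
#' double precision; the round trip reproduces forward probabilities to
#' numerical precision.
#'
#' @param model An `mlp_model`.
#' @param path JSON file path.
#' @return `save_mlp_json`: `path`, invisibly. `load_mlp_json`: the model.
#' @export
save_mlp_json <- function(model, path) {
  jsonlite::write_json(
    list(n_in = model$n_in, n_hidden = model$n_hidden,
         W1 = model$W1, b1 = model$b1,
         W2 = as.numeric(model$W2), b2 = model$b2,
         center = model$center, scale = model$scale, impute = model$impute),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_mlp_json
#' @export
load_mlp_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mlp_model(W1 = matrix(unlist(j$W1), j$n_in, j$n_hidden),
            b1 = j$b1, W2 = matrix(j$W2, j$n_hidden, 1L), b2 = j$b2,
            center = j$center, scale = j$scale, impute = j$impute)
}
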