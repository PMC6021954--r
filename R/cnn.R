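# Cellular-neural-network classifier with echo-state training.
#
# Each sensor's feature block drives its own lattice of n coupled cells,
#   dx/dt = -x + A tansig(x) + B u + bias,
# integrated by explicit Euler (step 0.5, zero initial state, input held
# constant). A is random sparse symmetric with unit spectral radius and is
# never trained (echo-state principle); only the linear readout mapping the
# multiplexed cell outputs to the four one-hot class targets is fitted, by
# ridge regression.

#' Hyperbolic tangent sigmoid
#'
#' `tansig(x) = 2 / (1 + exp(-2x)) - 1`, the cell output nonlinearity;
#' identical to `tanh`.
#'
#' @param x numeric vector or matrix.
#' @return same shape, values in (-1, 1).
#' @export
tansig <- function(x) 2 / (1 + exp(-2 * x)) - 1

#' Chua-Yang piecewise-linear cell output
#'
#' `y = 0.5 (|x + 1| - |x - 1|)`: identity on [-1, 1], saturating at +/-1
#' outside. Provided for completeness/ablation; the classifier uses
#' [tansig()].
#'
#' @param x numeric vector or matrix.
#' @return same shape.
#' @export
chua_output <- function(x) 0.5 * (abs(x + 1) - abs(x - 1))

#' Generate one sensor's echo-state CNN templates
#'
#' The feedback template A is a sparse (zero with probability 0.5)
#' symmetric matrix with N(0, 1) entries, scaled by its own largest
#' absolute eigenvalue so the spectral radius is exactly 1. Sparsity is
#' applied to the upper triangle (including the diagonal) and mirrored, so
#' the realized zero fraction stays at 0.5. The control template B (n x m)
#' and the cell bias (n) are N(0, 1) scaled by 0.1.
#'
#' @param n number of cells.
#' @param m input dimension (features of this sensor).
#' @param sensor sensor tag (`"ecg"`, `"eda"`, `"st"`).
#' @param seed integer seed; templates are a pure function of
#'   (n, m, sensor, seed).
#' @return object of class `cnn_templates`: list with `A`, `B`, `bias`,
#'   `n`, `m`, `sensor`, `seed`.
#' @export
generate_templates <- function(n, m, sensor = c("ecg", "eda", "st"), seed = 0L) {
  sensor <- match.arg(sensor)
  if (n < 1 || m < 1) stop_named("invalid_dims", "n and m must be >= 1")
  s <- as.integer(seed)
  repeat {
    tpl <- with_seed(derive_seed(s, sensor, n, m), {
      A <- matrix(0, n, n)
      up <- upper.tri(A, diag = TRUE)
      nz <- stats::rbinom(sum(up), 1, 0.5) == 1
      vals <- numeric(sum(up))
      vals[nz] <- stats::rnorm(sum(nz))
      A[up] <- vals
      A <- A + t(A) - diag(diag(A), n)
      B <- matrix(stats::rnorm(n * m), n, m) * 0.1
      bias <- stats::rnorm(n) * 0.1
      list(A = A, B = B, bias = bias)
    })
    ev <- if (n == 1L) abs(tpl$A[1, 1]) else
      max(abs(eigen(tpl$A, symmetric = TRUE, only.values = TRUE)$values))
    if (ev > 0) {
      tpl$A <- tpl$A / ev
      break
    }
    message("generate_templates: all-zero feedback template; reseeding")
    s <- s + 1L
  }
  structure(list(A = tpl$A, B = tpl$B, bias = tpl$bias,
                 n = as.integer(n), m = as.integer(m),
                 sensor = sensor, seed = as.integer(seed)),
            class = "cnn_templates")
}

#' Integrate the CNN state equation for constant input
#'
#' Explicit Euler on `dx/dt = -x + A tansig(x) + B u + bias` from zero
#' initial state with the input held constant; returns the cell outputs
#' `tansig(x)` after `steps` iterations (early stop when the state update's
#' max-norm falls below `tol`). `u` may be a matrix with one column per
#' trial; all trials are integrated jointly.
#'
#' @param templates a [generate_templates()] result.
#' @param u input vector of length m, or an m x T matrix.
#' @param h Euler step size (default 0.5).
#' @param steps iteration cap (default 20).
#' @param tol early-stop tolerance on the state update (default 1e-8).
#' @param x0 initial state (test hook; default zero).
#' @return cell outputs: n-vector, or n x T matrix if `u` was a matrix.
#' @export
cnn_integrate <- function(templates, u, h = 0.5, steps = 20L, tol = 1e-8,
                          x0 = NULL) {
  stopifnot(inherits(templates, "cnn_templates"))
  U <- if (is.matrix(u)) u else matrix(u, ncol = 1)
  if (nrow(U) != templates$m)
    stop_named("invalid_input", "input dimension does not match templates")
  if (!all(is.finite(U))) stop_named("invalid_input", "non-finite input")
  drive <- templates$B %*% U + templates$bias
  X <- if (is.null(x0)) matrix(0, templates$n, ncol(U)) else
    matrix(x0, templates$n, ncol(U))
  for (k in seq_len(steps)) {
    dX <- h * (-X + templates$A %*% tansig(X) + drive)
    X <- X + dX
    if (!all(is.finite(X)))
      stop_named("diverged", "non-finite CNN state at step %d", k)
    if (max(abs(dX)) < tol) break
  }
  Y <- tansig(X)
  if (is.matrix(u)) Y else as.numeric(Y)
}

#' Multiplex per-sensor cell outputs into one readout column
#'
#' Concatenates the final cell outputs of the enabled sensors in the fixed
#' order ecg, eda, st and appends the bias constant 1.
#'
#' @param y_by_sensor named list of output vectors (or n x T matrices).
#' @param sensor_set character subset of `c("ecg", "eda", "st")`.
#' @return numeric vector of length sum(n) + 1 (or matrix with T columns).
#' @export
multiplex <- function(y_by_sensor, sensor_set) {
  sensor_set <- intersect(c("ecg", "eda", "st"), sensor_set)
  missing <- setdiff(sensor_set, names(y_by_sensor))
  if (length(missing))
    stop_named("missing_sensor", "no outputs for sensor(s): %s",
               paste(missing, collapse = ", "))
  parts <- lapply(sensor_set, function(s) {
    y <- y_by_sensor[[s]]
    if (is.matrix(y)) y else matrix(y, ncol = 1)
  })
  Y <- do.call(rbind, parts)
  rbind(Y, rep(1, ncol(Y)))
}

#' Ridge-regression readout
#'
#' Closed-form echo-state readout `A_global = G Y' (Y Y' + beta I)^{-1}`,
#' computed by solving the (symmetric) linear system rather than inverting.
#'
#' @param G 4 x T matrix of one-hot class targets.
#' @param Y (sum(n)+1) x T matrix of multiplexed cell outputs.
#' @param beta ridge coefficient (> 0).
#' @return the 4 x (sum(n)+1) readout matrix.
#' @export
ridge_readout <- function(G, Y, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop_named("invalid_beta", "beta must be a positive scalar")
  if (ncol(G) != ncol(Y))
    stop_named("invalid_dims", "G and Y must have the same number of columns")
  M <- Y %*% t(Y) + beta * diag(nrow(Y))
  sol <- tryCatch(solve(M, Y %*% t(G)), error = function(e)
    stop_named("singular_system", "readout system singular even with ridge: %s",
               conditionMessage(e)))
  t(sol)
}

#' Decode a 4-vector of readout outputs to a class index
#'
#' Argmax over the four class outputs; ties go to the lowest index.
#'
#' @param g numeric vector of length 4 (or 4 x T matrix).
#' @return integer class index/indices in 0..3.
#' @export
decode <- function(g) {
  G <- if (is.matrix(g)) g else matrix(g, ncol = 1)
  if (!all(is.finite(G))) stop_named("invalid_output", "non-finite readout output")
  as.integer(max.col(t(G), ties.method = "first") - 1L)
}

## ---- Fitting ------------------------------------------------------------

sensor_blocks <- function(feat_names) {
  list(eda = grep("^(scl|scr)_", feat_names, value = TRUE),
       ecg = grep("^(nn|sdnn|rmssd|pnn50|lf|hf)", feat_names, value = TRUE),
       st = grep("^st_", feat_names, value = TRUE))
}

# Reservoir outputs for all trials of a feature matrix (rows = trials,
# z-scored), for given templates per sensor. Returns (sum(n)+1) x T.
reservoir_outputs <- function(Z, blocks, templates, sensor_set, h, steps) {
  ys <- lapply(sensor_set, function(s) {
    U <- t(Z[, blocks[[s]], drop = FALSE])
    cnn_integrate(templates[[s]], U, h = h, steps = steps)
  })
  names(ys) <- sensor_set
  multiplex(ys, sensor_set)
}

templates_for <- function(n, blocks, sensor_set, seed) {
  tpl <- lapply(sensor_set, function(s)
    generate_templates(n, length(blocks[[s]]), s, derive_seed(seed, "tpl", s)))
  stats::setNames(tpl, sensor_set)
}

one_hot <- function(classes) {
  G <- matrix(0, 4, length(classes))
  G[cbind(classes + 1L, seq_along(classes))] <- 1
  G
}

subject_folds <- function(subjects, folds, seed) {
  us <- sort(unique(subjects))
  if (length(us) < folds) {
    message(sprintf("cnn_esn: only %d subjects; reducing folds from %d",
                    length(us), folds))
    folds <- length(us)
  }
  perm <- with_seed(seed, sample(us))
  grp <- rep(seq_len(folds), length.out = length(us))
  fold_of_subject <- stats::setNames(grp, perm)
  list(fold = unname(fold_of_subject[subjects]), k = folds)
}

#' Fit the cellular-neural-network emotion classifier
#'
#' Fits one echo-state CNN reservoir per enabled sensor and a joint
#' ridge-regression readout onto the four valence/arousal classes. The
#' reservoir size n and ridge coefficient beta are selected by
#' subject-grouped cross-validated grid search (mean held-out accuracy;
#' ties prefer smaller n, then larger beta), after which the readout is
#' refitted on all training data. Features are z-scored on training
#' statistics.
#'
#' @param x numeric feature matrix (rows = trials) with the column names of
#'   [feature_names()], or a feature table from
#'   [extract_features_dataset()].
#' @param classes integer class indices 0-3 (ignored, taken from the table,
#'   if `x` is a feature table).
#' @param subjects subject id per trial, for grouped cross-validation
#'   (likewise taken from a feature table).
#' @param sensor_set sensors to use, subset of `c("ecg", "eda", "st")`.
#' @param grid_n candidate cell counts (default `c(50, 100, 150, 1000,
#'   1500)`).
#' @param grid_beta candidate ridge coefficients (default `c(0.1, 0.01,
#'   0.001, 1e-4, 1e-5)`).
#' @param folds cross-validation folds (default 10; reduced to the number
#'   of subjects when fewer).
#' @param h Euler step size (default 0.5).
#' @param steps Euler iteration cap (default 20).
#' @param seed integer seed governing template draws and fold assignment.
#' @return an object of class `cnn_esn`: list with per-sensor `templates`,
#'   readout `A_global`, selected `n`/`beta`, `zscore`, `cv` (grid of mean
#'   CV accuracies), `sensor_set`, `feature_names`, `h`, `steps`, `seed`.
#' @seealso [predict.cnn_esn()], [write_model()], [read_model()]
#' @export
cnn_esn <- function(x, classes = NULL, subjects = NULL,
                    sensor_set = c("ecg", "eda", "st"),
                    grid_n = c(50, 100, 150, 1000, 1500),
                    grid_beta = c(0.1, 0.01, 0.001, 1e-4, 1e-5),
                    folds = 10L, h = 0.5, steps = 20L, seed = 0L) {
  if (is.data.frame(x)) {
    fm <- feature_matrix(x)
    if (is.null(classes)) classes <- fm$classes
    if (is.null(subjects)) subjects <- fm$subjects
    x <- fm$x
  }
  sensor_set <- intersect(c("ecg", "eda", "st"), sensor_set)
  if (length(sensor_set) == 0L) stop_named("invalid_sensors", "empty sensor set")
  classes <- as.integer(classes)
  stopifnot(length(classes) == nrow(x), all(classes %in% 0:3))
  if (is.null(subjects)) subjects <- rep("S01", nrow(x))
  blocks <- sensor_blocks(colnames(x))
  for (s in sensor_set) if (length(blocks[[s]]) == 0L)
    stop_named("missing_sensor", "no feature columns for sensor %s", s)

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- scale(x, center = ctr, scale = scl)

  fl <- subject_folds(subjects, folds, derive_seed(seed, "folds"))
  G <- one_hot(classes)
  cv <- expand.grid(n = grid_n, beta = grid_beta)
  cv$accuracy <- NA_real_
  for (n in grid_n) {
    acc_fold <- matrix(NA_real_, fl$k, length(grid_beta))
    for (f in seq_len(fl$k)) {
      tpl <- templates_for(n, blocks, sensor_set, derive_seed(seed, "fold", f, n))
      tr <- fl$fold != f
      Ytr <- reservoir_outputs(Z[tr, , drop = FALSE], blocks, tpl, sensor_set, h, steps)
      Yte <- reservoir_outputs(Z[!tr, , drop = FALSE], blocks, tpl, sensor_set, h, steps)
      for (b in seq_along(grid_beta)) {
        A <- ridge_readout(G[, tr, drop = FALSE], Ytr, grid_beta[b])
        pred <- decode(A %*% Yte)
        acc_fold[f, b] <- mean(pred == classes[!tr])
      }
    }
    for (b in seq_along(grid_beta))
      cv$accuracy[cv$n == n & cv$beta == grid_beta[b]] <- mean(acc_fold[, b])
  }
  # best mean CV accuracy; ties -> smaller n, then larger beta
  ord <- order(-cv$accuracy, cv$n, -cv$beta)
  best <- cv[ord[1], ]
  tpl <- templates_for(best$n, blocks, sensor_set, derive_seed(seed, "final", best$n))
  Yall <- reservoir_outputs(Z, blocks, tpl, sensor_set, h, steps)
  A_global <- ridge_readout(G, Yall, best$beta)
  fit <- structure(list(
    templates = tpl, A_global = A_global,
    n = as.integer(best$n), beta = best$beta,
    zscore = list(center = ctr, scale = scl),
    cv = cv, sensor_set = sensor_set,
    feature_names = colnames(x), blocks = blocks,
    h = h, steps = as.integer(steps), seed = as.integer(seed),
    n_trials = nrow(x), n_subjects = length(unique(subjects))
  ), class = "cnn_esn")
  fit$train_accuracy <- 100 * mean(predict(fit, x) == classes)
  fit
}

#' Predict emotion classes with a fitted CNN classifier
#'
#' Applies the stored z-score, integrates each sensor's reservoir on each
#' trial's features, multiplexes, applies the readout and argmax-decodes.
#'
#' @param object a [cnn_esn()] fit.
#' @param newdata feature matrix or feature table with the training feature
#'   columns.
#' @param type `"class"` (default) for integer class indices 0-3,
#'   `"response"` for the 4 x T readout output matrix.
#' @param ... unused.
#' @return integer vector of class indices, or the readout matrix.
#' @export
predict.cnn_esn <- function(object, newdata, type = c("class", "response"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)$x
  if (!identical(colnames(newdata), object$feature_names))
    stop_named("feature_mismatch", "feature columns do not match the model")
  Z <- scale(newdata, center = object$zscore$center, scale = object$zscore$scale)
  Y <- reservoir_outputs(Z, object$blocks, object$templates, object$sensor_set,
                         object$h, object$steps)
  g <- object$A_global %*% Y
  if (type == "response") g else decode(g)
}

#' @export
print.cnn_esn <- function(x, ...) {
  cat("Cellular-neural-network emotion classifier (echo-state training)\n")
  cat(sprintf("  sensors: %s | cells per reservoir n = %d | ridge beta = %g\n",
              paste(x$sensor_set, collapse = ","), x$n, x$beta))
  cat(sprintf("  fitted on %d trials from %d subjects; training accuracy %.1f%%\n",
              x$n_trials, x$n_subjects, x$train_accuracy))
  invisible(x)
}

#' @export
summary.cnn_esn <- function(object, ...) {
  structure(list(fit = object), class = "summary.cnn_esn")
}

#' @export
print.summary.cnn_esn <- function(x, ...) {
  print(x$fit)
  cat("\nCross-validated grid search (mean held-out accuracy):\n")
  cvt <- x$fit$cv
  cvt$accuracy <- round(100 * cvt$accuracy, 1)
  print(cvt, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cnn_esn <- function(object, ...) object$A_global

## ---- Serialization ------------------------------------------------------

#' Write a fitted model to a JSON file
#'
#' Reservoir templates are not stored; they are regenerated exactly from
#' the stored seeds and dimensions on load. The readout matrix, z-score
#' statistics, configuration and a feature-ordering record are stored at
#' full precision.
#'
#' @param model a [cnn_esn()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_esn"))
  obj <- list(
    feature_names = model$feature_names, sensor_set = model$sensor_set,
    n = model$n, beta = model$beta, h = model$h, steps = model$steps,
    seed = model$seed, n_trials = model$n_trials,
    n_subjects = model$n_subjects, train_accuracy = model$train_accuracy,
    zscore = model$zscore,
    template_seeds = lapply(model$templates, function(tp)
      list(n = tp$n, m = tp$m, sensor = tp$sensor, seed = tp$seed)),
    A_global = apply(model$A_global, 1, identity, simplify = FALSE),
    cv = model$cv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model written by [write_model()]
#' @param path model JSON path.
#' @return a `cnn_esn` object predicting identically to the saved one.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpl <- lapply(obj$template_seeds, function(ts)
    generate_templates(ts$n, ts$m, ts$sensor, ts$seed))
  A <- obj$A_global
  A <- if (is.list(A)) do.call(rbind, A) else as.matrix(A)
  fnames <- obj$feature_names
  structure(list(
    templates = tpl, A_global = A, n = as.integer(obj$n), beta = obj$beta,
    zscore = list(center = stats::setNames(obj$zscore$center, fnames),
                  scale = stats::setNames(obj$zscore$scale, fnames)),
    cv = obj$cv, sensor_set = obj$sensor_set, feature_names = fnames,
    blocks = sensor_blocks(fnames), h = obj$h,
    steps = as.integer(obj$steps), seed = as.integer(obj$seed),
    n_trials = obj$n_trials, n_subjects = obj$n_subjects,
    train_accuracy = obj$train_accuracy
  ), class = "cnn_esn")
}
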