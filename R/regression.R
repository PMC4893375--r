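#' Random forest hyperparameters
#'
#' Defaults are the cross-validated optimum for this pipeline: 10 trees,
#' maximum depth 9, at least 10 samples per leaf.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param min_samples_leaf minimum samples per terminal node.
#' @param seed integer seed for the forest construction.
#' @return an `rf_hyperparams` list.
#' @export
rf_hyperparams <- function(n_trees = 10, max_depth = 9,
                           min_samples_leaf = 10, seed = 1) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_samples_leaf >= 1)
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 min_samples_leaf = min_samples_leaf, seed = seed),
            class = "rf_hyperparams")
}

#' Assemble a training set of features and labels
#'
#' @param features p x K matrix of normalized feature vectors
#'   (see [normalize_features()]).
#' @param labels p x 2 data frame or matrix with columns `s` and `v_hb`,
#'   both fractions in \[0, 1\].
#' @return a `training_set`.
#' @export
training_set <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.data.frame(labels)
  stopifnot(nrow(features) == nrow(labels),
            all(c("s", "v_hb") %in% names(labels)))
  if (any(labels$s < 0 | labels$s > 1) || any(labels$v_hb < 0 | labels$v_hb > 1)) {
    stop("labels must be fractions in [0, 1]")
  }
  colnames(features) <- sprintf("a%02d", seq_len(ncol(features)))
  structure(list(features = features,
                 labels = labels[c("s", "v_hb")]),
            class = "training_set")
}

new_regressor <- function(kind, fits, bands, meta) {
  structure(list(kind = kind, fits = fits,
                 band_signature = if (!is.null(bands)) band_signature(bands),
                 meta = meta, version = 1L),
            class = "mcti_regressor")
}

#' Train the random forest regressor
#'
#' The estimator of record: a forest jointly covering both targets
#' (oxygenation `s` and first-layer blood volume fraction `v_hb`), trained
#' on normalized absorption features. Implemented as paired
#' \pkg{ranger} forests (one response column each) grown from the same
#' features and seed behind a single model object. All trees use every
#' feature as split candidate.
#'
#' @param data a [training_set()].
#' @param hp an [rf_hyperparams()] object.
#' @param bands optional [band_system()] the features came from; recorded
#'   so predictions on another band system are refused.
#' @return an `mcti_regressor`.
#' @export
train_rf <- function(data, hp = rf_hyperparams(), bands = NULL) {
  stopifnot(inherits(data, "training_set"))
  if (nrow(data$features) < 2 * hp$min_samples_leaf) {
    stop("too few training samples for the requested leaf size")
  }
  for (target in c("s", "v_hb")) {
    if (sd(data$labels[[target]]) == 0) {
      warning(sprintf("training labels for '%s' are constant", target))
    }
  }
  fit_one <- function(y) {
    df <- data.frame(y = y, data$features)
    ranger::ranger(
      y ~ ., data = df,
      num.trees = hp$n_trees, max.depth = hp$max_depth,
      min.bucket = hp$min_samples_leaf,
      mtry = ncol(data$features),
      seed = hp$seed, num.threads = 1)
  }
  fits <- list(s = fit_one(data$labels$s), v_hb = fit_one(data$labels$v_hb))
  new_regressor("rf", fits, bands,
                meta = list(hp = unclass(hp), n_train = nrow(data$features),
                            n_features = ncol(data$features)))
}

#' Train the support vector regression comparator
#'
#' RBF-kernel epsilon-SVR with C = 100 and gamma = 10, one model per
#' target (SVR is not inherently multivariate). Features are used as-is
#' (already normalized), without further scaling.
#'
#' @param data a [training_set()].
#' @param cost,gamma RBF-SVR parameters.
#' @param bands optional [band_system()], as in [train_rf()].
#' @return an `mcti_regressor`.
#' @export
train_svr <- function(data, cost = 100, gamma = 10, bands = NULL) {
  stopifnot(inherits(data, "training_set"))
  fit_one <- function(y) {
    # epsilon-tube scaled to the target's spread: a blood volume fraction
    # spanning only 0-0.1 would otherwise sit entirely inside the default
    # tube of 0.1, leaving an empty model
    eps <- 0.1 * max(diff(range(y)), 1e-3)
    fit <- e1071::svm(x = data$features, y = y, type = "eps-regression",
                      kernel = "radial", cost = cost, gamma = gamma,
                      epsilon = eps, scale = FALSE)
    if (fit$tot.nSV == 0) {
      fit <- e1071::svm(x = data$features, y = y, type = "eps-regression",
                        kernel = "radial", cost = cost, gamma = gamma,
                        epsilon = eps / 10, scale = FALSE)
    }
    fit
  }
  fits <- list(s = fit_one(data$labels$s), v_hb = fit_one(data$labels$v_hb))
  new_regressor("svr", fits, bands,
                meta = list(cost = cost, gamma = gamma,
                            n_train = nrow(data$features),
                            n_features = ncol(data$features)))
}

#' Train the k-nearest-neighbors comparator
#'
#' @param data a [training_set()].
#' @param k number of neighbors (default 5).
#' @param bands optional [band_system()], as in [train_rf()].
#' @return an `mcti_regressor`.
#' @export
train_knn <- function(data, k = 5, bands = NULL) {
  stopifnot(inherits(data, "training_set"), k >= 1)
  fit_one <- function(y) caret::knnreg(data$features, y, k = k)
  fits <- list(s = fit_one(data$labels$s), v_hb = fit_one(data$labels$v_hb))
  new_regressor("knn", fits, bands,
                meta = list(k = k, n_train = nrow(data$features),
                            n_features = ncol(data$features)))
}

#' Predict oxygenation and blood volume fraction from features
#'
#' @param object an `mcti_regressor`.
#' @param features matrix (or vector) of normalized feature vectors.
#' @param bands optional [band_system()]; if both the model and this call
#'   carry one, mismatching systems are refused.
#' @param ... unused.
#' @return data frame with columns `s_hat` and `v_hb_hat`, clamped to
#'   \[0, 1\].
#' @export
predict.mcti_regressor <- function(object, features, bands = NULL, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (features_dim(object) != ncol(features)) {
    stop(sprintf("feature dimension %d does not match the model (%d)",
                 ncol(features), features_dim(object)))
  }
  if (!is.null(bands) && !is.null(object$band_signature) &&
      !identical(band_signature(bands), object$band_signature)) {
    stop("band system does not match the one the model was trained for")
  }
  colnames(features) <- sprintf("a%02d", seq_len(ncol(features)))
  predict_one <- function(fit) {
    if (inherits(fit, "ranger")) {
      predict(fit, data = as.data.frame(features), num.threads = 1)$predictions
    } else {
      as.numeric(predict(fit, features))
    }
  }
  data.frame(
    s_hat = pmin(1, pmax(0, predict_one(object$fits$s))),
    v_hb_hat = pmin(1, pmax(0, predict_one(object$fits$v_hb))))
}

features_dim <- function(model) model$meta$n_features

#' @export
print.mcti_regressor <- function(x, ...) {
  cat(sprintf("<mcti_regressor> kind = %s, %d features, trained on %d samples\n",
              x$kind, x$meta$n_features, x$meta$n_train %||% NA))
  invisible(x)
}

#' Grid search for random forest hyperparameters by cross-validation
#'
#' Five-fold cross-validation over maximum depths 3..10 and minimum leaf
#' sizes 1, 5, 10, 20, 100, scored by the mean (over folds) median absolute
#' error on oxygenation. Ties are broken toward the simpler model: smaller
#' depth first, then larger leaf.
#'
#' @param data a [training_set()].
#' @param depth_grid candidate maximum depths.
#' @param leaf_grid candidate minimum leaf sizes.
#' @param folds number of CV folds.
#' @param n_trees trees per candidate forest.
#' @param seed integer seed for fold assignment and forests.
#' @return the selected [rf_hyperparams()], with the full CV table in
#'   attribute `"cv_table"`.
#' @export
grid_search_rf <- function(data, depth_grid = 3:10,
                           leaf_grid = c(1, 5, 10, 20, 100),
                           folds = 5, n_trees = 10, seed = 1) {
  stopifnot(inherits(data, "training_set"))
  p <- nrow(data$features)
  if (p < folds) stop("fewer samples than folds")
  fold_id <- with_local_seed(seed, function() sample(rep_len(seq_len(folds), p)))

  grid <- expand.grid(max_depth = depth_grid, min_samples_leaf = leaf_grid)
  grid$cv_error <- NA_real_
  for (i in seq_len(nrow(grid))) {
    errs <- numeric(0)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sd(data$labels$s[tr]) == 0) {
        warning(sprintf("fold %d skipped: constant labels", f))
        next
      }
      hp <- rf_hyperparams(n_trees = n_trees, max_depth = grid$max_depth[i],
                           min_samples_leaf = grid$min_samples_leaf[i],
                           seed = seed)
      fit <- tryCatch(
        train_rf(training_set(data$features[tr, , drop = FALSE],
                              data$labels[tr, , drop = FALSE]), hp),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict(fit, data$features[!tr, , drop = FALSE])
      errs <- c(errs, median(abs(pred$s_hat - data$labels$s[!tr])))
    }
    grid$cv_error[i] <- mean(errs)
  }
  ord <- order(grid$cv_error, grid$max_depth, -grid$min_samples_leaf)
  best <- grid[ord[1], ]
  out <- rf_hyperparams(n_trees = n_trees, max_depth = best$max_depth,
                        min_samples_leaf = best$min_samples_leaf, seed = seed)
  attr(out, "cv_table") <- grid
  out
}

#' Modified Beer-Lambert oxygenation estimate (training-free baseline)
#'
#' Linear spectral unmixing of the band absorbances: with
#' A_k = -log(r_k / sum_j r_j), fit by least squares
#' A ~ x1 * eps_HbO2_k + x2 * eps_Hb_k + x3, where the extinction
#' coefficients are band-averaged over each transmission profile and the
#' constant offset absorbs wavelength-independent scattering losses. The
#' oxygenation estimate is x1 / (x1 + x2), clamped to \[0, 1\]; when
#' x1 + x2 <= 0 the estimate is undefined and `NA` is returned.
#'
#' This baseline assumes a wavelength-independent optical pathlength and
#' scattering loss, which real tissue violates — the bias this induces is
#' what the learned regressors avoid. It has no training stage and cannot
#' estimate blood volume fraction (only the ratio of the two hemoglobin
#' species is identified).
#'
#' @param r_k numeric vector of K >= 3 band values, or an n x K matrix.
#' @param bands the [band_system()] the measurement came from.
#' @param table a [chromophore_table][load_extinction_table].
#' @return numeric vector of oxygenation estimates (NA where undefined).
#' @export
beer_lambert_estimate <- function(r_k, bands, table = default_extinction_table()) {
  stopifnot(inherits(bands, "band_system"))
  K <- length(bands$centers)
  if (K < 3) stop("the Beer-Lambert fit needs at least three bands")
  eps <- extinction_at(table, bands$grid)
  X <- cbind(hbo2 = as.numeric(bands$transmissions %*% eps$eps_hbo2),
             hb = as.numeric(bands$transmissions %*% eps$eps_hb),
             offset = 1)
  if (qr(X)$rank < 3) stop("singular Beer-Lambert design matrix")

  one <- function(r) {
    l1 <- sum(abs(r))
    if (l1 == 0) return(NA_real_)
    r <- pmax(r, 1e-6 * l1)
    A <- -log(r / sum(r))
    coefs <- qr.coef(qr(X), A)
    x1 <- coefs[["hbo2"]]; x2 <- coefs[["hb"]]
    if (!is.finite(x1) || !is.finite(x2) || (x1 + x2) <= 0) return(NA_real_)
    min(1, max(0, x1 / (x1 + x2)))
  }
  if (is.matrix(r_k)) apply(r_k, 1, one) else one(as.numeric(r_k))
}

#' Save / load a trained regressor
#'
#' The on-disk model carries a format version and the band-system
#' signature; loading refuses files from a different format version. A
#' human-readable YAML sidecar (`<path>.yaml`) records kind,
#' hyperparameters, training size and the band-system signature.
#'
#' @param model an `mcti_regressor`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mcti_regressor"))
  saveRDS(model, path)
  yaml::write_yaml(
    list(kind = model$kind, meta = model$meta,
         band_signature = model$band_signature, version = model$version),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("cannot read model file: ",
                                             conditionMessage(e)))
  if (!inherits(model, "mcti_regressor")) stop("not an mcti model file")
  if (!identical(model$version, 1L)) {
    stop("unsupported model format version: ", model$version)
  }
  model
}
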