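#' Extract the curated 22-feature vector per specimen
#'
#' Maps each specimen's binned activity series to the curated set of 22
#' canonical time-series features (distributional shape, autocorrelation
#' timescales, binary/motif symbolic statistics, fluctuation scaling,
#' spectral summaries, outlier timing, periodicity). The mapping is
#' deterministic: identical series give identical rows. Series shorter
#' than `min_len` bins are excluded and reported via the `excluded`
#' attribute; constant series keep their row with the affected features
#' `NA` and are listed in the `flagged` attribute.
#'
#' @param binned A tibble (`id`, `t`, value column) of per-specimen binned
#'   activity, e.g. [bin_time()] output.
#' @param value_col Name of the activity column (default `"value"`).
#' @param min_len Minimum series length in bins (default 10).
#' @return A tibble: `id` plus 22 named feature columns, row order
#'   following the input's specimen order.
#' @export
extract_curated_features <- function(binned, value_col = "value",
                                     min_len = 10) {
  stopifnot(all(c("id", value_col) %in% names(binned)))
  ids <- unique(binned$id)
  rows <- list(); excluded <- character(); flagged <- character()
  for (one_id in ids) {
    x <- binned[[value_col]][binned$id == one_id]
    if ("t" %in% names(binned)) {
      x <- x[order(binned$t[binned$id == one_id])]
    }
    if (length(x) < min_len || any(!is.finite(x))) {
      excluded <- c(excluded, one_id)
      next
    }
    f <- compute_curated_features(x)
    if (all(is.na(f))) flagged <- c(flagged, one_id)
    rows[[length(rows) + 1]] <-
      dplyr::bind_cols(tibble::tibble(id = one_id),
                       tibble::as_tibble(as.list(f)))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    empty <- stats::setNames(rep(list(numeric(0)),
                                 length(curated_feature_names())),
                             curated_feature_names())
    dplyr::bind_cols(tibble::tibble(id = character(0)),
                     tibble::as_tibble(empty))
  }
  attr(out, "excluded") <- excluded
  attr(out, "flagged") <- flagged
  out
}

#' Standardize feature columns
#'
#' Centres and scales every feature column to mean 0, sd 1. Zero-variance
#' (or all-`NA`) columns are set to 0 and reported via the
#' `zero_variance` attribute; remaining `NA` cells are imputed with the
#' column mean (0 after standardization).
#'
#' @param fm A feature matrix tibble from [extract_curated_features()].
#' @return The standardized tibble.
#' @export
zscore_features <- function(fm) {
  stopifnot("id" %in% names(fm))
  num_cols <- setdiff(names(fm), "id")
  zero_var <- character()
  for (col in num_cols) {
    v <- fm[[col]]
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      fm[[col]] <- rep(0, nrow(fm))
      zero_var <- c(zero_var, col)
    } else {
      v <- (v - mu) / s
      v[is.na(v)] <- 0
      fm[[col]] <- v
    }
  }
  attr(fm, "zero_variance") <- zero_var
  fm
}

#' Cross-validated phenotype classification
#'
#' Fits an RBF-kernel support vector machine (one-vs-one for more than two
#' classes) to the standardized feature matrix and estimates accuracy by
#' stratified k-fold cross-validation with seeded fold assignment.
#'
#' @param fm Feature matrix tibble (`id` + numeric columns); standardized
#'   internally via [zscore_features()].
#' @param labels Class label per row of `fm` (character or factor), or the
#'   name of a metadata column together with `meta`.
#' @param meta Optional metadata table supplying `labels` by id.
#' @param k_folds Number of stratified folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses the
#'   1/(number of features) heuristic.
#' @return A list of class `phenotype_cv`: `$accuracy`, `$predictions`
#'   (tibble `id`, `label`, `predicted`, `fold`), `$confusion`, `$model`
#'   (an SVM refit on all data), `$k_folds`.
#' @export
classify_phenotypes <- function(fm, labels, meta = NULL, k_folds = 5,
                                seed = 1, cost = 1, gamma = NULL) {
  if (is.character(labels) && length(labels) == 1 && !is.null(meta)) {
    lab_map <- stats::setNames(as.character(meta[[labels]]), meta$id)
    labels <- lab_map[fm$id]
  }
  y <- factor(as.character(labels))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  counts <- table(y)
  if (any(counts < k_folds)) {
    small <- names(counts)[counts < k_folds]
    stop("class(es) ", paste(small, collapse = ", "), " have fewer than ",
         k_folds, " specimens; use a smaller k_folds", call. = FALSE)
  }
  fm_std <- zscore_features(fm)
  X <- as.matrix(fm_std[setdiff(names(fm_std), "id")])
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  # stratified fold assignment, seeded
  set.seed(seed)
  fold <- integer(nrow(X))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }

  pred <- rep(NA_character_, nrow(X))
  for (k in seq_len(k_folds)) {
    train <- fold != k
    model <- svm_fit(X[train, , drop = FALSE], y[train],
                     cost = cost, gamma = gamma)
    pred[!train] <- as.character(svm_predict(model, X[!train, , drop = FALSE]))
  }
  predictions <- tibble::tibble(id = fm$id, label = as.character(y),
                                predicted = pred, fold = fold)
  accuracy <- mean(pred == as.character(y))
  full <- svm_fit(X, y, cost = cost, gamma = gamma)
  structure(list(accuracy = accuracy, predictions = predictions,
                 confusion = table(truth = y, predicted = pred),
                 model = full, k_folds = k_folds, gamma = gamma,
                 cost = cost),
            class = "phenotype_cv")
}

#' @export
print.phenotype_cv <- function(x, ...) {
  cat(sprintf("<phenotype_cv> %d-fold CV accuracy: %.3f\n",
              x$k_folds, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' @method tidy phenotype_cv
#' @export
tidy.phenotype_cv <- function(x, ...) x$predictions

#' @method glance phenotype_cv
#' @export
glance.phenotype_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, k_folds = x$k_folds,
                 n = nrow(x$predictions),
                 n_classes = nlevels(factor(x$predictions$label)),
                 cost = x$cost, gamma = x$gamma)
}

#' Decision surface of the classifier in feature space
#'
#' Projects the standardized features onto their first two principal axes,
#' fits the SVM in that plane, and evaluates it on a rectangular grid
#' covering the bounding box of the projected data -- the standard way to
#' draw classifier decision boundaries.
#'
#' @param fm Feature matrix tibble.
#' @param labels Class labels (vector, or metadata column name with
#'   `meta`).
#' @param meta Optional metadata.
#' @param grid_resolution Nodes per axis (default 100).
#' @param cost,gamma SVM hyperparameters as in [classify_phenotypes()].
#' @return A list of class `decision_surface`: `$grid` (tibble `pc1`,
#'   `pc2`, `predicted`), `$points` (projected specimens with labels and
#'   model predictions), `$explained` (variance share of the two axes),
#'   `$model`.
#' @export
decision_surface <- function(fm, labels, meta = NULL,
                             grid_resolution = 100, cost = 1,
                             gamma = NULL) {
  if (is.character(labels) && length(labels) == 1 && !is.null(meta)) {
    lab_map <- stats::setNames(as.character(meta[[labels]]), meta$id)
    labels <- lab_map[fm$id]
  }
  y <- factor(as.character(labels))
  fm_std <- zscore_features(fm)
  X <- as.matrix(fm_std[setdiff(names(fm_std), "id")])
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  pca <- stats::prcomp(X[, keep, drop = FALSE], center = FALSE,
                       scale. = FALSE)
  P <- pca$x[, 1:2, drop = FALSE]
  colnames(P) <- c("pc1", "pc2")
  if (is.null(gamma)) gamma <- 1 / 2
  one_class <- nlevels(y) < 2
  model <- if (one_class) NULL else svm_fit(P, y, cost = cost,
                                            gamma = gamma)
  predict_fn <- function(nodes) {
    if (one_class) rep(levels(y)[1], nrow(nodes))
    else as.character(svm_predict(model, nodes))
  }

  gx <- seq(min(P[, 1]), max(P[, 1]), length.out = grid_resolution)
  gy <- seq(min(P[, 2]), max(P[, 2]), length.out = grid_resolution)
  nodes <- as.matrix(expand.grid(pc1 = gx, pc2 = gy))
  grid <- tibble::tibble(
    pc1 = nodes[, 1], pc2 = nodes[, 2],
    predicted = predict_fn(nodes)
  )
  points <- tibble::tibble(
    id = fm$id, pc1 = P[, 1], pc2 = P[, 2],
    label = as.character(y),
    predicted = predict_fn(P)
  )
  explained <- (pca$sdev^2 / sum(pca$sdev^2))[1:2]
  structure(list(grid = grid, points = points, explained = explained,
                 model = model),
            class = "decision_surface")
}

#' Export per-specimen series for external feature toolboxes
#'
#' Writes one plain-text file per specimen (one value per line) plus a CSV
#' manifest (`id`, `file`, metadata columns) -- the interchange bundle for
#' massive external feature-extraction toolboxes, whose execution is out
#' of scope here.
#'
#' @param binned A tibble (`id`, `t`, value column).
#' @param out_dir Output directory (created if needed).
#' @param value_col Activity column name.
#' @param meta Optional metadata merged into the manifest.
#' @return The manifest tibble, invisibly.
#' @export
export_timeseries_bundle <- function(binned, out_dir, value_col = "value",
                                     meta = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- unique(binned$id)
  files <- character(length(ids))
  for (k in seq_along(ids)) {
    df <- binned[binned$id == ids[k], ]
    if ("t" %in% names(df)) df <- df[order(df$t), ]
    fname <- paste0("series_", sprintf("%04d", k), ".txt")
    writeLines(format(df[[value_col]], trim = TRUE, scientific = FALSE),
               file.path(out_dir, fname))
    files[k] <- fname
  }
  manifest <- tibble::tibble(id = ids, file = files)
  if (!is.null(meta)) {
    manifest <- dplyr::left_join(manifest, meta, by = "id")
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
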