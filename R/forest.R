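# Bagged decision-tree (random forest) baseline: bootstrap resampling,
# random feature subsetting at each split, equal-weight majority vote.
# Tree growing is delegated to the randomForest package; the vote
# aggregation, tie rule, tree-count tuning and cross-validation protocol
# live here.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500; learning-curve tuning via
#'   [tune_n_trees()] selects a count for a given dataset).
#' @param max_features `"sqrt"` (floor of the square root of the feature
#'   count, the standard classification rule) or an explicit integer number
#'   of candidate features per split.
#' @param seed Integer seed; fits and fold assignments are deterministic
#'   given it.
#' @param cv_folds Folds for cross-validation (default 10).
#' @return A `forest_config` object.
#' @export
forest_config <- function(n_trees = 500, max_features = "sqrt", seed = 1L,
                          cv_folds = 10) {
  stopifnot(n_trees >= 1, cv_folds >= 2)
  if (!identical(max_features, "sqrt")) {
    stopifnot(is.numeric(max_features), max_features >= 1)
  }
  structure(
    list(n_trees = as.integer(n_trees), max_features = max_features,
         seed = as.integer(seed), cv_folds = as.integer(cv_folds)),
    class = "forest_config"
  )
}

resolve_mtry <- function(config, p) {
  m <- if (identical(config$max_features, "sqrt")) floor(sqrt(p)) else config$max_features
  m <- max(1L, min(as.integer(m), p))
  m
}

forest_features <- function(data, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c("crash_id", "year", "severity",
                                         "numvehs", "vehno"))
  }
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    abort(paste0("Feature column(s) absent: ", paste(missing, collapse = ", ")))
  }
  covariates
}

#' Fit the random-forest severity classifier
#'
#' Each of `n_trees` trees is grown on a bootstrap resample of the data
#' (same size, with replacement), choosing among a random subset of
#' features at every split (`sqrt` rule by default). The same seed always
#' yields the same ensemble.
#'
#' @param data Crash tibble with a `severity` column.
#' @param config A [forest_config()].
#' @param covariates Feature columns; defaults to every column except
#'   identifiers and the outcome.
#' @return A `severity_forest` object.
#' @export
fit_forest <- function(data, config = forest_config(), covariates = NULL) {
  covariates <- forest_features(data, covariates)
  y <- droplevels(as_severity(data$severity))
  if (nlevels(y) < 2) abort("Training data must contain at least two severity classes.")
  x <- as.data.frame(lapply(data[covariates], as.numeric))
  rf <- withr::with_seed(config$seed, {
    randomForest::randomForest(
      x = x, y = y,
      ntree = config$n_trees,
      mtry = resolve_mtry(config, length(covariates))
    )
  })
  structure(
    list(rf = rf, covariates = covariates, config = config,
         classes = levels(y)),
    class = "severity_forest"
  )
}

#' Majority vote over per-class vote counts
#'
#' Collapses a matrix of per-tree vote counts (columns named by severity
#' level) to predicted labels: the class with the most votes wins, and ties
#' break toward the less severe level.
#'
#' @param votes Numeric matrix, one row per observation, columns a subset
#'   of [severity_levels()].
#' @return Factor of predicted labels over [severity_levels()].
#' @export
#' @examples
#' majority_vote(rbind(c(PDO = 2, I = 1, FI = 0), c(PDO = 1, I = 1, FI = 1)))
majority_vote <- function(votes) {
  lv <- severity_levels()
  cols <- intersect(lv, colnames(votes))
  if (length(cols) == 0) abort("`votes` must have severity-level column names.")
  full <- matrix(0, nrow(votes), length(lv), dimnames = list(NULL, lv))
  full[, cols] <- as.matrix(votes[, cols, drop = FALSE])
  idx <- apply(full, 1, which.max) # first maximum = least severe level
  factor(lv[idx], levels = lv)
}

#' Predict severity with a fitted forest
#'
#' Collects each tree's vote (equal weights) and applies [majority_vote()].
#'
#' @param fit A `severity_forest`.
#' @param data Crash tibble with the fit's feature columns.
#' @return A tibble with per-level vote counts (summing to `n_trees` per
#'   row) and the `.pred_class` label.
#' @export
predict_forest <- function(fit, data) {
  stopifnot(inherits(fit, "severity_forest"))
  x <- as.data.frame(lapply(data[forest_features(data, fit$covariates)],
                            as.numeric))
  votes <- stats::predict(fit$rf, newdata = x, type = "vote", norm.votes = FALSE)
  out <- tibble::as_tibble(as.data.frame(votes))
  out$.pred_class <- majority_vote(votes)
  out
}

# Seeded stratified fold assignment: within each class, indices are
# shuffled and dealt round-robin; the deal continues across classes (one
# global stream), so every fold's class shares track the global shares as
# closely as integer counts allow and fold sizes differ by at most one.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  offset <- 0L
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) > 0 && length(idx) < k) {
        warn(sprintf(
          "Class %s has %d member(s), fewer than %d folds; stratification is degraded for it.",
          dQuote(as.character(cls), q = FALSE), length(idx), k
        ))
      }
      idx <- sample(idx)
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `cv_folds` stratified folds, fits the model on each
#' training complement and predicts the held-out fold, so every row is
#' predicted exactly once out-of-fold. The pooled predictions define the
#' cross-validated confusion matrix and accuracy.
#'
#' @param data Crash tibble with a `severity` column.
#' @param config A [forest_config()] (supplies folds and the fold seed).
#' @param fitter Function `(train_data) -> model`; defaults to
#'   [fit_forest()] with `config`.
#' @param predictor Function `(model, test_data) -> labels`; defaults to
#'   [predict_forest()]'s `.pred_class`.
#' @return A list: `predictions` (tibble with `.row`, `fold`, `actual`,
#'   `predicted`), `confusion` (a [confusion_matrix()]), `accuracy`.
#' @export
kfold_cv <- function(data, config = forest_config(), fitter = NULL,
                     predictor = NULL) {
  stopifnot(nrow(data) >= config$cv_folds)
  y <- as_severity(data$severity)
  folds <- stratified_folds(y, config$cv_folds, config$seed)
  if (is.null(fitter)) {
    fitter <- function(train) fit_forest(train, config)
  }
  if (is.null(predictor)) {
    predictor <- function(model, test) predict_forest(model, test)$.pred_class
  }
  predicted <- factor(rep(NA_character_, nrow(data)), levels = severity_levels())
  for (f in seq_len(config$cv_folds)) {
    test_idx <- which(folds == f)
    model <- withr::with_seed(config$seed + f, fitter(data[-test_idx, , drop = FALSE]))
    predicted[test_idx] <- predictor(model, data[test_idx, , drop = FALSE])
  }
  preds <- tibble::tibble(
    .row = seq_len(nrow(data)), fold = folds,
    actual = y, predicted = predicted
  )
  cm <- confusion_matrix(preds$actual, preds$predicted)
  list(predictions = preds, confusion = cm, accuracy = overall_accuracy(cm))
}

#' Tune the number of trees by cross-validated learning curve
#'
#' Evaluates cross-validated accuracy for each candidate tree count and
#' selects the maximiser, preferring the smallest count on ties. The full
#' curve is returned for plotting (see [plot_learning_curve()]).
#'
#' @param data Crash tibble.
#' @param grid Candidate tree counts (positive integers).
#' @param config A [forest_config()]; its `n_trees` is overridden per
#'   candidate.
#' @return A list: `curve` (tibble `n_trees`, `cv_accuracy`) and
#'   `selected` (the chosen count).
#' @export
tune_n_trees <- function(data, grid, config = forest_config()) {
  if (length(grid) == 0) abort("`grid` must be nonempty.")
  if (any(grid < 1)) abort("Tree counts must be positive.")
  grid <- sort(unique(as.integer(grid)))
  acc <- vapply(grid, function(nt) {
    cfg <- config
    cfg$n_trees <- nt
    kfold_cv(data, cfg)$accuracy
  }, numeric(1))
  curve <- tibble::tibble(n_trees = grid, cv_accuracy = acc)
  list(curve = curve, selected = grid[which.max(acc)])
}
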