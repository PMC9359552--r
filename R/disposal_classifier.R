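#' Random-Forest configuration for the disposal classifier
#'
#' The final model hyperparameters: 500 trees, maximum depth 10, minimum of
#' 50 samples to split a node, minimum leaf size 5, Gini impurity, and an
#' 80:20 train/test split. `elim_tol` is the macro-F1 tolerance used by the
#' importance-guided feature elimination (a removal counts as a performance
#' decrease only when held-out macro-F1 falls more than `elim_tol` below the
#' best seen); `val_fraction` is the share of the training data carved out
#' as the elimination's held-out fold.
#'
#' @param n_trees,max_depth,min_split,min_leaf Forest constraints.
#' @param criterion Split criterion; only `"gini"` is supported.
#' @param train_fraction Fraction of samples in the training split.
#' @param seed Integer seed controlling the split and the forest.
#' @param val_fraction Validation share for feature elimination.
#' @param elim_tol Macro-F1 decrease tolerance for elimination.
#' @return Object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500L, max_depth = 10L, min_split = 50L,
                      min_leaf = 5L, criterion = "gini", train_fraction = 0.8,
                      seed = 1L, val_fraction = 0.1, elim_tol = 0.01) {
  stopifnot(
    n_trees > 0, max_depth > 0, min_split > 0, min_leaf > 0,
    train_fraction > 0, train_fraction < 1, criterion == "gini",
    val_fraction > 0, val_fraction < 1, elim_tol >= 0
  )
  structure(
    list(
      n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
      min_split = as.integer(min_split), min_leaf = as.integer(min_leaf),
      criterion = criterion, train_fraction = train_fraction,
      seed = as.integer(seed), val_fraction = val_fraction,
      elim_tol = elim_tol
    ),
    class = "rf_config"
  )
}

## Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Stratified index split: n_take indices overall, class shares preserved by
## the floor rule with the remainder going to the largest fractional parts.
.stratified_take <- function(y, fraction, seed) {
  y <- as.factor(y)
  n <- length(y)
  n_take <- floor(fraction * n)
  classes <- levels(y)
  n_c <- table(y)[classes]
  raw <- fraction * as.numeric(n_c)
  base <- floor(raw)
  rem <- n_take - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(classes))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  .with_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      idx <- which(y == classes[k])
      sort(sample(idx, base[k]))
    }), use.names = FALSE)
  })
}

#' Stratified train/test split
#'
#' Deterministic stratified split: the training set holds
#' `floor(train_fraction * n)` samples with per-class counts preserved
#' (floor rule, remainder to the largest fractional shares), drawn with the
#' configured seed.
#'
#' @param x Feature data frame.
#' @param y Class labels (factor or character), one per row of `x`.
#' @param config An [rf_config()].
#' @return List with integer index vectors `train` and `test`.
#' @export
split_data <- function(x, y, config = rf_config()) {
  stopifnot(nrow(x) == length(y))
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts == 0)) {
    stop(
      "class absent from data: ",
      paste(names(counts)[counts == 0], collapse = ", "),
      call. = FALSE
    )
  }
  if (any(counts < 10)) {
    stop(
      "need at least 10 samples per class; short: ",
      paste(names(counts)[counts < 10], collapse = ", "),
      call. = FALSE
    )
  }
  train <- sort(.stratified_take(y, config$train_fraction, config$seed))
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Train the disposal-congestion Random Forest
#'
#' Fits a classification forest with the configured constraints (number of
#' trees, maximum depth, minimum split size, minimum leaf size, Gini
#' impurity) and impurity-based feature importances, reproducible under the
#' configured seed.
#'
#' @param x Feature data frame (numeric columns).
#' @param y Class labels, one per row of `x`.
#' @param config An [rf_config()].
#' @return Object of class `congestion_rf` wrapping the fitted forest.
#' @export
train_rf <- function(x, y, config = rf_config()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    max.depth = config$max_depth,
    min.node.size = config$min_split,
    min.bucket = config$min_leaf,
    splitrule = "gini",
    importance = "impurity",
    probability = FALSE,
    seed = config$seed,
    num.threads = 1,
    verbose = FALSE
  )
  structure(
    list(fit = fit, features = colnames(x), levels = levels(y), config = config),
    class = "congestion_rf"
  )
}

#' @export
print.congestion_rf <- function(x, ...) {
  cat(sprintf(
    "<congestion_rf> %d trees on %d feature(s), classes: %s\n",
    x$config$n_trees, length(x$features), paste(x$levels, collapse = ", ")
  ))
  invisible(x)
}

#' Class scores as forest vote fractions
#'
#' Fraction of the trees voting for each class, per sample. These are the
#' scores the ROC and PR curves are computed from.
#'
#' @param model A `congestion_rf` from [train_rf()].
#' @param x Feature data frame with the model's feature columns.
#' @return Numeric matrix, one column per class (model level order).
#' @export
predict_votes <- function(model, x) {
  stopifnot(inherits(model, "congestion_rf"))
  x <- x[, model$features, drop = FALSE]
  pred <- stats::predict(model$fit,
    data = x, predict.all = TRUE,
    num.threads = 1
  )$predictions
  forest_levels <- model$fit$forest$levels # predict.all codes index these
  votes <- vapply(
    model$levels,
    function(l) rowMeans(pred == match(l, forest_levels)),
    numeric(nrow(x))
  )
  votes <- matrix(votes, nrow = nrow(x))
  colnames(votes) <- model$levels
  votes
}

#' Predicted classes
#'
#' Majority vote over the forest; ties resolve to the earliest class level,
#' making predictions deterministic.
#'
#' @inheritParams predict_votes
#' @return Factor of predicted classes.
#' @export
predict_class <- function(model, x) {
  votes <- predict_votes(model, x)
  factor(model$levels[max.col(votes, ties.method = "first")],
    levels = model$levels
  )
}

#' Importance-guided feature elimination
#'
#' Carves a stratified held-out fold from the supplied training data,
#' then iteratively removes the feature with the lowest impurity importance
#' and refits, stopping (and restoring the last removal) once held-out
#' macro-F1 drops more than `elim_tol` below the best seen.
#'
#' @param x Training feature data frame.
#' @param y Training labels.
#' @param config An [rf_config()].
#' @return Character vector of retained feature names; the elimination trace
#'   (feature dropped, macro-F1 after each refit) is attached as attribute
#'   `trace`.
#' @export
eliminate_features <- function(x, y, config = rf_config()) {
  stopifnot(ncol(x) >= 2L)
  y <- as.factor(y)
  val_idx <- sort(.stratified_take(y, config$val_fraction, config$seed + 1L))
  fit_idx <- setdiff(seq_along(y), val_idx)

  score_with <- function(feats) {
    m <- train_rf(x[fit_idx, feats, drop = FALSE], y[fit_idx], config)
    list(
      model = m,
      f1 = macro_f1(y[val_idx], predict_class(m, x[val_idx, feats, drop = FALSE]),
        levels = levels(y)
      )
    )
  }

  feats <- colnames(x)
  cur <- score_with(feats)
  best_f1 <- cur$f1
  trace <- data.frame(
    dropped = NA_character_, macro_f1 = cur$f1,
    n_features = length(feats), stringsAsFactors = FALSE
  )
  while (length(feats) > 1L) {
    imp <- cur$model$fit$variable.importance[feats]
    weakest <- feats[which.min(imp)]
    cand <- setdiff(feats, weakest)
    nxt <- score_with(cand)
    trace <- rbind(trace, data.frame(
      dropped = weakest, macro_f1 = nxt$f1,
      n_features = length(cand), stringsAsFactors = FALSE
    ))
    if (nxt$f1 < best_f1 - config$elim_tol) break # restore last drop and stop
    feats <- cand
    cur <- nxt
    best_f1 <- max(best_f1, nxt$f1)
  }
  attr(feats, "trace") <- trace
  feats
}

#' Evaluate the classifier on a test set
#'
#' Computes the full evaluation report: per-class precision, recall and F1,
#' the confusion matrix, per-class one-vs-all ROC-AUC and PR-AUC from the
#' forest vote fractions, the micro-average ROC curve and its AUC, and the
#' normalised impurity feature importances.
#'
#' @param model A `congestion_rf`.
#' @param x Test feature data frame.
#' @param y Test labels.
#' @return Object of class `eval_report`.
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "congestion_rf"), nrow(x) == length(y))
  y <- factor(y, levels = model$levels)
  votes <- predict_votes(model, x)
  pred <- factor(model$levels[max.col(votes, ties.method = "first")],
    levels = model$levels
  )
  cm <- confusion_matrix(y, pred, levels = model$levels)
  per_class <- precision_recall_f1(cm)
  per_class$roc_auc <- vapply(
    model$levels,
    function(l) roc_auc(y == l, votes[, l]), numeric(1)
  )
  per_class$pr_auc <- vapply(
    model$levels,
    function(l) pr_auc(y == l, votes[, l]), numeric(1)
  )
  mr <- micro_roc(y, votes)
  imp <- model$fit$variable.importance
  imp <- imp / sum(imp)
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      macro_f1 = mean(per_class$f1, na.rm = TRUE),
      accuracy = sum(diag(cm)) / sum(cm),
      roc_auc_micro = mr$auc,
      micro_roc_points = mr$points,
      importance = imp
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  m <- round(
    as.matrix(x$per_class[, c("precision", "recall", "f1", "roc_auc", "pr_auc")]),
    3
  )
  rownames(m) <- x$per_class$class
  print(m)
  cat(sprintf(
    "macro-F1 %.3f | accuracy %.3f | micro ROC-AUC %.3f\n",
    x$macro_f1, x$accuracy, x$roc_auc_micro
  ))
  invisible(x)
}
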