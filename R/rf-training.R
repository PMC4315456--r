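# Per-rank random-forest training with the tuning protocol:
# default-mtry formula, stepFactor/improve OOB search, ntree saturation,
# and the permutation-importance variable-pruning experiment.

#' Default mtry for a k-mer model
#'
#' Half of the square root of the number of possible k-mers, floored and at
#' least 1: `floor(sqrt(4^k) / 2)`. For k = 4 this is 8, the value used for
#' the final models.
#'
#' @param k k-mer size.
#' @return an integer.
#' @export
default_mtry <- function(k) {
  max(1L, as.integer(floor(sqrt(feature_space_size(k)) / 2)))
}

# One OOB-error evaluation at a fixed mtry; the shared seed keeps the
# bootstrap streams identical across mtry values so errors are comparable.
oob_error_at <- function(features, labels, mtry, ntree, seed) {
  fit <- with_seed(seed, randomForest::randomForest(
    x = features, y = labels, ntree = ntree, mtry = mtry))
  unname(fit$err.rate[ntree, "OOB"])
}

# k-fold cross-validated error at a fixed mtry; folds are drawn once from
# the shared seed so every mtry sees the same partition.
cv_error_at <- function(features, labels, mtry, ntree, seed, folds) {
  n <- nrow(features)
  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(folds), n))
    wrong <- 0L
    for (f in seq_len(folds)) {
      test <- fold_id == f
      train_y <- droplevels(labels[!test])
      fit <- randomForest::randomForest(
        x = features[!test, , drop = FALSE], y = train_y,
        ntree = ntree, mtry = min(mtry, ncol(features)))
      pred <- stats::predict(fit, features[test, , drop = FALSE])
      wrong <- wrong + sum(as.character(pred) !=
                             as.character(labels[test]))
    }
    wrong / n
  })
}

#' Search for the mtry with lowest out-of-bag error
#'
#' Starts from `floor(sqrt(p)/2)` (p = number of feature columns) and, in
#' the manner of `randomForest::tuneRF`, walks downward (divide by
#' `step_factor`, round half-up) and then upward (multiply), continuing in a
#' direction while the relative OOB improvement over the best error so far
#' exceeds `improve`. Deterministic given `seed`: every candidate forest is
#' grown from the same seeded RNG state.
#'
#' @param features numeric feature matrix (rows = sequences).
#' @param labels factor or character vector of class labels (>= 2 classes).
#' @param ntree trees per candidate forest.
#' @param step_factor multiplicative step for the mtry walk (default 1.5).
#' @param improve minimum relative OOB improvement to keep walking
#'   (default 0.02).
#' @param seed integer seed.
#' @param error_estimate `"oob"` (default; tuneRF semantics) or `"cv"`,
#'   which scores each candidate mtry by `cv_folds`-fold cross-validated
#'   error instead of the forest's out-of-bag estimate.
#' @param cv_folds folds for `error_estimate = "cv"` (default 10).
#' @return a `tune_trace`: data.frame of visited `(mtry, oob_error)` in
#'   visit order, with attribute `chosen_mtry` (the visited mtry attaining
#'   the minimum OOB error; ties go to the first visited).
#' @export
tune_mtry <- function(features, labels, ntree = 100, step_factor = 1.5,
                      improve = 0.02, seed = 1L,
                      error_estimate = c("oob", "cv"), cv_folds = 10) {
  error_estimate <- match.arg(error_estimate)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("degenerate label space", call. = FALSE)
  p <- ncol(features)
  start <- max(1L, as.integer(floor(sqrt(p) / 2)))
  visited <- integer(0)
  errors <- numeric(0)
  eval_mtry <- function(m) {
    e <- if (error_estimate == "oob") {
      oob_error_at(features, labels, m, ntree, seed)
    } else {
      cv_error_at(features, labels, m, ntree, seed, cv_folds)
    }
    visited <<- c(visited, m)
    errors <<- c(errors, e)
    e
  }
  best <- eval_mtry(start)
  for (dir in c("down", "up")) {
    cur <- start
    repeat {
      nxt <- if (dir == "down") round_half_up(cur / step_factor)
             else round_half_up(cur * step_factor)
      nxt <- max(1L, min(p, as.integer(nxt)))
      if (nxt == cur || nxt %in% visited) break
      e <- eval_mtry(nxt)
      gain <- if (best > 0) (best - e) / best else (best - e)
      if (gain > improve) {
        best <- min(best, e)
        cur <- nxt
      } else break
    }
  }
  trace <- data.frame(mtry = visited, oob_error = errors)
  chosen <- visited[which.min(errors)]
  structure(trace, chosen_mtry = chosen, class = c("tune_trace",
                                                   "data.frame"))
}

#' Train one rank's forest
#'
#' Fits a bagged classification forest (each tree grown on a bootstrap
#' sample, about two-thirds of the data in-bag) and records the out-of-bag
#' error and the unscaled permutation importance (mean decrease in OOB
#' accuracy) of every variable.
#'
#' @param features numeric feature matrix.
#' @param labels class labels aligned with rows of `features`.
#' @param rank the taxonomic rank these labels come from.
#' @param k k-mer size used to build `features`.
#' @param ntree number of trees (default 1000).
#' @param mtry variables tried per split; default [default_mtry()] of `k`.
#' @param seed integer seed.
#' @param rare_label_action what to do with labels having fewer than 2
#'   training sequences: `"drop"` them with a warning or `"error"`.
#' @return a `rank_model` list: `rank`, `label_space`, `k`,
#'   `variable_subset`, `mtry`, `ntree`, `oob_error`,
#'   `permutation_importance`, `model` (the randomForest fit) and
#'   `training_manifest`.
#' @export
train_rank_model <- function(features, labels, rank, k, ntree = 1000,
                             mtry = NULL, seed = 1L,
                             rare_label_action = c("drop", "error")) {
  rare_label_action <- match.arg(rare_label_action)
  labels <- as.character(labels)
  counts <- table(labels)
  rare <- names(counts)[counts < 2]
  if (length(rare)) {
    if (rare_label_action == "error") {
      stop("label(s) with < 2 training sequences: ",
           paste(rare, collapse = ", "), call. = FALSE)
    }
    warning(sprintf("dropping %d label(s) with < 2 training sequences",
                    length(rare)))
    keep <- !labels %in% rare
    features <- features[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop("degenerate label space", call. = FALSE)
  mtry <- mtry %||% min(default_mtry(k), ncol(features))
  fit <- with_seed(seed, randomForest::randomForest(
    x = features, y = y, ntree = ntree, mtry = mtry, importance = TRUE,
    keep.forest = TRUE))
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)
  structure(list(
    rank = rank,
    label_space = levels(y),
    k = k,
    variable_subset = colnames(features),
    mtry = mtry,
    ntree = ntree,
    oob_error = unname(fit$err.rate[ntree, "OOB"]),
    permutation_importance = stats::setNames(imp[, 1], rownames(imp)),
    model = fit,
    training_manifest = list(
      n_per_label = as.list(table(y)),
      n_dropped_labels = length(rare),
      seed = seed,
      trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "rank_model")
}

#' OOB error while pruning least-important variables in blocks
#'
#' Trains on the full variable set, ranks variables by permutation
#' importance, then retrains after removing the `block` least important
#' variables `steps` times (for k = 4 defaults: 256, 231, 206, 181
#' variables). Pruning order is fixed by the full model's importance.
#'
#' @param features numeric feature matrix.
#' @param labels class labels.
#' @param block variables removed per step (default 25; 0 = full set only).
#' @param steps number of pruning steps (default 3).
#' @param ntree trees per forest (default 100).
#' @param mtry variables tried per split (default 8), clipped to the
#'   current variable count.
#' @param seed integer seed.
#' @return a data.frame of `(n_variables, oob_error)`, one row per subset.
#' @export
variable_pruning_experiment <- function(features, labels, block = 25,
                                        steps = 3, ntree = 100, mtry = 8,
                                        seed = 1L) {
  if (block * steps >= ncol(features)) {
    stop("block x steps must be smaller than the number of variables",
         call. = FALSE)
  }
  y <- droplevels(as.factor(labels))
  full <- train_rank_model(features, y, rank = "experiment",
                           k = round(log(ncol(features), 4)),
                           ntree = ntree,
                           mtry = min(mtry, ncol(features)), seed = seed)
  order_asc <- names(sort(full$permutation_importance))  # least important first
  sizes <- ncol(features)
  errs <- full$oob_error
  if (block > 0) {
    for (s in seq_len(steps)) {
      drop_vars <- order_asc[seq_len(block * s)]
      keep <- setdiff(colnames(features), drop_vars)
      e <- oob_error_at(features[, keep, drop = FALSE], y,
                        mtry = min(mtry, length(keep)), ntree = ntree,
                        seed = seed)
      sizes <- c(sizes, length(keep))
      errs <- c(errs, e)
    }
  }
  data.frame(n_variables = sizes, oob_error = errs)
}

#' OOB error as a function of forest size
#'
#' Grows a single forest to the largest requested size under the given seed
#' and reads the cumulative OOB error at each grid point — equivalent to
#' training each size from the same seed base, and what saturation plots
#' are made from.
#'
#' @param features numeric feature matrix.
#' @param labels class labels.
#' @param mtry variables tried per split.
#' @param ntree_grid ascending vector of forest sizes.
#' @param seed integer seed.
#' @return a data.frame of `(ntree, oob_error)`.
#' @export
ntree_saturation_curve <- function(features, labels, mtry, ntree_grid,
                                   seed = 1L) {
  stopifnot(length(ntree_grid) >= 1, !is.unsorted(ntree_grid))
  y <- droplevels(as.factor(labels))
  fit <- with_seed(seed, randomForest::randomForest(
    x = features, y = y, ntree = max(ntree_grid), mtry = mtry))
  data.frame(ntree = ntree_grid,
             oob_error = unname(fit$err.rate[ntree_grid, "OOB"]))
}
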