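#' Stratified k-fold split
#'
#' Partitions indices `1..n` into k disjoint folds whose sizes differ by at
#' most one, preserving the class proportions of `labels` within each fold
#' (round-robin assignment after a seeded within-class shuffle).
#'
#' @param labels 0/1 label vector; its length is the dataset size.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return List of k integer vectors of fold indices.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n < k) {
    abort(paste0("cannot make ", k, " folds from ", n, " samples"))
  }
  withr::with_seed(seed, {
    by_class <- split(seq_len(n), labels)
    ordered <- unlist(lapply(by_class, sample), use.names = FALSE)
    fold_of <- rep_len(seq_len(k), n)
    lapply(seq_len(k), function(f) sort(ordered[fold_of == f]))
  })
}

#' Hyperparameter grid for the staged search
#'
#' Three stages, tuned in order with winners carried forward: (1) batch
#' size and epoch budget, (2) channel count and filter height, (3) learning
#' rate and dropout probability. Defaults are the full search ranges of the
#' original study.
#'
#' @param batch_size,max_epochs stage-1 candidate lists.
#' @param n_channels,filter_height stage-2 candidate lists (a height
#'   candidate sets all channels to that height).
#' @param learning_rate,dropout_p stage-3 candidate lists.
#' @param k fold count for cross-validation.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(batch_size = c(16L, 32L, 64L, 128L),
                      max_epochs = c(10L, 50L, 100L, 200L),
                      n_channels = c(5L, 7L, 9L, 11L),
                      filter_height = c(3L, 5L, 7L, 9L),
                      learning_rate = c(1e-4, 3e-4, 5e-4, 7e-4, 1e-3),
                      dropout_p = c(0.4, 0.45, 0.5, 0.55, 0.6),
                      k = 5L) {
  stages <- list(
    stage1 = list(batch_size = batch_size, max_epochs = max_epochs),
    stage2 = list(n_channels = n_channels, filter_height = filter_height),
    stage3 = list(learning_rate = learning_rate, dropout_p = dropout_p)
  )
  if (any(vapply(unlist(stages, recursive = FALSE), length, 0L) == 0L)) {
    abort("every candidate list must be non-empty")
  }
  if (k < 2L) {
    abort("k must be at least 2")
  }
  structure(c(stages, list(k = as.integer(k))), class = "grid_spec")
}

apply_overrides <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    if (nm == "filter_height") {
      cfg$filter_heights <- rep_len(as.integer(overrides[[nm]]), cfg$n_channels)
    } else if (nm == "n_channels") {
      h <- cfg$filter_heights[1]
      cfg$n_channels <- as.integer(overrides[[nm]])
      cfg$filter_heights <- rep_len(h, cfg$n_channels)
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
  cfg
}

#' Staged cross-validated grid search
#'
#' Reproduces the three-stage tuning protocol: within each stage every
#' combination of that stage's candidates is scored by mean k-fold
#' cross-validated accuracy (other hyperparameters held at the base
#' configuration or at winners of earlier stages), and the best mean
#' accuracy is carried forward; ties go to the earlier combination in
#' candidate-list order. Folds are stratified, seeded, and shared across
#' all combinations. A combination whose evaluation fails is logged and
#' excluded rather than aborting the search.
#'
#' @param data list with `x` (n x rows x cols array) and `y` (0/1 labels),
#'   normally the merged-seq encoding of the training set.
#' @param grid a [grid_spec()].
#' @param base_cfg starting [model_config()]; its `seed` also seeds the
#'   fold split.
#' @param evaluator scoring function `function(cfg, train, validation)`
#'   returning held-out accuracy. The default builds and trains the
#'   network with `cfg` (the held-out fold doubles as the early-stopping
#'   validation set) and returns accuracy on that fold. Injectable for
#'   testing.
#' @return A `tuning_result`: list with `selected` (the final
#'   `model_config`), `results` (per-combination tibble with stage, the
#'   candidate values, mean and per-fold accuracies), and `n_fits`.
#' @export
staged_grid_search <- function(data, grid, base_cfg, evaluator = cv_evaluator) {
  stopifnot(inherits(grid, "grid_spec"))
  folds <- kfold_split(data$y, grid$k, seed = base_cfg$seed)
  cfg <- base_cfg
  rows <- list()
  n_fits <- 0L
  for (stage in 1:3) {
    cand <- grid[[paste0("stage", stage)]]
    combos <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    scores <- rep(NA_real_, nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      overrides <- as.list(combos[ci, , drop = FALSE])
      fold_acc <- rep(NA_real_, grid$k)
      ok <- TRUE
      for (f in seq_len(grid$k)) {
        test_idx <- folds[[f]]
        train <- list(x = data$x[-test_idx, , , drop = FALSE],
                      y = data$y[-test_idx])
        heldout <- list(x = data$x[test_idx, , , drop = FALSE],
                        y = data$y[test_idx])
        acc <- tryCatch(
          evaluator(apply_overrides(cfg, overrides), train, heldout),
          error = function(e) {
            warn(paste0("stage ", stage, " combination ", ci, ", fold ", f,
                        " failed: ", conditionMessage(e)))
            NA_real_
          }
        )
        n_fits <- n_fits + 1L
        fold_acc[f] <- acc
        if (is.na(acc)) {
          ok <- FALSE
          break
        }
      }
      scores[ci] <- if (ok) mean(fold_acc) else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stage = stage,
        combination = ci,
        !!!as.list(combos[ci, , drop = FALSE]),
        mean_cv_accuracy = scores[ci],
        failed = !ok
      )
    }
    if (all(is.na(scores))) {
      abort(paste0("every combination of stage ", stage, " failed"))
    }
    best <- which.max(scores)  # ties: first in candidate-list order
    cfg <- apply_overrides(cfg, as.list(combos[best, , drop = FALSE]))
  }
  structure(
    list(selected = cfg, results = dplyr::bind_rows(rows), n_fits = n_fits,
         folds = folds),
    class = "tuning_result"
  )
}

#' @rdname staged_grid_search
#' @param cfg,train,validation see `evaluator` above.
#' @export
cv_evaluator <- function(cfg, train, validation) {
  model <- build_model(cfg)
  model <- train_cnn(model, train, validation)
  pred <- predict(model, validation)
  mean(pred$label == validation$y)
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> ", x$n_fits, " fits over ",
      nrow(x$results), " combinations\n", sep = "")
  sel <- x$selected
  cat("selected: batch ", sel$batch_size, ", epochs ", sel$max_epochs,
      ", channels ", sel$n_channels, ", height ", sel$filter_heights[1],
      ", lr ", sel$learning_rate, ", dropout ", sel$dropout_p, "\n", sep = "")
  invisible(x)
}
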