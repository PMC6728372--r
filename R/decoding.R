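# Condition-ordered run averaging and nested cross-validated 4-way linear
# classification.

#' Order trials by condition and average across runs
#'
#' Within each run, trials are grouped by the to-be-decoded direction
#' label; the order of trials within a label is randomly permuted,
#' independently per run, so that the positional average across the three
#' runs strengthens the condition of interest while weakening signal tied
#' to other conditions (head direction, texture, cue side). Positional
#' means across runs yield 96 samples, 24 per direction.
#'
#' @param betas_runs List of `trial_betas`, one per run.
#' @param table The `trial_table` that generated the runs.
#' @param factor `"allo_boundary"` or `"allo_goal"`.
#' @param seed Averaging seed controlling the within-label permutations.
#' @return Object of class `sample_set`: list with `factor`, `samples`
#'   (96 x n_voxels), `labels` (96 directions), `averaging_seed`.
#' @export
order_and_average <- function(betas_runs, table, factor = c("allo_boundary", "allo_goal"),
                              seed = 1L) {
  factor <- match.arg(factor)
  dirs <- compass_directions()
  n_runs <- length(betas_runs)
  ordered <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    labels <- table$runs[[r]][[factor]]
    counts <- table(base::factor(labels, levels = dirs))
    if (length(unique(as.vector(counts))) != 1L) {
      stop("run ", r, ": direction labels are not balanced; cannot average")
    }
    idx <- withr::with_seed(derive_seed(seed, r), {
      unlist(lapply(dirs, function(d) sample(which(labels == d))))
    })
    ordered[[r]] <- betas_runs[[r]]$betas[idx, , drop = FALSE]
  }
  per_dir <- nrow(ordered[[1]]) / length(dirs)
  samples <- Reduce(`+`, ordered) / n_runs
  structure(list(factor = factor, samples = samples,
                 labels = rep(dirs, each = per_dir), averaging_seed = seed),
            class = "sample_set")
}

# One-vs-rest multiclass reduction over binary linear C-SVCs (e1071).
# Returns the fitted binary machines plus the class order.
fit_linear_ovr <- function(x, y, cost) {
  classes <- sort(unique(y))
  models <- lapply(classes, function(cl) {
    yy <- base::factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, yy, kernel = "linear", cost = cost, scale = FALSE)
  })
  list(classes = classes, models = models)
}

predict_linear_ovr <- function(fit, x) {
  scores <- vapply(fit$models, function(m) {
    p <- predict(m, x, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # libsvm orients the decision value towards the first class in the
    # column name "first/second"; flip so positive always means "pos"
    sign <- if (startsWith(colnames(dv)[1], "pos")) 1 else -1
    sign * dv[, 1]
  }, numeric(nrow(x)))
  fit$classes[max.col(scores, ties.method = "first")]
}

# Stratified shuffle split: floor(test_frac * n) test samples, allocated
# across classes proportionally (remainder to seeded random classes).
stratified_shuffle_split <- function(y, test_frac, seed) {
  n <- length(y)
  classes <- sort(unique(y))
  n_test <- floor(test_frac * n)
  base_per_class <- vapply(classes, function(cl) {
    floor(n_test * sum(y == cl) / n)
  }, numeric(1))
  remainder <- n_test - sum(base_per_class)
  withr::with_seed(seed, {
    extra <- if (remainder > 0) sample(classes, remainder) else character(0)
    test_idx <- unlist(lapply(classes, function(cl) {
      k <- base_per_class[match(cl, classes)] + sum(extra == cl)
      sample(which(y == cl), k)
    }))
  })
  list(test = sort(test_idx), train = setdiff(seq_len(n), test_idx))
}

# Stratified k-fold assignment: per class, shuffle then deal round-robin.
stratified_kfold <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Nested cross-validated linear classification accuracy
#'
#' Three outer stratified shuffle splits, each holding out 20% of the
#' samples. Within each outer training set, a 3-fold stratified grid
#' search over the regularisation constant C in {1, 10, 100, 1000} picks
#' the C with the best inner accuracy (ties to the smallest C); a linear
#' L2-regularised support vector classifier (one-vs-rest) is then refit on
#' the full outer training set and scored on the held-out samples.
#'
#' @param samples A `sample_set`, or a samples x features matrix (then
#'   `labels` is required).
#' @param labels Class labels for matrix input.
#' @param cv_seed Seed controlling all splits.
#' @param C_grid Candidate regularisation constants.
#' @param n_outer Number of outer shuffle splits.
#' @param test_frac Outer held-out fraction.
#' @param n_inner Inner stratified folds for the grid search.
#' @return Object of class `decoding_score`: list with `factor`,
#'   `fold_accuracy`, `mean_accuracy`, `chosen_C`, `cv_seed`.
#' @export
nested_cv_accuracy <- function(samples, labels = NULL, cv_seed = 1L,
                               C_grid = c(1, 10, 100, 1000), n_outer = 3,
                               test_frac = 0.2, n_inner = 3) {
  if (inherits(samples, "sample_set")) {
    x <- samples$samples
    y <- samples$labels
    factor_name <- samples$factor
  } else {
    x <- as.matrix(samples)
    y <- labels
    factor_name <- NA_character_
  }
  if (is.null(y) || length(y) != nrow(x)) stop("labels must match samples")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")

  fold_acc <- numeric(n_outer)
  chosen_C <- numeric(n_outer)
  for (f in seq_len(n_outer)) {
    split <- stratified_shuffle_split(y, test_frac, derive_seed(cv_seed, f))
    x_tr <- x[split$train, , drop = FALSE]; y_tr <- y[split$train]
    if (length(unique(y_tr)) < length(unique(y))) {
      stop("a class is absent from an outer training split")
    }
    inner_folds <- stratified_kfold(y_tr, n_inner, derive_seed(cv_seed, f, 1))
    inner_acc <- vapply(C_grid, function(C) {
      mean(vapply(seq_len(n_inner), function(k) {
        tr <- inner_folds != k
        fit <- fit_linear_ovr(x_tr[tr, , drop = FALSE], y_tr[tr], C)
        mean(predict_linear_ovr(fit, x_tr[!tr, , drop = FALSE]) == y_tr[!tr])
      }, numeric(1)))
    }, numeric(1))
    chosen_C[f] <- C_grid[which.max(inner_acc)]   # which.max ties to smallest C
    fit <- fit_linear_ovr(x_tr, y_tr, chosen_C[f])
    pred <- predict_linear_ovr(fit, x[split$test, , drop = FALSE])
    fold_acc[f] <- mean(pred == y[split$test])
  }
  structure(list(factor = factor_name, fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc), chosen_C = chosen_C,
                 cv_seed = cv_seed),
            class = "decoding_score")
}

#' @export
print.decoding_score <- function(x, ...) {
  cat(sprintf("Decoding score (%s): mean accuracy %.3f [folds: %s; C: %s]\n",
              x$factor, x$mean_accuracy,
              paste(sprintf("%.3f", x$fold_accuracy), collapse = ", "),
              paste(x$chosen_C, collapse = ", ")))
  invisible(x)
}
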