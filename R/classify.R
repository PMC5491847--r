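# Linear discriminant classification of hand tasks from window features:
# Gaussian classes with a shared (pooled, optionally shrunk) covariance,
# maximum-posterior decisions, repetition-level train/test splitting and
# stratified k-fold cross-validation.

CLASS_ORDER <- c("relax", "open", "grasp")

#' Split window features into train and test sets at repetition granularity
#'
#' Whole repetitions (trials) are assigned to one side, stratified by task,
#' so that overlapping windows from the same trial can never straddle the
#' split.  Deterministic given `seed`.
#'
#' @param feats a `window_features`.
#' @param train_frac fraction of repetitions per task used for training.
#' @param seed integer seed.
#' @return list with `train`, `test` (`window_features`) and
#'   `assignment` (data.frame task, repetition, part).
#' @export
split_train_test <- function(feats, train_frac = 0.75, seed = 1L) {
  stopifnot(inherits(feats, "window_features"))
  tasks <- unique(feats$groups$task)
  assign_rows <- with_seed(derive_seed(seed, "split"), {
    do.call(rbind, lapply(tasks, function(tk) {
      reps <- sort(unique(feats$groups$repetition[feats$groups$task == tk]))
      if (length(reps) < 2L) {
        stop(sprintf("task '%s' needs >= 2 repetitions to split", tk))
      }
      n_train <- min(length(reps) - 1L,
                     max(1L, round(train_frac * length(reps))))
      tr <- sample(reps, n_train)
      data.frame(task = tk, repetition = reps,
                 part = ifelse(reps %in% tr, "train", "test"))
    }))
  })
  key <- paste(feats$groups$task, feats$groups$repetition)
  trkey <- with(assign_rows[assign_rows$part == "train", ],
                paste(task, repetition))
  sel <- key %in% trkey
  list(train = subset_features(feats, sel),
       test = subset_features(feats, !sel),
       assignment = assign_rows)
}

subset_features <- function(feats, idx) {
  structure(
    list(X = feats$X[idx, , drop = FALSE], y = feats$y[idx],
         groups = feats$groups[idx, , drop = FALSE],
         channels = feats$channels, spec = feats$spec,
         epsilon = feats$epsilon),
    class = "window_features")
}

#' Fit a (shrinkage) linear discriminant model
#'
#' Gaussian classes sharing one covariance: per-class means, empirical
#' priors, and the pooled within-class covariance shrunk toward a scaled
#' identity, `(1 - lambda) * S + lambda * (tr(S)/p) * I`.  With
#' `shrinkage = 0` a singular pooled covariance is an error (increase the
#' shrinkage).
#'
#' @param feats a `window_features` (or list with `X`, `y`).
#' @param shrinkage lambda in `[0, 1]`.
#' @return an object of class `lda_model`.
#' @export
lda_fit <- function(feats, shrinkage = 1e-3) {
  X <- feats$X; y <- as.character(feats$y)
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0,1]")
  classes <- intersect(CLASS_ORDER, unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes")
  p <- ncol(X)
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(X[y == cl, , drop = FALSE])
  }))
  rownames(means) <- classes
  Sp <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    Xc <- sweep(Xc, 2, means[cl, ])
    Sp <- Sp + crossprod(Xc)
  }
  Sp <- Sp / (nrow(X) - length(classes))
  Sigma <- (1 - shrinkage) * Sp +
    shrinkage * (sum(diag(Sp)) / p) * diag(p)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("pooled covariance is singular; use a nonzero shrinkage")
  }
  priors <- as.numeric(table(factor(y, levels = classes))) / length(y)
  structure(
    list(classes = classes, means = means, sigma = Sigma, chol = ch,
         priors = stats::setNames(priors, classes), shrinkage = shrinkage,
         p = p),
    class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes (%s), %d features, shrinkage %g\n",
              length(x$classes), paste(x$classes, collapse = ", "), x$p,
              x$shrinkage))
  invisible(x)
}

#' Posterior probabilities and labels from a linear discriminant model
#'
#' Evaluates the Gaussian log-discriminants
#' `x' S^-1 mu_j - mu_j' S^-1 mu_j / 2 + log prior_j`, soft-maxes them into
#' posteriors (rows sum to 1), and assigns the class with the largest
#' posterior; exact ties go to the earlier class in the canonical order
#' relax, open, grasp.
#'
#' @param model an `lda_model`.
#' @param X feature matrix (windows x features).
#' @return list with `labels` (character) and `posterior` (matrix windows x
#'   classes).
#' @export
lda_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop(sprintf("feature dimension %d does not match model (%d)",
                 ncol(X), model$p))
  }
  # discriminants via the Cholesky factor of Sigma
  Minv <- backsolve(model$chol, forwardsolve(t(model$chol), t(model$means)))
  D <- X %*% Minv
  quad <- colSums(t(model$means) * Minv)
  D <- sweep(D, 2, quad / 2)
  D <- sweep(D, 2, log(model$priors), `+`)
  colnames(D) <- model$classes
  post <- exp(D - apply(D, 1, max))
  post <- post / rowSums(post)
  labels <- model$classes[max.col(post, ties.method = "first")]
  list(labels = labels, posterior = post)
}

#' Stratified k-fold cross-validation over repetitions for the shrinkage
#'
#' Folds partition the training repetitions (stratified by task; `k` is
#' capped at the smallest per-task repetition count).  For each candidate
#' shrinkage, fits on k-1 folds and scores window accuracy on the held-out
#' fold; picks the candidate with the highest mean accuracy, breaking ties
#' toward the smallest shrinkage.
#'
#' @param feats training `window_features`.
#' @param k requested fold count (default 10).
#' @param shrinkage_grid candidate lambdas.
#' @param seed integer seed for fold assignment.
#' @return list with `shrinkage` (selected), `cv_accuracy` (its mean fold
#'   accuracy), `table` (per-candidate mean accuracy), `k` (folds used).
#' @export
cross_validate <- function(feats, k = 10L,
                           shrinkage_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                           seed = 1L) {
  stopifnot(inherits(feats, "window_features"))
  g <- feats$groups
  per_task <- lapply(split(g$repetition, g$task), unique)
  k_eff <- min(k, min(lengths(per_task)))
  if (k_eff < 2L) stop("k-fold CV needs >= 2 repetitions per task")
  fold_of <- with_seed(derive_seed(seed, "cv"), {
    do.call(rbind, lapply(names(per_task), function(tk) {
      reps <- sample(per_task[[tk]])
      data.frame(task = tk, repetition = reps,
                 fold = rep_len(seq_len(k_eff), length(reps)))
    }))
  })
  key <- paste(g$task, g$repetition)
  fold <- fold_of$fold[match(key, paste(fold_of$task, fold_of$repetition))]
  acc <- vapply(shrinkage_grid, function(lam) {
    fold_acc <- vapply(seq_len(k_eff), function(f) {
      tr <- subset_features(feats, fold != f)
      te <- subset_features(feats, fold == f)
      fit <- tryCatch(lda_fit(tr, lam), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      mean(lda_predict(fit, te$X)$labels == te$y)
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  acc[is.na(acc)] <- -Inf
  best <- which(acc == max(acc))[1]   # ties -> smallest shrinkage
  list(shrinkage = shrinkage_grid[best], cv_accuracy = acc[best],
       table = data.frame(shrinkage = shrinkage_grid, accuracy = acc),
       k = k_eff, folds = fold_of)
}

#' Evaluate a model on held-out windows
#'
#' Builds the confusion matrix (rows = true task, columns = predicted),
#' per-task accuracies (diagonal over row sum, in %), and the overall
#' accuracy as the unweighted mean of the per-task accuracies.
#'
#' @param model an `lda_model`.
#' @param feats test `window_features`.
#' @return object of class `eval_report`: `confusion`, `per_task_accuracy`
#'   (named %, in canonical class order), `overall_accuracy` (%).
#' @export
evaluate <- function(model, feats) {
  stopifnot(inherits(feats, "window_features"))
  pred <- lda_predict(model, feats$X)$labels
  classes <- model$classes
  conf <- table(factor(feats$y, levels = classes),
                factor(pred, levels = classes))
  rs <- rowSums(conf)
  if (any(rs == 0)) {
    stop("test set lacks task(s): ",
         paste(classes[rs == 0], collapse = ", "))
  }
  per_task <- 100 * diag(as.matrix(conf)) / rs
  structure(
    list(confusion = conf,
         per_task_accuracy = stats::setNames(as.numeric(per_task), classes),
         overall_accuracy = mean(per_task)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall %.1f%% (%s)\n", x$overall_accuracy,
              paste(sprintf("%s %.1f%%", names(x$per_task_accuracy),
                            x$per_task_accuracy), collapse = ", ")))
  print(x$confusion)
  invisible(x)
}
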