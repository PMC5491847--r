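sim_features <- function(n_per_class = 60, reps = 12, sep = 6, seed = 1,
                         p = 4) {
  set.seed(seed)
  classes <- c("relax", "open", "grasp")
  mu <- rbind(relax = rep(0, p), open = c(rep(sep, p %/% 2), rep(0, p - p %/% 2)),
              grasp = c(rep(0, p - p %/% 2), rep(sep, p %/% 2)))
  X <- NULL; y <- NULL; rep_id <- NULL
  for (cl in classes) {
    Xc <- matrix(rnorm(n_per_class * p), n_per_class, p) +
      matrix(mu[cl, ], n_per_class, p, byrow = TRUE)
    X <- rbind(X, Xc)
    y <- c(y, rep(cl, n_per_class))
    rep_id <- c(rep_id, rep_len(seq_len(reps), n_per_class))
  }
  colnames(X) <- paste0("f", seq_len(p))
  structure(list(X = X, y = y,
                 groups = data.frame(task = y, loading = "sabd50",
                                     repetition = rep_id),
                 channels = "x", spec = window_spec(), epsilon = 1),
            class = "window_features")
}

test_that("repetition-level split is stratified, disjoint, deterministic", {
  fe <- sim_features(reps = 12)
  sp1 <- split_train_test(fe, 0.75, seed = 5)
  sp2 <- split_train_test(fe, 0.75, seed = 5)
  expect_identical(sp1$assignment, sp2$assignment)
  a <- sp1$assignment
  for (tk in unique(a$task)) {
    expect_equal(sum(a$part == "train" & a$task == tk), 9L)
    expect_equal(sum(a$part == "test" & a$task == tk), 3L)
  }
  trk <- with(sp1$train$groups, paste(task, repetition))
  tek <- with(sp1$test$groups, paste(task, repetition))
  expect_length(intersect(unique(trk), unique(tek)), 0L)
  sp3 <- split_train_test(fe, 0.75, seed = 6)
  expect_false(identical(sp1$assignment, sp3$assignment))
})

test_that("lda posterior matches the closed-form Bayes rule", {
  # fix parameters analytically and compare posteriors point by point
  p <- 3
  means <- rbind(relax = c(0, 0, 0), open = c(2, 0, 1), grasp = c(0, 2, -1))
  sigma <- matrix(c(1, .3, .1, .3, 1.5, .2, .1, .2, 0.8), 3, 3)
  priors <- c(relax = .5, open = .3, grasp = .2)
  model <- structure(
    list(classes = rownames(means), means = means, sigma = sigma,
         chol = chol(sigma), priors = priors, shrinkage = 0, p = p),
    class = "lda_model")
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  pred <- lda_predict(model, X)
  for (i in seq_len(nrow(X))) {
    expect_equal(unname(pred$posterior[i, ]),
                 unname(bayes_posterior(X[i, ], means, sigma, priors)),
                 tolerance = 1e-6)
  }
  expect_equal(unname(rowSums(pred$posterior)), rep(1, nrow(X)),
               tolerance = 1e-9)
  # a point at a class mean of a well-separated model gets that class
  far <- structure(model, class = "lda_model")
  far$means <- 10 * means
  for (cl in rownames(means)) {
    pr <- lda_predict(far, matrix(10 * means[cl, ], 1))
    expect_identical(pr$labels, cl)
    expect_gt(pr$posterior[1, cl], 0.99)
  }
  # equidistant point with equal priors -> uniform posterior
  eq <- model
  eq$means <- rbind(relax = c(1, 0, 0), open = c(0, 1, 0),
                    grasp = c(0, 0, 1))
  eq$sigma <- diag(3); eq$chol <- chol(diag(3))
  eq$priors <- rep(1 / 3, 3)
  pr <- lda_predict(eq, matrix(0, 1, 3))
  expect_equal(unname(pr$posterior[1, ]), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("fitted two-class boundary sits near the symmetric midpoint", {
  set.seed(11)
  n <- 2000
  fe <- structure(list(
    X = cbind(f1 = c(rnorm(n, -3), rnorm(n, 3))),
    y = rep(c("relax", "grasp"), each = n),
    groups = data.frame(task = rep(c("relax", "grasp"), each = n),
                        loading = "table",
                        repetition = rep_len(1:10, 2 * n)),
    channels = "x", spec = window_spec(), epsilon = 1),
    class = "window_features")
  fit <- lda_fit(fe, shrinkage = 0)
  # decision boundary: posterior equal -> x where discriminants match
  grid <- seq(-1, 1, by = 0.001)
  post <- lda_predict(fit, matrix(grid, ncol = 1))$posterior
  boundary <- grid[which.min(abs(post[, "relax"] - post[, "grasp"]))]
  expect_lt(abs(boundary), 0.2)
  expect_equal(sum(fit$priors), 1)
})

test_that("lda agrees with MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  fe <- sim_features(n_per_class = 90, sep = 2.5, seed = 9)
  fit <- lda_fit(fe, shrinkage = 0)
  m <- MASS::lda(fe$X, grouping = fe$y)
  pr_ours <- lda_predict(fit, fe$X)$labels
  pr_mass <- as.character(predict(m, fe$X)$class)
  expect_gt(mean(pr_ours == pr_mass), 0.99)
})

test_that("singular covariance at zero shrinkage raises, shrinkage fixes", {
  fe <- sim_features(n_per_class = 30, seed = 2, p = 4)
  fe$X <- cbind(fe$X, dup = fe$X[, 1])   # exactly collinear
  expect_error(lda_fit(fe, 0), "shrinkage")
  expect_s3_class(lda_fit(fe, 1e-3), "lda_model")
})

test_that("cross-validation partitions reps, is deterministic, finds an
           accurate model on separable data", {
  fe <- sim_features(n_per_class = 120, reps = 12, sep = 5, seed = 3)
  cv1 <- cross_validate(fe, k = 10, seed = 4)
  cv2 <- cross_validate(fe, k = 10, seed = 4)
  expect_identical(cv1$folds, cv2$folds)
  expect_gt(cv1$cv_accuracy, 0.9)
  # folds partition each task's repetitions exactly
  for (tk in unique(fe$groups$task)) {
    f <- cv1$folds[cv1$folds$task == tk, ]
    expect_setequal(f$repetition, unique(fe$groups$repetition))
    expect_false(any(duplicated(f$repetition)))
  }
  # k is capped at the repetition count
  expect_equal(cv1$k, 10L)
  expect_equal(cross_validate(fe, k = 50, seed = 1)$k, 12L)
})

test_that("evaluation computes per-task and mean-of-tasks accuracy", {
  classes <- c("relax", "open", "grasp")
  model <- structure(
    list(classes = classes,
         means = rbind(relax = 0, open = 5, grasp = 10),
         sigma = matrix(1), chol = matrix(1),
         priors = stats::setNames(rep(1 / 3, 3), classes),
         shrinkage = 0, p = 1),
    class = "lda_model")
  # craft a test set with known per-task hit rates 100%, 50%, 90%
  mk <- function(cl, vals) {
    structure(list(X = matrix(vals, ncol = 1), y = rep(cl, length(vals)),
                   groups = data.frame(task = cl, loading = "table",
                                       repetition = 1),
                   channels = "x", spec = window_spec(), epsilon = 1),
              class = "window_features")
  }
  fe <- bind_features(
    mk("relax", rep(0, 10)),
    mk("open", c(rep(5, 5), rep(0, 5))),
    mk("grasp", c(rep(10, 9), 0)))
  rep_ <- evaluate(model, fe)
  expect_equal(unname(rep_$per_task_accuracy), c(100, 50, 90))
  expect_equal(rep_$overall_accuracy, 80)
  expect_equal(unname(rowSums(rep_$confusion)), c(10, 10, 10))
  # all-correct gives 100
  fe2 <- bind_features(mk("relax", rep(0, 4)), mk("open", rep(5, 4)),
                       mk("grasp", rep(10, 4)))
  expect_equal(evaluate(model, fe2)$overall_accuracy, 100)
})
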