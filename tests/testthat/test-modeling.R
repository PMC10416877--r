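test_that("external split is stratified, rounded half-up, deterministic", {
  labels <- rep(c(1L, 0L), c(60, 40))
  plan <- split_external(labels, fraction = 0.2, seed = 5)
  expect_equal(sum(labels[plan$external] == 1L), 12L)
  expect_equal(sum(labels[plan$external] == 0L), 8L)
  expect_setequal(c(plan$modeling, plan$external), seq_along(labels))
  plan2 <- split_external(labels, fraction = 0.2, seed = 5)
  expect_identical(plan, plan2)
  # small class: warning, but at least one record goes external
  expect_warning(p3 <- split_external(rep(c(1L, 0L), c(10, 2)), seed = 1),
                 "class 0")
  expect_equal(sum(rep(c(1L, 0L), c(10, 2))[p3$external] == 0L), 1L)
})

test_that("stratification preserves class ratio within one record per class", {
  set.seed(99)
  for (n in c(10, 57, 200, 1000)) {
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    plan <- suppressWarnings(split_external(labels, 0.2, seed = n))
    for (cl in 0:1) {
      expected <- floor(sum(labels == cl) * 0.2 + 0.5)
      got <- sum(labels[plan$external] == cl)
      expect_lte(abs(got - max(1, expected)), 1L)
    }
  }
})

test_that("train/test division: random sizes and euclidean stride", {
  plan <- split_train_test(100, "random", 0.2, seed = 2)
  expect_equal(length(plan$test), 20L)
  expect_equal(length(plan$train), 80L)
  expect_error(split_train_test(100, fraction = 0.9), "fraction")
  # 10 collinear points: distance rank equals coordinate order from centroid
  f <- cbind(x = c(5, 4, 6, 3, 7, 2, 8, 1, 9, 0))  # centroid 4.5
  plan_e <- split_train_test(method = "euclidean", fraction = 0.2, features = f)
  d <- abs(f[, 1] - mean(f[, 1]))
  ranking <- order(d)
  expect_equal(plan_e$test, sort(ranking[c(5, 10)]))  # every 5th by rank
})

test_that("Wilks lambda closed forms against the MANOVA oracle", {
  # identical class means -> no separation -> lambda = 1
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(0:1, each = 3)
  expect_equal(wilks_lambda(x, g), 1)
  # hand arithmetic: {1,2} vs {3,4}: W = 0.5+0.5 = 1, T = 5
  expect_equal(wilks_lambda(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1 / 5)
  # hand arithmetic: {1,2} vs {4,5}: W = 1, T = 10
  expect_equal(wilks_lambda(c(1, 2, 4, 5), c(0, 0, 1, 1)), 1 / 10)
  # oracle: MANOVA Wilks statistic on a random 3-column instance
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(0:1, 20)
  X[y == 1, 1] <- X[y == 1, 1] + 1
  fit <- manova(X ~ factor(y))
  oracle <- summary(fit, test = "Wilks")$stats[1, "Wilks"]
  expect_equal(wilks_lambda(X, y), unname(oracle), tolerance = 1e-10)
  # vanishing within-class variance drives lambda toward 0
  expect_lt(wilks_lambda(c(0, 0 + 1e-8, 10, 10 - 1e-8), c(0, 0, 1, 1)), 1e-10)
  # singular total matrix -> descriptive error
  Xs <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(wilks_lambda(Xs, c(0, 0, 1, 1)), "singular")
})

planted_instance <- function(n = 200, n_noise = 20, seed = 8) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  inf <- cbind(rnorm(n) + 1.5 * y, rnorm(n) - 1.5 * y)
  noise <- matrix(rnorm(n * n_noise), n, n_noise)
  X <- cbind(inf, noise)
  colnames(X) <- c("inf1", "inf2", paste0("noise", seq_len(n_noise)))
  list(X = X, y = y)
}

test_that("GA recovers planted columns and matches exhaustive search", {
  inst <- planted_instance()
  sel <- ga_select(inst$X, inst$y, n_features = 2, seed = 3)
  expect_setequal(sel$columns, c("inf1", "inf2"))
  # exhaustive oracle over all C(22, 2) subsets
  pairs <- combn(ncol(inst$X), 2)
  lambdas <- apply(pairs, 2, function(ix) {
    wilks_lambda(inst$X[, ix], inst$y)
  })
  best <- pairs[, which.min(lambdas)]
  expect_setequal(colnames(inst$X)[best], sel$columns)
  expect_equal(-sel$fitness, min(lambdas), tolerance = 1e-12)
  # determinism and the generations = 0 contract
  sel2 <- ga_select(inst$X, inst$y, n_features = 2, seed = 3)
  expect_identical(sel$columns, sel2$columns)
  sel0 <- ga_select(inst$X, inst$y, n_features = 2, generations = 0, seed = 3)
  expect_length(sel0$trace, 1L)
  expect_error(ga_select(inst$X[1:2, ], inst$y[1:2], n_features = 2),
               "overfit")
})

test_that("GA mcc and combined fitness options run and are seeded", {
  inst <- planted_instance(n = 80, n_noise = 6)
  for (f in c("mcc", "combined")) {
    s1 <- ga_select(inst$X, inst$y, 2, pop_size = 20, generations = 8,
                    seed = 5, fitness = f)
    s2 <- ga_select(inst$X, inst$y, 2, pop_size = 20, generations = 8,
                    seed = 5, fitness = f)
    expect_identical(s1$columns, s2$columns)
  }
})

test_that("LDA separates, matches MASS on well-conditioned data, ridges when singular", {
  # 1-D separated clusters
  x <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1)
  y <- rep(0:1, each = 20)
  m <- fit_lda(x, y)
  expect_equal(as.integer(predict(m, x)), y)
  # agreement with MASS::lda (equal priors) as the independent route
  inst <- planted_instance(n = 100, n_noise = 2, seed = 10)
  ours <- fit_lda(inst$X, inst$y)
  mass <- MASS::lda(inst$X, grouping = inst$y, prior = c(0.5, 0.5))
  mass_pred <- as.integer(as.character(predict(mass, inst$X)$class))
  expect_equal(as.integer(predict(ours, inst$X)), mass_pred)
  # permuted labels: no signal, MCC concentrates near zero
  set.seed(21)
  Xn <- matrix(rnorm(500 * 4), 500, 4)
  yn <- sample(rep(0:1, 250))
  mn <- fit_lda(Xn, yn)
  mcc <- classification_metrics(predict(mn, Xn), yn)["mcc"]
  expect_lt(abs(mcc), 0.15)
  # constant feature -> singular pooled covariance -> ridge applied
  Xc <- cbind(const = rep(1, 20), x = c(rnorm(10, -2), rnorm(10, 2)))
  mc <- fit_lda(Xc, rep(0:1, each = 10))
  expect_true(mc$ridge_applied)
})

test_that("random forest learns XOR and is reproducible", {
  set.seed(31)
  X <- matrix(runif(400 * 2), 400, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(xor(X[, 1] > 0.5, X[, 2] > 0.5))
  m <- fit_rf(X, y, seed = 9)
  acc <- mean(predict(m, X) == y)
  expect_gte(acc, 0.95)
  m2 <- fit_rf(X, y, seed = 9)
  expect_identical(predict(m, X), predict(m2, X))
  expect_error(fit_rf(X, y, n_trees = 0), "n_trees")
})

test_that("metric suite matches hand arithmetic and flags undefined", {
  # TP=3, FP=1, TN=4, FN=2
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  obs  <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1)
  m <- classification_metrics(pred, obs)
  expect_equal(unname(m[c("tp", "fp", "tn", "fn")]), c(3, 1, 4, 2))
  expect_equal(unname(m["accuracy"]), 70)
  expect_equal(unname(m["precision"]), 75)
  expect_equal(unname(m["sensitivity"]), 60)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["f_measure"]), 2 * 0.75 * 0.6 / 1.35)
  # perfect prediction
  p <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unname(p["accuracy"]), 100)
  expect_equal(unname(p["mcc"]), 1)
  # degenerate: everything predicted positive -> specificity defined (0),
  # MCC undefined, and all-positive truth leaves specificity undefined
  d <- classification_metrics(rep(1, 6), rep(1, 6))
  expect_true(is.na(d["specificity"]))
  expect_true(is.na(d["mcc"]))
})

test_that("evaluate reports confusion metrics and stratified CV mean/SD", {
  inst <- planted_instance(n = 120, n_noise = 2, seed = 12)
  m <- fit_lda(inst$X, inst$y)
  rep <- evaluate(m, inst$X, inst$y, folds = 10, seed = 2)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$n_positive, 60L)
  expect_length(rep$cv_mean, 6L)
  expect_true(all(rep$cv_sd >= 0))
  expect_equal(unname(rep$metrics["accuracy"]),
               100 * mean(predict(m, inst$X) == inst$y))
})
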