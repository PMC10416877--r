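#' Stratified external split
#'
#' Sets aside an external validation fraction by activity-stratified
#' division: records are shuffled within each class (seeded) and a fixed
#' fraction per class (rounded half-up) goes to the external set, so the
#' class ratio is preserved within one record per class. The external set
#' plays no part in fitting condition means, feature selection or model
#' fitting.
#'
#' @param labels integer vector of class labels (0/1), one per record.
#' @param fraction external fraction, default 0.2.
#' @param seed RNG seed.
#' @return a `split_plan`: list(modeling, external) of record indices, plus
#'   the method tag and seed.
#' @export
split_external <- function(labels, fraction = 0.2, seed = 1L) {
  stopifnot(is.numeric(fraction), fraction > 0, fraction < 1)
  labels <- as.integer(labels)
  if (any(is.na(labels))) stop("all records need class labels before splitting")
  external <- integer()
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 5L) {
      warning("class ", cl, " has only ", length(idx),
              " records; sending a minimum of 1 to the external set")
    }
    take <- max(1L, floor(length(idx) * fraction + 0.5))
    external <- c(external, sample(idx)[seq_len(take)])
  }
  external <- sort(external)
  structure(list(modeling = setdiff(seq_along(labels), external),
                 external = external, method = "stratified", seed = seed),
            class = "split_plan")
}

#' Train/test division of the modeling set
#'
#' `random` is a seeded shuffle sending `fraction` of the records to the
#' test set. `euclidean` sorts records by Euclidean distance from the
#' modeling-set centroid in modified-descriptor space and takes every k-th
#' record (k = round(1/fraction)) of that ranking into the test set, giving
#' a test set that spans the density of the data.
#'
#' @param n number of modeling records (random method), or ignored when
#'   `features` is given.
#' @param method "random" or "euclidean".
#' @param fraction test fraction in (0, 0.5], default 0.2.
#' @param seed RNG seed (random method).
#' @param features modified-descriptor matrix of the modeling records
#'   (required for the euclidean method).
#' @return a `split_plan`: list(train, test) of indices into the modeling
#'   records.
#' @export
split_train_test <- function(n, method = c("random", "euclidean"),
                             fraction = 0.2, seed = 1L, features = NULL) {
  method <- match.arg(method)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("fraction must be in (0, 0.5]")
  }
  if (method == "euclidean") {
    if (is.null(features)) stop("euclidean division needs the feature matrix")
    n <- nrow(features)
    centroid <- colMeans(features)
    d <- sqrt(rowSums(sweep(features, 2, centroid)^2))
    ranking <- order(d)
    k <- round(1 / fraction)
    test <- ranking[seq_along(ranking) %% k == 0L]
  } else {
    old <- .save_rng(seed)
    on.exit(.restore_rng(old))
    test <- sort(sample(n)[seq_len(floor(n * fraction + 0.5))])
  }
  structure(list(train = setdiff(seq_len(n), test), test = sort(test),
                 method = method, seed = seed),
            class = "split_plan")
}

#' Wilks lambda for a two-class feature set
#'
#' The ratio of the determinants of the within-group and total
#' sum-of-squares-and-cross-products matrices, \eqn{\lambda = |W| / |T|}.
#' Values near 0 mean well-separated classes; 1 means the class means
#' coincide.
#'
#' @param features numeric matrix (records x features) or vector.
#' @param labels two-class labels, each class with at least 2 records.
#' @return lambda in (0, 1].
#' @export
wilks_lambda <- function(features, labels) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("wilks_lambda needs exactly two classes")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 records")
  W <- matrix(0, ncol(X), ncol(X))
  for (cl in cls) {
    Xc <- X[labels == cl, , drop = FALSE]
    Xc <- sweep(Xc, 2, colMeans(Xc))
    W <- W + crossprod(Xc)
  }
  Xt <- sweep(X, 2, colMeans(X))
  Tm <- crossprod(Xt)
  dT <- det(Tm)
  if (!is.finite(dT) || abs(dT) < 1e-300) {
    stop("total scatter matrix is singular; prune collinear or constant columns")
  }
  det(W) / dT
}

.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Genetic-algorithm feature selection
#'
#' Selects a fixed-size subset of modified-descriptor columns. Chromosomes
#' are column subsets of size `n_features`; generations apply tournament
#' selection (size 2), uniform crossover repaired back to fixed size, and
#' point mutation that swaps one column for an unused one. Elitism carries
#' the best chromosome forward unchanged; everything is seeded.
#'
#' Fitness options: `wilks` maximizes class separation as -lambda of the
#' subset; `mcc` maximizes the training MCC of an LDA fit on the subset;
#' `combined` maximizes the rank-sum of both within the current population.
#'
#' @param matrix numeric feature matrix (records x columns).
#' @param labels two-class labels.
#' @param n_features subset size; must be below the number of records.
#' @param pop_size population size, default 50.
#' @param generations number of generations, default 30; 0 returns the best
#'   of the random initial population.
#' @param crossover_p crossover probability, default 0.9.
#' @param mutation_p per-chromosome mutation probability, default 0.2.
#' @param seed RNG seed.
#' @param fitness "wilks", "mcc" or "combined".
#' @return list(columns, fitness, trace) — selected column names, the best
#'   raw fitness, and the best fitness per generation.
#' @export
ga_select <- function(matrix, labels, n_features,
                      pop_size = 50L, generations = 30L,
                      crossover_p = 0.9, mutation_p = 0.2, seed = 1L,
                      fitness = c("wilks", "mcc", "combined")) {
  fitness <- match.arg(fitness)
  stopifnot(is.matrix(matrix), ncol(matrix) >= n_features, n_features >= 1L)
  if (n_features >= nrow(matrix)) {
    stop("n_features must be smaller than the number of records (overfit guard)")
  }
  p <- ncol(matrix)
  labels <- as.integer(labels)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))

  raw_wilks <- function(cols) {
    tryCatch(-wilks_lambda(matrix[, cols, drop = FALSE], labels),
             error = function(e) -Inf)
  }
  raw_mcc <- function(cols) {
    tryCatch({
      m <- fit_lda(matrix[, cols, drop = FALSE], labels)
      pred <- predict(m, matrix[, cols, drop = FALSE])
      mcc <- classification_metrics(pred, labels)["mcc"]
      if (is.na(mcc)) -Inf else unname(mcc)
    }, error = function(e) -Inf)
  }
  score_pop <- function(pop) {
    if (fitness == "wilks") {
      vapply(pop, raw_wilks, numeric(1))
    } else if (fitness == "mcc") {
      vapply(pop, raw_mcc, numeric(1))
    } else {
      a <- vapply(pop, raw_wilks, numeric(1))
      b <- vapply(pop, raw_mcc, numeric(1))
      rank(a, ties.method = "average") + rank(b, ties.method = "average")
    }
  }

  new_chrom <- function() sort(sample.int(p, n_features))
  pop <- replicate(pop_size, new_chrom(), simplify = FALSE)
  fit <- score_pop(pop)
  trace <- max(fit)
  if (generations > 0L) {
    for (g in seq_len(generations)) {
      nxt <- list(pop[[which.max(fit)]])  # elitism
      while (length(nxt) < pop_size) {
        pick <- function() {
          cand <- sample.int(pop_size, 2L)
          pop[[cand[which.max(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- if (stats::runif(1) < crossover_p) {
          take1 <- stats::runif(n_features) < 0.5
          ch <- unique(ifelse(take1, p1, p2))
          pool <- setdiff(union(p1, p2), ch)
          if (length(ch) < n_features) {
            extra <- n_features - length(ch)
            add <- if (length(pool) >= extra) sample(pool)[seq_len(extra)] else {
              c(pool, sample(setdiff(seq_len(p), c(ch, pool)))[
                seq_len(extra - length(pool))])
            }
            ch <- c(ch, add)
          }
          sort(ch)
        } else p1
        if (stats::runif(1) < mutation_p) {
          slot <- sample.int(n_features, 1L)
          child[slot] <- sample(setdiff(seq_len(p), child), 1L)
          child <- sort(child)
        }
        nxt[[length(nxt) + 1L]] <- child
      }
      pop <- nxt
      fit <- score_pop(pop)
      trace <- c(trace, max(fit))
    }
  }
  best <- pop[[which.max(fit)]]
  best_raw <- if (fitness == "wilks") raw_wilks(best) else if (fitness == "mcc") {
    raw_mcc(best)
  } else max(fit)
  list(columns = colnames(matrix)[best], fitness = best_raw, trace = trace)
}

#' Fit a two-class linear discriminant
#'
#' Pooled-covariance linear discriminant with equal priors: a compound is
#' predicted positive when its discriminant score
#' \eqn{w^\top x + b} exceeds the threshold (default 0, the midpoint
#' between the class means). When the pooled covariance is singular a ridge
#' of 1e-6 on the diagonal is applied and recorded on the fitted object.
#'
#' @param matrix numeric feature matrix (records x features).
#' @param labels two-class labels (0/1).
#' @param threshold decision threshold on the discriminant score, default 0.
#' @return an object of class `qsar_lda` with `weights`, `intercept`,
#'   `columns`, and `ridge_applied`.
#' @export
fit_lda <- function(matrix, labels, threshold = 0) {
  X <- as.matrix(matrix)
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("fit_lda needs exactly two classes")
  X0 <- X[labels == cls[1], , drop = FALSE]
  X1 <- X[labels == cls[2], , drop = FALSE]
  n0 <- nrow(X0); n1 <- nrow(X1)
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) / (n0 + n1 - 2)
  ridge <- FALSE
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    ridge <- TRUE
    w <- solve(S + diag(1e-6, ncol(X)), mu1 - mu0)
  }
  b <- -sum(w * (mu0 + mu1) / 2)
  structure(list(kind = "LDA", weights = w, intercept = b,
                 columns = colnames(X), classes = cls,
                 threshold = threshold, ridge_applied = ridge),
            class = "qsar_lda")
}

#' @export
predict.qsar_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(X))) {
    if (!identical(colnames(X), object$columns)) {
      stop("feature columns do not match the fitted model")
    }
  }
  score <- drop(X %*% object$weights) + object$intercept
  if (type == "score") return(score)
  ifelse(score > object$threshold, object$classes[2], object$classes[1])
}

#' Fit a random forest classifier
#'
#' Bootstrap-sampled decision-tree ensemble with majority vote, via the
#' randomForest package. Defaults: 500 trees, unlimited depth, minimum
#' leaf size 1.
#'
#' @param matrix numeric feature matrix.
#' @param labels two-class labels (0/1).
#' @param n_trees number of trees, default 500 (must be >= 1).
#' @param max_nodes optional cap on terminal nodes per tree (depth control).
#' @param min_leaf minimum terminal-node size, default 1.
#' @param seed RNG seed; fixed so refits reproduce predictions exactly.
#' @return an object of class `qsar_rf`.
#' @export
fit_rf <- function(matrix, labels, n_trees = 500L, max_nodes = NULL,
                   min_leaf = 1L, seed = 1L) {
  if (n_trees < 1L) stop("n_trees must be at least 1")
  X <- as.data.frame(as.matrix(matrix))
  names(X) <- make.names(names(X))
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees, nodesize = min_leaf,
    maxnodes = max_nodes)
  structure(list(kind = "RF", forest = rf, columns = colnames(matrix),
                 params = list(n_trees = n_trees, max_nodes = max_nodes,
                               min_leaf = min_leaf, seed = seed)),
            class = "qsar_rf")
}

#' @export
predict.qsar_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(X))) {
    if (!identical(colnames(X), object$columns)) {
      stop("feature columns do not match the fitted model")
    }
  }
  df <- as.data.frame(X)
  names(df) <- make.names(names(df))
  as.integer(as.character(predict(object$forest, df)))
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, sensitivity and specificity (as percentages),
#' F-measure (harmonic mean of precision and sensitivity, on [0, 1]) and
#' the Matthews correlation coefficient. A metric whose denominator is zero
#' is reported as NA (undefined), never silently as 0.
#'
#' @param pred predicted classes (0/1).
#' @param obs observed classes (0/1).
#' @return named numeric vector with tp/tn/fp/fn counts and the six metrics.
#' @export
classification_metrics <- function(pred, obs) {
  pred <- as.integer(pred); obs <- as.integer(obs)
  stopifnot(length(pred) == length(obs))
  tp <- sum(pred == 1L & obs == 1L)
  tn <- sum(pred == 0L & obs == 0L)
  fp <- sum(pred == 1L & obs == 0L)
  fn <- sum(pred == 0L & obs == 1L)
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  acc  <- sdiv(tp + tn, tp + tn + fp + fn) * 100
  prec <- sdiv(tp, tp + fp) * 100
  sens <- sdiv(tp, tp + fn) * 100
  spec <- sdiv(tn, tn + fp) * 100
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else {
    2 * (prec / 100) * (sens / 100) / ((prec + sens) / 100)
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = acc, precision = prec, sensitivity = sens,
    specificity = spec, f_measure = f1, mcc = mcc)
}

.refit <- function(model, matrix, labels) {
  if (inherits(model, "qsar_lda")) {
    fit_lda(matrix, labels, threshold = model$threshold)
  } else if (inherits(model, "qsar_rf")) {
    do.call(fit_rf, c(list(matrix = matrix, labels = labels), model$params))
  } else stop("unknown classifier kind")
}

#' Evaluate a classifier on a labeled set
#'
#' Computes the confusion-matrix metric suite on the supplied set. With
#' `folds` set, additionally runs stratified k-fold cross-validation: the
#' classifier (and only the classifier — feature selection and condition
#' means stay fixed, matching the workflow where CV validates the already
#' selected model) is refit on each training fold and scored on the held
#' fold, and each metric is reported as mean and SD over folds.
#'
#' @param model a `qsar_lda` or `qsar_rf`.
#' @param matrix feature matrix of the evaluation set.
#' @param labels observed classes.
#' @param folds optional number of CV folds (e.g. 10).
#' @param seed seed for fold assignment.
#' @return a `validation_report`: list(metrics, n_positive, n_negative,
#'   cv_mean, cv_sd).
#' @export
evaluate <- function(model, matrix, labels, folds = NULL, seed = 1L) {
  labels <- as.integer(labels)
  metrics <- classification_metrics(predict(model, matrix), labels)
  out <- list(metrics = metrics,
              n_positive = sum(labels == 1L), n_negative = sum(labels == 0L),
              cv_mean = NULL, cv_sd = NULL)
  if (!is.null(folds)) {
    old <- .save_rng(seed)
    on.exit(.restore_rng(old))
    fold_id <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    per_fold <- t(vapply(seq_len(folds), function(k) {
      tr <- fold_id != k; te <- !tr
      m <- .refit(model, matrix[tr, , drop = FALSE], labels[tr])
      classification_metrics(predict(m, matrix[te, , drop = FALSE]), labels[te])
    }, numeric(10)))
    keep <- c("accuracy", "precision", "sensitivity", "specificity",
              "f_measure", "mcc")
    out$cv_mean <- colMeans(per_fold[, keep, drop = FALSE], na.rm = TRUE)
    out$cv_sd <- apply(per_fold[, keep, drop = FALSE], 2, stats::sd, na.rm = TRUE)
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation (P:", x$n_positive, " N:", x$n_negative, ")\n", sep = "")
  m <- x$metrics
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              m["accuracy"], m["precision"], m["sensitivity"], m["specificity"]))
  cat(sprintf("  F-measure %.3f  MCC %.3f\n", m["f_measure"], m["mcc"]))
  if (!is.null(x$cv_mean)) {
    cat("  CV: ", paste(sprintf("%s %.2f+/-%.2f", names(x$cv_mean),
                                x$cv_mean, x$cv_sd), collapse = "  "), "\n")
  }
  invisible(x)
}
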