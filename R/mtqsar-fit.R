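#' Fit a multi-tasking QSAR classification model
#'
#' One call runs the modeling workflow on a curated, labeled dataset:
#' descriptor pretreatment, activity-stratified external split, fitting of
#' per-condition descriptor means on the modeling set only, the
#' Box-Jenkins transform, train/test division (random or
#' Euclidean-distance based), genetic-algorithm feature selection on the
#' training set, classifier fitting (linear discriminant or random
#' forest), applicability-domain construction from the training data, and
#' the full validation-metric suite on training, 10-fold CV, test,
#' external and external-within-AD sets.
#'
#' @param dataset a labeled `qsar_dataset` (run [curate_dataset()] first).
#' @param descriptors optional `descriptor_matrix`; computed with the
#'   builtin backend when NULL.
#' @param method classifier kind, "lda" or "rf".
#' @param n_features number of modified-descriptor columns the GA selects.
#' @param external_fraction fraction per class held out untouched, default 0.2.
#' @param test_fraction fraction of the modeling set used as test, default 0.2.
#' @param test_method "random" or "euclidean" train/test division.
#' @param fitness GA fitness: "wilks", "mcc" or "combined".
#' @param ga further GA settings (pop_size, generations, crossover_p,
#'   mutation_p) overriding the [ga_select()] defaults.
#' @param rf_params RF settings (n_trees, max_nodes, min_leaf) overriding
#'   the [fit_rf()] defaults.
#' @param average_over Box-Jenkins averaging set, "all" or "positives".
#' @param cv_folds cross-validation folds on the training set, default 10.
#' @param fingerprints optional precomputed 166-key fingerprint matrix for
#'   the AD; computed from the structures when NULL.
#' @param seed seed driving every random stage.
#' @return an object of class `mtqsar`.
#' @seealso [screen_compounds()], [summary.mtqsar()], [predict.mtqsar()]
#' @export
mtqsar <- function(dataset, descriptors = NULL,
                   method = c("lda", "rf"), n_features = 5L,
                   external_fraction = 0.2, test_fraction = 0.2,
                   test_method = c("random", "euclidean"),
                   fitness = c("wilks", "mcc", "combined"),
                   ga = list(), rf_params = list(),
                   average_over = "all", cv_folds = 10L,
                   fingerprints = NULL, seed = 1L) {
  method <- match.arg(method)
  test_method <- match.arg(test_method)
  fitness <- match.arg(fitness)
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (any(is.na(dataset$records$class_label))) {
    stop("dataset has unset class labels; run curate_dataset()/label_dataset()")
  }
  cl <- match.call()

  if (is.null(descriptors)) descriptors <- compute_descriptors(dataset$compounds)
  pt <- pretreat(descriptors)
  dropped <- drop_missing_descriptor_rows(pt$matrix, dataset)
  descriptors <- dropped$matrix
  dataset <- dropped$dataset
  records <- dataset$records
  rownames(records) <- NULL
  labels <- records$class_label

  ext_plan <- split_external(labels, fraction = external_fraction, seed = seed)
  mod_rec <- records[ext_plan$modeling, , drop = FALSE]
  ext_rec <- records[ext_plan$external, , drop = FALSE]

  means <- fit_condition_means(mod_rec, descriptors, dataset$schema,
                               average_over = average_over)
  mod_X <- bj_transform(mod_rec, descriptors, means)
  ext_X <- bj_transform(ext_rec, descriptors, means)

  tt_plan <- split_train_test(nrow(mod_X), method = test_method,
                              fraction = test_fraction, seed = seed + 1L,
                              features = if (test_method == "euclidean") mod_X)
  tr_X <- mod_X[tt_plan$train, , drop = FALSE]
  te_X <- mod_X[tt_plan$test, , drop = FALSE]
  tr_y <- mod_rec$class_label[tt_plan$train]
  te_y <- mod_rec$class_label[tt_plan$test]

  ga_args <- utils::modifyList(
    list(matrix = tr_X, labels = tr_y, n_features = n_features,
         seed = seed + 2L, fitness = fitness), ga)
  sel <- do.call(ga_select, ga_args)
  cols <- sel$columns

  classifier <- if (method == "lda") {
    fit_lda(tr_X[, cols, drop = FALSE], tr_y)
  } else {
    do.call(fit_rf, c(list(matrix = tr_X[, cols, drop = FALSE], labels = tr_y,
                           seed = seed + 3L), rf_params))
  }

  if (is.null(fingerprints)) fingerprints <- compute_fingerprints(dataset$compounds)
  tr_ids <- unique(mod_rec$compound_id[tt_plan$train])
  ad_ref <- build_ad_reference(fingerprints[tr_ids, , drop = FALSE],
                               tr_X[, cols, drop = FALSE])

  eval_on <- function(X, y, folds = NULL) {
    evaluate(classifier, X[, cols, drop = FALSE], y, folds = folds,
             seed = seed + 4L)
  }
  ext_inside <- vapply(seq_len(nrow(ext_X)), function(i) {
    ad_verdict(fingerprints[ext_rec$compound_id[i], ],
               ext_X[i, cols], ad_ref)$inside
  }, logical(1))

  validation <- list(
    train = eval_on(tr_X, tr_y),
    cv = eval_on(tr_X, tr_y, folds = cv_folds),
    test = eval_on(te_X, te_y),
    external = eval_on(ext_X, ext_rec$class_label),
    external_in_ad = if (any(ext_inside)) {
      eval_on(ext_X[ext_inside, , drop = FALSE],
              ext_rec$class_label[ext_inside])
    })

  structure(list(
    classifier = classifier, method = method,
    selected_columns = cols, ga = sel,
    condition_means = means, ad_reference = ad_ref,
    schema = dataset$schema, backend = descriptors$backend,
    endpoint = unique(records$endpoint_name),
    splits = list(external = ext_plan, train_test = tt_plan),
    validation = validation, n_records = nrow(records),
    seed = seed, call = cl), class = "mtqsar")
}

#' @export
print.mtqsar <- function(x, ...) {
  cat("Multi-tasking QSAR model (", toupper(x$method), ")\n", sep = "")
  cat("  endpoint: ", paste(x$endpoint, collapse = ", "),
      "   records: ", x$n_records, "\n", sep = "")
  cat("  features: ", length(x$selected_columns), " modified descriptors [",
      paste(x$selected_columns, collapse = ", "), "]\n", sep = "")
  m <- x$validation$external$metrics
  cat(sprintf("  external set: accuracy %.1f%%, MCC %.3f\n",
              m["accuracy"], m["mcc"]))
  invisible(x)
}

#' Validation table of a fitted model
#'
#' @param object a fitted `mtqsar` model.
#' @param ... unused.
#' @return `summary.mtqsar` object wrapping a metric x evaluation-set table
#'   (training, 10-fold CV mean and SD, test, external,
#'   external-within-AD).
#' @export
summary.mtqsar <- function(object, ...) {
  v <- object$validation
  keep <- c("accuracy", "precision", "sensitivity", "specificity",
            "f_measure", "mcc")
  col <- function(rep) if (is.null(rep)) rep(NA_real_, 6) else rep$metrics[keep]
  tab <- data.frame(train = col(v$train),
                    cv_mean = v$cv$cv_mean[keep], cv_sd = v$cv$cv_sd[keep],
                    test = col(v$test), external = col(v$external),
                    external_in_ad = col(v$external_in_ad),
                    row.names = keep)
  counts <- data.frame(
    set = c("train", "test", "external", "external_in_ad"),
    positive = c(v$train$n_positive, v$test$n_positive,
                 v$external$n_positive,
                 if (is.null(v$external_in_ad)) NA else v$external_in_ad$n_positive),
    negative = c(v$train$n_negative, v$test$n_negative,
                 v$external$n_negative,
                 if (is.null(v$external_in_ad)) NA else v$external_in_ad$n_negative))
  structure(list(table = tab, counts = counts, method = object$method,
                 columns = object$selected_columns), class = "summary.mtqsar")
}

#' @export
print.summary.mtqsar <- function(x, ...) {
  cat("Validation metrics (", toupper(x$method), ", ",
      length(x$columns), " features)\n", sep = "")
  print(round(x$table, 3))
  cat("\nSet sizes:\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mtqsar <- function(object, ...) {
  if (object$method == "lda") {
    c(object$classifier$weights, `(intercept)` = object$classifier$intercept)
  } else {
    imp <- randomForest::importance(object$classifier$forest)
    stats::setNames(imp[, 1], object$selected_columns)
  }
}

#' Predict classes for new records
#'
#' @param object fitted `mtqsar` model.
#' @param records data.frame with `compound_id` and the schema's condition
#'   fields.
#' @param descriptors `descriptor_matrix` covering the records' compounds,
#'   from the same backend the model was trained on.
#' @param type "class" or (LDA only) "score".
#' @param ... unused.
#' @return integer class vector (or discriminant scores).
#' @export
predict.mtqsar <- function(object, records, descriptors, type = "class", ...) {
  if (!identical(descriptors$backend, object$backend)) {
    stop("descriptor backend mismatch: model was trained on '",
         object$backend, "', matrix is from '", descriptors$backend, "'")
  }
  X <- bj_transform(records, descriptors, object$condition_means)
  sub <- X[, object$selected_columns, drop = FALSE]
  if (type == "score") {
    if (object$method != "lda") stop("scores are only defined for LDA models")
    return(predict(object$classifier, sub, type = "score"))
  }
  as.integer(predict(object$classifier, sub))
}

#' @export
plot.mtqsar <- function(x, ...) {
  tr <- x$ga$trace
  graphics::plot(seq_along(tr) - 1L, tr, type = "b", pch = 16,
                 xlab = "generation", ylab = "best fitness",
                 main = "GA feature selection", ...)
  invisible(x)
}

#' Export the validation table as delimited text
#'
#' Writes the metric x set table of [summary.mtqsar()] (10-fold CV as
#' mean and SD columns) to a tab-separated file.
#'
#' @param object fitted `mtqsar` model.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_validation <- function(object, path) {
  s <- summary(object)
  utils::write.table(cbind(metric = rownames(s$table), round(s$table, 4)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
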