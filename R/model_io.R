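#' Save a fitted model bundle
#'
#' Writes a self-contained model directory: JSON metadata (method, backend
#' tag, selected columns, schema, per-file checksums), the condition means
#' as JSON, the classifier parameters (JSON for the linear discriminant,
#' serialized object for the random forest) and the applicability-domain
#' reference. The stored condition means and AD reference make screening of
#' new compounds self-contained; [load_model()] refuses bundles whose
#' checksums do not match.
#'
#' @param object fitted `mtqsar` model.
#' @param dir bundle directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(object, dir) {
  stopifnot(inherits(object, "mtqsar"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  means <- object$condition_means
  jsonlite::write_json(
    list(descriptors = means$descriptors, average_over = means$average_over,
         counts = means$counts,
         fields = lapply(means$fields, function(cats) {
           lapply(cats, function(v) unname(v))
         })),
    file.path(dir, "condition_means.json"), auto_unbox = TRUE, digits = NA)
  if (object$method == "lda") {
    cf <- object$classifier
    jsonlite::write_json(
      list(kind = "LDA", weights = unname(cf$weights), columns = cf$columns,
           intercept = cf$intercept, classes = cf$classes,
           threshold = cf$threshold, ridge_applied = cf$ridge_applied),
      file.path(dir, "classifier.json"), auto_unbox = TRUE, digits = NA)
  } else {
    saveRDS(object$classifier, file.path(dir, "classifier.rds"))
  }
  saveRDS(object$ad_reference, file.path(dir, "ad_reference.rds"))
  payload <- setdiff(list.files(dir), "metadata.json")
  meta <- list(
    package = "mtqsar", method = object$method, backend = object$backend,
    endpoint = object$endpoint, selected_columns = object$selected_columns,
    schema = list(fields = object$schema$fields, derived = object$schema$derived),
    seed = object$seed,
    checksums = as.list(tools::md5sum(file.path(dir, payload))))
  names(meta$checksums) <- payload
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model bundle
#'
#' Validates the per-file checksums recorded at save time, reconstructs the
#' classifier, condition means and AD reference, and returns a `mtqsar`
#' object whose predictions are bit-for-bit identical to the saved model's.
#'
#' @param dir bundle directory written by [save_model()].
#' @return a `mtqsar` object (validation tables are not persisted).
#' @export
load_model <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("not a model bundle: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in names(meta$checksums)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("model bundle incomplete: missing ", f)
    got <- unname(tools::md5sum(p))
    if (!identical(got, meta$checksums[[f]])) {
      stop("checksum mismatch for ", f, "; bundle was modified after saving")
    }
  }
  cm_path <- file.path(dir, "condition_means.json")
  if (!file.exists(cm_path)) stop("model bundle incomplete: missing condition_means.json")
  cm <- jsonlite::read_json(cm_path, simplifyVector = TRUE)
  means <- structure(list(
    fields = lapply(cm$fields, function(cats) {
      lapply(cats, function(v) stats::setNames(as.numeric(v), cm$descriptors))
    }),
    counts = cm$counts, descriptors = cm$descriptors,
    average_over = cm$average_over), class = "condition_means")
  classifier <- if (meta$method == "lda") {
    cj <- jsonlite::read_json(file.path(dir, "classifier.json"),
                              simplifyVector = TRUE)
    structure(list(kind = "LDA",
                   weights = stats::setNames(as.numeric(cj$weights), cj$columns),
                   intercept = cj$intercept, columns = cj$columns,
                   classes = as.integer(cj$classes), threshold = cj$threshold,
                   ridge_applied = cj$ridge_applied), class = "qsar_lda")
  } else {
    readRDS(file.path(dir, "classifier.rds"))
  }
  structure(list(
    classifier = classifier, method = meta$method,
    selected_columns = meta$selected_columns,
    condition_means = means,
    ad_reference = readRDS(file.path(dir, "ad_reference.rds")),
    schema = condition_schema(meta$schema$fields, derived = meta$schema$derived),
    backend = meta$backend, endpoint = meta$endpoint,
    splits = NULL, validation = NULL, n_records = NA_integer_,
    seed = meta$seed, call = NULL), class = "mtqsar")
}
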