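#' @name box_jenkins
#' @title Box-Jenkins condition-modified descriptors
#'
#' @description
#' A multi-tasking QSAR model must see, in one feature space, both the
#' structure of a compound and the experimental conditions under which its
#' activity was measured. The Box-Jenkins moving-average approach does this
#' by replacing each descriptor D with its deviation from the mean of D
#' over all modeling-set records sharing the record's category on a
#' condition field:
#' \deqn{\Delta D(i, d, f) = D_{c(i)}(d) - \bar{D}_{f = c_f(i)}(d)}
#' giving one modified column per (descriptor, condition field) pair. The
#' per-category means are estimated once on the modeling set only — the
#' external set never contributes — and are stored so unseen compounds can
#' be transformed identically at screening time.
NULL

#' Fit per-condition descriptor means
#'
#' Computes, for every (descriptor, condition field, category) triple, the
#' mean descriptor value over the supplied records whose field equals that
#' category, together with the record counts. Call this on the modeling set
#' only; the resulting object is the reference the transform and all later
#' screening use.
#'
#' @param records data.frame of records (rows of a `qsar_dataset$records`)
#'   restricted to the modeling set.
#' @param descriptor_matrix a `descriptor_matrix` covering every compound
#'   referenced by the records.
#' @param schema the `condition_schema`; only its fields are averaged over.
#' @param average_over "all" (default) averages over every record of the
#'   category; "positives" restricts to records with class_label 1.
#' @return a `condition_means` object.
#' @export
fit_condition_means <- function(records, descriptor_matrix, schema,
                                average_over = c("all", "positives")) {
  average_over <- match.arg(average_over)
  vals <- if (inherits(descriptor_matrix, "descriptor_matrix")) {
    descriptor_matrix$values
  } else descriptor_matrix
  if (!all(records$compound_id %in% rownames(vals))) {
    stop("every record's compound needs a descriptor row")
  }
  base <- records
  if (average_over == "positives") {
    base <- base[!is.na(base$class_label) & base$class_label == 1L, , drop = FALSE]
    if (nrow(base) == 0L) stop("no positive records to average over")
  }
  X <- vals[base$compound_id, , drop = FALSE]
  fields <- list()
  counts <- list()
  for (f in condition_fields(schema)) {
    cats <- unique(base[[f]])
    fields[[f]] <- lapply(stats::setNames(cats, cats), function(cc) {
      colMeans(X[base[[f]] == cc, , drop = FALSE])
    })
    counts[[f]] <- vapply(cats, function(cc) sum(base[[f]] == cc), integer(1))
  }
  structure(list(fields = fields, counts = counts,
                 descriptors = colnames(vals), average_over = average_over),
            class = "condition_means")
}

#' @export
print.condition_means <- function(x, ...) {
  cat("condition_means over ", length(x$descriptors), " descriptors (",
      x$average_over, " records)\n", sep = "")
  for (f in names(x$fields)) {
    cat("  ", f, ": ", paste(names(x$fields[[f]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Transform records to condition-modified descriptors
#'
#' Builds the modified-descriptor matrix: one row per record, one column
#' per (descriptor, condition field) pair named `descriptor|field`, holding
#' the deviation of the compound's descriptor value from the stored mean of
#' the record's category on that field.
#'
#' @param records data.frame of records to transform.
#' @param descriptor_matrix a `descriptor_matrix` covering the records'
#'   compounds.
#' @param means a `condition_means` fitted on the modeling set.
#' @param unseen "error" (default) fails with the offending field and
#'   category when a record's category has no stored mean; "skip" drops
#'   such records and flags them in the `skipped` attribute.
#' @return numeric matrix with attribute `record_index` mapping rows back to
#'   `records`, and class `modified_descriptor_matrix`.
#' @export
bj_transform <- function(records, descriptor_matrix, means,
                         unseen = c("error", "skip")) {
  unseen <- match.arg(unseen)
  stopifnot(inherits(means, "condition_means"))
  vals <- if (inherits(descriptor_matrix, "descriptor_matrix")) {
    descriptor_matrix$values
  } else descriptor_matrix
  if (!identical(colnames(vals), means$descriptors)) {
    stop("descriptor columns do not match the fitted condition means")
  }
  fields <- names(means$fields)
  ok <- rep(TRUE, nrow(records))
  for (f in fields) {
    known <- records[[f]] %in% names(means$fields[[f]])
    if (!all(known)) {
      if (unseen == "error") {
        bad <- unique(records[[f]][!known])
        stop("no stored mean for field '", f, "', category '", bad[1],
             "'; refit means or use unseen = \"skip\"")
      }
      ok <- ok & known
    }
  }
  recs <- records[ok, , drop = FALSE]
  X <- vals[recs$compound_id, , drop = FALSE]
  nd <- ncol(vals)
  out <- matrix(NA_real_, nrow(recs), nd * length(fields))
  colnames(out) <- as.vector(vapply(fields, function(f) {
    paste0(means$descriptors, "|", f)
  }, character(nd)))
  for (k in seq_along(fields)) {
    f <- fields[k]
    mmat <- do.call(rbind, means$fields[[f]])  # categories x descriptors
    out[, ((k - 1) * nd + 1):(k * nd)] <- X - mmat[recs[[f]], , drop = FALSE]
  }
  rownames(out) <- rownames(recs)
  structure(out, record_index = which(ok), skipped = which(!ok),
            class = c("modified_descriptor_matrix", class(out)))
}
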