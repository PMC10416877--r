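#' @name curation
#' @title Chemical and biological data curation
#'
#' @description
#' The curation chain prepares a raw multi-condition bioactivity table for
#' modeling: structure repair and normalization, salt stripping, removal of
#' inorganic/organometallic species, removal of records with missing
#' endpoints, and a two-stage duplicate analysis. Stage I collapses records
#' that are identical in structure, all experimental conditions and endpoint
#' value. Stage II handles records identical in structure and conditions but
#' with differing values: close values (range below `diff_cutoff`, native
#' units) are averaged into one record; distant values that still fall in
#' the same activity class keep a single representative (the one closest to
#' the group median, ties broken by input order); class-conflicting groups
#' are removed outright. The full chain is idempotent and every action is
#' counted in a [curation_report].
NULL

curation_actions <- c("fixed", "normalized", "removed_unparseable",
                      "removed_inorganic", "removed_missing_endpoint",
                      "merged_dupI", "averaged_dupII", "kept_same_class_dupII",
                      "removed_conflicting")

new_curation_report <- function(counts = NULL, audit = NULL,
                                n_in = NA_integer_, n_out = NA_integer_) {
  full <- stats::setNames(integer(length(curation_actions)), curation_actions)
  if (!is.null(counts)) full[names(counts)] <- counts
  structure(list(counts = full,
                 audit = audit %||% data.frame(id = character(), action = character(),
                                               detail = character()),
                 n_in = n_in, n_out = n_out),
            class = "curation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report: ", x$n_in, " records in, ", x$n_out, " out\n", sep = "")
  nz <- x$counts[x$counts > 0]
  for (a in names(nz)) cat("  ", a, ": ", nz[[a]], "\n", sep = "")
  invisible(x)
}

merge_reports <- function(...) {
  reps <- list(...)
  out <- new_curation_report()
  for (r in reps) out$counts <- out$counts + r$counts
  out$audit <- do.call(rbind, lapply(reps, `[[`, "audit"))
  out$n_in <- reps[[1]]$n_in
  out$n_out <- reps[[length(reps)]]$n_out
  out
}

#' Curate chemical structures
#'
#' Applies, per compound and in order: a parse/repair check; salt and
#' solvent stripping that keeps the largest organic fragment (most heavy
#' atoms, ties to the first); removal of purely inorganic or organometallic
#' species; and normalization to OpenBabel canonical SMILES with
#' standardized charge notation. Unsalvageable structures are removed with a
#' reason rather than raising. The report records that descriptor backends
#' should treat hydrogens as explicit (`explicit_hydrogens` attribute).
#'
#' @param dataset a `qsar_dataset` with raw structure strings.
#' @return list with elements `dataset` (curated) and `report`
#'   (a [curation_report]).
#' @export
curate_chemistry <- function(dataset) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  cmp <- dataset$compounds
  n_in <- nrow(dataset$records)
  keep <- logical(nrow(cmp))
  new_smiles <- character(nrow(cmp))
  audit <- list()
  counts <- stats::setNames(integer(length(curation_actions)), curation_actions)
  note <- function(id, action, detail = "") {
    audit[[length(audit) + 1L]] <<- data.frame(id = id, action = action,
                                               detail = detail)
    counts[action] <<- counts[action] + 1L
  }
  for (i in seq_len(nrow(cmp))) {
    raw <- cmp$smiles[i]
    frags <- strsplit(trimws(raw %||% ""), ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    parsed <- lapply(frags, .parse_fragment)
    valid <- !vapply(parsed, is.null, logical(1))
    if (!any(valid)) {
      note(cmp$id[i], "removed_unparseable", raw)
      next
    }
    parsed <- parsed[valid]
    organic <- vapply(parsed, function(p) p$organic, logical(1))
    if (!any(organic)) {
      note(cmp$id[i], "removed_inorganic", raw)
      next
    }
    org <- parsed[organic]
    heavy <- vapply(org, function(p) p$heavy, numeric(1))
    best <- org[[which.max(heavy)]]
    if (length(frags) > 1L) note(cmp$id[i], "fixed", "stripped counter-ions/solvent")
    if (!identical(best$canonical, raw)) {
      note(cmp$id[i], "normalized", paste(raw, "->", best$canonical))
    }
    keep[i] <- TRUE
    new_smiles[i] <- best$canonical
  }
  cmp$smiles[keep] <- new_smiles[keep]
  kept_ids <- cmp$id[keep]
  recs <- dataset$records[dataset$records$compound_id %in% kept_ids, , drop = FALSE]
  out <- new_qsar_dataset(cmp[keep, , drop = FALSE], recs, dataset$schema,
                          rejects = dataset$rejects)
  attr(out, "explicit_hydrogens") <- TRUE
  rep <- new_curation_report(counts, do.call(rbind, audit),
                             n_in = n_in, n_out = nrow(recs))
  list(dataset = out, report = rep)
}

#' Remove records with missing endpoint values
#'
#' @param dataset a `qsar_dataset`.
#' @return list(dataset, report); warns when nothing remains.
#' @export
drop_missing_endpoints <- function(dataset) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  n_in <- nrow(dataset$records)
  miss <- is.na(dataset$records$value)
  audit <- if (any(miss)) {
    data.frame(id = dataset$records$compound_id[miss],
               action = "removed_missing_endpoint", detail = "")
  } else NULL
  dataset$records <- dataset$records[!miss, , drop = FALSE]
  if (nrow(dataset$records) == 0L) {
    warning("all records had missing endpoints; dataset is empty")
  }
  rep <- new_curation_report(c(removed_missing_endpoint = sum(miss)), audit,
                             n_in = n_in, n_out = nrow(dataset$records))
  list(dataset = dataset, report = rep)
}

.dup_key <- function(dataset, with_value = TRUE) {
  r <- dataset$records
  smi <- dataset$compounds$smiles[match(r$compound_id, dataset$compounds$id)]
  parts <- c(list(smi),
             lapply(condition_fields(dataset$schema), function(f) r[[f]]),
             list(r$endpoint_name))
  if (with_value) parts <- c(parts, list(format(r$value, digits = 15)))
  do.call(paste, c(parts, sep = "\r"))
}

#' Duplicate analysis, stage I
#'
#' Collapses groups of records that are exactly identical in canonical
#' structure, every experimental-condition field, endpoint name and endpoint
#' value down to a single record (the first by input order).
#'
#' @param dataset a curated `qsar_dataset`.
#' @return list(dataset, report).
#' @export
duplicate_analysis_I <- function(dataset) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  n_in <- nrow(dataset$records)
  key <- .dup_key(dataset, with_value = TRUE)
  first <- !duplicated(key)
  dropped <- dataset$records$compound_id[!first]
  audit <- if (length(dropped)) {
    data.frame(id = dropped, action = "merged_dupI", detail = "exact duplicate")
  } else NULL
  dataset$records <- dataset$records[first, , drop = FALSE]
  rep <- new_curation_report(c(merged_dupI = sum(!first)), audit,
                             n_in = n_in, n_out = nrow(dataset$records))
  list(dataset = dataset, report = rep)
}

#' Duplicate analysis, stage II
#'
#' Groups records by (canonical structure, all condition fields); groups
#' whose endpoint values span less than `diff_cutoff` (native units) are
#' replaced by a single record holding the arithmetic mean. Wider groups
#' whose values all map to the same activity class keep the record closest
#' to the group median (ties to the first by input order); groups whose
#' values straddle the class cutoff are removed entirely.
#'
#' @param dataset a `qsar_dataset` already passed through
#'   [duplicate_analysis_I()].
#' @param diff_cutoff value-range window for averaging, default 0.5 on the
#'   endpoint's native scale; may be a named vector per endpoint name.
#' @return list(dataset, report).
#' @export
duplicate_analysis_II <- function(dataset, diff_cutoff = 0.5) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  n_in <- nrow(dataset$records)
  key <- .dup_key(dataset, with_value = FALSE)
  groups <- split(seq_len(n_in), key)
  keep_rows <- logical(n_in)
  new_value <- dataset$records$value
  counts <- c(averaged_dupII = 0L, kept_same_class_dupII = 0L,
              removed_conflicting = 0L)
  audit <- list()
  for (g in groups) {
    if (length(g) == 1L) { keep_rows[g] <- TRUE; next }
    g <- sort(g)
    vals <- dataset$records$value[g]
    ep <- dataset$records$endpoint_name[g[1]]
    cut <- if (!is.null(names(diff_cutoff)) && ep %in% names(diff_cutoff)) {
      diff_cutoff[[ep]]
    } else diff_cutoff[[1]]
    if (max(vals) - min(vals) < cut) {
      keep_rows[g[1]] <- TRUE
      new_value[g[1]] <- mean(vals)
      counts["averaged_dupII"] <- counts["averaged_dupII"] + 1L
      audit[[length(audit) + 1L]] <- data.frame(
        id = dataset$records$compound_id[g[1]], action = "averaged_dupII",
        detail = sprintf("%d values averaged to %g", length(g), mean(vals)))
    } else {
      classes <- label_endpoint(ep, vals)
      if (length(unique(classes)) == 1L) {
        med <- stats::median(vals)
        pick <- g[which.min(abs(vals - med))]
        keep_rows[pick] <- TRUE
        counts["kept_same_class_dupII"] <- counts["kept_same_class_dupII"] + 1L
        audit[[length(audit) + 1L]] <- data.frame(
          id = dataset$records$compound_id[pick], action = "kept_same_class_dupII",
          detail = sprintf("kept median-closest of %d same-class values", length(g)))
      } else {
        counts["removed_conflicting"] <- counts["removed_conflicting"] + 1L
        audit[[length(audit) + 1L]] <- data.frame(
          id = dataset$records$compound_id[g[1]], action = "removed_conflicting",
          detail = sprintf("%d class-conflicting values removed", length(g)))
      }
    }
  }
  dataset$records$value <- new_value
  dataset$records <- dataset$records[keep_rows, , drop = FALSE]
  rep <- new_curation_report(counts, do.call(rbind, audit),
                             n_in = n_in, n_out = nrow(dataset$records))
  list(dataset = dataset, report = rep)
}

#' Run the full curation chain
#'
#' [curate_chemistry()], then [drop_missing_endpoints()],
#' [duplicate_analysis_I()] and [duplicate_analysis_II()], then class
#' labeling via [label_dataset()]. Running the chain on its own output is a
#' fixed point.
#'
#' @param dataset a raw `qsar_dataset`.
#' @param diff_cutoff passed to [duplicate_analysis_II()].
#' @return list(dataset, report) with a merged report.
#' @export
curate_dataset <- function(dataset, diff_cutoff = 0.5) {
  s1 <- curate_chemistry(dataset)
  s2 <- drop_missing_endpoints(s1$dataset)
  s3 <- duplicate_analysis_I(s2$dataset)
  s4 <- duplicate_analysis_II(s3$dataset, diff_cutoff = diff_cutoff)
  list(dataset = label_dataset(s4$dataset),
       report = merge_reports(s1$report, s2$report, s3$report, s4$report))
}

#' Export a curation audit trail
#'
#' @param report a [curation_report].
#' @param path output path for a tab-separated audit table.
#' @return the path, invisibly.
#' @export
write_curation_audit <- function(report, path) {
  utils::write.table(report$audit, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
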