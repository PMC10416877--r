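#' Declare an experimental-condition schema
#'
#' A schema names the condition fields of a multi-tasking model and the
#' vocabulary (allowed categories) of each. Numeric conditions such as
#' exposure time or ligand-to-G4 ratio are declared as discrete levels and
#' treated as categories throughout. A field may be declared derived from
#' another field through a lookup table (e.g. the oncogene/target implied by
#' a G4-forming sequence), in which case it is not an independent factor in
#' condition grids.
#'
#' @param ... named character vectors, one per condition field, giving the
#'   allowed values in their canonical order.
#' @param derived optional named list; each element is a named character
#'   vector mapping values of the field named by attribute `from` to values
#'   of the derived field. See `default_condition_grids()` for the bundled
#'   sequence-to-oncogene lookup.
#' @return an object of class `condition_schema`.
#' @examples
#' sch <- condition_schema(buffer = c("K100", "Na100"), lgr = c("5", "10"))
#' @export
condition_schema <- function(..., derived = NULL) {
  fields <- list(...)
  if (length(fields) == 1L && is.list(fields[[1]]) && is.null(names(fields))) {
    fields <- fields[[1]]
  }
  if (length(fields) == 0L) stop("a schema needs at least one condition field")
  if (is.null(names(fields)) || any(names(fields) == "")) {
    stop("every condition field must be named")
  }
  fields <- lapply(fields, as.character)
  structure(list(fields = fields, derived = derived), class = "condition_schema")
}

#' @export
print.condition_schema <- function(x, ...) {
  cat("Condition schema (", length(x$fields), " fields)\n", sep = "")
  for (f in names(x$fields)) {
    cat("  ", f, ": ", paste(x$fields[[f]], collapse = ", "), "\n", sep = "")
  }
  if (length(x$derived)) {
    cat("  derived: ", paste(names(x$derived), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Condition field names of a schema
#'
#' @param schema a `condition_schema`.
#' @return character vector of field names in declaration order.
#' @export
condition_fields <- function(schema) names(schema$fields)

check_conditions <- function(records, schema) {
  for (f in condition_fields(schema)) {
    if (!f %in% names(records)) stop("condition field '", f, "' missing from records")
    bad <- !(records[[f]] %in% schema$fields[[f]]) & !is.na(records[[f]])
    if (any(bad)) {
      stop("field '", f, "': value(s) outside declared vocabulary: ",
           paste(unique(records[[f]][bad]), collapse = ", "))
    }
  }
  invisible(TRUE)
}

new_qsar_dataset <- function(compounds, records, schema, rejects = NULL) {
  stopifnot(is.data.frame(compounds), is.data.frame(records))
  if (anyDuplicated(compounds$id)) stop("compound ids must be unique")
  if (!all(records$compound_id %in% compounds$id)) {
    stop("every record must reference a known compound id")
  }
  structure(list(compounds = compounds, records = records,
                 schema = schema, rejects = rejects),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat("qsar_dataset: ", nrow(x$compounds), " compounds, ",
      nrow(x$records), " records\n", sep = "")
  if (!is.null(x$rejects) && nrow(x$rejects)) {
    cat("  rejects: ", nrow(x$rejects), " rows (see $rejects)\n", sep = "")
  }
  cl <- x$records$class_label
  if (!all(is.na(cl))) {
    cat("  classes: ", sum(cl == 1L, na.rm = TRUE), " positive / ",
        sum(cl == 0L, na.rm = TRUE), " negative\n", sep = "")
  }
  invisible(x)
}

# Autodetect comma vs tab separation from the header line.
.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0L) stop("file is empty: ", path)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0L) "\t" else ","
}

#' Read a multi-condition bioactivity table
#'
#' Reads a delimited text file (comma or tab, autodetected) holding one
#' bioactivity measurement per row: a SMILES column, one column per
#' condition field of the schema, and an endpoint value column. Malformed
#' rows (unknown condition category, non-numeric endpoint where one is
#' required) are collected in the dataset's `$rejects` table rather than
#' silently dropped; rows with an empty endpoint are kept and flagged so the
#' curation step can remove and count them.
#'
#' @param path delimited text file with a header.
#' @param schema a `condition_schema`.
#' @param endpoint_name endpoint identifier ("Kd", "dTm", "IC50"); also the
#'   expected name of the value column unless `endpoint_col` says otherwise.
#' @param endpoint_col name of the value column; defaults to `endpoint_name`.
#' @param smiles_col name of the structure column, default "smiles".
#' @return a `qsar_dataset` with unset class labels.
#' @export
read_dataset <- function(path, schema, endpoint_name,
                         endpoint_col = endpoint_name, smiles_col = "smiles") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE)
  need <- c(smiles_col, condition_fields(schema), endpoint_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  value <- suppressWarnings(as.numeric(raw[[endpoint_col]]))
  blank <- is.na(raw[[endpoint_col]]) | trimws(raw[[endpoint_col]]) == ""
  bad_cond <- rep(FALSE, n)
  why <- rep(NA_character_, n)
  for (f in condition_fields(schema)) {
    off <- !(raw[[f]] %in% schema$fields[[f]])
    why[off & !bad_cond] <- paste0("unknown category in field '", f, "'")
    bad_cond <- bad_cond | off
  }
  nonnum <- !blank & is.na(value)
  why[nonnum & is.na(why)] <- "non-numeric endpoint"
  reject <- bad_cond | nonnum
  rejects <- if (any(reject)) cbind(raw[reject, , drop = FALSE],
                                    reason = why[reject]) else NULL

  keep <- which(!reject)
  smiles <- raw[[smiles_col]][keep]
  ids <- paste0("cmp", formatC(seq_along(keep), width = 5, flag = "0"))
  recs <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (f in condition_fields(schema)) recs[[f]] <- raw[[f]][keep]
  recs$endpoint_name <- endpoint_name
  recs$value <- value[keep]
  recs$class_label <- NA_integer_
  compounds <- data.frame(id = ids, smiles = smiles,
                          provenance = paste0(basename(path), ":row", keep),
                          stringsAsFactors = FALSE)
  new_qsar_dataset(compounds, recs, schema, rejects = rejects)
}

#' Assign binary class labels to every record of a dataset
#'
#' Applies the pre-defined activity cutoff of each record's endpoint
#' (see [label_endpoint()]) to fill the `class_label` column.
#'
#' @param dataset a `qsar_dataset`.
#' @return the dataset with `class_label` set for records with a value.
#' @export
label_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  r <- dataset$records
  ok <- !is.na(r$value)
  for (ep in unique(r$endpoint_name[ok])) {
    i <- ok & r$endpoint_name == ep
    r$class_label[i] <- label_endpoint(ep, r$value[i])
  }
  dataset$records <- r
  dataset
}

#' Validate raw structure inputs
#'
#' Gives a per-item verdict for a vector of SMILES strings:
#' \describe{
#'   \item{ok}{parses to a single connected structure within the size cap}
#'   \item{disconnected}{multiple fragments, at most one of them organic
#'     (a salt or solvate)}
#'   \item{mixture}{two or more organic fragments}
#'   \item{too_large}{more than `max_heavy_atoms` heavy atoms}
#'   \item{unparseable}{not valid SMILES}
#' }
#' Never raises on arbitrary input; failures are encoded in the verdict.
#'
#' @param smiles_list character vector of structure strings.
#' @param max_heavy_atoms heavy-atom cap above which a molecule counts as
#'   too large; default 150.
#' @return character vector of verdicts, aligned 1:1 with the input.
#' @export
validate_input_structures <- function(smiles_list, max_heavy_atoms = 150) {
  vapply(as.character(smiles_list), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return("unparseable")
    frags <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (length(frags) == 0L) return("unparseable")
    info <- lapply(frags, .parse_fragment)
    if (any(vapply(info, is.null, logical(1)))) return("unparseable")
    n_org <- sum(vapply(info, function(x) x$organic, logical(1)))
    heavy <- sum(vapply(info, function(x) x$heavy, numeric(1)))
    if (length(frags) > 1L) {
      if (n_org >= 2L) return("mixture") else return("disconnected")
    }
    if (heavy > max_heavy_atoms) return("too_large")
    "ok"
  }, character(1), USE.NAMES = FALSE)
}

#' Export a prediction matrix
#'
#' Writes per-model screening predictions to disk. The delimited format
#' stacks all models in one table (a `model` column plus the union of
#' condition fields); the workbook format writes a single-file XML
#' spreadsheet (SpreadsheetML) with one worksheet per model, each sheet
#' holding SMILES, the model's condition fields, the predicted class and
#' the applicability-domain flag.
#'
#' @param matrix a `prediction_matrix` from [screen_compounds()].
#' @param path output file path.
#' @param format "delimited" (tab-separated) or "workbook".
#' @param sep field separator for the delimited format.
#' @return the path, invisibly.
#' @export
write_prediction_matrix <- function(matrix, path,
                                    format = c("delimited", "workbook"),
                                    sep = "\t") {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "prediction_matrix"))
  if (length(matrix$results) == 0L || all(vapply(matrix$results, nrow, 0L) == 0L)) {
    stop("prediction matrix is empty; nothing to write")
  }
  if (format == "delimited") {
    tabs <- lapply(names(matrix$results), function(m) {
      df <- matrix$results[[m]]
      cbind(model = m, df, stringsAsFactors = FALSE)
    })
    cols <- Reduce(union, lapply(tabs, names))
    tabs <- lapply(tabs, function(df) {
      for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
      df[, cols, drop = FALSE]
    })
    out <- do.call(rbind, tabs)
    ok <- try(utils::write.table(out, path, sep = sep, row.names = FALSE,
                                 quote = FALSE), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write to ", path)
  } else {
    .write_spreadsheetml(matrix$results, path)
  }
  invisible(path)
}

# Single-file SpreadsheetML (XML Spreadsheet 2003) workbook writer:
# text-only, one <Worksheet> per model, readable by Excel and LibreOffice.
.write_spreadsheetml <- function(sheets, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- try(file(path, "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<?mso-application progid="Excel.Sheet"?>',
    paste0('<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet" ',
           'xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">')), con)
  for (m in names(sheets)) {
    df <- sheets[[m]]
    writeLines(sprintf('<Worksheet ss:Name="%s"><Table>', esc(m)), con)
    cell <- function(v) {
      if (is.na(v)) return('<Cell><Data ss:Type="String"></Data></Cell>')
      if (is.numeric(v)) {
        sprintf('<Cell><Data ss:Type="Number">%s</Data></Cell>',
                format(v, digits = 15))
      } else {
        sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>', esc(as.character(v)))
      }
    }
    hdr <- paste0("<Row>", paste0(vapply(names(df), cell, character(1)),
                                  collapse = ""), "</Row>")
    writeLines(hdr, con)
    for (i in seq_len(nrow(df))) {
      vals <- lapply(df, function(col) col[[i]])
      writeLines(paste0("<Row>", paste0(vapply(vals, cell, character(1)),
                                        collapse = ""), "</Row>"), con)
    }
    writeLines("</Table></Worksheet>", con)
  }
  writeLines("</Workbook>", con)
  invisible(path)
}

#' Write a dataset back to delimited text
#'
#' Inverse of [read_dataset()]: one row per record with the compound's
#' SMILES, the condition fields and the endpoint value, so a dataset
#' round-trips through disk with record counts and field values intact.
#'
#' @param dataset a `qsar_dataset`.
#' @param path output path.
#' @param sep separator, default tab.
#' @return the path, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "qsar_dataset"))
  idx <- match(dataset$records$compound_id, dataset$compounds$id)
  ep <- unique(dataset$records$endpoint_name)
  out <- data.frame(smiles = dataset$compounds$smiles[idx], stringsAsFactors = FALSE)
  for (f in condition_fields(dataset$schema)) out[[f]] <- dataset$records[[f]]
  out[[if (length(ep) == 1L) ep else "value"]] <- dataset$records$value
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
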