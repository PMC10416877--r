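#' Load screening condition grids
#'
#' Condition grids declare, per model, the lists of G4 sequences, buffers,
#' assays, ligand-to-G4 ratios, cell lines and exposure times a compound
#' library is screened over; the screening engine enumerates their
#' cartesian product. Grids live in a versioned JSON config so the
#' condition choice is auditable and replaceable; the bundled default
#' reproduces the four deployed model grids (selectivity 18, interaction
#' 24, stabilization 24, cytotoxicity 10 condition rows).
#'
#' @param path JSON config path; default the bundled grids.
#' @return named list of `condition_grid` objects.
#' @export
default_condition_grids <- function(path = system.file("extdata",
                                                       "default_grids.json",
                                                       package = "mtqsar")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(cfg$models), function(m) {
    spec <- cfg$models[[m]]
    structure(list(model = m,
                   fields = lapply(spec$fields, as.character),
                   derived = spec$derived,
                   endpoint = spec$endpoint,
                   sequence_targets = cfg$sequence_targets),
              class = "condition_grid")
  })
  stats::setNames(out, names(cfg$models))
}

#' @export
print.condition_grid <- function(x, ...) {
  sizes <- lengths(x$fields)
  cat("condition_grid '", x$model, "': ",
      paste(names(sizes), sizes, sep = "=", collapse = " x "),
      " -> ", prod(sizes), " conditions\n", sep = "")
  invisible(x)
}

#' Schema implied by a condition grid
#'
#' @param grid a `condition_grid`.
#' @return the matching `condition_schema`.
#' @export
grid_schema <- function(grid) {
  stopifnot(inherits(grid, "condition_grid"))
  condition_schema(grid$fields, derived = grid$derived)
}

#' Enumerate the condition profiles of a grid
#'
#' Cartesian product of the grid's field vocabularies in deterministic
#' order: fields in declared order with the last field varying fastest,
#' values in config order. Derived fields (e.g. the oncogene implied by a
#' sequence) are filled by lookup, not multiplied into the product.
#'
#' @param grid a `condition_grid`.
#' @param schema optional `condition_schema` the grid must agree with; the
#'   call errors when the grid names a field absent from the schema.
#' @return data.frame, one row per condition profile.
#' @export
enumerate_conditions <- function(grid, schema = NULL) {
  stopifnot(inherits(grid, "condition_grid"))
  if (!is.null(schema)) {
    missing <- setdiff(names(grid$fields), condition_fields(schema))
    if (length(missing)) {
      stop("grid field(s) not in the model schema: ",
           paste(missing, collapse = ", "))
    }
  }
  rev_fields <- rev(grid$fields)
  grid_df <- expand.grid(rev_fields, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  grid_df <- grid_df[, rev(names(grid_df)), drop = FALSE]
  # expand.grid varies the first supplied factor fastest; after reversal
  # the last declared field is the fast axis and rows follow config order.
  grid_df <- grid_df[do.call(order, lapply(names(grid$fields), function(f) {
    match(grid_df[[f]], grid$fields[[f]])
  })), , drop = FALSE]
  rownames(grid_df) <- NULL
  if (!is.null(grid$derived)) {
    for (dcol in names(grid$derived)) {
      src <- grid$derived[[dcol]]
      grid_df[[dcol]] <- unname(unlist(grid$sequence_targets[grid_df[[src]]]))
    }
  }
  grid_df
}

#' Drug-likeness filter (rule of 5)
#'
#' Passes compounds satisfying MW <= 500, logP <= 5, H-bond donors <= 5 and
#' H-bond acceptors <= 10. The default is strict (zero violations);
#' `max_violations = 1` reproduces the common one-violation allowance.
#' Properties come from the builtin descriptor backend (OpenBabel
#' atom-contribution logP).
#'
#' @param compounds data.frame with `id` and `smiles`.
#' @param max_violations violations tolerated before failing, default 0.
#' @return list(pass, fail): data.frames, `fail` carrying a `violations`
#'   column naming the violated rules (or "unparseable").
#' @export
lipinski_filter <- function(compounds, max_violations = 0L) {
  stopifnot(is.data.frame(compounds), all(c("id", "smiles") %in% names(compounds)))
  if (nrow(compounds) == 0L) {
    empty <- cbind(compounds, violations = character(0))
    return(list(pass = compounds, fail = empty))
  }
  desc <- compute_descriptors(compounds)$values
  viol <- character(nrow(compounds))
  ok <- logical(nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    row <- desc[compounds$id[i], ]
    if (any(is.na(row[c("MW", "logP", "HBD", "HBA")]))) {
      viol[i] <- "unparseable"
      next
    }
    v <- c(if (row["MW"] > 500) "MW>500",
           if (row["logP"] > 5) "logP>5",
           if (row["HBD"] > 5) "HBD>5",
           if (row["HBA"] > 10) "HBA>10")
    viol[i] <- paste(v, collapse = ",")
    ok[i] <- length(v) <= max_violations
  }
  list(pass = compounds[ok, , drop = FALSE],
       fail = cbind(compounds[!ok, , drop = FALSE],
                    violations = viol[!ok]))
}

#' Screen a compound library over condition grids
#'
#' For each model: descriptors are computed once per compound, every
#' compound is crossed with the model's enumerated condition grid,
#' Box-Jenkins-transformed with the model's stored condition means,
#' classified, and given an applicability-domain verdict per row.
#' Per-compound failures (unparseable structures should be rejected
#' upstream by [validate_input_structures()]) are isolated: the affected
#' compound's rows carry NA predictions, other compounds are unaffected.
#'
#' @param compounds data.frame with `id` and `smiles`.
#' @param models named list of fitted `mtqsar` models.
#' @param grids named list of `condition_grid`s matching `models`; default
#'   the bundled grids for the models supplied.
#' @return a `prediction_matrix`: list(results = per-model data.frames with
#'   SMILES, condition fields, `prediction` and `in_ad`).
#' @export
screen_compounds <- function(compounds, models, grids = NULL) {
  stopifnot(is.data.frame(compounds), length(models) >= 1L,
            !is.null(names(models)))
  if (is.null(grids)) grids <- default_condition_grids()[names(models)]
  results <- list()
  desc_cache <- list()
  for (mname in names(models)) {
    model <- models[[mname]]
    stopifnot(inherits(model, "mtqsar"))
    grid <- grids[[mname]]
    if (is.null(grid)) stop("no condition grid for model '", mname, "'")
    conds <- enumerate_conditions(grid, schema = model$schema)
    tag <- model$backend
    if (is.null(desc_cache[[tag]])) {
      desc_cache[[tag]] <- list(
        desc = compute_descriptors(compounds, backend = "builtin"),
        fp = compute_fingerprints(compounds))
    }
    if (!identical(model$backend, desc_cache[[tag]]$desc$backend)) {
      stop("descriptor backend mismatch: model was trained on '",
           model$backend, "'")
    }
    # align query descriptors with the columns the model's condition means
    # were fitted on (pretreatment pruned the rest)
    need <- model$condition_means$descriptors
    avail <- colnames(desc_cache[[tag]]$desc$values)
    if (!all(need %in% avail)) {
      stop("query descriptor matrix lacks column(s) the model needs: ",
           paste(setdiff(need, avail), collapse = ", "))
    }
    mdesc <- desc_cache[[tag]]$desc
    mdesc$values <- mdesc$values[, need, drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(compounds))) {
      cid <- compounds$id[i]
      block <- cbind(compound_id = cid, conds, stringsAsFactors = FALSE)
      pred <- rep(NA_integer_, nrow(conds))
      inside <- rep(NA, nrow(conds))
      feat <- tryCatch(
        bj_transform(block, mdesc, model$condition_means),
        error = function(e) NULL)
      if (!is.null(feat) && !anyNA(feat)) {
        sub <- feat[, model$selected_columns, drop = FALSE]
        pred <- as.integer(predict(model$classifier, sub))
        inside <- vapply(seq_len(nrow(sub)), function(r) {
          ad_verdict(desc_cache[[tag]]$fp[cid, ], sub[r, ], model$ad_reference)$inside
        }, logical(1))
      }
      rows[[i]] <- cbind(data.frame(smiles = compounds$smiles[i],
                                    stringsAsFactors = FALSE),
                         conds,
                         data.frame(prediction = pred, in_ad = inside))
    }
    results[[mname]] <- do.call(rbind, rows)
  }
  structure(list(results = results), class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat("prediction_matrix:\n")
  for (m in names(x$results)) {
    df <- x$results[[m]]
    cat("  ", m, ": ", nrow(df), " rows (",
        sum(df$prediction == 1L, na.rm = TRUE), " positive)\n", sep = "")
  }
  invisible(x)
}

#' Consensus-positive compounds across models
#'
#' Under `any_condition` (default) a compound is retained when, for every
#' model in the matrix, at least one of its condition rows is predicted
#' positive; under `all_conditions` every row of every model must be
#' positive. The `all_conditions` set is always a subset of the
#' `any_condition` set.
#'
#' @param matrix a `prediction_matrix`.
#' @param rule "any_condition" or "all_conditions".
#' @param required_models model names that must be present; defaults to the
#'   models in the matrix, and the call errors when one is absent.
#' @return character vector of SMILES of retained compounds, in input order.
#' @export
consensus_positive <- function(matrix, rule = c("any_condition", "all_conditions"),
                               required_models = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(matrix, "prediction_matrix"))
  if (!is.null(required_models)) {
    missing <- setdiff(required_models, names(matrix$results))
    if (length(missing)) {
      stop("prediction matrix missing model(s): ", paste(missing, collapse = ", "))
    }
  }
  per_model <- lapply(matrix$results, function(df) {
    agg <- if (rule == "any_condition") {
      tapply(df$prediction == 1L, df$smiles, any)
    } else {
      tapply(df$prediction == 1L, df$smiles, all)
    }
    agg[is.na(agg)] <- FALSE
    agg
  })
  all_smiles <- unique(matrix$results[[1]]$smiles)
  keep <- vapply(all_smiles, function(s) {
    all(vapply(per_model, function(a) isTRUE(a[[s]]), logical(1)))
  }, logical(1))
  all_smiles[keep]
}
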