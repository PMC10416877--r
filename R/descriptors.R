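#' Compute molecular descriptors
#'
#' The builtin backend is a self-contained descriptor set so the whole
#' pipeline runs with no external tools: atom and bond counts, molecular
#' weight, an atom-contribution logP estimate, H-bond donor/acceptor
#' counts, topological polar surface area, molar refractivity, ring and
#' aromatic-ring counts, topological indices (Wiener, first and second
#' Zagreb) and a 166-key structural fingerprint (MACCS-type keys), all
#' derived through OpenBabel. It is deliberately not a clone of any larger
#' commercial/academic descriptor suite; matrices are tagged with the
#' backend that produced them and models refuse matrices from a different
#' backend. An external backend can be plugged in by supplying a function
#' that maps a compound table to a numeric matrix.
#'
#' Per-compound computation failures do not abort: the affected row is
#' filled with NA and flagged in the missing mask.
#'
#' @param compounds data.frame with `id` and `smiles` columns (e.g. the
#'   `$compounds` slot of a `qsar_dataset`).
#' @param backend "builtin", or a function(compounds) returning a numeric
#'   matrix with rownames = compound ids.
#' @param backend_tag label stored in the matrix when a function backend is
#'   used.
#' @return a `descriptor_matrix`: list(values, backend, missing) where
#'   `values` is compounds x descriptors and `missing` marks failed rows.
#' @examples
#' \donttest{
#' m <- compute_descriptors(data.frame(id = "a", smiles = "CCO"))
#' m$values[, c("n_heavy", "HBD", "HBA")]
#' }
#' @export
compute_descriptors <- function(compounds, backend = "builtin",
                                backend_tag = "external") {
  stopifnot(is.data.frame(compounds), all(c("id", "smiles") %in% names(compounds)))
  if (is.function(backend)) {
    vals <- backend(compounds)
    stopifnot(is.matrix(vals), identical(rownames(vals), compounds$id))
    return(structure(list(values = vals, backend = backend_tag,
                          missing = is.na(vals)),
                     class = "descriptor_matrix"))
  }
  if (!identical(backend, "builtin")) stop("unknown backend: ", backend)
  vals <- .builtin_descriptors(compounds)
  structure(list(values = vals, backend = "builtin", missing = is.na(vals)),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("descriptor_matrix [", x$backend, "]: ", nrow(x$values), " compounds x ",
      ncol(x$values), " descriptors", sep = "")
  nf <- sum(apply(x$missing, 1, any))
  if (nf) cat(" (", nf, " rows with missing values)", sep = "")
  cat("\n")
  invisible(x)
}

.builtin_descriptor_names <- function() {
  c("MW", "logP", "TPSA", "MR", "HBD", "HBA",
    "n_heavy", "n_C", "n_N", "n_O", "n_S", "n_halogen",
    "n_bonds", "n_rings", "n_aromatic_rings",
    "wiener", "zagreb1", "zagreb2",
    sprintf("fp_%03d", 1:166))
}

.builtin_descriptors <- function(compounds) {
  nms <- .builtin_descriptor_names()
  vals <- matrix(NA_real_, nrow(compounds), length(nms),
                 dimnames = list(compounds$id, nms))
  for (i in seq_len(nrow(compounds))) {
    id <- compounds$id[i]
    smi <- compounds$smiles[i]
    props <- .ob_props(smi)
    if (is.null(props)) next  # row stays masked
    counts <- .formula_counts(props$formula)
    cnt <- function(e) if (e %in% names(counts)) unname(counts[[e]]) else 0
    heavy <- sum(counts[names(counts) != "H"])
    mol <- .smiles_to_mol(smi)
    if (!is.null(mol)) {
      bb <- ChemmineR::bondblock(mol)
      ring <- .quiet(tryCatch(
        ChemmineR::rings(mol, type = "count", arom = TRUE),
        error = function(e) c(RINGS = NA_real_, AROMATIC = NA_real_)))
      el <- sub("_.*$", "", rownames(ChemmineR::atomblock(mol)))
      topo <- .topological_indices(bb, sum(el != "H"), which(el == "H"))
      nb <- nrow(bb)
    } else if (heavy == 1L) {
      ring <- c(RINGS = 0, AROMATIC = 0)
      topo <- c(wiener = 0, zagreb1 = 0, zagreb2 = 0)
      nb <- 0
    } else next
    row <- c(MW = props$MW, logP = props$logP, TPSA = props$TPSA,
             MR = props$MR, HBD = props$HBD, HBA = props$HBA1,
             n_heavy = heavy, n_C = cnt("C"), n_N = cnt("N"),
             n_O = cnt("O"), n_S = cnt("S"),
             n_halogen = cnt("F") + cnt("Cl") + cnt("Br") + cnt("I"),
             n_bonds = nb,
             n_rings = unname(ring["RINGS"]),
             n_aromatic_rings = unname(ring["AROMATIC"]),
             topo)
    vals[id, 1:18] <- row
    fp <- .ob_maccs(smi)
    if (!is.null(fp)) vals[id, 19:184] <- fp
  }
  vals
}

# Wiener index and Zagreb indices on the heavy-atom graph.
.topological_indices <- function(bondblock, n_heavy, h_idx) {
  if (n_heavy < 1L) return(c(wiener = NA_real_, zagreb1 = NA_real_,
                             zagreb2 = NA_real_))
  if (nrow(bondblock) == 0L || n_heavy == 1L) {
    return(c(wiener = 0, zagreb1 = 0, zagreb2 = 0))
  }
  e <- bondblock[, 1:2, drop = FALSE]
  keep <- !(e[, 1] %in% h_idx) & !(e[, 2] %in% h_idx)
  e <- e[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(e[, 1], e[, 2]), directed = FALSE)
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  d[!is.finite(d)] <- 0  # disconnected pairs contribute nothing
  z2 <- if (nrow(e)) sum(deg[e[, 1]] * deg[e[, 2]]) else 0
  c(wiener = sum(d[upper.tri(d)]), zagreb1 = sum(deg^2), zagreb2 = z2)
}

#' Compute 166-key structural fingerprints
#'
#' MACCS-type structural keys via OpenBabel, as a 0/1 matrix used by the
#' similarity branch of the applicability domain.
#'
#' @param compounds data.frame with `id` and `smiles`.
#' @return integer matrix, compounds x 166 keys; failed rows are all-zero.
#' @export
compute_fingerprints <- function(compounds) {
  stopifnot(is.data.frame(compounds), all(c("id", "smiles") %in% names(compounds)))
  out <- matrix(0L, nrow(compounds), 166,
                dimnames = list(compounds$id, sprintf("fp_%03d", 1:166)))
  for (i in seq_len(nrow(compounds))) {
    fp <- .ob_maccs(compounds$smiles[i])
    if (!is.null(fp)) out[compounds$id[i], ] <- fp
  }
  out
}

#' Pretreat a descriptor matrix
#'
#' Removes constant/near-constant columns (sample variance below
#' `variance_cutoff`), then applies greedy correlation filtering: columns
#' are scanned in input order and a column is dropped when its absolute
#' Pearson correlation with any already-retained column reaches
#' `correlation_cutoff`. The scan order makes the filter deterministic:
#' the first of a correlated pair wins.
#'
#' @param matrix a `descriptor_matrix` or plain numeric matrix.
#' @param variance_cutoff minimum column variance, default 1e-4.
#' @param correlation_cutoff absolute Pearson r at or above which the later
#'   column is dropped, default 0.99.
#' @return list(matrix, removed) where `removed` is a data.frame naming each
#'   dropped column and the reason.
#' @export
pretreat <- function(matrix, variance_cutoff = 1e-4, correlation_cutoff = 0.99) {
  dm <- NULL
  if (inherits(matrix, "descriptor_matrix")) { dm <- matrix; matrix <- dm$values }
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) stop("empty descriptor matrix")
  v <- apply(matrix, 2, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  low <- v < variance_cutoff
  removed <- data.frame(column = colnames(matrix)[low],
                        reason = rep("low_variance", sum(low)))
  kept <- matrix[, !low, drop = FALSE]
  if (ncol(kept) > 1L) {
    cors <- suppressWarnings(stats::cor(kept, use = "pairwise.complete.obs"))
    cors[is.na(cors)] <- 0
    retained <- 1L
    dropped <- integer()
    for (j in 2:ncol(kept)) {
      if (any(abs(cors[j, retained]) >= correlation_cutoff)) {
        dropped <- c(dropped, j)
      } else {
        retained <- c(retained, j)
      }
    }
    if (length(dropped)) {
      removed <- rbind(removed,
                       data.frame(column = colnames(kept)[dropped],
                                  reason = "correlated"))
      kept <- kept[, retained, drop = FALSE]
    }
  }
  if (!is.null(dm)) {
    dm$values <- kept
    dm$missing <- is.na(kept)
    kept <- dm
  }
  list(matrix = kept, removed = removed)
}

#' Drop rows with missing descriptors
#'
#' Removes compounds whose descriptor row has any missing value in the
#' retained columns, from both the matrix and (when supplied) the dataset's
#' compound and record tables. A value that was only missing in a column
#' already removed by [pretreat()] does not cost the row.
#'
#' @param matrix a `descriptor_matrix`.
#' @param dataset optional `qsar_dataset` to filter in step.
#' @return list(matrix, dataset, n_dropped).
#' @export
drop_missing_descriptor_rows <- function(matrix, dataset = NULL) {
  stopifnot(inherits(matrix, "descriptor_matrix"))
  bad <- apply(is.na(matrix$values), 1, any)
  matrix$values <- matrix$values[!bad, , drop = FALSE]
  matrix$missing <- is.na(matrix$values)
  if (!is.null(dataset)) {
    gone <- names(bad)[bad]
    dataset$compounds <- dataset$compounds[!dataset$compounds$id %in% gone, ,
                                           drop = FALSE]
    dataset$records <- dataset$records[!dataset$records$compound_id %in% gone, ,
                                       drop = FALSE]
  }
  list(matrix = matrix, dataset = dataset, n_dropped = sum(bad))
}
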