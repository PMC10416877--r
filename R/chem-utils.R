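# Internal chemistry helpers on top of ChemmineR / ChemmineOB (OpenBabel).
# All SMILES handling funnels through these so curation, descriptors and
# screening agree on what parses and what the canonical form is.

# Elements allowed in an "organic" fragment; anything else (metals etc.)
# marks the fragment inorganic/organometallic.
.organic_elements <- c("C", "H", "N", "O", "S", "P",
                       "F", "Cl", "Br", "I", "B", "Se", "Si")

.quiet <- function(expr) {
  withCallingHandlers(expr,
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
}

# Canonical SMILES via OpenBabel; NA when conversion fails.
.ob_canonical <- function(s) {
  out <- .quiet(tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = s),
    error = function(e) ""))
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

# OpenBabel property block (canonical SMILES, formula, MW, logP, TPSA, MR,
# HBD/HBA counts ...) for one SMILES; NULL when unparseable.
.ob_props <- function(s) {
  res <- .quiet(tryCatch(
    ChemmineOB::forEachMol("SMILES", s, ChemmineOB::prop_OB),
    error = function(e) NULL))
  if (is.null(res)) return(NULL)
  if (!is.data.frame(res)) res <- res[[1]]
  if (!is.data.frame(res) || nrow(res) != 1L) return(NULL)
  res
}

# 166-key MACCS-type structural fingerprint for one SMILES; NULL on failure.
.ob_maccs <- function(s) {
  res <- .quiet(tryCatch(
    ChemmineOB::forEachMol("SMILES", s, function(m) {
      ChemmineOB::fingerprint_OB(list(m), "MACCS")
    }),
    error = function(e) NULL))
  if (is.null(res)) return(NULL)
  bits <- if (is.list(res)) res[[1]] else res
  if (is.matrix(bits)) bits <- bits[1, ]
  if (length(bits) < 166L) return(NULL)
  as.integer(bits[1:166])
}

# Element counts from a molecular formula string ("C8H11N" -> c(C=8,H=11,N=1)).
.formula_counts <- function(formula) {
  formula <- as.character(formula)[1]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?\\d*", formula))[[1]]
  el <- sub("\\d+$", "", toks)
  cnt <- as.integer(sub("^[A-Za-z]+", "", toks))
  cnt[is.na(cnt)] <- 1L
  tapply(cnt, el, sum)
}

# Parse one SMILES fragment (no "." allowed). NULL when unparseable,
# else list(canonical, elements, heavy, organic).
.parse_fragment <- function(s) {
  s <- trimws(s)
  if (!nzchar(s) || grepl(".", s, fixed = TRUE)) return(NULL)
  canonical <- .ob_canonical(s)
  if (is.na(canonical)) return(NULL)
  props <- .ob_props(canonical)
  if (is.null(props)) return(NULL)
  counts <- .formula_counts(props$formula)
  elements <- names(counts)
  heavy <- sum(counts[elements != "H"])
  if (heavy < 1L) return(NULL)
  list(canonical = canonical,
       elements = elements,
       heavy = heavy,
       organic = "C" %in% elements && all(elements %in% .organic_elements))
}

# SMILES -> single-molecule SDF with usable atom/bond blocks, or NULL.
# (Connectivity-derived descriptors need the blocks; single-atom molecules
# come back degenerate and are handled by the caller.)
.smiles_to_mol <- function(s) {
  sdf <- .quiet(tryCatch(ChemmineR::smiles2sdf(s), error = function(e) NULL))
  if (is.null(sdf) || length(sdf) == 0L) return(NULL)
  mol <- sdf[[1]]
  ab <- tryCatch(ChemmineR::atomblock(mol), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0L || !any(grepl("_", rownames(ab)))) {
    return(NULL)
  }
  mol
}
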