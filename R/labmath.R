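#' Degree of dissociation of an ionizable group
#'
#' Fraction of an ionizable group in its dissociated form at a given pH,
#' from the Henderson-Hasselbalch relation:
#' \deqn{\alpha = \frac{1}{10^{pKa - pH} + 1}}
#'
#' @param pKa acid dissociation constant (log scale), finite numeric.
#' @param pH solution pH; default 7.4 (physiological).
#' @return alpha in (0, 1). Vectorized over both arguments.
#' @examples
#' degree_of_dissociation(7.4, 7.4)  # 0.5
#' @export
degree_of_dissociation <- function(pKa, pH = 7.4) {
  stopifnot(is.numeric(pKa), is.numeric(pH), all(is.finite(pKa)), all(is.finite(pH)))
  1 / (10^(pKa - pH) + 1)
}

#' Formal charge over an ionizable group at a given pH
#'
#' Acid groups carry \eqn{-\alpha}; basic groups carry \eqn{+(1-\alpha)},
#' with \eqn{\alpha} the degree of dissociation at the stated pH.
#'
#' @param kind "acid" or "base".
#' @param pKa group pKa.
#' @param pH solution pH, default 7.4.
#' @return signed fractional charge.
#' @examples
#' group_charge("base", pKa = 9.4, pH = 7.4)  # ~ +0.990
#' @export
group_charge <- function(kind = c("acid", "base"), pKa, pH = 7.4) {
  kind <- match.arg(kind)
  a <- degree_of_dissociation(pKa, pH)
  if (kind == "acid") -a else +(1 - a)
}

#' Percentage displacement in a fluorescent-indicator displacement assay
#'
#' Converts the fluorescence area after ligand addition (FA) relative to the
#' area before addition (FA0) into percentage displacement of the indicator:
#' PD = 100 - (FA / FA0) * 100.
#'
#' @param FA fluorescence area after ligand addition, >= 0.
#' @param FA0 fluorescence area before ligand addition, > 0.
#' @return percentage displacement. Vectorized.
#' @export
percent_displacement <- function(FA, FA0) {
  stopifnot(is.numeric(FA), is.numeric(FA0))
  if (any(!is.finite(FA0)) || any(FA0 <= 0)) {
    stop("FA0 must be a positive, finite fluorescence area")
  }
  if (any(FA < 0)) stop("FA must be non-negative")
  100 - (FA / FA0) * 100
}

# Endpoint class thresholds on native units. Positives:
#   Kd   < 1 uM, strict
#   dTm  >= 15 degC
#   IC50 < 10 uM, strict
.endpoint_thresholds <- list(
  Kd   = list(cutoff = 1,  positive_when = "lt"),
  dTm  = list(cutoff = 15, positive_when = "ge"),
  IC50 = list(cutoff = 10, positive_when = "lt")
)

#' Binary class label for a continuous endpoint value
#'
#' Applies the pre-defined activity cutoffs on each endpoint's native scale:
#' Kd positive when < 1 uM, delta-Tm positive when >= 15 degC, IC50 positive
#' when < 10 uM. Boundary values follow these inequalities exactly, so
#' Kd = 1 uM and IC50 = 10 uM are negative while delta-Tm = 15 degC is
#' positive.
#'
#' @param endpoint_name one of "Kd", "dTm", "IC50".
#' @param value numeric endpoint value(s) on native units (uM or degC).
#' @return integer 1 (positive) or 0 (negative), vectorized over value.
#' @export
label_endpoint <- function(endpoint_name, value) {
  th <- .endpoint_thresholds[[endpoint_name]]
  if (is.null(th)) {
    stop("unknown endpoint '", endpoint_name, "'; known: ",
         paste(names(.endpoint_thresholds), collapse = ", "))
  }
  stopifnot(is.numeric(value))
  out <- if (th$positive_when == "lt") value < th$cutoff else value >= th$cutoff
  as.integer(out)
}

#' Call a ligand a G4 stabilizer from a FRET melting shift
#'
#' A ligand counts as a G-quadruplex stabilizer when the ligand-induced
#' melting-temperature shift exceeds 4 degC (strictly).
#'
#' @param dTm melting-temperature shift(s) in degC.
#' @return logical, TRUE when dTm > 4.
#' @export
fret_stabilizer_call <- function(dTm) {
  stopifnot(is.numeric(dTm))
  dTm > 4
}
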