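#' Build an applicability-domain reference
#'
#' Stores the training-set data needed by the three AD methods:
#' \describe{
#'   \item{similarity}{166-key structural fingerprints of the training
#'     compounds; a query is inside when its maximum Tanimoto similarity to
#'     any training compound reaches `tanimoto_min`.}
#'   \item{euclidean}{the training modified-descriptor matrix; a query is
#'     inside when its nearest-neighbor Euclidean distance is at most
#'     mean + `euclidean_k` * SD of the training nearest-neighbor
#'     distances.}
#'   \item{leverage}{the projection data for h = x' (X'X)^-1 x with the
#'     standard warning limit h* = 3 (k + 1) / n, k = number of model
#'     columns (intercept excluded), n = training rows. Disabled with a
#'     warning when n <= k + 1.}
#' }
#' A compound is inside the overall domain when at least one method accepts
#' it (union rule).
#'
#' @param fingerprints 0/1 matrix of training fingerprints (rows =
#'   compounds).
#' @param features training modified-descriptor matrix (rows = records).
#' @param tanimoto_min minimum Tanimoto similarity, default 0.3.
#' @param euclidean_k SD multiplier for the distance cutoff, default 3.
#' @return an `ad_reference`.
#' @export
build_ad_reference <- function(fingerprints, features,
                               tanimoto_min = 0.3, euclidean_k = 3) {
  stopifnot(is.matrix(fingerprints), is.matrix(features))
  if (nrow(fingerprints) == 0L || nrow(features) == 0L) {
    stop("cannot build an applicability domain from an empty training set")
  }
  n <- nrow(features); k <- ncol(features)
  leverage <- NULL
  if (n <= k + 1L) {
    warning("leverage method disabled: n = ", n, " <= k + 1 = ", k + 1L)
  } else {
    xtx_inv <- MASS::ginv(crossprod(features))
    leverage <- list(xtx_inv = xtx_inv, hstar = leverage_warning_limit(k, n))
  }
  # training nearest-neighbor distances (self excluded)
  dmat <- as.matrix(stats::dist(features))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, min)
  structure(list(
    fingerprints = fingerprints != 0,
    features = features,
    nn_cutoff = mean(nn) + euclidean_k * stats::sd(nn),
    thresholds = list(tanimoto_min = tanimoto_min, euclidean_k = euclidean_k),
    leverage = leverage, n = n, k = k),
    class = "ad_reference")
}

#' Leverage warning limit
#'
#' h* = 3 (k + 1) / n for a model with k columns fit on n training rows.
#'
#' @param k number of model columns (intercept excluded).
#' @param n number of training rows.
#' @return the warning limit.
#' @examples
#' leverage_warning_limit(9, 463)  # 0.0648...
#' @export
leverage_warning_limit <- function(k, n) 3 * (k + 1) / n

#' Tanimoto similarity between bit vectors
#'
#' @param a logical/0-1 vector or matrix (rows = queries).
#' @param b logical/0-1 matrix (rows = references).
#' @return matrix of similarities, queries x references; the similarity of
#'   two empty fingerprints is defined as 0.
#' @export
tanimoto_similarity <- function(a, b) {
  A <- if (is.matrix(a)) a != 0 else matrix(a != 0, nrow = 1)
  B <- if (is.matrix(b)) b != 0 else matrix(b != 0, nrow = 1)
  common <- (A * 1) %*% t(B * 1)
  tot <- outer(rowSums(A), rowSums(B), "+") - common
  out <- ifelse(tot == 0, 0, common / tot)
  out
}

#' Leverage of a query point
#'
#' @param x query feature row.
#' @param ref an `ad_reference` with the leverage method enabled.
#' @return h = x' (X'X)^-1 x.
#' @export
leverage_of <- function(x, ref) {
  stopifnot(inherits(ref, "ad_reference"))
  if (is.null(ref$leverage)) stop("leverage method is disabled for this reference")
  drop(t(x) %*% ref$leverage$xtx_inv %*% x)
}

#' Applicability-domain verdict for one query
#'
#' Evaluates the three membership tests against a reference and combines
#' them by the union rule: the compound is inside the overall domain when
#' any single method accepts it.
#'
#' @param fingerprint query 166-key fingerprint (0/1 vector).
#' @param features query modified-descriptor row, columns matching the
#'   reference.
#' @param ref an `ad_reference`.
#' @return an `ad_verdict`: list(similarity, euclidean, leverage, inside).
#'   A disabled leverage method contributes FALSE.
#' @export
ad_verdict <- function(fingerprint, features, ref) {
  stopifnot(inherits(ref, "ad_reference"))
  features <- as.numeric(features)
  if (length(features) != ref$k) {
    stop("query feature columns do not match the reference (",
         length(features), " vs ", ref$k, ")")
  }
  sim <- max(tanimoto_similarity(fingerprint, ref$fingerprints))
  in_sim <- sim >= ref$thresholds$tanimoto_min
  d <- sqrt(colSums((t(ref$features) - features)^2))
  in_euc <- min(d) <= ref$nn_cutoff
  in_lev <- if (is.null(ref$leverage)) FALSE else {
    leverage_of(features, ref) <= ref$leverage$hstar
  }
  structure(list(similarity = in_sim, euclidean = in_euc, leverage = in_lev,
                 inside = in_sim || in_euc || in_lev,
                 max_tanimoto = sim, nn_distance = min(d)),
            class = "ad_verdict")
}

#' @export
print.ad_verdict <- function(x, ...) {
  cat("AD verdict:", if (x$inside) "inside" else "outside",
      sprintf("(similarity %s, euclidean %s, leverage %s)\n",
              x$similarity, x$euclidean, x$leverage))
  invisible(x)
}
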