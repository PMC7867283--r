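# Euclidean applicability domain: APD = d_bar + Z * sigma over the retained
# training pairwise-distance subset (Tropsha-style reading). A prediction is
# trusted only for queries whose nearest training neighbour lies within APD.

#' Fit the applicability domain of a training set
#'
#' Computes all pairwise Euclidean distances between training compounds,
#' retains the distances no larger than their grand mean, and sets the
#' domain threshold to `APD = d_bar + z * sigma`, where `d_bar` and `sigma`
#' are the mean and the (population) standard deviation of the retained
#' subset. The population form means a single retained distance yields
#' `sigma = 0`.
#'
#' @param descriptors Training descriptor matrix with at least two rows.
#' @param z Empirical cutoff multiplier, default 0.5.
#' @return An object of class `applicability_domain` with fields
#'   `reference` (the training rows), `d_bar`, `sigma`, `z`, and
#'   `threshold` (= `d_bar + z * sigma`).
#' @examples
#' m <- matrix(c(0, 0, 2, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("d1", "d2")))
#' fit_apd(m)$threshold  # single pair at distance 2 -> APD = 2
#' @export
fit_apd <- function(descriptors, z = 0.5) {
  m <- as_descriptor_matrix(descriptors)
  stopifnot_scalar_number(z, "z")
  if (nrow(m) < 2L) {
    stop("applicability domain needs at least 2 training compounds", call. = FALSE)
  }
  d <- as.vector(dist(m))
  grand_mean <- mean(d)
  retained <- d[d <= grand_mean]
  d_bar <- mean(retained)
  sigma <- sqrt(mean((retained - d_bar)^2))
  structure(
    list(reference = m, d_bar = d_bar, sigma = sigma, z = z,
         threshold = d_bar + z * sigma),
    class = "applicability_domain"
  )
}

#' @export
print.applicability_domain <- function(x, ...) {
  cat(sprintf(
    "Applicability domain: %d reference compounds, d_bar=%.4f sigma=%.4f z=%.2f APD=%.4f\n",
    nrow(x$reference), x$d_bar, x$sigma, x$z, x$threshold))
  invisible(x)
}

#' Test whether query compounds fall inside the applicability domain
#'
#' A query is in-domain iff the Euclidean distance to its nearest training
#' compound is at most the APD threshold; boundary equality counts as
#' in-domain.
#'
#' @param domain An `applicability_domain`.
#' @param query A descriptor row (named numeric vector) or matrix with the
#'   same descriptors as the training set.
#' @return Logical vector, one entry per query row.
#' @export
is_in_domain <- function(domain, query) {
  ref <- domain$reference
  if (is.null(dim(query))) {
    qnames <- names(query)
    query <- matrix(query, nrow = 1)
    if (length(qnames) == ncol(query)) colnames(query) <- qnames
  }
  if (ncol(query) != ncol(ref)) {
    stop("query dimensionality (", ncol(query),
         ") does not match the reference points (", ncol(ref), ")",
         call. = FALSE)
  }
  if (!is.null(colnames(query)) && !identical(colnames(query), colnames(ref))) {
    query <- query[, colnames(ref), drop = FALSE]
  }
  apply(query, 1, function(q) {
    dmin <- sqrt(min(colSums((t(ref) - as.numeric(q))^2)))
    dmin <= domain$threshold
  })
}
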