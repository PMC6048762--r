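#' Project independent-context signature parameters onto the 96 channels
#'
#' The channel probability is the product of the substitution-class
#' probability and the two flanking-base probabilities; the 96 products sum
#' to 1 by construction.
#'
#' @param sig A list with `class` (named 6-vector over C>A..T>G), `flank5`
#'   and `flank3` (4-vectors over A,C,G,T), and optionally `flank` (must be
#'   1; wider flanks would need explicit marginalization, which is not
#'   implemented).
#' @return Named 96-vector of channel probabilities.
#' @export
signature_to_96 <- function(sig) {
  if (!is.null(sig$flank) && sig$flank != 1L)
    stop("signature_to_96 requires flank = 1")
  check_simplex <- function(p, d, nm) {
    if (length(p) != d || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("'", nm, "' is not a valid probability vector of length ", d)
  }
  check_simplex(sig$class, 6L, "class")
  check_simplex(sig$flank5, 4L, "flank5")
  check_simplex(sig$flank3, 4L, "flank3")
  st <- channel_structure()
  out <- sig$class[st$class_idx] * sig$flank5[st$base5_idx] *
    sig$flank3[st$base3_idx]
  names(out) <- st$channel
  out
}

#' Cosine similarity of two non-negative signature vectors
#'
#' @param a,b Numeric vectors of equal length (channel probabilities or
#'   counts); zero vectors are an error.
#' @return `sum(a*b) / (||a|| ||b||)`, in \[0, 1\] for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

#' Match fitted signatures to a reference set by cosine similarity
#'
#' @param fit A `signature_fit`, or a fitted K x 96 spectra matrix with
#'   channel-label column names.
#' @param reference Reference signatures x 96 matrix
#'   ([read_reference_signatures()] output), columns named by channel label.
#' @return Object of class `"similarity_report"`: list with `similarity`
#'   (fitted x reference matrix), and `best_match` data frame (fitted
#'   signature, best reference, cosine similarity, tie flag). Ties are
#'   broken toward the lowest reference index and flagged.
#' @export
match_to_reference <- function(fit, reference) {
  spectra <- if (inherits(fit, "signature_fit")) fit$spectra else as.matrix(fit)
  labs <- channel_labels()
  if (is.null(colnames(reference)) || !setequal(colnames(reference), labs))
    stop("reference channel labels cannot be aligned to the 96-channel set")
  if (is.null(colnames(spectra))) colnames(spectra) <- labs
  if (!setequal(colnames(spectra), labs))
    stop("fitted spectra channel labels cannot be aligned")
  reference <- reference[, labs, drop = FALSE]
  spectra <- spectra[, labs, drop = FALSE]
  sim <- matrix(NA_real_, nrow(spectra), nrow(reference),
                dimnames = list(rownames(spectra), rownames(reference)))
  for (i in seq_len(nrow(spectra)))
    for (j in seq_len(nrow(reference)))
      sim[i, j] <- cosine_similarity(spectra[i, ], reference[j, ])
  best_j <- apply(sim, 1L, which.max)  # first maximum = lowest index on ties
  tied <- vapply(seq_len(nrow(sim)), function(i)
    sum(sim[i, ] == sim[i, best_j[i]]) > 1L, logical(1))
  report <- list(
    similarity = sim,
    best_match = data.frame(
      fitted = rownames(sim),
      reference = colnames(sim)[best_j],
      cosine = sim[cbind(seq_len(nrow(sim)), best_j)],
      tie = tied,
      row.names = NULL, stringsAsFactors = FALSE)
  )
  class(report) <- "similarity_report"
  report
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Signature-to-reference cosine similarity (",
      nrow(x$similarity), " fitted x ", ncol(x$similarity),
      " reference)\n\nBest matches:\n", sep = "")
  print(transform(x$best_match, cosine = round(cosine, 4)))
  invisible(x)
}
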