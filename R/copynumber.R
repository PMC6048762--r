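CN_STATUSES <- c("amplification", "deletion", "neutral")

#' Classify gene-level copy-number status from a log2 depth ratio
#'
#' A log2 tumour/normal ratio strictly above 0.5 is an amplification,
#' strictly below -0.5 a deletion, anything else (boundaries included)
#' neutral. Non-finite ratios give a missing status.
#'
#' @param log2_ratio Numeric vector of gene-level log2 copy-number ratios.
#' @return Character vector in amplification/deletion/neutral, `NA` for
#'   non-finite input.
#' @export
classify_cn <- function(log2_ratio) {
  out <- rep(NA_character_, length(log2_ratio))
  ok <- is.finite(log2_ratio)
  out[ok & log2_ratio > 0.5] <- "amplification"
  out[ok & log2_ratio < -0.5] <- "deletion"
  out[ok & abs(log2_ratio) <= 0.5] <- "neutral"
  out
}

#' Copy-number status matrix and per-gene alteration frequencies
#'
#' @param ratios Long data frame with `gene`, `sample_id`, `log2_ratio`
#'   ([read_cn_ratios()] output), or a genes-in-columns numeric matrix with
#'   sample rownames.
#' @return List with `status` (samples x genes character matrix) and
#'   `frequencies` (genes x 3 matrix of cohort fractions over non-missing
#'   samples; rows sum to 1).
#' @export
cn_status_matrix <- function(ratios) {
  if (is.matrix(ratios)) {
    m <- ratios
  } else {
    if (anyDuplicated(ratios[, c("gene", "sample_id")]))
      stop("duplicate (gene, sample) rows in copy-number table")
    samples <- unique(ratios$sample_id)
    genes <- unique(ratios$gene)
    m <- matrix(NA_real_, length(samples), length(genes),
                dimnames = list(samples, genes))
    m[cbind(match(ratios$sample_id, samples),
            match(ratios$gene, genes))] <- ratios$log2_ratio
  }
  status <- matrix(classify_cn(m), nrow = nrow(m), dimnames = dimnames(m))
  freq <- t(apply(status, 2L, function(s) {
    s <- s[!is.na(s)]
    if (length(s) == 0L) return(c(0, 0, 0))
    as.numeric(table(factor(s, levels = CN_STATUSES)) / length(s))
  }))
  colnames(freq) <- CN_STATUSES
  list(status = status, frequencies = freq)
}
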