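#' Call a germline genotype from allele depths by ACR rules
#'
#' Site filters are applied first: mapping quality >= 30, alternate-allele
#' depth >= 5, total depth >= 20; a record failing any filter is a missing
#' call. The alternate-allele coverage rate ACR = alt / (ref + alt) is then
#' thresholded: ACR <= 0.1 gives homozygous reference (dosage 0),
#' 0.2 <= ACR <= 0.8 heterozygous (1), ACR >= 0.9 homozygous alternate (2).
#' ACR falling in the uncovered gaps (0.1, 0.2) or (0.8, 0.9) is a missing
#' call — the rules are silent there and a conservative no-call keeps the
#' ambiguity visible in missingness QC.
#'
#' @param ref_depth,alt_depth Non-negative integer vectors of read depths.
#' @param mapping_quality Numeric vector of site mapping qualities.
#' @param min_mq,min_alt,min_depth Filter thresholds (defaults 30, 5, 20).
#' @return Integer vector of dosages in `{0, 1, 2}`, `NA` for missing.
#' @export
call_genotype <- function(ref_depth, alt_depth, mapping_quality,
                          min_mq = 30, min_alt = 5, min_depth = 20) {
  n <- max(length(ref_depth), length(alt_depth), length(mapping_quality))
  ref_depth <- rep_len(ref_depth, n)
  alt_depth <- rep_len(alt_depth, n)
  mapping_quality <- rep_len(mapping_quality, n)
  total <- ref_depth + alt_depth
  pass <- mapping_quality >= min_mq & alt_depth >= min_alt &
    total >= min_depth
  acr <- ifelse(total > 0, alt_depth / total, NA_real_)
  out <- rep(NA_integer_, n)
  out[pass & acr <= 0.1] <- 0L
  out[pass & acr >= 0.2 & acr <= 0.8] <- 1L
  out[pass & acr >= 0.9] <- 2L
  out
}

#' Build a samples x sites genotype matrix from pileup records
#'
#' @param pileups Data frame with `sample_id`, `site`, `ref_depth`,
#'   `alt_depth`, `mapping_quality` ([read_pileups()] output).
#' @param samples,sites Optional orderings; default to first appearance.
#' @param ... Filter thresholds passed to [call_genotype()].
#' @return Integer matrix of dosages (NA = missing call), samples in rows.
#' @export
genotype_matrix <- function(pileups, samples = unique(pileups$sample_id),
                            sites = unique(pileups$site), ...) {
  if (anyDuplicated(pileups[, c("sample_id", "site")]))
    stop("duplicate (sample, site) pileup rows")
  g <- call_genotype(pileups$ref_depth, pileups$alt_depth,
                     pileups$mapping_quality, ...)
  m <- matrix(NA_integer_, nrow = length(samples), ncol = length(sites),
              dimnames = list(samples, sites))
  m[cbind(match(pileups$sample_id, samples), match(pileups$site, sites))] <- g
  m
}

#' Per-site minor-allele frequency, weight and missingness
#'
#' Sites with more than `max_missing` missing calls are dropped, as are
#' monomorphic sites (folded MAF of 0). The MAF is the alternate-allele
#' frequency over non-missing calls, folded at 0.5; the burden weight is
#' `W = 1 / sqrt(MAF * (1 - MAF))`, which up-weights rare alleles.
#'
#' @param genotypes Samples x sites dosage matrix (NA = missing).
#' @param max_missing Maximum tolerated missing-call fraction (default 0.5).
#' @return Data frame with `site`, `maf`, `weight`, `missing_frac` for
#'   retained sites; zero rows (with a warning) if none survive.
#' @export
site_info <- function(genotypes, max_missing = 0.5) {
  if (nrow(genotypes) < 1L) stop("genotype matrix has no samples")
  n_missing <- colSums(is.na(genotypes))
  n_called <- nrow(genotypes) - n_missing
  missing_frac <- n_missing / nrow(genotypes)
  alt_freq <- colSums(genotypes, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(alt_freq, 1 - alt_freq)
  keep <- missing_frac <= max_missing & n_called > 0L & maf > 0
  out <- data.frame(site = colnames(genotypes),
                    maf = maf, weight = 1 / sqrt(maf * (1 - maf)),
                    missing_frac = missing_frac,
                    row.names = NULL, stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no sites retained after filters")
  out
}

#' MAF-weighted genetic burden score for one gene
#'
#' The burden is the weighted dosage sum over the gene's retained sites,
#' `G_i = sum_j W_j g_ij`. Missing dosages are imputed at the site's mean
#' dosage `2 * MAF` by default (so samples with unequal coverage stay
#' comparable), or the site can be skipped per sample.
#'
#' @param genotypes Samples x sites dosage matrix.
#' @param info Site-info data frame ([site_info()] output); only sites
#'   present here (i.e. retained) enter the score.
#' @param site_gene Data frame mapping `site` to `gene`.
#' @param gene Gene symbol.
#' @param impute_missing Impute missing dosages at `2 * MAF` (default TRUE);
#'   otherwise missing sites contribute 0 for that sample.
#' @return Named numeric vector of burden scores, one per sample.
#' @export
burden_score <- function(genotypes, info, site_gene, gene,
                         impute_missing = TRUE) {
  sites <- intersect(site_gene$site[site_gene$gene == gene], info$site)
  if (length(sites) == 0L)
    stop("gene '", gene, "' has no retained sites")
  idx <- match(sites, info$site)
  w <- info$weight[idx]
  maf <- info$maf[idx]
  G <- genotypes[, sites, drop = FALSE]
  storage.mode(G) <- "double"
  if (impute_missing) {
    for (j in seq_along(sites)) {
      miss <- is.na(G[, j])
      G[miss, j] <- 2 * maf[j]
    }
  } else {
    G[is.na(G)] <- 0
  }
  drop(G %*% w)
}

#' Burden scores for several genes
#' @inheritParams burden_score
#' @param genes Character vector; genes without retained sites are skipped
#'   with a warning.
#' @return Samples x genes numeric matrix.
#' @export
burden_matrix <- function(genotypes, info, site_gene, genes,
                          impute_missing = TRUE) {
  cols <- lapply(genes, function(g)
    tryCatch(burden_score(genotypes, info, site_gene, g, impute_missing),
             error = function(e) {
               warning("skipping gene '", g, "': ", conditionMessage(e))
               NULL
             }))
  keep <- !vapply(cols, is.null, logical(1))
  out <- do.call(cbind, cols[keep])
  colnames(out) <- genes[keep]
  out
}

#' Ancestry principal components from a genotype matrix
#'
#' Dosages are mean-imputed per site, column-centered and decomposed; the
#' top components serve as ancestry covariates in the association models.
#' The sign of each component is fixed by making its largest-magnitude
#' loading positive, so scores are reproducible across platforms.
#'
#' @param genotypes Samples x sites dosage matrix (NA = missing).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x n_components), `explained`
#'   (variance fractions), `loadings`.
#' @export
pca_ancestry <- function(genotypes, n_components = 2L) {
  X <- genotypes
  storage.mode(X) <- "double"
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need >= 2 samples and >= 2 sites")
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(samples, sites)")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X, nu = n_components, nv = n_components)
  total_var <- sum(sv$d^2)
  flip <- vapply(seq_len(n_components), function(i) {
    v <- sv$v[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(X %*% sv$v[, seq_len(n_components), drop = FALSE],
                  2, flip, `*`)
  rownames(scores) <- rownames(genotypes)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores,
       explained = if (total_var > 0)
         sv$d[seq_len(n_components)]^2 / total_var
       else rep(0, n_components),
       loadings = sweep(sv$v[, seq_len(n_components), drop = FALSE],
                        2, flip, `*`))
}
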