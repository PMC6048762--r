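#' Cluster samples on relative signature activities
#'
#' Agglomerative hierarchical clustering with Ward's linkage on Euclidean
#' distances between exposure rows, cut into `k` groups. Cluster labels are
#' renumbered deterministically: clusters are ordered by the index of the
#' signature with the highest mean activity within the cluster (ties by
#' decreasing dominant-activity mean), so "subtype 1" always means the
#' cluster dominated by the first signature regardless of dendrogram order.
#'
#' @param exposures Samples x K activity matrix, rows on the simplex,
#'   rownames = sample ids.
#' @param k Number of subtypes (1 <= k <= n).
#' @return Object of class `"subtype_assignment"`: list with `labels`
#'   (named integer vector), `k`, `tree` (the `hclust` object), and
#'   `cluster_means` (k x K mean activities).
#' @export
cluster_activities <- function(exposures, k) {
  exposures <- as.matrix(exposures)
  n <- nrow(exposures)
  if (is.null(rownames(exposures)))
    rownames(exposures) <- paste0("sample", seq_len(n))
  if (anyDuplicated(rownames(exposures))) stop("duplicate sample ids")
  if (k < 1L || k > n) stop("k must be between 1 and the number of samples")
  tree <- stats::hclust(stats::dist(exposures, method = "euclidean"),
                        method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  means <- t(vapply(seq_len(k), function(g)
    colMeans(exposures[raw == g, , drop = FALSE]), numeric(ncol(exposures))))
  dominant <- apply(means, 1L, which.max)
  ord <- order(dominant, -means[cbind(seq_len(k), dominant)])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[raw]
  names(labels) <- rownames(exposures)
  structure(list(labels = labels, k = k, tree = tree,
                 cluster_means = means[ord, , drop = FALSE]),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("Subtype assignment: k =", x$k, "subtypes,",
      length(x$labels), "samples\n")
  print(table(subtype = x$labels))
  invisible(x)
}

#' Export the linkage tree in Newick format
#'
#' @param assignment A `subtype_assignment`.
#' @return Newick string (branch lengths from merge heights). Requires the
#'   `ape` package.
#' @export
subtype_tree_newick <- function(assignment) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export")
  ape::write.tree(ape::as.phylo(assignment$tree))
}

#' Test subtype enrichment of one clinical or molecular feature
#'
#' Categorical features are tested with a chi-squared test on the
#' subtype x level contingency table (Fisher's exact test available for
#' sparse tables); quantitative features with one-way ANOVA across
#' subtypes. Missing feature values are dropped pairwise. Constant
#' features return p = 1 with a degeneracy flag.
#'
#' @param assignment A `subtype_assignment`.
#' @param feature Vector named by (or aligned to) the assignment's samples;
#'   factor/character/logical is treated as categorical, numeric as
#'   quantitative.
#' @param name Feature name carried into the result.
#' @param exact Use Fisher's exact test instead of chi-squared for
#'   categorical features.
#' @return One-row data frame: `feature`, `test`, `statistic`, `df`, `p`,
#'   `degenerate`, `low_expected` (any chi-squared expected cell < 5), with
#'   the per-subtype counts (categorical) or means (quantitative) in the
#'   `"summary"` attribute.
#' @export
enrichment_test <- function(assignment, feature, name = "feature",
                            exact = FALSE) {
  labels <- assignment$labels
  if (!is.null(names(feature))) feature <- feature[names(labels)]
  if (length(feature) != length(labels))
    stop("feature is not aligned to the assignment's samples")
  ok <- !is.na(feature)
  f <- feature[ok]; g <- factor(labels[ok])
  categorical <- !is.numeric(f)
  degenerate <- length(unique(f)) < 2L || nlevels(g) < 2L
  low_expected <- FALSE
  if (degenerate) {
    stat <- if (categorical) 0 else NA_real_
    p <- 1; df <- NA_real_; test <- if (categorical) "chisq" else "anova"
    summ <- table(subtype = g)
  } else if (categorical) {
    tab <- table(subtype = g, level = factor(f))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low_expected <- any(expected < 5)
    if (exact) {
      ht <- stats::fisher.test(tab)
      stat <- NA_real_; df <- NA_real_; p <- ht$p.value; test <- "fisher"
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ht$statistic); df <- unname(ht$parameter)
      p <- ht$p.value; test <- "chisq"
    }
    summ <- tab
  } else {
    fit <- stats::aov(f ~ g)
    an <- summary(fit)[[1]]
    stat <- an[["F value"]][1]; df <- an[["Df"]][1]
    p <- an[["Pr(>F)"]][1]; test <- "anova"
    summ <- tapply(f, g, mean)
  }
  res <- data.frame(feature = name, test = test, statistic = stat,
                    df = df, p = p, degenerate = degenerate,
                    low_expected = low_expected,
                    stringsAsFactors = FALSE)
  attr(res, "summary") <- summ
  res
}

#' Subtype enrichment over a family of features, with joint BH FDR
#'
#' @param assignment A `subtype_assignment`.
#' @param features Data frame of features (rows = samples, aligned by
#'   rownames when present).
#' @param exact Passed to [enrichment_test()].
#' @return Data frame, one row per feature, with a `fdr` column adjusted
#'   jointly across the supplied family (Benjamini-Hochberg).
#' @export
enrichment_suite <- function(assignment, features, exact = FALSE) {
  rows <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    if (!is.null(rownames(features))) names(f) <- rownames(features)
    enrichment_test(assignment, f, name = nm, exact = exact)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out
}
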