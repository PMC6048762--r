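#' Wilcoxon rank-sum association between a proxy and a binary status
#'
#' Two-sided rank-sum test comparing the mutational-process proxy between
#' status groups. The exact null distribution is enumerated when both
#' groups have at most 10 observations and there are no ties; otherwise the
#' normal approximation with continuity and tie corrections is used
#' (p-values near thresholds can differ slightly between the two
#' conventions, hence the explicit rule).
#'
#' @param proxy Numeric vector (activity, frequency or count).
#' @param status 0/1 vector of the same length.
#' @return List with `p` (two-sided), `direction` (sign of median
#'   difference, status 1 minus status 0), `statistic` (rank-sum W),
#'   `method`, `n1`, `n0`.
#' @export
wilcoxon_assoc <- function(proxy, status) {
  ok <- !is.na(proxy) & !is.na(status)
  proxy <- proxy[ok]; status <- status[ok]
  x1 <- proxy[status == 1]; x0 <- proxy[status == 0]
  if (length(x1) == 0L || length(x0) == 0L)
    stop("both status groups must be non-empty")
  ties <- anyDuplicated(proxy) > 0L
  use_exact <- length(x1) <= 10L && length(x0) <= 10L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x1, x0, exact = use_exact, correct = TRUE))
  list(p = ht$p.value,
       direction = sign(stats::median(x1) - stats::median(x0)),
       statistic = unname(ht$statistic),
       method = if (use_exact) "exact" else "normal-approximation",
       n1 = length(x1), n0 = length(x0))
}

#' Weighted-kernel (SKAT-style) score test of a variant set
#'
#' Variance-component score test for association between a gene's weighted
#' germline dosages and a quantitative phenotype, adjusting for covariates.
#' The null model is an ordinary linear regression of the phenotype on the
#' covariates; the score statistic is `Q = r' G W W G' r` with `r` the null
#' residuals, `G` the dosage matrix and `W = diag(weights)`. Under the null
#' `Q` follows a mixture of chi-squared distributions whose weights are the
#' eigenvalues of the projected weighted kernel; the p-value uses a
#' moment-matched (Satterthwaite) scaled chi-squared by default, or Imhof
#' numerical inversion of the exact mixture characteristic function with
#' `method = "davies"`.
#'
#' @param genotypes Samples x sites dosage matrix for the gene (missing
#'   dosages imputed at `2 * maf` when `maf` is supplied, else at the
#'   observed site mean).
#' @param weights Per-site weights (e.g. `site_info()$weight`).
#' @param phenotype Numeric phenotype vector.
#' @param covariates Numeric matrix or data frame of adjustment covariates
#'   (an intercept is added); typically age, stage and the first two
#'   ancestry principal components.
#' @param maf Optional per-site MAFs for missing-dosage imputation.
#' @param method `"satterthwaite"` (default) or `"davies"`.
#' @return List with `p`, `Q`, `lambda` (mixture eigenvalues, residual
#'   variance folded in), `n`, `n_sites`, `method`.
#' @export
skat_test <- function(genotypes, weights, phenotype, covariates = NULL,
                      maf = NULL, method = c("satterthwaite", "davies")) {
  method <- match.arg(method)
  G <- as.matrix(genotypes)
  storage.mode(G) <- "double"
  if (ncol(G) < 1L) stop("no sites in the variant set")
  if (length(weights) != ncol(G))
    stop("weights length does not match the number of sites")
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) {
      fill <- if (!is.null(maf)) 2 * maf[j] else mean(G[, j], na.rm = TRUE)
      G[miss, j] <- fill
    }
  }
  if (all(colSums(G != 0) == 0) && ncol(G) == 1L)
    stop("variant set is monomorphic after filtering")
  n <- nrow(G)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  keep <- stats::complete.cases(X, phenotype)
  X <- X[keep, , drop = FALSE]; y <- phenotype[keep]
  G <- G[keep, , drop = FALSE]
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank deficient")
  r <- qr.resid(qrX, y)
  sigma2 <- sum(r^2) / (n - qrX$rank)
  Z <- sweep(G, 2, weights, `*`)
  if (all(weights == 0)) {
    return(list(p = 1, Q = 0, lambda = numeric(0), n = n,
                n_sites = ncol(G), method = method))
  }
  Q <- sum(crossprod(Z, r)^2)
  # eigenvalues of Z' (I - H) Z give the chi-squared mixture weights
  MZ <- Z - qr.fitted(qrX, Z)
  lambda <- eigen(crossprod(Z, MZ), symmetric = TRUE,
                  only.values = TRUE)$values
  lambda <- sigma2 * lambda[lambda > 1e-10 * max(abs(lambda), 1)]
  if (length(lambda) == 0L)
    return(list(p = 1, Q = Q, lambda = lambda, n = n,
                n_sites = ncol(G), method = method))
  p <- if (method == "satterthwaite") {
    satterthwaite_pvalue(Q, lambda)
  } else {
    imhof_pvalue(Q, lambda)
  }
  list(p = min(max(p, 0), 1), Q = Q, lambda = lambda, n = n,
       n_sites = ncol(G), method = method)
}

satterthwaite_pvalue <- function(Q, lambda) {
  e1 <- sum(lambda)
  v <- 2 * sum(lambda^2)
  a <- v / (2 * e1)
  df <- 2 * e1^2 / v
  stats::pchisq(Q / a, df = df, lower.tail = FALSE)
}

# Imhof (1961) numerical inversion for P(sum lambda_i chi2_1 > q).
# The integrand oscillates with asymptotic period 4*pi/q and decays only
# algebraically, so the integral is taken piecewise over oscillation
# periods and the alternating tail is summed with repeated averaging
# (Euler acceleration) instead of relying on a single adaptive pass.
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  period <- 2 * pi / q   # half-period: consecutive pieces alternate in sign
  n_pieces <- 64L
  pieces <- vapply(seq_len(n_pieces), function(j) {
    stats::integrate(integrand, lower = (j - 1) * period, upper = j * period,
                     rel.tol = 1e-10, subdivisions = 200L,
                     stop.on.error = FALSE)$value
  }, numeric(1))
  head_sum <- sum(pieces[1:(n_pieces / 2)])
  # Euler-accelerate the slowly decaying tail of the piece series
  tail <- pieces[(n_pieces / 2 + 1):n_pieces]
  partial <- cumsum(tail)
  while (length(partial) > 1L)
    partial <- (partial[-1] + partial[-length(partial)]) / 2
  val <- head_sum + partial
  min(max(0.5 + val / pi, 0), 1)
}

#' Multivariate linear regression of a signature activity on burden and
#' somatic status
#'
#' Ordinary least squares of the proxy on the gene's germline burden, its
#' somatic 0/1 status, and clinical covariates (gender 0/1, age, ordinal
#' stage): `activity ~ burden + status + gender + age + stage`. Rows with
#' missing values (e.g. unknown stage) are dropped and counted. The burden
#' and status coefficients are the headline effects; significance stars
#' mark p < 0.05 / 0.01 / 0.001.
#'
#' @param proxy Numeric phenotype vector (e.g. one signature's activity).
#' @param burden Numeric burden vector (`G`).
#' @param status 0/1 somatic status vector (`S`).
#' @param covariates Data frame with columns `gender`, `age`, `stage`
#'   (extra columns are included as additional covariates).
#' @return Object of class `"burden_regression"`: coefficient table
#'   (estimate, std. error, t, p, stars), `sigma2`, `n_used`, `n_dropped`,
#'   and the underlying `lm` fit.
#' @export
multivariate_fit <- function(proxy, burden, status, covariates) {
  covariates <- as.data.frame(covariates)
  dat <- data.frame(proxy = proxy, burden = burden, status = status,
                    covariates)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) <= ncol(dat))
    stop("fewer usable samples than predictors")
  fit <- stats::lm(proxy ~ ., data = dat)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop("collinear predictor(s): ",
         paste(names(which(aliased)), collapse = ", "))
  sm <- summary(fit)
  tab <- as.data.frame(sm$coefficients)
  names(tab) <- c("estimate", "std_error", "t", "p")
  tab$stars <- stars_for(tab$p)
  out <- list(coefficients = tab, sigma2 = sm$sigma^2,
              n_used = nrow(dat), n_dropped = sum(!cc), lm = fit)
  class(out) <- "burden_regression"
  out
}

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "")))
}

#' @export
print.burden_regression <- function(x, ...) {
  cat("Multivariate regression of activity on burden and somatic status\n")
  cat("  n =", x$n_used,
      if (x$n_dropped > 0) paste0("(", x$n_dropped, " dropped)"), "\n")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 4)
  tab$std_error <- signif(tab$std_error, 4)
  tab$t <- round(tab$t, 3)
  tab$p <- signif(tab$p, 3)
  print(tab)
  cat("  residual variance:", signif(x$sigma2, 4), "\n")
  invisible(x)
}

#' @export
coef.burden_regression <- function(object, ...)
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; NAs are preserved.
#' The family label is attached so the adjustment scope stays auditable in
#' downstream tables.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @param family Optional family label recorded as an attribute.
#' @return Numeric vector of FDR-adjusted values.
#' @export
bh_fdr <- function(pvalues, family = NULL) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- stats::p.adjust(pvalues, method = "BH")
  if (!is.null(family)) attr(out, "family") <- family
  out
}

#' Run the full gene-by-proxy association suite
#'
#' For every gene in `genes` and every mutational-process proxy (total SNV
#' count, each signature's activity, each of the six substitution-class
#' frequencies), runs: a Wilcoxon rank-sum test on somatic status; Wilcoxon
#' tests on copy-number amplification and deletion status (altered vs
#' rest); the weighted-kernel burden test with age, stage and two ancestry
#' PCs as covariates; and the multivariate regression, whose burden and
#' somatic-status coefficients are reported as separate test rows. FDR is
#' adjusted by Benjamini-Hochberg within each (test, proxy-family) family.
#'
#' @param catalog Samples x 96 mutation catalog.
#' @param exposures Samples x K activity matrix.
#' @param genotypes Samples x sites germline dosage matrix.
#' @param site_gene Data frame mapping `site` to `gene`.
#' @param somatic Samples x genes 0/1 somatic-status matrix
#'   ([somatic_status_matrix()]).
#' @param cn_status Samples x genes copy-number status matrix (values in
#'   amplification/deletion/neutral), or NULL to skip those tests.
#' @param clinical Clinical data frame with `sample_id`, `age`, `gender`,
#'   `stage`.
#' @param genes Character vector of genes to test; empty gives an empty
#'   table.
#' @param subset Optional character vector of sample ids restricting the
#'   analysis (e.g. one subtype).
#' @return Tidy data frame: `gene`, `proxy`, `proxy_family`, `test`, `n`,
#'   `effect`, `p`, `fdr`, `family`.
#' @export
run_association_suite <- function(catalog, exposures, genotypes, site_gene,
                                  somatic, cn_status = NULL, clinical,
                                  genes, subset = NULL) {
  empty <- data.frame(gene = character(), proxy = character(),
                      proxy_family = character(), test = character(),
                      n = integer(), effect = numeric(), p = numeric(),
                      fdr = numeric(), family = character(),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0L) return(empty)
  samples <- rownames(catalog)
  check_aligned <- function(x, nm) {
    if (!identical(rownames(x), samples))
      stop("sample ids of '", nm, "' do not match the catalog: ",
           paste(utils::head(setdiff(samples, rownames(x)), 3),
                 collapse = ", "))
  }
  check_aligned(exposures, "exposures")
  check_aligned(genotypes, "genotypes")
  check_aligned(somatic, "somatic")
  if (!is.null(cn_status)) check_aligned(cn_status, "cn_status")
  if (!identical(clinical$sample_id, samples))
    stop("sample ids of 'clinical' do not match the catalog")
  if (!is.null(subset)) {
    keep <- samples %in% subset
    catalog <- catalog[keep, , drop = FALSE]
    exposures <- exposures[keep, , drop = FALSE]
    genotypes <- genotypes[keep, , drop = FALSE]
    somatic <- somatic[keep, , drop = FALSE]
    if (!is.null(cn_status)) cn_status <- cn_status[keep, , drop = FALSE]
    clinical <- clinical[keep, , drop = FALSE]
    samples <- samples[keep]
  }

  freqs <- substitution_frequencies(catalog)
  proxies <- cbind(total_snv = rowSums(unclass(catalog)),
                   exposures, freqs$frequencies)
  proxy_family <- c("count", rep("activity", ncol(exposures)),
                    rep("class_freq", 6L))
  names(proxy_family) <- colnames(proxies)

  info <- site_info(genotypes)
  pcs <- pca_ancestry(genotypes, n_components = 2L)$scores
  skat_cov <- cbind(age = clinical$age, stage = clinical$stage, pcs)
  lm_cov <- data.frame(gender = clinical$gender, age = clinical$age,
                       stage = clinical$stage)

  rows <- list()
  add <- function(gene, proxy, test, n, effect, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, proxy = proxy,
      proxy_family = unname(proxy_family[proxy]), test = test,
      n = n, effect = effect, p = p, stringsAsFactors = FALSE)
  }

  for (gene in genes) {
    gene_sites <- intersect(site_gene$site[site_gene$gene == gene],
                            info$site)
    w <- info$weight[match(gene_sites, info$site)]
    maf <- info$maf[match(gene_sites, info$site)]
    s_status <- if (gene %in% colnames(somatic)) somatic[, gene] else NULL
    cn <- if (!is.null(cn_status) && gene %in% colnames(cn_status))
      cn_status[, gene] else NULL
    for (proxy in colnames(proxies)) {
      y <- proxies[, proxy]
      if (!is.null(s_status) && length(unique(s_status)) > 1L) {
        wt <- wilcoxon_assoc(y, s_status)
        add(gene, proxy, "wilcoxon_somatic", wt$n1 + wt$n0,
            wt$direction, wt$p)
      }
      if (!is.null(cn)) {
        for (alt in c("amplification", "deletion")) {
          grp <- as.integer(cn == alt)
          if (length(unique(grp[!is.na(grp)])) > 1L) {
            wt <- wilcoxon_assoc(y, grp)
            add(gene, proxy, paste0("wilcoxon_cn_",
                                    substr(alt, 1, 3)),
                wt$n1 + wt$n0, wt$direction, wt$p)
          }
        }
      }
      if (length(gene_sites) > 0L) {
        sk <- skat_test(genotypes[, gene_sites, drop = FALSE], w, y,
                        covariates = skat_cov, maf = maf)
        add(gene, proxy, "skat_burden", sk$n, NA_real_, sk$p)
        if (!is.null(s_status) && length(unique(s_status)) > 1L) {
          G <- burden_score(genotypes, info,
                            data.frame(site = gene_sites, gene = gene),
                            gene)
          mv <- tryCatch(multivariate_fit(y, G, s_status, lm_cov),
                         error = function(e) NULL)
          if (!is.null(mv)) {
            tab <- mv$coefficients
            add(gene, proxy, "lm_burden", mv$n_used,
                tab["burden", "estimate"], tab["burden", "p"])
            add(gene, proxy, "lm_somatic", mv$n_used,
                tab["status", "estimate"], tab["status", "p"])
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$family <- paste(out$test, out$proxy_family, sep = ":")
  out$fdr <- NA_real_
  for (fam in unique(out$family)) {
    idx <- out$family == fam
    out$fdr[idx] <- bh_fdr(out$p[idx], family = fam)
  }
  rownames(out) <- NULL
  out
}
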