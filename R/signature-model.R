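#' Fit a mixed-membership mutational-signature model by EM
#'
#' Each sample's single-nucleotide variants are modeled as draws from a
#' sample-specific mixture of K signatures. In `independent` mode a
#' signature factorizes the probability of a 96-channel mutation into
#' independent categorical distributions over the six substitution classes
#' and the two flanking bases (the "independent-context" parameterization);
#' in `full96` mode each signature is an unconstrained multinomial over the
#' 96 channels. Parameters are estimated by expectation-maximization from
#' `n_restarts` random initializations, keeping the best log-likelihood.
#' The log-likelihood is asserted non-decreasing at every iteration.
#'
#' @param catalog Samples x 96 count matrix ([build_catalog()] output).
#' @param K Number of signatures (>= 1).
#' @param mode `"independent"` (default) or `"full96"`.
#' @param flank Flanking positions per side; only `1` (96 channels) is
#'   supported — wider contexts would require an extended catalog.
#' @param n_restarts Number of seeded random restarts (default 20).
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @param init Optional explicit initialization, a list with `exposures`
#'   (n x K, rows on the simplex) and `spectra` (K x 96, rows on the
#'   simplex). When given, a single EM run from this point is performed.
#' @return Object of class `"signature_fit"`: list with `spectra` (K x 96
#'   channel probabilities), `signatures` (independent mode: per-signature
#'   `class`, `flank5`, `flank3` categorical parameters), `exposures`
#'   (samples x K relative activities, rows sum to 1), `logLik`, `BIC`,
#'   `n_iter`, `converged`, `restart_logLik`, plus the call metadata.
#' @seealso [signature_to_96()], [match_to_reference()],
#'   [simulate.signature_fit()]
#' @export
fit_signature_model <- function(catalog, K, mode = c("independent", "full96"),
                                flank = 1L, n_restarts = 20L,
                                max_iter = 2000L, tol = 1e-6, seed = 1L,
                                init = NULL) {
  mode <- match.arg(mode)
  if (flank != 1L)
    stop("only flank = 1 (96-channel catalogs) is supported")
  X <- unclass(catalog)
  storage.mode(X) <- "double"
  if (is.null(dim(X)) || ncol(X) != 96L)
    stop("catalog must be a samples x 96 matrix")
  if (K < 1L) stop("K must be >= 1")
  if (all(rowSums(X) == 0)) stop("catalog has no mutations")
  occupied <- sum(colSums(X) > 0)
  if (K > occupied)
    stop("K (", K, ") exceeds the number of occupied channels (",
         occupied, ")")
  n <- nrow(X)

  runs <- if (is.null(init)) seq_len(n_restarts) else 1L
  best <- NULL
  restart_ll <- numeric(length(runs))
  for (r in runs) {
    if (is.null(init)) {
      set.seed(seed + r - 1L)
      start <- random_init(n, K, mode)
    } else {
      start <- normalize_init(init, n, K)
    }
    fit <- em_run(X, start$q, start$P, mode, max_iter, tol)
    restart_ll[r] <- fit$logLik
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }

  dimnames(best$P) <- list(paste0("S", seq_len(K)), colnames(X))
  dimnames(best$q) <- list(rownames(X), rownames(best$P))
  npar <- if (mode == "independent") K * 11L else K * 95L
  npar <- npar + n * (K - 1L)
  total_mut <- sum(X)
  out <- list(
    spectra = best$P,
    signatures = if (mode == "independent") decompose_spectra(best$P) else NULL,
    exposures = best$q,
    logLik = best$logLik,
    BIC = -2 * best$logLik + npar * log(total_mut),
    K = K, mode = mode, flank = 1L,
    n_iter = best$n_iter, converged = best$converged,
    restart_logLik = restart_ll,
    n_samples = n, n_mutations = total_mut,
    sample_totals = rowSums(X),
    seed = seed, call = match.call()
  )
  class(out) <- "signature_fit"
  if (!best$converged)
    warning("EM did not converge within ", max_iter,
            " iterations; best iterate returned")
  out
}

rdirichlet1 <- function(n, d) {
  m <- matrix(stats::rexp(n * d), nrow = n)
  m / rowSums(m)
}

random_init <- function(n, K, mode) {
  q <- rdirichlet1(n, K)
  if (mode == "full96") {
    P <- rdirichlet1(K, 96L)
  } else {
    P <- compose_spectra(rdirichlet1(K, 6L), rdirichlet1(K, 4L),
                         rdirichlet1(K, 4L))
  }
  list(q = q, P = P)
}

normalize_init <- function(init, n, K) {
  q <- as.matrix(init$exposures); P <- as.matrix(init$spectra)
  stopifnot(nrow(q) == n, ncol(q) == K, nrow(P) == K, ncol(P) == 96L)
  list(q = q / rowSums(q), P = P / rowSums(P))
}

# Build K x 96 spectra from independent-context categoricals and back.
compose_spectra <- function(class_probs, flank5, flank3) {
  st <- channel_structure()
  class_probs[, st$class_idx, drop = FALSE] *
    flank5[, st$base5_idx, drop = FALSE] *
    flank3[, st$base3_idx, drop = FALSE]
}

decompose_spectra <- function(P) {
  st <- channel_structure()
  K <- nrow(P)
  agg <- function(idx, d, nm) {
    m <- t(apply(P, 1L, function(p) tapply(p, idx, sum)))
    m <- matrix(m, nrow = K, dimnames = list(rownames(P), nm))
    m / rowSums(m)
  }
  list(class = agg(st$class_idx, 6L, SUB_CLASSES),
       flank5 = agg(st$base5_idx, 4L, BASES),
       flank3 = agg(st$base3_idx, 4L, BASES))
}

em_run <- function(X, q, P, mode, max_iter, tol) {
  st <- channel_structure()
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  pos <- X > 0
  repeat {
    iter <- iter + 1L
    L <- q %*% P                           # n x 96 mixture channel probs
    ll <- sum(X[pos] * log(pmax(L[pos], 1e-300)))
    if (ll < ll_old - 1e-8 * max(1, abs(ll_old)))
      stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * max(1, abs(ll_old))) {
      converged <- TRUE
      break
    }
    if (iter > max_iter) break
    ll_old <- ll
    R <- X / pmax(L, 1e-300)               # ratio matrix, 0 where X = 0
    q <- q * (R %*% t(P))                  # expected mutations per signature
    q <- q / pmax(rowSums(q), 1e-300)
    Tm <- P * (t(q) %*% R)                 # K x 96 expected counts
    if (mode == "full96") {
      P <- Tm / pmax(rowSums(Tm), 1e-300)
    } else {
      phi <- agg_rows(Tm, st$class_idx, 6L)
      p5 <- agg_rows(Tm, st$base5_idx, 4L)
      p3 <- agg_rows(Tm, st$base3_idx, 4L)
      P <- compose_spectra(phi, p5, p3)
    }
  }
  list(q = q, P = P, logLik = ll, n_iter = iter, converged = converged)
}

agg_rows <- function(Tm, idx, d) {
  # sum columns of Tm by idx groups, then normalize rows
  G <- matrix(0, nrow = ncol(Tm), ncol = d)
  G[cbind(seq_along(idx), idx)] <- 1
  M <- Tm %*% G
  M / pmax(rowSums(M), 1e-300)
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Mutational-signature model fit (", x$mode, " mode)\n", sep = "")
  cat("  K =", x$K, "signatures,", x$n_samples, "samples,",
      format(x$n_mutations, big.mark = ","), "mutations\n")
  cat("  log-likelihood:", format(x$logLik), " BIC:", format(x$BIC), "\n")
  cat("  converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' @export
summary.signature_fit <- function(object, ...) {
  cls <- channel_class(colnames(object$spectra))
  top <- apply(object$spectra, 1L, function(p) {
    cl <- tapply(p, cls, sum)
    names(which.max(cl))
  })
  res <- list(fit = object,
              mean_exposure = colMeans(object$exposures),
              dominant_class = top)
  class(res) <- "summary.signature_fit"
  res
}

#' @export
print.summary.signature_fit <- function(x, ...) {
  print(x$fit)
  cat("\nMean exposures:\n")
  print(round(x$mean_exposure, 4))
  cat("\nDominant substitution class per signature:\n")
  print(x$dominant_class)
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, type = c("exposures", "spectra"),
                               ...) {
  type <- match.arg(type)
  object[[type]]
}

#' @export
logLik.signature_fit <- function(object, ...) {
  npar <- (if (object$mode == "independent") object$K * 11L
           else object$K * 95L) + object$n_samples * (object$K - 1L)
  structure(object$logLik, df = npar, class = "logLik")
}

#' Expected channel counts under the fitted model
#' @param object A `signature_fit`.
#' @param ... Unused.
#' @return Samples x 96 matrix of expected counts (each sample's total
#'   mutations spread over channels by its fitted mixture).
#' @export
fitted.signature_fit <- function(object, ...) {
  probs <- object$exposures %*% object$spectra
  probs * object$sample_totals
}

#' Pearson residuals of a catalog against a fitted signature model
#' @param object A `signature_fit`.
#' @param catalog The catalog the model was fitted to.
#' @param ... Unused.
#' @export
residuals.signature_fit <- function(object, catalog, ...) {
  X <- unclass(catalog); storage.mode(X) <- "double"
  mu <- (object$exposures %*% object$spectra) * rowSums(X)
  (X - mu) / sqrt(pmax(mu, .Machine$double.eps))
}

#' Simulate catalogs from a fitted signature model
#'
#' Draws, for each sample, its observed number of mutations from the fitted
#' per-sample mixture over channels — a parametric-bootstrap generator.
#'
#' @param object A `signature_fit`.
#' @param nsim Number of catalogs.
#' @param seed Optional integer seed.
#' @param mutation_counts Per-sample mutation totals (defaults to the mean
#'   fitted total for every sample).
#' @param ... Unused.
#' @return List of `nsim` samples x 96 count matrices.
#' @export
simulate.signature_fit <- function(object, nsim = 1, seed = NULL,
                                   mutation_counts = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  probs <- object$exposures %*% object$spectra
  if (is.null(mutation_counts))
    mutation_counts <- object$sample_totals
  lapply(seq_len(nsim), function(s) {
    m <- t(vapply(seq_len(nrow(probs)), function(i)
      as.integer(stats::rmultinom(1L, mutation_counts[i], probs[i, ])),
      integer(96L)))
    dimnames(m) <- dimnames(probs)
    m
  })
}

#' Plot fitted signature spectra
#'
#' One panel per signature: 96 bars grouped and colored by substitution
#' class, the conventional signature-profile display.
#'
#' @param x A `signature_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.signature_fit <- function(x, ...) {
  cls <- channel_class(colnames(x$spectra))
  cols <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
            "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4")
  old <- graphics::par(mfrow = c(x$K, 1), mar = c(1.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(x$K)) {
    graphics::barplot(x$spectra[k, ], col = cols[cls], border = NA,
                      names.arg = rep("", 96L),
                      ylab = rownames(x$spectra)[k], ...)
  }
  invisible(x)
}
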