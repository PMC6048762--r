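test_that("rank-sum test is exact in the small no-tie regime", {
  # {1,2,3} vs {4,5,6}: 2 of the C(6,3)=20 rank splits are as extreme
  res <- wilcoxon_assoc(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$direction, 1)
  # identical groups
  res2 <- wilcoxon_assoc(rep(c(1, 2, 3), 2), rep(c(0, 1), each = 3))
  expect_equal(res2$p, 1)
  expect_error(wilcoxon_assoc(1:5, rep(0, 5)), "non-empty")
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(71)
  y <- rnorm(40); s <- rbinom(40, 1, 0.5); s[1] <- 0; s[2] <- 1
  p0 <- wilcoxon_assoc(y, s)$p
  expect_equal(wilcoxon_assoc(exp(y), s)$p, p0)
  expect_equal(wilcoxon_assoc(y^3, s)$p, p0)
  expect_equal(wilcoxon_assoc(qlogis(plogis(y)), s)$p, p0)
})

test_that("kernel score test handles degenerate weights and validates input", {
  set.seed(72)
  G <- sapply(runif(5, 0.1, 0.4), function(m) rbinom(50, 2, m))
  y <- rnorm(50)
  res <- skat_test(G, rep(0, 5), y)
  expect_equal(res$Q, 0)
  expect_equal(res$p, 1)
  expect_error(skat_test(G, rep(1, 4), y), "weights length")
  X <- cbind(1, rnorm(50))  # duplicates the added intercept? no: collinear pair
  expect_error(skat_test(G, rep(1, 5), y, covariates = cbind(X, X[, 2])),
               "rank deficient")
})

test_that("kernel score p is invariant to site order and weight scaling", {
  set.seed(73)
  G <- sapply(runif(8, 0.05, 0.5), function(m) rbinom(100, 2, m))
  w <- runif(8, 0.5, 3)
  y <- rnorm(100) + 0.2 * G[, 1]
  cov <- cbind(age = rnorm(100))
  p0 <- skat_test(G, w, y, cov)$p
  perm <- sample(8)
  expect_equal(skat_test(G[, perm], w[perm], y, cov)$p, p0)
  res_scaled <- skat_test(G, 10 * w, y, cov)
  expect_equal(res_scaled$p, p0, tolerance = 1e-10)
  expect_equal(res_scaled$Q, 100 * skat_test(G, w, y, cov)$Q)
})

test_that("moment-matched p agrees with a permutation oracle on a small set", {
  set.seed(74)
  n <- 30
  G <- sapply(c(0.2, 0.3, 0.4), function(m) rbinom(n, 2, m))
  w <- 1 / sqrt(c(0.2, 0.3, 0.4) * (1 - c(0.2, 0.3, 0.4)))
  # a modest planted effect keeps the p-value in a range the permutation
  # null can resolve at this number of permutations
  y <- rnorm(n) + 0.1 * G[, 2]
  res <- skat_test(G, w, y, method = "satterthwaite")
  # permutation oracle: residual permutation of the intercept-only null
  r <- y - mean(y)
  Z <- sweep(G, 2, w, `*`)
  q_obs <- sum(crossprod(Z, r)^2)
  q_perm <- replicate(50000, {
    rp <- r[sample.int(n)]
    sum(crossprod(Z, rp)^2)
  })
  p_perm <- mean(q_perm >= q_obs)
  expect_lt(res$p, 2 * p_perm + 1e-4)
  expect_gt(res$p, p_perm / 2 - 1e-4)
  # exact-mixture evaluation agrees closely with the permutation oracle too
  res_d <- skat_test(G, w, y, method = "davies")
  expect_lt(abs(res_d$p - p_perm), 0.01)
})

test_that("Imhof inversion matches pchisq for a single-component mixture", {
  # one eigenvalue -> the mixture is an exact scaled chi-squared
  for (lam in c(0.5, 2, 7)) {
    for (q in c(0.3, 2, 10)) {
      expect_equal(sigburden:::imhof_pvalue(q, lam),
                   pchisq(q / lam, df = 1, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  }
})

test_that("multivariate regression recovers coefficients exactly", {
  set.seed(75)
  n <- 60
  cov <- data.frame(gender = rbinom(n, 1, 0.5), age = rnorm(n, 60, 8),
                    stage = sample(1:4, n, TRUE))
  burden <- rnorm(n); status <- rbinom(n, 1, 0.4); status[1:2] <- 0:1
  beta <- c(0.3, 0.4, -0.2, 0.05, 0.01, 0.02)
  y <- beta[1] + beta[2] * burden + beta[3] * status +
    beta[4] * cov$gender + beta[5] * cov$age + beta[6] * cov$stage
  fit <- suppressWarnings(multivariate_fit(y, burden, status, cov))  # zero noise
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-20)
})

test_that("OLS equals the normal-equations oracle and flags collinearity", {
  set.seed(76)
  n <- 8
  cov <- data.frame(gender = c(0, 1, 0, 1, 0, 1, 0, 1),
                    age = c(55, 60, 62, 47, 71, 58, 66, 50),
                    stage = c(1, 2, 3, 4, 2, 3, 1, 2))
  burden <- c(0, 2, 4.2, 1.1, 0, 3.3, 2.2, 5)
  status <- c(0, 1, 1, 0, 0, 1, 0, 1)
  y <- rnorm(n)
  fit <- multivariate_fit(y, burden, status, cov)
  X <- cbind(1, burden, status, cov$gender, cov$age, cov$stage)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(fit)), unname(drop(oracle)), tolerance = 1e-10)
  # residuals orthogonal to every design column (machine precision)
  r <- residuals(fit$lm)
  expect_lt(max(abs(t(X) %*% r)), 1e-8)
  # constant status is collinear with the intercept
  expect_error(multivariate_fit(y, burden, rep(1, n), cov), "collinear")
})

test_that("stars and dropped-row accounting behave", {
  expect_equal(sigburden:::stars_for(c(0.2, 0.03, 0.004, 5e-5)),
               c("", "*", "**", "***"))
  set.seed(77)
  n <- 50
  cov <- data.frame(gender = rbinom(n, 1, 0.5), age = rnorm(n, 60, 8),
                    stage = c(NA, sample(1:4, n - 1, TRUE)))
  fit <- multivariate_fit(rnorm(n), rnorm(n), rbinom(n, 1, 0.5), cov)
  expect_equal(fit$n_used, n - 1)
  expect_equal(fit$n_dropped, 1)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(as.numeric(bh_fdr(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))
  expect_equal(as.numeric(bh_fdr(0.37)), 0.37)
  expect_equal(as.numeric(bh_fdr(rep(1, 5))), rep(1, 5))
  expect_equal(length(bh_fdr(numeric(0))), 0L)
  # monotone non-decreasing in sorted-p order, never above 1
  set.seed(78)
  p <- runif(50)
  f <- as.numeric(bh_fdr(p))
  expect_true(all(f <= 1))
  expect_true(all(diff(f[order(p)]) >= -1e-12))
  expect_equal(attr(bh_fdr(p, family = "demo"), "family"), "demo")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the suite flags a planted burden effect first", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_samples = 150, signatures = default_signatures(3),
                      mutations_per_sample = 80, seed = 100 + s)
    co <- simulate_cohort(cfg)
    res <- run_association_suite(co$catalog, co$exposures_true,
                                 co$genotypes_true, co$site_gene,
                                 co$somatic, NULL, co$clinical, cfg$genes)
    sk <- res[res$test == "skat_burden" &
                res$proxy == names(cfg$signatures)[cfg$causal_signature], ]
    if (sk$gene[which.min(sk$p)] == cfg$causal_gene) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("the suite validates alignment and handles empty gene sets", {
  cfg <- sim_config(n_samples = 40, signatures = default_signatures(2),
                    mutations_per_sample = 50, seed = 200)
  co <- simulate_cohort(cfg)
  empty <- run_association_suite(co$catalog, co$exposures_true,
                                 co$genotypes_true, co$site_gene,
                                 co$somatic, NULL, co$clinical, character(0))
  expect_equal(nrow(empty), 0L)
  bad_exp <- co$exposures_true
  rownames(bad_exp)[1] <- "intruder"
  expect_error(run_association_suite(co$catalog, bad_exp, co$genotypes_true,
                                     co$site_gene, co$somatic, NULL,
                                     co$clinical, cfg$genes),
               "exposures")
})

test_that("suite output is a tidy table with within-family FDR", {
  cfg <- sim_config(n_samples = 60, signatures = default_signatures(2),
                    mutations_per_sample = 50, seed = 300)
  co <- simulate_cohort(cfg)
  cns <- cn_status_matrix(co$cn_ratios)
  res <- run_association_suite(co$catalog, co$exposures_true,
                               co$genotypes_true, co$site_gene, co$somatic,
                               cns$status, co$clinical, cfg$genes)
  expect_true(all(c("gene", "proxy", "proxy_family", "test", "n", "effect",
                    "p", "fdr", "family") %in% names(res)))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  for (fam in unique(res$family)) {
    idx <- res$family == fam
    expect_equal(res$fdr[idx], as.numeric(bh_fdr(res$p[idx])))
  }
  # subgroup analysis runs on a subset flag
  sub <- run_association_suite(co$catalog, co$exposures_true,
                               co$genotypes_true, co$site_gene, co$somatic,
                               NULL, co$clinical, cfg$genes,
                               subset = rownames(co$catalog)[1:40])
  expect_true(all(sub$n <= 40))
})
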