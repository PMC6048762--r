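test_that("generators are deterministic given (config, seed)", {
  cfg <- sim_config(n_samples = 25, signatures = default_signatures(3),
                    mutations_per_sample = 40, seed = 9)
  a <- simulate_catalog(cfg); b <- simulate_catalog(cfg)
  expect_identical(unclass(a$catalog), unclass(b$catalog))
  expect_identical(a$exposures, b$exposures)
  g1 <- simulate_genotypes_and_pileups(cfg)
  g2 <- simulate_genotypes_and_pileups(cfg)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_identical(g1$pileups, g2$pileups)
  c1 <- simulate_cohort(cfg); c2 <- simulate_cohort(cfg)
  expect_identical(c1$burdens, c2$burdens)
  expect_identical(unclass(c1$catalog), unclass(c2$catalog))
})

test_that("catalog sampling respects the generating channel distribution", {
  # 1e5 mutations from a single signature: empirical freq within L1 0.02
  sig <- default_signatures(1)
  cfg <- sim_config(n_samples = 1, signatures = sig,
                    mutations_per_sample = 1e5, seed = 33)
  sim <- simulate_catalog(cfg)
  emp <- unclass(sim$catalog)[1, ] / sum(sim$catalog)
  expect_lt(sum(abs(emp - sim$spectra[1, ])), 0.02)
})

test_that("near-degenerate Dirichlet concentrates exposures, zero errors", {
  cfg <- sim_config(n_samples = 200, signatures = default_signatures(3),
                    exposure_conc = 5000, mutations_per_sample = 10,
                    seed = 12)
  sim <- simulate_catalog(cfg)
  expect_lt(max(apply(sim$exposures, 2, sd)), 0.02)
  expect_error(sim_config(exposure_conc = 0), "concentration")
})

test_that("genotypes follow Hardy-Weinberg at the stated MAF", {
  cfg <- sim_config(n_samples = 10000, genes = "G1", sites_per_gene = 3,
                    maf_range = c(0.3, 0.3), seed = 44)
  germ <- simulate_genotypes_and_pileups(cfg)
  freqs <- table(factor(germ$genotypes[, 1], levels = 0:2)) / 10000
  expect_equal(as.numeric(freqs), c(0.49, 0.42, 0.09), tolerance = 0.02)
  expect_error(sim_config(maf_range = c(0, 0.5)), "MAF")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "MAF")
})

test_that("deep clean pileups let the ACR caller recover true dosages", {
  # the alt-depth >= 5 filter means homozygous-reference sites are only
  # callable once depth * error_rate comfortably exceeds 5
  cfg <- sim_config(n_samples = 150, genes = c("G1", "G2"),
                    sites_per_gene = 8, depth_mean = 5000, depth_size = 100,
                    error_rate = 0.005, low_mq_rate = 0, seed = 55)
  germ <- simulate_genotypes_and_pileups(cfg)
  called <- genotype_matrix(germ$pileups,
                            samples = rownames(germ$genotypes),
                            sites = colnames(germ$genotypes))
  ok <- !is.na(called)
  expect_gt(mean(ok), 0.98)
  expect_gt(mean(called[ok] == germ$genotypes[ok]), 0.99)
})

test_that("zero-depth pileups are all missing calls", {
  cfg <- sim_config(n_samples = 30, genes = "G1", sites_per_gene = 4,
                    depth_mean = 1e-9, depth_size = 1, seed = 66)
  germ <- simulate_genotypes_and_pileups(cfg)
  called <- genotype_matrix(germ$pileups)
  expect_true(all(is.na(called)))
})

test_that("activity generator follows the planted regression model", {
  cfg <- sim_config(n_samples = 400, seed = 77,
                    beta = c(b0 = 0.5, b1 = 0, b2 = 0, b3 = 0, b4 = 0,
                             b5 = 0))
  germ <- simulate_genotypes_and_pileups(cfg)
  info <- site_info(germ$genotypes)
  G <- burden_score(germ$genotypes, info, germ$site_gene, "GENE1")
  clin <- simulate_clinical(cfg)
  S <- rbinom(400, 1, 0.3)
  # null effects: recovered burden coefficient unbiased around zero
  est <- replicate(40, {
    act <- simulate_activities(cfg, G, S, clin,
                               seed = sample.int(1e6, 1))
    coef(multivariate_fit(act$activities[, cfg$causal_signature],
                          act$predictors$burden, S,
                          data.frame(gender = clin$gender,
                                     age = act$predictors$age,
                                     stage = act$predictors$stage)))["burden"]
  })
  expect_lt(abs(mean(est)), 0.02)
  # sigma -> 0: exact recovery of the planted coefficients
  cfg2 <- sim_config(n_samples = 400, seed = 78, sigma = 1e-12)
  act2 <- simulate_activities(cfg2, G, S, clin)
  fit2 <- multivariate_fit(act2$activities[, cfg2$causal_signature],
                           act2$predictors$burden, S,
                           data.frame(gender = clin$gender,
                                      age = act2$predictors$age,
                                      stage = act2$predictors$stage))
  expect_equal(unname(coef(fit2)[c("burden", "status")]),
               unname(cfg2$beta[c("b1", "b2")]), tolerance = 1e-6)
  expect_error(sim_config(sigma = 0), "sigma")
})

test_that("simplex-bounded activities are valid exposure rows", {
  cfg <- sim_config(n_samples = 300, seed = 88)
  germ <- simulate_genotypes_and_pileups(cfg)
  info <- site_info(germ$genotypes)
  G <- burden_score(germ$genotypes, info, germ$site_gene, "GENE1")
  clin <- simulate_clinical(cfg)
  act <- simulate_activities(cfg, G, rbinom(300, 1, 0.3), clin,
                             bound = "simplex")
  expect_true(all(act$activities >= 0 & act$activities <= 1))
  expect_equal(unname(rowSums(act$activities)), rep(1, 300))
})

test_that("simulated cohorts round-trip through the module readers", {
  cfg <- sim_config(n_samples = 15, signatures = default_signatures(2),
                    mutations_per_sample = 25, genes = c("GA", "GB"),
                    sites_per_gene = 4, seed = 99)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  sigburden:::write_cohort(co, dir)
  # catalog TSV round-trips exactly
  cat2 <- read_catalog(file.path(dir, "catalog.tsv"))
  expect_equal(unclass(cat2), unclass(co$catalog),
               ignore_attr = "class")
  # MAF reader rebuilds the same catalog and somatic statuses
  recs <- read_maf(file.path(dir, "mutations.maf.tsv"))
  cat3 <- build_catalog(recs, rownames(co$catalog))
  snv_channels <- build_catalog(
    recs[recs$gene == "UNASSIGNED", ], rownames(co$catalog))
  expect_equal(unclass(snv_channels), unclass(co$catalog),
               ignore_attr = TRUE)
  st <- somatic_status_matrix(recs, cfg$genes, rownames(co$catalog))
  expect_equal(unname(st), unname(co$somatic))
  # pileups round-trip into the same genotype calls
  pil <- read_pileups(file.path(dir, "pileups.tsv"))
  m1 <- genotype_matrix(pil, samples = rownames(co$genotypes_true),
                        sites = colnames(co$genotypes_true))
  m2 <- genotype_matrix(co$pileups, samples = rownames(co$genotypes_true),
                        sites = colnames(co$genotypes_true))
  expect_identical(m1, m2)
  # clinical and copy-number tables
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(clin$age, co$clinical$age)
  expect_equal(clin$stage, co$clinical$stage)
  cn <- read_cn_ratios(file.path(dir, "cn.tsv"))
  cnm <- cn_status_matrix(cn)
  expect_equal(sort(rownames(cnm$status)), sort(rownames(co$cn_ratios)))
})

test_that("reference-signature reader accepts COSMIC v2 layout", {
  labs <- channel_labels()
  df <- data.frame(
    `Substitution Type` = substr(labs, 3, 5),
    Trinucleotide = paste0(substr(labs, 1, 1), substr(labs, 3, 3),
                           substr(labs, 7, 7)),
    SigA = as.numeric(runif_simplex(1, 96)),
    SigB = as.numeric(runif_simplex(1, 96)),
    check.names = FALSE)
  # shuffle rows: reader must reorder by channel label
  df <- df[sample(96), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ref <- read_reference_signatures(path)
  expect_equal(dim(ref), c(2L, 96L))
  expect_equal(colnames(ref), labs)
  expect_equal(unname(rowSums(ref)), rep(1, 2), tolerance = 1e-8)
  row <- df[df$Trinucleotide == "ACG" & df$`Substitution Type` == "C>T", ]
  expect_equal(unname(ref["SigA", "A[C>T]G"]), row$SigA)
})
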