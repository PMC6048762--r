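#' Default independent-context signatures for simulation
#'
#' Four synthetic signatures emulating processes commonly active in
#' squamous tumours: a CpG-deamination-like signature (C>T with a 3' G), two
#' APOBEC-like signatures (C>G and C>T with a 5' T), and a broad background.
#' They are constructed for this package's simulations and are not copies of
#' any reference catalog.
#'
#' @param K Number of signatures to return (1--4, in the order above).
#' @return Named list of signatures, each a list with `class`, `flank5`,
#'   `flank3` probability vectors.
#' @export
default_signatures <- function(K = 4L) {
  u4 <- stats::setNames(rep(0.25, 4), BASES)
  peak <- function(levels, at, p) {
    v <- stats::setNames(rep((1 - p) / (length(levels) - 1), length(levels)),
                         levels)
    v[at] <- p
    v
  }
  sigs <- list(
    npcpg = list(class = peak(SUB_CLASSES, "C>T", 0.85),
                 flank5 = u4, flank3 = peak(BASES, "G", 0.85)),
    apobec_cg = list(class = peak(SUB_CLASSES, "C>G", 0.80),
                     flank5 = peak(BASES, "T", 0.85), flank3 = u4),
    apobec_ct = list(class = peak(SUB_CLASSES, "C>T", 0.80),
                     flank5 = peak(BASES, "T", 0.85), flank3 = u4),
    background = list(class = stats::setNames(
                        c(0.12, 0.08, 0.30, 0.10, 0.28, 0.12), SUB_CLASSES),
                      flank5 = u4, flank3 = u4)
  )
  if (K < 1L || K > 4L) stop("default signature set covers K in 1..4")
  sigs[seq_len(K)]
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults
#' emulate a ~300-sample squamous-carcinoma exome cohort: about 46 SNVs per
#' sample, four active signatures, germline sites at common-to-low minor
#' allele frequencies under Hardy-Weinberg equilibrium, ~60x pileup depth,
#' and signature activities generated from the linear model
#' `activity = b0 + b1*burden + b2*status + b3*gender + b4*age + b5*stage + e`
#' with Gaussian noise.
#'
#' @param n_samples Cohort size.
#' @param signatures List of independent-context signatures
#'   ([default_signatures()] format).
#' @param exposure_conc Dirichlet concentration for true exposures (length 1
#'   or K; must be > 0).
#' @param mutations_per_sample Poisson mean SNV count per sample.
#' @param genes Character vector of germline gene names.
#' @param sites_per_gene Sites simulated per gene.
#' @param maf_range Range the per-site minor allele frequencies are drawn
#'   from, within (0, 0.5].
#' @param depth_mean,depth_size Negative-binomial read-depth model (mean and
#'   size/overdispersion).
#' @param error_rate Sequencing error rate (alt-read fraction for dosage 0,
#'   mirrored for dosage 2).
#' @param mq_mean,mq_sd,low_mq_rate Mapping-quality model: Gaussian around
#'   `mq_mean` with a `low_mq_rate` fraction of contaminating low-MQ
#'   (< 30) sites.
#' @param somatic_rate Bernoulli rate of non-synonymous somatic status per
#'   gene.
#' @param beta Named numeric vector of generating regression coefficients
#'   `b0` (baseline activity), `b1` (per-SD burden effect), `b2` (somatic
#'   status), `b3` (gender), `b4` (per-SD age), `b5` (stage, centered).
#' @param sigma Gaussian noise standard deviation (> 0).
#' @param causal_gene,causal_signature Which gene's burden/status drives
#'   which signature's activity.
#' @param seed Base seed recorded in every output.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 302L,
                       signatures = default_signatures(4L),
                       exposure_conc = 1,
                       mutations_per_sample = 46,
                       genes = paste0("GENE", 1:5),
                       sites_per_gene = 10L,
                       maf_range = c(0.05, 0.5),
                       depth_mean = 60, depth_size = 10,
                       error_rate = 0.005,
                       mq_mean = 60, mq_sd = 3, low_mq_rate = 0.02,
                       somatic_rate = 0.3,
                       beta = c(b0 = 0.5, b1 = 0.3, b2 = 0.2,
                                b3 = 0.01, b4 = 0.01, b5 = 0.01),
                       sigma = 0.1,
                       causal_gene = genes[1], causal_signature = 1L,
                       seed = 1L) {
  K <- length(signatures)
  if (length(exposure_conc) == 1L) exposure_conc <- rep(exposure_conc, K)
  if (any(exposure_conc <= 0)) stop("Dirichlet concentration must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("MAF range must lie within (0, 0.5]")
  structure(list(n_samples = as.integer(n_samples), signatures = signatures,
                 K = K, exposure_conc = exposure_conc,
                 mutations_per_sample = mutations_per_sample,
                 genes = genes, sites_per_gene = as.integer(sites_per_gene),
                 maf_range = maf_range, depth_mean = depth_mean,
                 depth_size = depth_size, error_rate = error_rate,
                 mq_mean = mq_mean, mq_sd = mq_sd,
                 low_mq_rate = low_mq_rate, somatic_rate = somatic_rate,
                 beta = beta, sigma = sigma, causal_gene = causal_gene,
                 causal_signature = as.integer(causal_signature),
                 seed = as.integer(seed)),
            class = "sim_config")
}

signature_spectra <- function(signatures) {
  t(vapply(signatures, function(s) signature_to_96(s), numeric(96L)))
}

#' Simulate a mutation catalog from known signatures
#'
#' True exposures are drawn from a Dirichlet; each sample's SNV count from a
#' Poisson; each mutation picks a signature by the exposure weights and a
#' channel from that signature's 96-channel distribution.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @param exposures Optional fixed samples x K exposure matrix overriding
#'   the Dirichlet draw (rows must be on the simplex).
#' @return List with `catalog` (`mutation_catalog`), `exposures` (truth),
#'   `spectra` (true K x 96 matrix), `signatures` (the generating
#'   parameters).
#' @export
simulate_catalog <- function(cfg, seed = cfg$seed, exposures = NULL) {
  set.seed(seed)
  P <- signature_spectra(cfg$signatures)
  n <- cfg$n_samples
  if (is.null(exposures)) {
    exposures <- matrix(stats::rgamma(n * cfg$K, shape = cfg$exposure_conc),
                        nrow = n, byrow = TRUE)
    exposures <- exposures / rowSums(exposures)
  } else {
    exposures <- as.matrix(exposures)
    stopifnot(nrow(exposures) == n, ncol(exposures) == cfg$K)
  }
  counts <- stats::rpois(n, cfg$mutations_per_sample)
  probs <- exposures %*% P
  X <- t(vapply(seq_len(n), function(i)
    as.integer(stats::rmultinom(1L, counts[i], probs[i, ])), integer(96L)))
  dimnames(X) <- list(paste0("sample", seq_len(n)), channel_labels())
  rownames(exposures) <- rownames(X)
  colnames(exposures) <- names(cfg$signatures)
  rownames(P) <- names(cfg$signatures); colnames(P) <- channel_labels()
  list(catalog = structure(X, class = c("mutation_catalog", class(X))),
       exposures = exposures, spectra = P, signatures = cfg$signatures)
}

#' Simulate germline genotypes and matching pileup records
#'
#' True dosages follow Hardy-Weinberg equilibrium at each site's MAF.
#' Pileups draw a negative-binomial total depth and split reads binomially
#' with alternate-read fraction `error_rate`, 0.5, or `1 - error_rate` for
#' dosages 0/1/2; mapping quality is Gaussian with a configurable
#' contamination rate of low-MQ sites.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed.
#' @return List with `genotypes` (true samples x sites dosage matrix),
#'   `pileups` (long data frame), `site_gene` (site-to-gene map), `maf`
#'   (named true MAF vector).
#' @export
simulate_genotypes_and_pileups <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$n_samples
  site_gene <- data.frame(
    site = paste0("chr1:", seq_len(length(cfg$genes) * cfg$sites_per_gene),
                  ":A:G"),
    gene = rep(cfg$genes, each = cfg$sites_per_gene),
    stringsAsFactors = FALSE)
  p <- ncol_sites <- nrow(site_gene)
  maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  names(maf) <- site_gene$site
  geno <- vapply(maf, function(m) stats::rbinom(n, 2L, m), integer(n))
  rownames(geno) <- paste0("sample", seq_len(n))
  depth <- matrix(stats::rnbinom(n * p, mu = cfg$depth_mean,
                                 size = cfg$depth_size), nrow = n)
  alt_frac <- matrix(c(cfg$error_rate, 0.5, 1 - cfg$error_rate)[geno + 1L],
                     nrow = n)
  alt <- matrix(stats::rbinom(n * p, as.vector(depth),
                              as.vector(alt_frac)), nrow = n)
  mq <- matrix(stats::rnorm(n * p, cfg$mq_mean, cfg$mq_sd), nrow = n)
  low <- matrix(stats::runif(n * p) < cfg$low_mq_rate, nrow = n)
  mq[low] <- stats::runif(sum(low), 0, 29)
  pileups <- data.frame(
    sample_id = rep(rownames(geno), times = p),
    site = rep(site_gene$site, each = n),
    ref_depth = as.vector(depth - alt),
    alt_depth = as.vector(alt),
    mapping_quality = round(as.vector(mq), 2),
    stringsAsFactors = FALSE)
  list(genotypes = geno, pileups = pileups, site_gene = site_gene,
       maf = maf)
}

#' Simulate signature activities from the generating regression model
#'
#' The causal signature's activity is the linear predictor
#' `b0 + b1*z(burden) + b2*status + b3*gender + b4*z(age) + b5*(stage - mean)`
#' plus Gaussian noise, with the burden and age standardized so effect
#' sizes are per standard deviation. With `bound = "none"` (default) the
#' raw Gaussian response is returned — exactly the regression model's
#' assumption, so coefficient recovery is unbiased. With
#' `bound = "simplex"` the causal activity is clipped to \[0, 1\] and the
#' remaining signatures share the complement by Dirichlet proportions,
#' yielding valid exposure rows for catalog generation (clipping slightly
#' attenuates effects near the boundary).
#'
#' @param cfg A [sim_config()].
#' @param burdens Numeric burden vector for the causal gene.
#' @param statuses 0/1 somatic-status vector for the causal gene.
#' @param covariates Data frame with `gender`, `age`, `stage`.
#' @param seed Seed.
#' @param bound `"none"` or `"simplex"` (see above).
#' @return List with `activities` (samples x K matrix; the causal column is
#'   the modeled response), `beta` (the generating coefficients), `linear`
#'   (the noiseless predictor), `n_clipped`.
#' @export
simulate_activities <- function(cfg, burdens, statuses, covariates,
                                seed = cfg$seed,
                                bound = c("none", "simplex")) {
  bound <- match.arg(bound)
  if (cfg$sigma <= 0) stop("sigma must be > 0")
  n <- length(burdens)
  stopifnot(length(statuses) == n, nrow(covariates) == n)
  set.seed(seed)
  b <- cfg$beta
  zb <- standardize(burdens)
  za <- standardize(covariates$age)
  zs <- covariates$stage - mean(covariates$stage, na.rm = TRUE)
  linear <- b["b0"] + b["b1"] * zb + b["b2"] * statuses +
    b["b3"] * covariates$gender + b["b4"] * za + b["b5"] * zs
  causal <- linear + stats::rnorm(n, 0, cfg$sigma)
  n_clipped <- 0L
  act <- matrix(NA_real_, n, cfg$K,
                dimnames = list(names(burdens), names(cfg$signatures)))
  if (bound == "simplex") {
    clipped <- pmin(pmax(causal, 0), 1)
    n_clipped <- sum(clipped != causal)
    causal <- clipped
    share <- matrix(stats::rgamma(n * (cfg$K - 1L), shape = 1), nrow = n)
    share <- share / rowSums(share)
    act[, cfg$causal_signature] <- causal
    act[, -cfg$causal_signature] <- (1 - causal) * share
  } else {
    base <- (1 - mean(causal)) / max(cfg$K - 1L, 1L)
    act[, cfg$causal_signature] <- causal
    act[, -cfg$causal_signature] <- base
  }
  list(activities = act, beta = b, linear = linear,
       predictors = data.frame(burden = zb, status = statuses,
                               gender = covariates$gender, age = za,
                               stage = zs),
       n_clipped = n_clipped)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Simulate a clinical covariate table
#' @param cfg A [sim_config()].
#' @param seed Seed.
#' @return Data frame with `sample_id`, `age`, `gender`, `stage`,
#'   `smoking`, `alcohol`.
#' @export
simulate_clinical <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$n_samples
  data.frame(
    sample_id = paste0("sample", seq_len(n)),
    age = round(stats::rnorm(n, 60, 9)),
    gender = stats::rbinom(n, 1L, 0.5),
    stage = sample(1:4, n, replace = TRUE,
                   prob = c(0.10, 0.35, 0.40, 0.15)),
    smoking = stats::rbinom(n, 1L, 0.34),
    alcohol = stats::rbinom(n, 1L, 0.30),
    stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort with planted truth
#'
#' Chains the generators: germline genotypes and pileups; clinical
#' covariates; somatic statuses (Bernoulli per gene); burden scores from the
#' true genotypes; signature activities from the regression model with the
#' planted effects on the causal gene/signature; a mutation catalog whose
#' exposures are the simplex-projected activities; a MAF-like mutation
#' record table consistent with the catalog and statuses; and gene-level
#' copy-number ratios. All generating parameters are returned as `truth`.
#'
#' @param cfg A [sim_config()].
#' @param seed Base seed (sub-generators use fixed offsets).
#' @param dir Optional directory: when given, writes `mutations.maf.tsv`,
#'   `pileups.tsv`, `catalog.tsv`, `cn.tsv`, `clinical.tsv` and
#'   `truth.json` (the latter if the jsonlite package is available).
#' @return List with all simulated components and `truth`.
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed, dir = NULL) {
  germ <- simulate_genotypes_and_pileups(cfg, seed = seed)
  clinical <- simulate_clinical(cfg, seed = seed + 1L)
  set.seed(seed + 2L)
  samples <- paste0("sample", seq_len(cfg$n_samples))
  somatic <- vapply(cfg$genes, function(g)
    stats::rbinom(cfg$n_samples, 1L, cfg$somatic_rate),
    integer(cfg$n_samples))
  rownames(somatic) <- samples
  info <- site_info(germ$genotypes)
  burdens <- burden_matrix(germ$genotypes, info, germ$site_gene, cfg$genes)
  acts <- simulate_activities(cfg, burdens[, cfg$causal_gene],
                              somatic[, cfg$causal_gene], clinical,
                              seed = seed + 3L, bound = "simplex")
  cat_sim <- simulate_catalog(cfg, seed = seed + 4L,
                              exposures = acts$activities)
  set.seed(seed + 5L)
  records <- records_from_catalog(cat_sim$catalog, somatic)
  cn <- matrix(stats::rnorm(cfg$n_samples * length(cfg$genes), 0, 0.35),
               nrow = cfg$n_samples,
               dimnames = list(samples, cfg$genes))
  truth <- list(seed = seed, beta = as.list(cfg$beta), sigma = cfg$sigma,
                causal_gene = cfg$causal_gene,
                causal_signature = cfg$causal_signature,
                maf = as.list(germ$maf),
                exposure_rows_clipped = acts$n_clipped)
  out <- list(catalog = cat_sim$catalog, records = records,
              exposures_true = acts$activities,
              spectra_true = cat_sim$spectra,
              activities = acts, genotypes_true = germ$genotypes,
              pileups = germ$pileups, site_gene = germ$site_gene,
              site_info = info, burdens = burdens, somatic = somatic,
              cn_ratios = cn, clinical = clinical, truth = truth)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

# Expand a catalog back into MAF-like mutation records, adding
# non-synonymous records consistent with the somatic status matrix.
records_from_catalog <- function(catalog, somatic) {
  labs <- colnames(catalog)
  rows <- list()
  pos <- 0L
  for (i in seq_len(nrow(catalog))) {
    counts <- catalog[i, ]
    idx <- rep(seq_along(labs), counts)
    if (length(idx)) {
      lab <- labs[idx]
      pos_i <- pos + seq_along(idx)
      rows[[length(rows) + 1L]] <- data.frame(
        Hugo_Symbol = "UNASSIGNED",
        Tumor_Sample_Barcode = rownames(catalog)[i],
        Chromosome = "chr1", Start_Position = pos_i,
        Reference_Allele = substr(lab, 3, 3),
        Tumor_Seq_Allele2 = substr(lab, 5, 5),
        Variant_Type = "SNP", Variant_Classification = "Silent",
        Context_5 = substr(lab, 1, 1), Context_3 = substr(lab, 7, 7),
        stringsAsFactors = FALSE)
      pos <- pos + length(idx)
    }
  }
  mut <- do.call(rbind, rows)
  hits <- which(somatic == 1L, arr.ind = TRUE)
  if (nrow(hits)) {
    extra <- data.frame(
      Hugo_Symbol = colnames(somatic)[hits[, 2]],
      Tumor_Sample_Barcode = rownames(somatic)[hits[, 1]],
      Chromosome = "chr2", Start_Position = seq_len(nrow(hits)),
      Reference_Allele = "C", Tumor_Seq_Allele2 = "T",
      Variant_Type = "SNP", Variant_Classification = "Missense_Mutation",
      Context_5 = "A", Context_3 = "G", stringsAsFactors = FALSE)
    mut <- rbind(mut, extra)
  }
  mut
}

write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(cohort$records, "mutations.maf.tsv")
  tsv(cohort$pileups, "pileups.tsv")
  write_catalog(cohort$catalog, file.path(dir, "catalog.tsv"))
  cn_long <- data.frame(
    gene = rep(colnames(cohort$cn_ratios), each = nrow(cohort$cn_ratios)),
    sample_id = rep(rownames(cohort$cn_ratios), ncol(cohort$cn_ratios)),
    log2_ratio = as.vector(cohort$cn_ratios), stringsAsFactors = FALSE)
  tsv(cn_long, "cn.tsv")
  tsv(cohort$clinical, "clinical.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
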