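# sigburden

Linking germline variation and somatic gene status to somatic
mutational-signature activities in tumour cohorts.

## The problem

Somatic mutations in a tumour exome are the footprint of mutational
processes — CpG deamination, APOBEC cytidine-deaminase activity,
exposure-driven damage — each leaving a characteristic distribution over
the 96 trinucleotide substitution channels (6 pyrimidine-centered
substitution classes × 16 flanking-base combinations). A recurring
question in cancer genomics is *what modulates these processes*: does a
patient's germline variation in a gene, or a somatic hit to it, shift the
activity of a mutational process in their tumour?

`sigburden` implements that analysis chain end to end for cohorts with
paired somatic and germline exome calls:

1. **Catalogs** — per-sample 96-channel mutation catalogs from MAF-like
   tables, six-class substitution frequencies, per-gene somatic statuses.
2. **Signature model** — a mixed-membership probabilistic model fitted by
   EM: sample $i$'s mutations are a mixture over $K$ signatures with
   exposures $q_{ik}$ (its relative activities), each signature a
   distribution over channels, either factorized into independent
   substitution-class and flanking-base categoricals (default) or a free
   96-channel multinomial. Fitted signatures are matched to a reference
   set (COSMIC v2 layout) by cosine similarity.
3. **Subtypes** — Ward-linkage hierarchical clustering of activity
   profiles, with chi-squared / ANOVA enrichment tests and BH FDR.
4. **Germline** — genotype calls from pileup summaries by
   alternate-allele coverage rate (ACR) rules with depth and
   mapping-quality filters; per-site minor-allele frequencies and weights
   $W_j = 1/\sqrt{\mathrm{MAF}_j(1-\mathrm{MAF}_j)}$; per-gene burden
   scores $G_i = \sum_j W_j g_{ij}$; ancestry principal components.
5. **Association** — for each gene and each proxy of the mutational
   processes (total SNV count, signature activities, six-class
   frequencies): Wilcoxon rank-sum tests on somatic and copy-number
   status, a weighted-kernel (SKAT-style) variance-component score test
   on the germline variant set with covariate adjustment, and the
   multivariate regression
   $\mathrm{Sig}_{ki} \sim \beta_0 + \beta_1 G_{li} + \beta_2 S_{li} +
   \beta_3\,\mathrm{gender}_i + \beta_4\,\mathrm{age}_i +
   \beta_5\,\mathrm{stage}_i + \varepsilon_{kli}$,
   with Benjamini–Hochberg FDR within declared families.
6. **Synthetic cohorts** — a fully parameterized generator with planted
   truth (known signatures, exposures, Hardy–Weinberg genotypes, pileups,
   regression effects) so every stage is testable without external data.

See the methods vignette (`vignettes/signature-burden-methods.Rmd`) for
the model details and design decisions.

## Worked example

Simulate a cohort with a planted effect — germline burden in `GENE1`
drives the first signature's activity — then run the pipeline blind and
see whether it recovers the truth:

```r
library(sigburden)

cfg <- sim_config(n_samples = 150, signatures = default_signatures(3),
                  mutations_per_sample = 120, seed = 7)
cohort <- simulate_cohort(cfg)

fit <- fit_signature_model(cohort$catalog, K = 3, n_restarts = 5, seed = 7)
fit
#> Mutational-signature model fit (independent mode)
#>   K = 3 signatures, 150 samples, 17,929 mutations
#>   log-likelihood: -56290.07  BIC: 115841.6
#>   converged: TRUE in 97 iterations

match_to_reference(fit, cohort$spectra_true)
#> Signature-to-reference cosine similarity (3 fitted x 3 reference)
#>
#> Best matches:
#>   fitted reference cosine   tie
#> 1     S1     npcpg 0.9998 FALSE
#> 2     S2 apobec_cg 0.9995 FALSE
#> 3     S3 apobec_ct 0.9988 FALSE

cluster_activities(fit$exposures, k = 3)
#> Subtype assignment: k = 3 subtypes, 150 samples
#> subtype
#>  1  2  3
#> 46 71 33

res <- run_association_suite(cohort$catalog, fit$exposures,
                             cohort$genotypes_true, cohort$site_gene,
                             cohort$somatic, NULL, cohort$clinical,
                             cfg$genes)
top <- res[res$test == "skat_burden", ]
head(top[order(top$p), c("gene", "proxy", "test", "n", "p", "fdr")], 3)
#>     gene proxy        test   n        p      fdr
#> 6  GENE1    S1 skat_burden 150 7.31e-17 1.10e-15
#> 14 GENE1    S3 skat_burden 150 8.25e-07 6.18e-06
#> 26 GENE1   C>T skat_burden 150 2.05e-05 6.14e-04
```

Each fitted signature matches its generating signature at cosine
similarity > 0.998, and the kernel burden test ranks the causal
(gene, signature) pair first by some ten orders of magnitude — the
planted effect is recovered. (The echoes on `S3` and the `C>T` frequency
are expected: the causal signature is C>T-dominated, so its activity
leaks into correlated proxies.)

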