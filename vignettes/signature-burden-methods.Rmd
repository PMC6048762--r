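---
title: "Methods: mutational-signature activities and germline burden association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational-signature activities and germline burden association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigburden)
```

# Scope

`sigburden` implements a complete analysis chain for tumour cohorts with
paired somatic and germline exome calls: build per-sample mutation catalogs
over the 96 trinucleotide substitution channels, extract mutational
signatures and their per-sample activities with a probabilistic
mixed-membership model, cluster samples into activity subtypes, call
germline genotypes from pileup summaries, score per-gene germline burden,
and test somatic status, copy-number status and germline burden against
proxies of the mutational processes. Upstream steps (alignment, variant
calling, annotation, copy-number segmentation) are out of scope: the
pipeline starts from variant tables and gene-level summaries.

# Mutation catalogs

Every single-nucleotide variant is mapped to one of 96 channels
`c5[ref>alt]c3`, pyrimidine-centered: when the reference allele is a purine
the substitution and both flanks are reverse-complemented first, so the two
strand representations of a mutation coincide. Flanking bases are taken
from input columns rather than fetched from a reference genome; this keeps
the package download-free, at the cost of trusting the caller's context
annotation. Records with ambiguous bases (N) are excluded from the catalog
and counted in a QC attribute — the alternative, guessing a context, would
silently distort channel frequencies. Insertions and deletions never enter
the catalog but do count toward per-gene somatic status.

# The signature model

Let $x_{ic}$ be the count of mutations of sample $i$ in channel $c$, and
let $q_{ik}$ (exposures, rows on the simplex) and $p_{kc}$ (signature
spectra) parameterize a mixture: each mutation of sample $i$ draws a
signature $k \sim q_{i\cdot}$ and then a channel $c \sim p_{k\cdot}$, so

$$\log L = \sum_{i,c} x_{ic} \log \sum_k q_{ik}\, p_{kc}.$$

Two parameterizations of $p_{k\cdot}$ are available:

* **independent** (default): the channel probability factorizes into a
  6-category substitution-class distribution times a 4-category
  distribution per flanking base,
  $p_{kc} = \phi_k(\mathrm{class}) \cdot \psi^{5'}_k(b_5) \cdot
  \psi^{3'}_k(b_3)$. With 11 free parameters per signature instead of 95
  this is far better determined at cohort-scale mutation counts, and it is
  the parameterization under which the package's default simulated
  signatures are defined.
* **full96**: an unconstrained multinomial per signature, useful as a
  robustness check and for the label-permutation invariance property
  (the factorized model is, by construction, not invariant to arbitrary
  channel permutations).

Estimation is plain EM. The E-step computes per-(sample, channel)
responsibilities over signatures; the M-step re-estimates exposures and
categorical parameters from responsibility-weighted counts. The
implementation works with the $n \times 96$ count matrix throughout (three
matrix products per iteration), guards denominators at `1e-300`, and
asserts at every iteration that the log-likelihood did not decrease — a
violated assertion is a bug, not a warning. Defaults: 20 random restarts
(Dirichlet(1) initialization, restart $r$ seeded `seed + r - 1`),
convergence at relative log-likelihood change `1e-6`, at most 2000
iterations. The number of signatures $K$ is user-set; log-likelihood and a
BIC (penalizing $11K$ or $95K$ signature parameters plus $n(K-1)$ exposure
parameters) are reported, but no automatic selection is attempted — with
mixed-membership models the effective sample size per parameter is
ambiguous enough that a fixed, declared $K$ is the honest interface.

Only single-base flanks (96 channels) are supported. The catalog container
is 96-channel; wider contexts would require an extended catalog and an
explicit marginalization path, neither of which earns its complexity here.

Fitted signatures are compared to a reference set (COSMIC v2 layout TSV)
by cosine similarity of the 96-channel vectors, with full similarity
matrices reported and argmax assignments; ties break toward the lowest
reference index and are flagged.

# Activity subtypes

Samples are clustered on their exposure rows — raw relative activities,
not standardized: the rows already live on the simplex and share units —
with Ward's linkage on Euclidean distances, cut at a user-chosen $k$
(default 3 in the examples). Dendrogram label order is arbitrary, so
subtype labels are renumbered by the index of each cluster's
dominant-mean signature, making "subtype 1" reproducible across runs and
sample orders. Enrichment of clinical or molecular features across
subtypes uses a chi-squared test for categorical features (Fisher's exact
test behind a flag for sparse tables, with a low-expected-count flag
either way) and one-way ANOVA for quantitative ones, with
Benjamini–Hochberg FDR computed jointly across whatever feature family the
caller supplies.

# Germline genotyping and burden

Genotypes are called from per-site allele depths by fixed
alternate-allele-coverage-rate (ACR) rules after site filters: mapping
quality $\ge 30$, alternate depth $\ge 5$, total depth $\ge 20$. Then
ACR $\le 0.1$ is homozygous reference, $0.2 \le \mathrm{ACR} \le 0.8$
heterozygous, ACR $\ge 0.9$ homozygous alternate. The rules leave the
intervals $(0.1, 0.2)$ and $(0.8, 0.9)$ uncovered; such calls are set
missing rather than rounded to the nearest rule — conservative, and
visible in missingness QC. A practical consequence of the alternate-depth
filter worth stating explicitly: a homozygous-reference sample can only be
called when depth times the sequencing error rate comfortably exceeds 5,
so at routine exome depth most hom-ref records are no-calls under these
rules.

Sites with more than 50% missing calls are dropped; the minor allele
frequency is computed within the analysis cohort over non-missing calls
and folded at 0.5; monomorphic sites are excluded. The per-site weight is
$W_j = 1/\sqrt{\mathrm{MAF}_j(1-\mathrm{MAF}_j)}$ — strictly decreasing in
MAF, so rare alleles weigh more — and the per-gene burden is the weighted
dosage sum $G_i = \sum_j W_j\, g_{ij}$. Missing dosages are imputed at the
site mean $2\cdot\mathrm{MAF}$ by default so that samples with unequal
coverage remain comparable; a skip-site-per-sample alternative is a flag.
Ancestry covariates are the top principal components of the mean-imputed,
column-centered dosage matrix, with each component's sign fixed by its
largest-magnitude loading.

# Association suite

Proxies of the mutational processes are: total SNV count, each signature's
activity, and the six substitution-class frequencies. For each gene of
interest the suite runs:

* **Wilcoxon rank-sum** of each proxy between somatic-status groups, and
  between copy-number-altered (amplification, separately deletion) and
  other samples. The exact null is enumerated when both groups have at
  most 10 observations and no ties; otherwise the normal approximation
  with continuity and tie corrections is used. The convention is stated
  because p-values near significance thresholds can differ between the
  two.
* **Weighted-kernel score test** of the gene's variant set against the
  proxy, adjusting for age, stage, and the first two ancestry PCs. The
  null model is a linear regression on the covariates; the statistic is
  $Q = r' G W W G' r$ with null residuals $r$, and its null law is the
  eigenvalue-weighted mixture of $\chi^2_1$ variables given by the
  spectrum of $W G' (I - H) G W$ scaled by the residual variance. The
  default p-value moment-matches a scaled chi-squared (Satterthwaite);
  `method = "davies"` evaluates the exact mixture by Imhof numerical
  inversion. Because the characteristic-function integrand oscillates
  with period $4\pi/q$ and decays only algebraically, the inversion
  integrates piecewise over half-periods and Euler-accelerates the
  alternating tail, which reaches machine precision where a single
  adaptive pass stalls at about `1e-4`. The per-site weights default to
  the same $W_j$ as the burden score, keeping the two burden views
  internally consistent; conventional Beta-density weights can be passed
  instead since weights are an explicit argument.
* **Multivariate regression** of the proxy on burden, somatic status,
  gender, age and ordinal stage (I–IV as 1–4; unknown stage rows dropped
  and counted), by OLS with per-coefficient t-tests. The burden and
  somatic-status coefficients are emitted as separate result rows. Note
  the two covariate sets deliberately differ: the kernel test adjusts for
  age/stage/ancestry-PCs, the regression for gender/age/stage — each test
  mirrors its own declared design rather than forcing one shared set.
* **FDR**: Benjamini–Hochberg within each (test type × proxy family)
  family. "FDR" without a named procedure conventionally means BH; the
  family labels are carried in the output so the adjustment scope is
  auditable, and subgroup analyses run through a sample-subset argument
  rather than a separate code path.

Copy-number status is classified from gene-level log2 ratios: strictly
above 0.5 amplification, strictly below −0.5 deletion, boundaries neutral
(the thresholds are worded as strict inequalities, so ±0.5 exactly is
neutral). Segmentation and peak-significance analysis are out of scope;
the module consumes gene-level ratios.

# The synthetic-data generator

`sim_config()` fixes the study conditions; every generator is a pure
function of (config, seed). Defaults emulate a ~300-sample squamous-cell
exome cohort: 302 samples, Poisson mean 46 SNVs per sample (cohort-scale
exome burden), four built-in independent-context signatures (a
CpG-deamination-like C>T-at-NpCpG signature, two APOBEC-like signatures,
and a broad background — constructed for simulation, not copied from any
reference catalog), Dirichlet(1) exposures, 50 germline sites in 5 genes
with MAF uniform on (0.05, 0.5] under Hardy–Weinberg equilibrium,
negative-binomial depth around 60×, Gaussian mapping quality around 60
with a 2% low-MQ contamination rate, 30% somatic-status rate, age
N(60, 9), balanced gender, stage marginals (10/35/40/15)%.

Activities are generated from the linear model the regression estimates:
$\mathrm{Sig}_{i} = \beta_0 + \beta_1 z(G_i) + \beta_2 S_i + \beta_3
\mathrm{gender}_i + \beta_4 z(\mathrm{age}_i) + \beta_5
\widetilde{\mathrm{stage}}_i + \varepsilon_i$, with burden and age
standardized so the planted effects ($\beta_1 = 0.3$, $\beta_2 = 0.2$,
$\sigma = 0.1$ by default) are per-SD. Two output modes exist, and the
distinction is a deliberate design decision:

* `bound = "none"` (default) returns the raw Gaussian response — exactly
  the model the regression assumes, so coefficient recovery is unbiased
  by construction. At the default effect sizes roughly a tenth of samples
  would fall outside $[0,1]$ if the response were read as a proportion;
  clipping them would censor the response and attenuate the recovered
  slope by several hundredths, which is precisely the bias the recovery
  tests must be able to rule out in the estimator itself.
* `bound = "simplex"` is for feeding the catalog generator: the causal
  activity is clipped to $[0,1]$ (clips counted and reported) and the
  remaining signatures share the complement via Dirichlet proportions, so
  rows sum to exactly 1 without a global renormalization — a global
  renormalization would divide the causal activity by a sum that
  co-varies with it and attenuate the planted effect by roughly the
  complement of its mean share.

What the generator does **not** emulate: linkage disequilibrium between
sites (sites are independent), sequencing error that varies along the
read, subclonal copy-number mixtures, and any coupling between somatic
status and burden (they are generated independently unless the user wires
them together). Passing recovery tests on these cohorts therefore shows
the estimators are correct under their own assumptions, not that real
cohorts satisfy those assumptions.

# Numerical choices and problem sizes

Responsibility and likelihood computations guard denominators at
`1e-300`; EM monotonicity is asserted in-loop with relative slack
`1e-8`. Ties in reference matching break to the lowest reference index
and are flagged. The chi-squared test runs without continuity correction
(the ANOVA/chi-squared pairing treats both as asymptotic tests); expected
cells below 5 raise a flag rather than an error. PCA uses one SVD of the
centered matrix rather than an eigendecomposition of the covariance, for
stability at many sites.

The shipped test and acceptance workloads use: signature recovery at
$K=3$, 300 samples × 500 mutations over 20 replicates; kernel-test
calibration over 1000 null simulations at $n=200$, 10 sites; coefficient
recovery over 200 replicates at $n=500$; exhaustive genotype-rule grids;
and planted-effect detection over 10 cohorts of 200 samples. These sizes
were chosen to make Monte-Carlo error small relative to the assertion
margins while keeping a full run in the low tens of seconds on one core.

# Known limitations

* Contexts come from input annotation; no reference-genome validation.
* Only 96-channel (single-flank) catalogs; no wider-context fitting.
* The kernel test's Satterthwaite tail is approximate far in the tail;
  the Imhof path is exact but slower, and neither implements Davies'
  error-bounded algorithm proper.
* Cohort-internal MAF and PCA: no external reference panel projection.
* The signature model assumes independent mutations given the signature;
  clustered mutational processes (kataegis) violate this.
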