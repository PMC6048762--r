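# Build a minimal mutation-record data frame from compact arguments.
make_records <- function(sample_id, ref, alt, c5, c3,
                         variant_type = "SNV", variant_class = "other",
                         gene = "GENEX") {
  n <- length(sample_id)
  data.frame(sample_id = sample_id, chrom = rep_len("chr1", n),
             pos = seq_len(n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             context5 = rep_len(c5, n), context3 = rep_len(c3, n),
             variant_type = rep_len(variant_type, n),
             variant_class = rep_len(variant_class, n),
             gene = rep_len(gene, n), stringsAsFactors = FALSE)
}

rc <- c(A = "T", C = "G", G = "C", T = "A")

# Dirichlet(1) rows, for toy exposure/spectra fixtures.
runif_simplex <- function(n, d) {
  m <- matrix(rexp(n * d), nrow = n)
  m / rowSums(m)
}

# Two disjoint-support 96-channel signatures (first / second 48 channels).
disjoint_spectra <- function() {
  labs <- sigburden::channel_labels()
  P <- rbind(c(rep(1 / 48, 48), rep(0, 48)),
             c(rep(0, 48), rep(1 / 48, 48)))
  colnames(P) <- labs
  rownames(P) <- c("first_half", "second_half")
  P
}

# Sample a catalog from fixed spectra and exposures.
sample_catalog <- function(exposures, spectra, m_per_sample, seed) {
  set.seed(seed)
  probs <- exposures %*% spectra
  X <- t(vapply(seq_len(nrow(probs)), function(i)
    as.integer(rmultinom(1, m_per_sample, probs[i, ])), integer(96L)))
  dimnames(X) <- list(paste0("s", seq_len(nrow(probs))),
                      colnames(spectra))
  X
}
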