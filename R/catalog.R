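BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 pyrimidine-centered substitution-context channel labels
#'
#' Channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' flanking base (A, C, G, T), then 3' flanking base, matching the
#' conventional COSMIC v2 layout once rows are sorted by class and
#' trinucleotide.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
channel_labels <- function() {
  unlist(lapply(SUB_CLASSES, function(cl) {
    unlist(lapply(BASES, function(b5) paste0(b5, "[", cl, "]", BASES)))
  }))
}

# Decompose channel labels into (class, 5' base, 3' base) index triples.
# Used by the independent-context signature model.
channel_structure <- function() {
  labs <- channel_labels()
  data.frame(
    channel = labs,
    class = substr(labs, 3, 5),
    base5 = substr(labs, 1, 1),
    base3 = substr(labs, 7, 7),
    class_idx = rep(seq_along(SUB_CLASSES), each = 16L),
    base5_idx = rep(rep(1:4, each = 4L), times = 6L),
    base3_idx = rep(1:4, times = 24L),
    stringsAsFactors = FALSE
  )
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-base substitution into one of the 96 channels
#'
#' Substitutions are reported pyrimidine-centered: when the reference allele
#' is a purine (A or G), the reference, alternate and both flanking bases are
#' reverse-complemented before labeling, so a mutation and its
#' opposite-strand representation map to the same channel.
#'
#' @param ref,alt Reference and alternate alleles (single bases). Vectorized.
#' @param c5,c3 5' and 3' flanking bases on the reference strand.
#' @return Character vector of channel labels (`"c5[ref>alt]c3"` after
#'   strand normalization); `NA` where any base is not in A/C/G/T (such
#'   records are unclassifiable and excluded from catalogs).
#' @examples
#' classify_substitution("C", "T", "A", "G")  # "A[C>T]G"
#' classify_substitution("G", "A", "C", "T")  # same channel, other strand
#' @export
classify_substitution <- function(ref, alt, c5, c3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(c5) == n, length(c3) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  c5 <- toupper(c5); c3 <- toupper(c3)
  ok <- ref %in% BASES & alt %in% BASES & c5 %in% BASES & c3 %in% BASES &
    ref != alt
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; f5 <- c5[ok]; f3 <- c3[ok]
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    # reverse complement swaps the flanks as well as complementing them
    tmp5 <- f5[pur]
    f5[pur] <- REV_COMP[f3[pur]]
    f3[pur] <- REV_COMP[tmp5]
    r[pur] <- REV_COMP[r[pur]]
    a[pur] <- REV_COMP[a[pur]]
  }
  out[ok] <- paste0(f5, "[", r, ">", a, "]", f3)
  out
}

#' Map a channel label to its six-class substitution bucket
#' @param channel Character vector of channel labels.
#' @return Character vector among `"C>A"`, ..., `"T>G"`.
#' @export
channel_class <- function(channel) substr(channel, 3, 5)

new_mutation_records <- function(df) {
  required <- c("sample_id", "ref", "alt", "context5", "context3",
                "variant_type", "variant_class", "gene")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("mutation records lack columns: ", paste(missing, collapse = ", "))
  df
}

#' Build a per-sample 96-channel mutation catalog
#'
#' Only SNV records contribute; insertions/deletions are retained elsewhere
#' (for somatic status and total-burden tallies) but never enter the
#' 96-channel catalog. SNVs whose reference, alternate or flanking bases are
#' ambiguous (e.g. N) are excluded and counted in the `n_unclassifiable`
#' attribute.
#'
#' @param records Data frame of mutation records, as returned by
#'   [read_maf()]: columns `sample_id`, `ref`, `alt`, `context5`, `context3`,
#'   `variant_type`, `variant_class`, `gene`.
#' @param samples Character vector of sample ids defining the catalog rows
#'   (samples with no mutations get all-zero rows). Every record's
#'   `sample_id` must appear here; unknown ids are an error, never silently
#'   dropped.
#' @return Integer matrix of class `"mutation_catalog"`, samples x 96, with
#'   attributes `n_unclassifiable` (excluded SNVs) and `n_indel`.
#' @export
build_catalog <- function(records, samples) {
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  records <- new_mutation_records(records)
  unknown <- setdiff(unique(records$sample_id), samples)
  if (length(unknown))
    stop("records reference samples not in 'samples': ",
         paste(utils::head(unknown, 5), collapse = ", "))
  labs <- channel_labels()
  counts <- matrix(0L, nrow = length(samples), ncol = 96L,
                   dimnames = list(samples, labs))
  is_snv <- records$variant_type == "SNV"
  snv <- records[is_snv, , drop = FALSE]
  ch <- classify_substitution(snv$ref, snv$alt, snv$context5, snv$context3)
  keep <- !is.na(ch)
  if (any(keep)) {
    tab <- table(factor(snv$sample_id[keep], levels = samples),
                 factor(ch[keep], levels = labs))
    counts[] <- counts + as.integer(tab)
  }
  structure(counts, class = c("mutation_catalog", class(counts)),
            n_unclassifiable = sum(!keep), n_indel = sum(!is_snv))
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("Mutation catalog:", nrow(x), "samples x 96 channels,",
      sum(x), "SNVs", "\n")
  if (isTRUE(attr(x, "n_unclassifiable") > 0))
    cat("  unclassifiable SNVs excluded:", attr(x, "n_unclassifiable"), "\n")
  invisible(x)
}

#' Six-class substitution frequencies per sample and cohort totals
#'
#' @param catalog A `mutation_catalog` (or any samples x 96 count matrix with
#'   channel-label column names).
#' @return List with `frequencies` (samples x 6 matrix; rows sum to 1, all-NA
#'   for zero-mutation samples), `counts` (samples x 6), and `cohort_totals`
#'   (named 6-vector summed over samples).
#' @export
substitution_frequencies <- function(catalog) {
  stopifnot(ncol(catalog) == 96L)
  cls <- channel_class(colnames(catalog))
  counts6 <- sapply(SUB_CLASSES, function(cl)
    rowSums(catalog[, cls == cl, drop = FALSE]))
  counts6 <- matrix(counts6, nrow = nrow(catalog),
                    dimnames = list(rownames(catalog), SUB_CLASSES))
  tot <- rowSums(counts6)
  freq <- counts6 / tot  # zero-mutation rows become NaN -> NA
  freq[tot == 0, ] <- NA_real_
  list(frequencies = freq, counts = counts6, cohort_totals = colSums(counts6))
}

#' Per-gene somatic mutation status
#'
#' A sample's status for a gene is 1 if it carries at least one
#' non-synonymous somatic mutation in that gene (SNV or indel), else 0.
#' Synonymous or other-class records never set the status.
#'
#' @param records Mutation record data frame with `variant_class` and `gene`.
#' @param gene Gene symbol.
#' @param samples Sample ids defining the output rows.
#' @return Data frame with `sample_id`, `n_nonsyn`, `status`.
#' @export
somatic_status <- function(records, gene, samples) {
  records <- new_mutation_records(records)
  hit <- records$gene == gene & records$variant_class == "non-synonymous"
  if (!any(records$gene == gene, na.rm = TRUE))
    message("gene '", gene, "' absent from all records; statuses all zero")
  n <- table(factor(records$sample_id[which(hit)], levels = samples))
  data.frame(sample_id = samples,
             n_nonsyn = as.integer(n),
             status = as.integer(n > 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Somatic status matrix for several genes
#'
#' @param records Mutation record data frame.
#' @param genes Character vector of gene symbols.
#' @param samples Sample ids.
#' @return Integer samples x genes 0/1 matrix.
#' @export
somatic_status_matrix <- function(records, genes, samples) {
  m <- vapply(genes, function(g)
    suppressMessages(somatic_status(records, g, samples)$status),
    integer(length(samples)))
  matrix(m, nrow = length(samples), dimnames = list(samples, genes))
}
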