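# Mapping from common MAF Variant_Classification strings to the three
# classes the pipeline distinguishes. Anything not listed maps to "other".
MAF_CLASS_MAP <- c(
  Missense_Mutation        = "non-synonymous",
  Nonsense_Mutation        = "non-synonymous",
  Nonstop_Mutation         = "non-synonymous",
  Splice_Site              = "non-synonymous",
  Translation_Start_Site   = "non-synonymous",
  Frame_Shift_Del          = "non-synonymous",
  Frame_Shift_Ins          = "non-synonymous",
  In_Frame_Del             = "non-synonymous",
  In_Frame_Ins             = "non-synonymous",
  Silent                   = "synonymous",
  Synonymous               = "synonymous"
)

#' Read a MAF-like somatic mutation table
#'
#' Required columns: `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Type`,
#' `Variant_Classification`, `Hugo_Symbol`, and flanking context as either
#' `Context_5`/`Context_3` columns or a `ref_context` string (odd length,
#' variant base centered). `Variant_Type` values `SNP`/`SNV` are treated as
#' SNV, `INS`/`DEL` as insertion/deletion. Multi-allelic rows must already
#' be split (one alternate allele per row).
#'
#' @param path Path to a tab-separated file.
#' @return Data frame of mutation records with normalized columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `context5`, `context3`,
#'   `variant_type`, `variant_class`, `gene`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  required <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Type",
                "Variant_Classification", "Hugo_Symbol")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("MAF file lacks columns: ", paste(missing, collapse = ", "))
  if (all(c("Context_5", "Context_3") %in% names(df))) {
    c5 <- df$Context_5; c3 <- df$Context_3
  } else if ("ref_context" %in% names(df)) {
    ctx <- toupper(df$ref_context)
    mid <- (nchar(ctx) + 1L) %/% 2L
    c5 <- substr(ctx, mid - 1L, mid - 1L)
    c3 <- substr(ctx, mid + 1L, mid + 1L)
  } else {
    stop("MAF file needs Context_5/Context_3 columns or ref_context")
  }
  vt <- toupper(df$Variant_Type)
  variant_type <- ifelse(vt %in% c("SNP", "SNV"), "SNV",
                  ifelse(vt == "INS", "insertion",
                  ifelse(vt == "DEL", "deletion", "other")))
  vc <- unname(MAF_CLASS_MAP[df$Variant_Classification])
  vc[is.na(vc)] <- "other"
  data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
             chrom = as.character(df$Chromosome),
             pos = as.integer(df$Start_Position),
             ref = toupper(df$Reference_Allele),
             alt = toupper(df$Tumor_Seq_Allele2),
             context5 = toupper(c5), context3 = toupper(c3),
             variant_type = variant_type, variant_class = vc,
             gene = as.character(df$Hugo_Symbol),
             stringsAsFactors = FALSE)
}

#' Write / read a mutation catalog as TSV
#'
#' Layout: one row per sample, first column `sample_id`, then the 96 labeled
#' channel columns — the samples x channels layout common signature tools
#' exchange.
#'
#' @param catalog A `mutation_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(sample_id = rownames(catalog),
                   as.data.frame(unclass(catalog), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @param path Path to a catalog TSV.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  labs <- channel_labels()
  if (!setequal(colnames(m), labs))
    stop("catalog columns are not the 96 channel labels")
  m <- m[, labs, drop = FALSE]
  storage.mode(m) <- "integer"
  structure(m, class = c("mutation_catalog", class(m)))
}

#' Read a reference signature matrix in COSMIC v2 layout
#'
#' Expects 96 rows and columns `Substitution Type` (or `SubstitutionType`),
#' `Trinucleotide`, plus one numeric column per signature. Rows are
#' reordered to this package's channel order by label, so any row order is
#' accepted.
#'
#' @param path Path to the TSV.
#' @return Signatures x 96 numeric matrix, rows named by signature.
#' @export
read_reference_signatures <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  sub_col <- intersect(c("Substitution Type", "SubstitutionType",
                         "Substitution.Type"), names(df))[1]
  tri_col <- intersect(c("Trinucleotide", "trinucleotide"), names(df))[1]
  if (is.na(sub_col) || is.na(tri_col))
    stop("reference file lacks SubstitutionType/Trinucleotide columns")
  lab <- paste0(substr(df[[tri_col]], 1, 1), "[", df[[sub_col]], "]",
                substr(df[[tri_col]], 3, 3))
  labs <- channel_labels()
  if (!setequal(lab, labs))
    stop("reference channel labels do not form the 96-channel set")
  num <- vapply(df, is.numeric, logical(1))
  m <- t(as.matrix(df[match(labs, lab), num, drop = FALSE]))
  colnames(m) <- labs
  m
}

#' Read a pileup-summary table
#'
#' One row per (sample, site): columns `sample_id`, `site`
#' (`chrom:pos:ref:alt`), `ref_depth`, `alt_depth`, `mapping_quality`.
#'
#' @param path Path to the TSV.
#' @return Data frame of pileup records.
#' @export
read_pileups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "site", "ref_depth", "alt_depth",
                "mapping_quality")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("pileup file lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' Read a clinical covariate table
#'
#' Columns `sample_id`, `age`, `gender` (0/1 or F/M), `stage` (I--IV or
#' 1--4), and optionally `smoking`, `alcohol`. Stage is recoded to ordinal
#' integers 1--4; unknown stages become NA.
#'
#' @param path Path to the TSV.
#' @return Data frame with normalized `gender` (0/1) and `stage` (integer).
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "age", "gender", "stage"), names(df))
  if (length(missing))
    stop("clinical file lacks columns: ", paste(missing, collapse = ", "))
  g <- df$gender
  if (!is.numeric(g)) {
    g <- toupper(as.character(g))
    g <- ifelse(g %in% c("M", "MALE", "1"), 1L,
         ifelse(g %in% c("F", "FEMALE", "0"), 0L, NA_integer_))
  }
  df$gender <- as.integer(g)
  df$stage <- encode_stage(df$stage)
  df
}

encode_stage <- function(stage) {
  if (is.numeric(stage)) return(as.integer(stage))
  s <- toupper(trimws(as.character(stage)))
  roman <- c(I = 1L, II = 2L, III = 3L, IV = 4L)
  out <- roman[s]
  numeric_like <- is.na(out) & s %in% c("1", "2", "3", "4")
  out[numeric_like] <- as.integer(s[numeric_like])
  unname(out)
}

#' Read a gene-level log2 copy-number-ratio table
#'
#' Long layout: columns `gene`, `sample_id`, `log2_ratio`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_cn_ratios <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "sample_id", "log2_ratio"), names(df))
  if (length(missing))
    stop("copy-number file lacks columns: ", paste(missing, collapse = ", "))
  df
}
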