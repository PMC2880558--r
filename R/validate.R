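# Validators for the pipeline's domain containers.  Containers are plain R
# objects: an expression matrix is a numeric matrix with probe rownames and
# sample colnames; phenotypes, twin pairs and gene annotation are
# data.frames; a dosage matrix is a small S3 list (see dosage_matrix()).

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of normalized intensities
#' (arbitrary units, finite and non-negative) with unique probe identifiers
#' as rownames and unique sample identifiers as colnames.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe id: ", rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample id: ", colnames(x)[duplicated(colnames(x))][1L])
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  if (any(x < 0))
    stop("expression matrix contains negative values")
  invisible(x)
}

#' Validate a phenotype table
#'
#' Required columns: `sample_id` (unique), `bmi` (kg/m^2, > 0), `sex`
#' (\"male\"/\"female\"), `age` (years, > 0), `cohort`.  Additional columns
#' are treated as optional covariates.
#'
#' @param x data.frame to validate.
#' @return `x`, invisibly, if valid.
#' @export
validate_phenotype_table <- function(x) {
  need <- c("sample_id", "bmi", "sex", "age", "cohort")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id in phenotype table")
  if (any(!is.finite(x$bmi)) || any(x$bmi <= 0))
    stop("bmi must be finite and positive")
  if (any(!is.finite(x$age)) || any(x$age <= 0))
    stop("age must be finite and positive")
  if (!all(x$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  invisible(x)
}

#' Construct a genotype dosage matrix
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos0` (0-based
#'   position), `ref`, `alt`.  Unique `snp_id`, `pos0 >= 0`.
#' @param dosages numeric matrix, SNPs x samples, alt-allele dosage in
#'   `[0, 2]`; `NA` marks a missing genotype.
#' @param sample_ids character vector of sample identifiers.
#' @return an object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(snps, dosages, sample_ids) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(snps))
    stop("dosages rows (", nrow(dosages), ") != snps rows (", nrow(snps), ")")
  if (ncol(dosages) != length(sample_ids))
    stop("dosages columns != number of sample ids")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in genotypes")
  if (any(snps$pos0 < 0))
    stop("pos0 must be >= 0")
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2))
  if (length(bad))
    stop("dosage outside [0,2] at entry ", bad[1L])
  rownames(dosages) <- snps$snp_id
  colnames(dosages) <- sample_ids
  structure(
    list(snps = as.data.frame(snps), dosages = dosages,
         sample_ids = as.character(sample_ids)),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosages), "SNPs x",
      ncol(x$dosages), "samples\n")
  invisible(x)
}

#' Validate a gene annotation table
#'
#' Coordinates are 0-based half-open throughout the package; `start < end`,
#' strand one of `+`, `-`, `*` (unknown).
#'
#' @param x data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return `x`, invisibly, if valid.
#' @export
validate_gene_annotation <- function(x) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("gene annotation missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$start >= x$end))
    stop("gene annotation has start >= end for: ",
         paste(x$gene_id[x$start >= x$end], collapse = ", "))
  if (!all(x$strand %in% c("+", "-", "*")))
    stop("strand must be '+', '-' or '*'")
  invisible(x)
}

#' Validate a twin pair set
#'
#' @param x data.frame with columns `pair_id`, `obese_sample`, `lean_sample`.
#' @return `x`, invisibly, if valid.
#' @export
validate_twin_pairs <- function(x) {
  need <- c("pair_id", "obese_sample", "lean_sample")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("twin pair table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$pair_id))
    stop("duplicate pair_id")
  ids <- c(x$obese_sample, x$lean_sample)
  if (anyDuplicated(ids))
    stop("a sample appears in more than one pair slot")
  invisible(x)
}
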