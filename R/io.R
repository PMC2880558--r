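# Readers/writers for the plain-text formats the pipeline exchanges:
# expression TSV (header = sample ids, first column = probe id), dosage TSV
# (five SNP metadata columns then samples), VCF (GT and/or DS), BED gene
# annotation, phenotype and twin-pair TSVs.  "." encodes a missing dosage.

MISSING_TOKEN <- "."

#' Read an expression matrix from a tab-delimited file
#'
#' The first column holds probe identifiers, the header row sample
#' identifiers, and the body numeric intensities.  Row and column order are
#' preserved from the file.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, probes x samples (see
#'   [validate_expression_matrix()]).
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L)
    stop("expression file needs a probe column plus >= 1 sample column: ",
         path)
  probes <- tab[[1L]]
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         samples[duplicated(samples)][1L])
  if (anyDuplicated(probes))
    stop("duplicate probe id: ", probes[duplicated(probes)][1L])
  body <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value at probe '", probes[bad[1L]],
         "', sample '", samples[bad[2L]], "'")
  }
  dimnames(vals) <- list(probes, samples)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param x expression matrix.
#' @param path output path.
#' @param digits significant digits retained (default keeps full precision).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, digits = 15L) {
  validate_expression_matrix(x)
  out <- data.frame(probe_id = rownames(x),
                    signif(x, digits),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from TSV or VCF
#'
#' TSV layout mirrors the expression layout prefixed by five SNP metadata
#' columns (`snp_id`, `chrom`, `pos`, `ref`, `alt`; positions 1-based in the
#' file, converted to the package's 0-based convention on read), `.` for a
#' missing dosage.  VCF files must carry `GT` and/or `DS` per sample: `DS`
#' is used verbatim when present, otherwise `GT` is converted to the count
#' of alt alleles; missing genotypes become `NA`.
#'
#' @param path path ending in `.tsv`/`.txt` or `.vcf`/`.vcf.gz`.
#' @return a [dosage_matrix()].
#' @export
read_genotypes <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.vcf(\\.gz)?$", lower)) {
    read_genotypes_vcf(path)
  } else if (grepl("\\.(tsv|txt)$", lower)) {
    read_genotypes_tsv(path)
  } else {
    stop("unknown genotype file extension (expect .tsv/.txt or .vcf[.gz]): ",
         path)
  }
}

read_genotypes_tsv <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (ncol(tab) < 6L || !identical(colnames(tab)[1:5], meta_cols))
    stop("dosage TSV must start with columns ",
         paste(meta_cols, collapse = ", "))
  samples <- colnames(tab)[-(1:5)]
  body <- as.matrix(tab[, -(1:5), drop = FALSE])
  body[body == MISSING_TOKEN] <- NA
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(vals) & !is.na(body)))
    stop("non-numeric dosage value in ", path)
  snps <- data.frame(snp_id = tab$snp_id, chrom = tab$chrom,
                     pos0 = as.integer(tab$pos) - 1L,
                     ref = tab$ref, alt = tab$alt)
  dosage_matrix(snps, vals, samples)
}

read_genotypes_vcf <- function(path) {
  vcf <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  samples <- colnames(vcf@gt)[-1L]
  n_snp <- nrow(fix)
  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    vals <- matrix(as.numeric(ds), nrow = n_snp)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    vals <- apply(gt, 2L, gt_to_dosage)
    vals <- matrix(vals, nrow = n_snp)
  }
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  snps <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     pos0 = as.integer(fix[, "POS"]) - 1L,
                     ref = fix[, "REF"], alt = fix[, "ALT"])
  dosage_matrix(snps, vals, samples)
}

# "0/1" or "0|1" -> 1; any missing allele -> NA
gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || any(is.na(a)) || any(a == "."))
      return(NA_real_)
    sum(a != "0")
  }, numeric(1))
}

#' Write genotype dosages as TSV
#'
#' Inverse of the TSV branch of [read_genotypes()]; positions are written
#' 1-based, missing dosages as `.`.
#'
#' @param x a [dosage_matrix()].
#' @param path output path (should end in `.tsv`).
#' @param digits significant digits retained.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, digits = 15L) {
  stopifnot(inherits(x, "dosage_matrix"))
  body <- signif(x$dosages, digits)
  chr <- matrix(as.character(body), nrow = nrow(body))
  chr[is.na(chr)] <- MISSING_TOKEN
  colnames(chr) <- x$sample_ids
  out <- data.frame(snp_id = x$snps$snp_id, chrom = x$snps$chrom,
                    pos = x$snps$pos0 + 1L, ref = x$snps$ref,
                    alt = x$snps$alt, chr, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED
#'
#' BED is 0-based half-open, which is also the package's internal
#' convention, so coordinates pass through unchanged.  At least four columns
#' (chrom, start, end, name) are required; strand is taken from column 6
#' when present, else `*`.  Overlapping genes are retained as-is (no
#' merging).
#'
#' @param path path to a BED file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (see [validate_gene_annotation()]).
#' @export
read_gene_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED ", path, ": ",
                                          conditionMessage(e)))
  nm <- gr$name
  if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
    stop("BED gene annotation requires a name in column 4: ", path)
  ann <- data.frame(
    gene_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED's 0-based start
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  validate_gene_annotation(ann)
  ann
}

#' Write gene annotation as BED
#'
#' @param annotation gene annotation data.frame (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  validate_gene_annotation(annotation)
  out <- data.frame(annotation$chrom, annotation$start, annotation$end,
                    annotation$gene_id, 0L, annotation$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' @param path TSV with columns `sample_id`, `bmi`, `sex`, `age`, `cohort`
#'   and any number of extra covariate columns.
#' @return validated data.frame.
#' @export
read_phenotype_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  validate_phenotype_table(tab)
  tab
}

#' Write a phenotype table as TSV
#' @param x phenotype data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(x, path) {
  validate_phenotype_table(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a twin-pair table from TSV
#'
#' @param path TSV with columns `pair_id`, `obese_sample`, `lean_sample`.
#' @return validated data.frame.
#' @export
read_twin_pairs <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  validate_twin_pairs(tab)
  tab
}

#' Write a twin-pair table as TSV
#' @param x twin pair data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_twin_pairs <- function(x, path) {
  validate_twin_pairs(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
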