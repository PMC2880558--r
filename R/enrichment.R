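# Gene-set enrichment of small association P-values: Q-Q coordinates
# against uniform order statistics and a categorized-P Pearson chi-square
# test of uniformity, with optional best-SNP-per-gene pruning.

#' Q-Q coordinates for a set of P-values
#'
#' Pairs the i-th smallest observed P-value with the uniform order-statistic
#' expectation `(i - 0.5) / n`; points falling below the `y = x` line
#' indicate an excess of small P-values in the set.
#'
#' @param pvalues numeric vector of P-values in (0, 1].
#' @param label set label carried into the output.
#' @return data.frame with columns `set_label`, `expected_p`, `observed_p`
#'   (observed sorted ascending).
#' @export
qq_series <- function(pvalues, label = "set") {
  if (!length(pvalues))
    stop("empty P-value list")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("P-values must lie in (0, 1]")
  n <- length(pvalues)
  data.frame(set_label = label,
             expected_p = (seq_len(n) - 0.5) / n,
             observed_p = sort(pvalues))
}

#' Pearson chi-square test of P-value uniformity
#'
#' Bins the P-values into `n_bins` equal-width categories on \[0, 1\] and
#' compares observed counts with the uniform expectation `n / n_bins` by
#' Pearson's X-squared on `n_bins - 1` degrees of freedom (upper tail).
#' When the expected count per bin would fall below 5 the number of bins is
#' reduced automatically; fewer than 10 P-values is an error (the test is
#' meaningless).
#'
#' @param pvalues numeric vector of P-values in (0, 1].
#' @param n_bins requested number of bins (default 20, so the 0.05
#'   nominal threshold is a bin edge).
#' @param label set label carried into the output.
#' @return one-row data.frame: `set_label`, `n`, `n_bins`, `chi2`, `df`,
#'   `p_value`, plus the observed counts as an attribute `counts`.
#' @export
chisq_uniformity <- function(pvalues, n_bins = 20, label = "set") {
  if (length(pvalues) < 10L)
    stop("need >= 10 P-values for the uniformity test")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("P-values must lie in (0, 1]")
  n <- length(pvalues)
  n_bins <- min(n_bins, n %/% 5L)
  n_bins <- max(n_bins, 2L)
  bin <- pmin(ceiling(pvalues * n_bins), n_bins)  # p in ((b-1)/k, b/k]
  observed <- tabulate(bin, nbins = n_bins)
  expected <- n / n_bins
  chi2 <- sum((observed - expected)^2 / expected)
  out <- data.frame(set_label = label, n = n, n_bins = n_bins, chi2 = chi2,
                    df = n_bins - 1L,
                    p_value = pchisq(chi2, df = n_bins - 1L,
                                     lower.tail = FALSE))
  attr(out, "counts") <- observed
  out
}

#' Keep the best SNP per gene
#'
#' For each gene with at least one assigned SNP, retains the meta-analysis
#' record with the smallest overall P (ties broken by lexicographic SNP
#' id).  A SNP assigned to two overlapping genes may represent both, so the
#' output has one row per gene, not per SNP.
#'
#' @param meta meta-analysis records with `snp_id` and `p_overall`.
#' @param assignments SNP-to-gene assignments with `snp_id`, `gene_id`.
#' @return `meta` rows (one per gene) with a `gene_id` column prepended.
#' @export
best_snp_per_gene <- function(meta, assignments) {
  m <- merge(assignments[, c("snp_id", "gene_id")], meta, by = "snp_id")
  if (!nrow(m))
    return(cbind(data.frame(gene_id = character()), meta[0, ]))
  m <- m[order(m$gene_id, m$p_overall, m$snp_id), ]
  best <- m[!duplicated(m$gene_id), ]
  cols <- c("gene_id", setdiff(names(best), "gene_id"))
  out <- best[, cols]
  rownames(out) <- NULL
  out
}

#' Count SNPs and genes with nominal association
#'
#' @param meta meta-analysis records with `snp_id` and `p_overall`.
#' @param assignments SNP-to-gene assignments with `snp_id`, `gene_id`.
#' @param alpha nominal threshold (default 0.05).
#' @return list with `n_snps` (SNPs with overall P < alpha) and `n_genes`
#'   (unique genes those SNPs map to).
#' @export
count_nominal_hits <- function(meta, assignments, alpha = 0.05) {
  hit <- meta$snp_id[!is.na(meta$p_overall) & meta$p_overall < alpha]
  genes <- unique(assignments$gene_id[assignments$snp_id %in% hit])
  list(n_snps = length(hit), n_genes = length(genes))
}
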