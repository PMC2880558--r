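# Causative-vs-reactive transcript classification: a liberal intrapair test
# in the twin design (so that anything plausibly responding to obesity is
# removed), a stringent BMI-correlation screen in the unrelated sample, and
# set subtraction.

#' Test for intrapair expression differences
#'
#' Default mode tests the mean log2 co-twin ratio against 0 with a
#' one-sample t-test on `n_pairs - 1` degrees of freedom (the coherent test
#' on one-ratio-per-pair data).  `welch_two_sample` instead compares the
#' obese twins' raw intensities against the lean twins' with a Welch
#' unequal-variance t-test (Welch–Satterthwaite df); it requires `matrix`
#' and `pairs`.  The median fold change is always reported on the linear
#' obese/lean ratio scale.
#'
#' @param ratios pair-ratio matrix from [cotwin_normalize()].
#' @param mode `"log_ratio_one_sample"` (default) or `"welch_two_sample"`.
#' @param matrix,pairs raw expression matrix and twin-pair table, required
#'   for the Welch mode only.
#' @return data.frame with columns `probe_id`, `median_fold_change`,
#'   `t_statistic`, `p_value`.
#' @export
test_intrapair_difference <- function(ratios,
                                      mode = c("log_ratio_one_sample",
                                               "welch_two_sample"),
                                      matrix = NULL, pairs = NULL) {
  mode <- match.arg(mode)
  if (ncol(ratios) < 2L)
    stop("need >= 2 twin pairs")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("all co-twin ratios must be finite and > 0")
  fold <- apply(ratios, 1L, median)
  if (mode == "log_ratio_one_sample") {
    lr <- log2(ratios)
    n <- ncol(lr)
    m <- rowMeans(lr)
    s <- apply(lr, 1L, sd)
    degenerate <- s == 0 & m != 0
    if (any(degenerate))
      stop("zero variance with nonzero mean log-ratio for probe '",
           rownames(ratios)[which(degenerate)[1L]],
           "': t statistic undefined")
    t_stat <- ifelse(s == 0, 0, m / (s / sqrt(n)))
    p <- ifelse(s == 0, 1, 2 * pt(-abs(m / (s / sqrt(n))), df = n - 1))
  } else {
    if (is.null(matrix) || is.null(pairs))
      stop("welch_two_sample mode needs the raw expression matrix and pairs")
    validate_twin_pairs(pairs)
    ob <- matrix[rownames(ratios), pairs$obese_sample, drop = FALSE]
    le <- matrix[rownames(ratios), pairs$lean_sample, drop = FALSE]
    res <- welch_t_rows(ob, le)
    t_stat <- res$t
    p <- res$p
  }
  data.frame(probe_id = rownames(ratios), median_fold_change = fold,
             t_statistic = t_stat, p_value = pmax(p, .Machine$double.xmin),
             row.names = NULL)
}

# Row-wise Welch t with Welch-Satterthwaite degrees of freedom.
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  if (any(va == 0 & vb == 0))
    stop("zero variance in both groups for probe '",
         rownames(a)[which(va == 0 & vb == 0)[1L]], "'")
  sed2 <- va / na + vb / nb
  t <- (rowMeans(a) - rowMeans(b)) / sqrt(sed2)
  df <- sed2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * pt(-abs(t), df = df), df = df)
}

#' Correlate probe expression with BMI
#'
#' Pearson correlation of each probe's intensity with BMI over the samples
#' shared between the matrix and the phenotype table; the two-sided P-value
#' comes from the t transform `t = r * sqrt(n-2) / sqrt(1-r^2)` on `n - 2`
#' degrees of freedom.  P-values that underflow are reported as the
#' smallest representable positive double so they stay in (0, 1].
#'
#' @param matrix expression matrix.
#' @param phenotypes phenotype table with a `bmi` column.
#' @return data.frame with columns `probe_id`, `pearson_r`, `p_value`, `n`.
#' @export
correlate_with_bmi <- function(matrix, phenotypes) {
  validate_expression_matrix(matrix)
  validate_phenotype_table(phenotypes)
  shared <- intersect(colnames(matrix), phenotypes$sample_id)
  if (length(shared) < 3L)
    stop("need >= 3 samples shared between expression and phenotypes")
  bmi <- phenotypes$bmi[match(shared, phenotypes$sample_id)]
  if (sd(bmi) == 0)
    stop("BMI is constant: correlation undefined")
  x <- matrix[, shared, drop = FALSE]
  constant <- apply(x, 1L, sd) == 0
  if (any(constant))
    stop("constant expression for probe '",
         rownames(x)[which(constant)[1L]], "': correlation undefined")
  n <- length(shared)
  r <- as.vector(cor(t(x), bmi))
  r <- pmin(1, pmax(-1, r))
  t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  data.frame(probe_id = rownames(x), pearson_r = r,
             p_value = pmax(p, .Machine$double.xmin), n = n,
             row.names = NULL)
}

#' Classify transcripts as causative or reactive
#'
#' With R the reactive set (intrapair P below `alpha_reactive`) and C the
#' BMI-correlated set (correlation P below `alpha_corr`): `causative` is
#' C \ R, `correlated_and_reactive` is the overlap, `reactive` is R \ C and
#' everything else is `unclassified`.  The liberal reactive threshold is
#' deliberate: it errs on the side of removing transcripts from the
#' causative candidate list.  No multiple-testing correction is applied —
#' the design uses fixed nominal thresholds.
#'
#' @param differential output of [test_intrapair_difference()].
#' @param correlation output of [correlate_with_bmi()].
#' @param alpha_reactive intrapair threshold (default 0.05).
#' @param alpha_corr correlation threshold (default 1e-4).
#' @return data.frame with one row per probe: `probe_id`, `label`,
#'   `pearson_r`, `p_corr`, `median_fold_change`, `p_twin`.
#' @export
classify_transcripts <- function(differential, correlation,
                                 alpha_reactive = 0.05, alpha_corr = 1e-4) {
  stopifnot(alpha_reactive > 0, alpha_reactive <= 1,
            alpha_corr > 0, alpha_corr <= 1)
  only <- c(setdiff(differential$probe_id, correlation$probe_id),
            setdiff(correlation$probe_id, differential$probe_id))
  if (length(only))
    stop("probe(s) present in only one result list: ",
         paste(utils::head(only, 5L), collapse = ", "))
  i <- match(differential$probe_id, correlation$probe_id)
  corr <- correlation[i, ]
  in_r <- differential$p_value < alpha_reactive
  in_c <- corr$p_value < alpha_corr
  label <- ifelse(in_c & !in_r, "causative",
           ifelse(in_c & in_r, "correlated_and_reactive",
           ifelse(in_r, "reactive", "unclassified")))
  data.frame(probe_id = differential$probe_id, label = label,
             pearson_r = corr$pearson_r, p_corr = corr$p_value,
             median_fold_change = differential$median_fold_change,
             p_twin = differential$p_value, row.names = NULL)
}

#' Collapse a probe-level classification to genes
#'
#' A gene inherits the strongest label among its probes, with precedence
#' causative > correlated_and_reactive > reactive > unclassified (so a gene
#' with any causative probe is causative).  Probes mapping to the same gene
#' collapse to one record.
#'
#' @param classification data.frame from [classify_transcripts()].
#' @param probe_gene_map data.frame with columns `probe_id`, `gene_id`.
#' @return data.frame with columns `gene_id`, `label`, `n_probes`.
#' @export
collapse_probes_to_genes <- function(classification, probe_gene_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_gene_map)))
  m <- merge(classification[, c("probe_id", "label")], probe_gene_map,
             by = "probe_id")
  rank <- c(causative = 1L, correlated_and_reactive = 2L,
            reactive = 3L, unclassified = 4L)
  best <- tapply(rank[m$label], m$gene_id, min)
  counts <- tapply(m$probe_id, m$gene_id, length)
  genes <- names(best)
  data.frame(gene_id = genes,
             label = names(rank)[as.integer(best)],
             n_probes = as.integer(counts[genes]),
             row.names = NULL)
}
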