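# SNP-to-gene mapping, phenotype residualization, per-cohort additive
# association and inverse-variance fixed-effects meta-analysis.

#' Map SNPs to classified genes
#'
#' A SNP is assigned to a gene when its 0-based position lies inside the
#' gene span extended by `flank` bases on both sides, i.e. in
#' `[start - flank, end + flank)` — half-open on the right, matching the
#' package-wide coordinate convention.  The window is symmetric and
#' strand-free.  A SNP may be assigned to several (overlapping) genes; each
#' assignment carries the gene's set label.
#'
#' @param annotation gene annotation data.frame (0-based half-open).
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos0` (the
#'   `snps` element of a [dosage_matrix()] works directly).
#' @param gene_sets data.frame with columns `gene_id`, `gene_set` (labels
#'   such as "causative"/"reactive"); genes absent from it are dropped from
#'   the mapping.
#' @param flank symmetric flank in bases (default 1000).
#' @return data.frame with columns `snp_id`, `gene_id`, `gene_set`,
#'   `distance` (bases from the SNP to the unextended gene span; 0 inside).
#' @export
map_snps_to_genes <- function(annotation, snps, gene_sets, flank = 1000) {
  validate_gene_annotation(annotation)
  stopifnot(flank >= 0)
  ann <- merge(annotation, gene_sets, by = "gene_id")
  unmatched <- setdiff(unique(snps$chrom), unique(ann$chrom))
  if (length(unmatched))
    warning("SNP chromosome(s) absent from annotation: ",
            paste(unmatched, collapse = ", "))
  out <- list()
  for (chr in intersect(unique(ann$chrom), unique(snps$chrom))) {
    a <- ann[ann$chrom == chr, ]
    s <- snps[snps$chrom == chr, ]
    # windows in 1-based closed coordinates for IRanges:
    # 0-based half-open [start-flank, end+flank) -> [start-flank+1, end+flank]
    win <- IRanges::IRanges(start = a$start - flank + 1L,
                            end = a$end + flank)
    pos <- IRanges::IRanges(start = s$pos0 + 1L, width = 1L)
    hits <- IRanges::findOverlaps(pos, win)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    dist <- pmax(0L, a$start[si] - s$pos0[qi],
                 s$pos0[qi] - (a$end[si] - 1L))
    out[[chr]] <- data.frame(snp_id = s$snp_id[qi], gene_id = a$gene_id[si],
                             gene_set = a$gene_set[si], distance = dist)
  }
  if (!length(out))
    return(data.frame(snp_id = character(), gene_id = character(),
                      gene_set = character(), distance = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prepare sex-stratified, age-adjusted, standardized log-BMI residuals
#'
#' Within each (cohort, sex) stratum, natural-log BMI is regressed on age
#' (plus any extra covariates, e.g. a disease-status indicator) by ordinary
#' least squares and the residuals are standardized to mean 0, sd 1
#' (denominator `n - 1`).  Strata with fewer samples than model parameters
#' are skipped with a warning.
#'
#' @param phenotypes phenotype table.
#' @param extra_covariates character vector of additional covariate column
#'   names (default none).
#' @return data.frame with columns `sample_id`, `cohort`, `stratum`
#'   ("male"/"female"), `residual`.
#' @export
prepare_phenotype <- function(phenotypes, extra_covariates = character()) {
  validate_phenotype_table(phenotypes)
  miss <- setdiff(extra_covariates, names(phenotypes))
  if (length(miss))
    stop("extra covariate(s) not in phenotype table: ",
         paste(miss, collapse = ", "))
  out <- list()
  for (co in unique(phenotypes$cohort)) {
    for (sx in c("female", "male")) {
      ph <- phenotypes[phenotypes$cohort == co & phenotypes$sex == sx, ]
      n_par <- 2L + length(extra_covariates)
      if (nrow(ph) <= n_par) {
        warning("stratum (", co, ", ", sx, ") has ", nrow(ph),
                " samples for ", n_par, " parameters: skipped")
        next
      }
      rhs <- paste(c("age", extra_covariates), collapse = " + ")
      fit <- lm(stats::as.formula(paste("log(bmi) ~", rhs)), data = ph)
      res <- resid(fit)
      res <- (res - mean(res)) / sd(res)
      out[[paste(co, sx)]] <- data.frame(sample_id = ph$sample_id,
                                         cohort = co, stratum = sx,
                                         residual = as.numeric(res))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-SNP additive association within one cohort
#'
#' For each SNP, the standardized residual phenotype is regressed on allele
#' dosage (with intercept) over the non-missing samples; the additive
#' effect `beta`, its standard error and a two-sided P from the t
#' distribution on `n - 2` df are reported.  The `pooled` stratum
#' concatenates both sexes' standardized residuals.  SNPs monomorphic in
#' the analyzed samples, with fewer than 3 usable samples, or below the
#' minor-allele-frequency floor are flagged (`status` column) and carry no
#' estimate.
#'
#' @param genotypes a [dosage_matrix()] for one cohort.
#' @param residuals output of [prepare_phenotype()] (one cohort's rows are
#'   selected via `cohort`, or pass pre-filtered rows).
#' @param stratum `"pooled"` (default), `"male"` or `"female"`.
#' @param cohort cohort label to analyze; default the single label present
#'   in `residuals`.
#' @param maf_min minor-allele-frequency floor (default 0.01).
#' @return data.frame with columns `snp_id`, `cohort`, `stratum`, `beta`,
#'   `se`, `t`, `p`, `n`, `maf`, `status` ("ok", "monomorphic", "low_maf",
#'   "too_few").
#' @export
associate_snps <- function(genotypes, residuals,
                           stratum = c("pooled", "male", "female"),
                           cohort = NULL, maf_min = 0.01) {
  stopifnot(inherits(genotypes, "dosage_matrix"))
  stratum <- match.arg(stratum)
  if (is.null(cohort)) {
    cohort <- unique(residuals$cohort)
    if (length(cohort) != 1L)
      stop("residuals span several cohorts; pass `cohort` explicitly")
  }
  rs <- residuals[residuals$cohort == cohort, ]
  if (stratum != "pooled")
    rs <- rs[rs$stratum == stratum, ]
  shared <- intersect(genotypes$sample_ids, rs$sample_id)
  y_all <- rs$residual[match(shared, rs$sample_id)]
  g_all <- genotypes$dosages[, shared, drop = FALSE]
  snp_ids <- genotypes$snps$snp_id
  res <- lapply(seq_along(snp_ids), function(i) {
    g <- g_all[i, ]
    ok <- !is.na(g)
    g <- g[ok]; y <- y_all[ok]
    n <- length(g)
    af <- if (n) mean(g) / 2 else NA_real_
    maf <- if (is.na(af)) NA_real_ else min(af, 1 - af)
    if (n < 3L)
      return(assoc_row(snp_ids[i], cohort, stratum, n, maf, "too_few"))
    if (sd(g) == 0)
      return(assoc_row(snp_ids[i], cohort, stratum, n, maf, "monomorphic"))
    if (maf < maf_min)
      return(assoc_row(snp_ids[i], cohort, stratum, n, maf, "low_maf"))
    sxx <- sum((g - mean(g))^2)
    beta <- sum((g - mean(g)) * y) / sxx
    rss <- sum((y - mean(y) - beta * (g - mean(g)))^2)
    se <- sqrt(rss / (n - 2) / sxx)
    t <- beta / se
    p <- max(2 * pt(-abs(t), df = n - 2), .Machine$double.xmin)
    data.frame(snp_id = snp_ids[i], cohort = cohort, stratum = stratum,
               beta = beta, se = se, t = t, p = p, n = n, maf = maf,
               status = "ok")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

assoc_row <- function(snp_id, cohort, stratum, n, maf, status) {
  data.frame(snp_id = snp_id, cohort = cohort, stratum = stratum,
             beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
             n = n, maf = maf, status = status)
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Per SNP and stratum, cohort estimates are combined with weights
#' `w_i = 1 / se_i^2`: `beta_meta = sum(w * beta) / sum(w)`,
#' `se_meta = 1 / sqrt(sum(w))`, `z = beta_meta / se_meta` and a two-sided
#' normal P.  The `pooled` stratum supplies the overall P; `female` and
#' `male` strata supply the sex-specific columns.  Flagged per-cohort
#' records (no estimate) are dropped before combining.
#'
#' @param records data.frame of per-cohort results from [associate_snps()]
#'   (rows from any mix of cohorts and strata).
#' @return data.frame with one row per SNP: `snp_id`, `beta_meta`,
#'   `se_meta`, `z`, `p_overall`, `p_women`, `p_men`, `n` (total pooled
#'   sample count), `n_cohorts`.
#' @export
meta_fixed_effects <- function(records) {
  ok <- records[!is.na(records$se) & records$status == "ok", ]
  if (!nrow(ok))
    stop("no usable association records to meta-analyze")
  if (any(ok$se <= 0))
    stop("standard errors must be positive")
  combine <- function(d) {
    w <- 1 / d$se^2
    beta <- sum(w * d$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- beta / se
    data.frame(beta_meta = beta, se_meta = se, z = z,
               p = max(2 * pnorm(-abs(z)), .Machine$double.xmin),
               n = sum(d$n), k = nrow(d))
  }
  snp_ids <- unique(ok$snp_id)
  rows <- lapply(snp_ids, function(id) {
    d <- ok[ok$snp_id == id, ]
    pooled <- d[d$stratum == "pooled", ]
    fem <- d[d$stratum == "female", ]
    mal <- d[d$stratum == "male", ]
    if (!nrow(pooled))
      return(NULL)
    m <- combine(pooled)
    data.frame(snp_id = id, beta_meta = m$beta_meta, se_meta = m$se_meta,
               z = m$z, p_overall = m$p,
               p_women = if (nrow(fem)) combine(fem)$p else NA_real_,
               p_men = if (nrow(mal)) combine(mal)$p else NA_real_,
               n = m$n, n_cohorts = m$k)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no SNP had a pooled-stratum record to meta-analyze")
  rownames(out) <- NULL
  out
}
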