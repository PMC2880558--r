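# Genotype-expression-phenotype simulator with planted causal, reactive and
# null genes.  The generative model mirrors the causal logic the
# classification stage exploits:
#
#   causal gene g:   x_g = mu_g + b_g * u_g + c * C + noise
#   log-BMI (std):   z   = alpha * C + kappa * sum_g u_g + residual
#   reactive gene r: x_r = mu_r + delta * z_own + noise
#   null gene:       x   = mu + noise
#
# where u_g is the standardized dosage of the gene's cis-SNP and C is a
# constitutional factor shared by monozygotic co-twins.  Causal genes thus
# correlate with BMI across unrelated individuals (through both the cis-SNP
# and C) but show no expected intrapair difference in MZ pairs (G and C are
# shared within a pair; the discordance is environmental).  Reactive genes
# respond to each individual's own BMI, so they correlate with BMI *and*
# differ within discordant pairs.  All log-scale effects are solved in
# closed form so that each causal gene attains |corr(x, BMI)| = causal_r,
# its cis-SNP explains snp_h2 of var(x), and reactive genes show the target
# obese/lean fold change at the configured discordance.

#' Simulation configuration
#'
#' @param n_pairs number of discordant MZ pairs (default 13).
#' @param n_unrelated number of unrelated adults (default 77).
#' @param n_cohorts,n_per_cohort GWA panel shape (defaults 4 x 500, a
#'   desk-scale stand-in for a multi-cohort consortium).
#' @param n_causal_genes,n_reactive_genes,n_null_genes planted gene counts
#'   (defaults 20 / 20 / 200).
#' @param causal_r target |Pearson r| of each causal gene's expression with
#'   BMI in the unrelated sample (default 0.45).
#' @param reactive_fc target median obese/lean fold change of reactive
#'   genes in discordant pairs (default 1.3).
#' @param snp_h2 fraction of a causal gene's log-expression variance
#'   explained by its cis-SNP (default 0.3).
#' @param maf_range interval in (0, 0.5] for SNP allele frequencies
#'   (default c(0.05, 0.5)).
#' @param bmi_mean,bmi_sd target BMI moments, kg/m^2 (defaults 26.6, 4.1).
#' @param discordance_pct mean obese/lean weight excess within a pair
#'   (default 0.22, i.e. 22\%).
#' @param noise_sd residual sd of log expression (default 0.15).
#' @param bmi_genetic_share fraction of standardized log-BMI variance
#'   carried jointly by the causal cis-SNPs (default 0.2).
#' @param bmi_shared_share fraction carried by the shared constitutional
#'   factor (default 0.4); the remainder is individual environment.
#' @param seed integer seed; every simulate_* function derives its own
#'   sub-seed from it, so the whole generator is a pure function of the
#'   config.
#' @return a list of class `cotwin_config`.
#' @export
sim_config <- function(n_pairs = 13, n_unrelated = 77,
                       n_cohorts = 4, n_per_cohort = 500,
                       n_causal_genes = 20, n_reactive_genes = 20,
                       n_null_genes = 200,
                       causal_r = 0.45, reactive_fc = 1.3, snp_h2 = 0.3,
                       maf_range = c(0.05, 0.5),
                       bmi_mean = 26.6, bmi_sd = 4.1,
                       discordance_pct = 0.22, noise_sd = 0.15,
                       bmi_genetic_share = 0.2, bmi_shared_share = 0.4,
                       seed = 1) {
  cfg <- list(n_pairs = n_pairs, n_unrelated = n_unrelated,
              n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
              n_causal_genes = n_causal_genes,
              n_reactive_genes = n_reactive_genes,
              n_null_genes = n_null_genes,
              causal_r = causal_r, reactive_fc = reactive_fc,
              snp_h2 = snp_h2, maf_range = maf_range,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              discordance_pct = discordance_pct, noise_sd = noise_sd,
              bmi_genetic_share = bmi_genetic_share,
              bmi_shared_share = bmi_shared_share, seed = as.integer(seed))
  stopifnot(n_pairs >= 1, n_unrelated >= 1, n_cohorts >= 1,
            n_per_cohort >= 1, n_causal_genes >= 0, n_reactive_genes >= 0,
            n_null_genes >= 0,
            n_causal_genes + n_reactive_genes + n_null_genes >= 1,
            causal_r > 0, causal_r < 1, snp_h2 >= 0, snp_h2 < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            bmi_mean > 0, bmi_sd > 0, discordance_pct > 0, noise_sd > 0,
            bmi_genetic_share >= 0, bmi_shared_share > 0,
            bmi_genetic_share + bmi_shared_share < 1)
  class(cfg) <- "cotwin_config"
  cfg
}

# Closed-form scale parameters implied by the config; errors if the target
# causal correlation is unattainable at the given noise level.
sim_params <- function(config) {
  cv2 <- (config$bmi_sd / config$bmi_mean)^2
  sigma_ln <- sqrt(log(1 + cv2))
  mu_ln <- log(config$bmi_mean) - sigma_ln^2 / 2
  has_causal <- config$n_causal_genes > 0
  genetic <- if (has_causal) config$bmi_genetic_share else 0
  kappa <- if (has_causal)
    sqrt(genetic / config$n_causal_genes) else 0
  alpha <- sqrt(config$bmi_shared_share)
  sigma_zres <- sqrt(1 - genetic - config$bmi_shared_share)
  s <- config$noise_sd
  gap <- config$causal_r - kappa * sqrt(config$snp_h2)
  D <- alpha^2 * (1 - config$snp_h2) - gap^2
  if (has_causal && D <= 0)
    stop("causal_r = ", config$causal_r, " is unattainable: the shared ",
         "factor would need more than its available variance ",
         "(reduce causal_r or snp_h2, or raise bmi_shared_share)")
  v <- if (has_causal) alpha^2 * s^2 / D else NA_real_
  list(sigma_ln = sigma_ln, mu_ln = mu_ln, kappa = kappa, alpha = alpha,
       sigma_zres = sigma_zres,
       b_std = if (has_causal) sqrt(config$snp_h2 * v) else 0,
       c_load = if (has_causal) s * gap / sqrt(D) else 0,
       v_causal = v,
       delta = log(config$reactive_fc) * sigma_ln /
         log1p(config$discordance_pct))
}

# Gene panel: ids, classes, baselines, one cis-SNP per gene placed inside
# the gene body on a synthetic chromosome.  Draws mafs and baselines, so
# call under a set RNG state.
make_gene_map <- function(config) {
  classes <- rep(c("causal", "reactive", "null"),
                 c(config$n_causal_genes, config$n_reactive_genes,
                   config$n_null_genes))
  n <- length(classes)
  idx <- seq_len(n)
  gene_id <- sprintf("%s%03d", c(causal = "CAU", reactive = "REA",
                                 null = "NUL")[classes],
                     unlist(lapply(rle(classes)$lengths, seq_len)))
  start <- 10000L * idx
  mu <- ifelse(classes == "null",
               runif(n, log(10), log(3000)),
               runif(n, log(100), log(3000)))
  data.frame(gene_id = gene_id,
             probe_id = paste0(tolower(gene_id), "_at"),
             class = classes,
             chrom = "chr1", start = start, end = start + 2000L,
             strand = "+",
             snp_id = sprintf("rs%06d", 100000L + idx),
             snp_pos0 = start + 1000L,
             maf = runif(n, config$maf_range[1], config$maf_range[2]),
             mu = mu)
}

truth_object <- function(config, genes, params) {
  structure(list(genes = genes, params = params, config = config),
            class = "cotwin_truth")
}

#' @export
print.cotwin_truth <- function(x, ...) {
  cat("cotwin_truth:", nrow(x$genes), "genes (",
      sum(x$genes$class == "causal"), "causal,",
      sum(x$genes$class == "reactive"), "reactive,",
      sum(x$genes$class == "null"), "null )\n")
  invisible(x)
}

#' Gene annotation implied by a simulation truth
#'
#' @param truth a `cotwin_truth` object.
#' @return gene annotation data.frame (0-based half-open).
#' @export
truth_annotation <- function(truth) {
  g <- truth$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
             end = g$end, strand = g$strand)
}

snp_meta <- function(genes) {
  data.frame(snp_id = genes$snp_id, chrom = genes$chrom,
             pos0 = genes$snp_pos0, ref = "A", alt = "G")
}

# Raw binomial(2, f) genotype draw; no seeding (callers manage RNG state).
draw_dosages <- function(maf, n_samples) {
  matrix(rbinom(length(maf) * n_samples, 2L, rep(maf, n_samples)),
         nrow = length(maf))
}

#' Simulate a genotype dosage matrix
#'
#' Allele frequencies are drawn uniformly from `maf_range` (one cis-SNP per
#' configured gene) and genotypes independently as binomial(2, freq) across
#' SNPs and samples.  Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param n_samples number of samples to draw.
#' @return a [dosage_matrix()].
#' @export
simulate_genotypes <- function(config, n_samples) {
  stopifnot(inherits(config, "cotwin_config"), n_samples >= 1)
  set.seed(config$seed)
  genes <- make_gene_map(config)
  d <- draw_dosages(genes$maf, n_samples)
  dosage_matrix(snp_meta(genes), d, sprintf("S%04d", seq_len(n_samples)))
}

# standardized dosage by theoretical moments
std_dosage <- function(d, maf) (d - 2 * maf) / sqrt(2 * maf * (1 - maf))

# z: standardized log-BMI liability from shared factor + causal genotypes
liability <- function(u_causal, C, params, n) {
  gen <- if (nrow(u_causal)) params$kappa * colSums(u_causal) else 0
  params$alpha * C + gen + params$sigma_zres * rnorm(n)
}

# log-intensity matrix for the whole gene panel given per-sample genetics
# (u = standardized dosages, rows follow genes), shared factor C and each
# sample's standardized log-BMI z_own.
expression_panel <- function(genes, params, u, C, z_own, noise_sd) {
  n <- length(C)
  x <- matrix(rnorm(nrow(genes) * n, sd = noise_sd), nrow = nrow(genes))
  x <- x + genes$mu
  causal <- which(genes$class == "causal")
  reactive <- which(genes$class == "reactive")
  if (length(causal))
    x[causal, ] <- x[causal, ] + params$b_std * u[causal, , drop = FALSE] +
      params$c_load * rep(C, each = length(causal))
  if (length(reactive))
    x[reactive, ] <- x[reactive, ] +
      params$delta * rep(z_own, each = length(reactive))
  exp(x)
}

#' Simulate the unrelated-individuals study
#'
#' Generative order: (1) causal-gene expression from the cis-SNP plus the
#' constitutional factor; (2) BMI from the causal components plus
#' environment, rescaled so BMI is log-normal with the configured mean and
#' sd; (3) reactive-gene expression responding to each individual's own
#' BMI; (4) null genes as noise.  Intensities are exponentiated so they are
#' positive, matching normalized array output.
#'
#' @param config a [sim_config()].
#' @return list with `expression` (probes x samples matrix), `phenotypes`,
#'   `genotypes` (a [dosage_matrix()]) and `truth` (a `cotwin_truth`
#'   holding gene classes, cis-SNP ids and all planted effect sizes).
#' @export
simulate_unrelated <- function(config) {
  stopifnot(inherits(config, "cotwin_config"))
  params <- sim_params(config)
  set.seed(config$seed + 1L)
  genes <- make_gene_map(config)
  n <- config$n_unrelated
  samples <- sprintf("U%04d", seq_len(n))
  d <- draw_dosages(genes$maf, n)
  u <- std_dosage(d, genes$maf)
  C <- rnorm(n)
  causal <- genes$class == "causal"
  z <- liability(u[causal, , drop = FALSE], C, params, n)
  lnbmi <- params$mu_ln + params$sigma_ln * z
  expr <- expression_panel(genes, params, u, C, z, config$noise_sd)
  dimnames(expr) <- list(genes$probe_id, samples)
  phen <- data.frame(sample_id = samples, bmi = exp(lnbmi),
                     sex = sample(c("female", "male"), n, replace = TRUE),
                     age = runif(n, 27, 69), cohort = "unrelated")
  list(expression = expr, phenotypes = phen,
       genotypes = dosage_matrix(snp_meta(genes), d, samples),
       truth = truth_object(config, genes, params))
}

#' Simulate the discordant MZ twin-pair study
#'
#' Each pair shares one genotype vector and one constitutional factor; the
#' lean co-twin's BMI sits near the population mean (damped liability plus
#' pair noise) and the obese co-twin's is inflated by about
#' `discordance_pct` (environmental, with a small pair-to-pair jitter).
#' Causal genes therefore have identical pair means plus independent noise
#' (expected intrapair log-ratio 0) while reactive genes track each twin's
#' own BMI (expected obese/lean fold change `reactive_fc`).
#'
#' @param config a [sim_config()].
#' @param truth the `cotwin_truth` from [simulate_unrelated()] (shared gene
#'   classes and effect sizes).
#' @return list with `expression`, `pairs` (twin-pair table), `phenotypes`
#'   and `genotypes` (one column per twin; columns of a pair are equal).
#' @export
simulate_twin_pairs <- function(config, truth) {
  stopifnot(inherits(config, "cotwin_config"),
            inherits(truth, "cotwin_truth"))
  params <- truth$params
  genes <- truth$genes
  set.seed(config$seed + 2L)
  np <- config$n_pairs
  pair_id <- sprintf("P%03d", seq_len(np))
  obese_id <- paste0("T", sprintf("%03d", seq_len(np)), "O")
  lean_id <- paste0("T", sprintf("%03d", seq_len(np)), "L")
  d_pair <- draw_dosages(genes$maf, np)
  u_pair <- std_dosage(d_pair, genes$maf)
  C <- rnorm(np)
  causal <- genes$class == "causal"
  gen <- if (any(causal))
    params$kappa * colSums(u_pair[causal, , drop = FALSE]) else 0
  z_base <- params$alpha * C + gen
  dlog <- log1p(config$discordance_pct)
  ln_lean <- params$mu_ln + params$sigma_ln * (0.5 * z_base +
                                                 0.3 * rnorm(np))
  ln_obese <- ln_lean + dlog + 0.15 * dlog * rnorm(np)
  # interleave obese/lean columns; each twin reuses the pair's genetics
  lnbmi <- c(rbind(ln_obese, ln_lean))
  samples <- c(rbind(obese_id, lean_id))
  idx <- rep(seq_len(np), each = 2L)
  u_tw <- u_pair[, idx, drop = FALSE]
  z_own <- (lnbmi - params$mu_ln) / params$sigma_ln
  expr <- expression_panel(genes, params, u_tw, C[idx], z_own,
                           config$noise_sd)
  dimnames(expr) <- list(genes$probe_id, samples)
  sex <- sample(c("female", "male"), np, replace = TRUE)
  age <- runif(np, 24, 28)
  phen <- data.frame(sample_id = samples, bmi = exp(lnbmi),
                     sex = sex[idx], age = age[idx], cohort = "twins")
  pairs <- data.frame(pair_id = pair_id, obese_sample = obese_id,
                      lean_sample = lean_id)
  list(expression = expr, pairs = pairs, phenotypes = phen,
       genotypes = dosage_matrix(snp_meta(genes),
                                 d_pair[, idx, drop = FALSE], samples))
}

#' Simulate a multi-cohort genotype/phenotype panel
#'
#' Independent cohorts of `n_per_cohort` samples each; BMI depends on the
#' causal cis-SNPs through the same liability as the unrelated study, plus
#' a cohort-specific intercept, a sex shift and a linear age trend (which
#' the residualization stage removes).  Null and reactive SNPs have no BMI
#' effect.
#'
#' @param config a [sim_config()].
#' @param truth the `cotwin_truth` from [simulate_unrelated()].
#' @return list of length `n_cohorts`; each element has `cohort` (label),
#'   `genotypes` and `phenotypes`.
#' @export
simulate_cohort_panel <- function(config, truth) {
  stopifnot(inherits(config, "cotwin_config"),
            inherits(truth, "cotwin_truth"))
  params <- truth$params
  genes <- truth$genes
  causal <- genes$class == "causal"
  lapply(seq_len(config$n_cohorts), function(k) {
    set.seed(config$seed + 100L + k)
    n <- config$n_per_cohort
    label <- sprintf("cohort%02d", k)
    samples <- sprintf("%s_%04d", label, seq_len(n))
    d <- draw_dosages(genes$maf, n)
    u <- std_dosage(d, genes$maf)
    C <- rnorm(n)
    z <- liability(u[causal, , drop = FALSE], C, params, n)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    age <- runif(n, 25, 70)
    shift <- rnorm(1, 0, 0.02)
    lnbmi <- params$mu_ln + shift + 0.015 * (sex == "male") +
      0.003 * (age - 47.5) + params$sigma_ln * z
    phen <- data.frame(sample_id = samples, bmi = exp(lnbmi), sex = sex,
                       age = age, cohort = label)
    list(cohort = label,
         genotypes = dosage_matrix(snp_meta(genes), d, samples),
         phenotypes = phen)
  })
}
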