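test_that("SNP-to-gene mapping respects the half-open flank window", {
  ann <- data.frame(gene_id = "G", chrom = "chr1", start = 1000L,
                    end = 2000L, strand = "+")
  sets <- data.frame(gene_id = "G", gene_set = "causative")
  snps <- data.frame(snp_id = c("in_flank", "at_right_edge", "inside"),
                     chrom = "chr1", pos0 = c(999L, 3000L, 1500L))
  asn <- map_snps_to_genes(ann, snps, sets, flank = 1000)
  expect_setequal(asn$snp_id, c("in_flank", "inside"))
  expect_equal(asn$distance[asn$snp_id == "in_flank"], 1L)
  expect_equal(asn$distance[asn$snp_id == "inside"], 0L)
  expect_equal(unique(asn$gene_set), "causative")
})

test_that("mapping equals a brute-force interval scan on a random panel", {
  set.seed(51)
  n_gene <- 100; n_snp <- 10000
  start <- sort(sample.int(1e6, n_gene))
  ann <- data.frame(gene_id = sprintf("G%03d", 1:n_gene), chrom = "chr2",
                    start = start, end = start + sample(500:5000, n_gene,
                                                        replace = TRUE),
                    strand = "+")
  sets <- data.frame(gene_id = ann$gene_id,
                     gene_set = sample(c("causative", "reactive"), n_gene,
                                       replace = TRUE))
  snps <- data.frame(snp_id = sprintf("rs%05d", 1:n_snp), chrom = "chr2",
                     pos0 = sample.int(1.1e6, n_snp))
  asn <- map_snps_to_genes(ann, snps, sets, flank = 1000)
  brute <- do.call(rbind, lapply(seq_len(n_gene), function(i) {
    hit <- snps$pos0 >= ann$start[i] - 1000 & snps$pos0 < ann$end[i] + 1000
    if (!any(hit)) return(NULL)
    data.frame(snp_id = snps$snp_id[hit], gene_id = ann$gene_id[i])
  }))
  key <- function(d) sort(paste(d$snp_id, d$gene_id))
  expect_equal(key(asn), key(brute))
})

test_that("chromosome mismatches produce a warning listing them", {
  ann <- data.frame(gene_id = "G", chrom = "chr1", start = 0L, end = 10L,
                    strand = "+")
  sets <- data.frame(gene_id = "G", gene_set = "causative")
  snps <- data.frame(snp_id = "rs1", chrom = "chrX", pos0 = 5L)
  expect_warning(map_snps_to_genes(ann, snps, sets), "chrX")
})

test_that("phenotype residuals are standardized and orthogonal per stratum", {
  set.seed(52)
  ph <- rbind(random_phenotypes(60, cohort = "A"),
              transform(random_phenotypes(60, cohort = "B"),
                        sample_id = sprintf("t%03d", 1:60)))
  res <- prepare_phenotype(ph)
  for (co in c("A", "B")) for (sx in c("male", "female")) {
    r <- res$residual[res$cohort == co & res$stratum == sx]
    expect_lt(abs(mean(r)), 1e-10)
    expect_lt(abs(sd(r) - 1), 1e-10)
  }
  # when BMI does not depend on age, residuals track standardized ln(BMI)
  ph2 <- random_phenotypes(200)
  ph2$bmi <- exp(rnorm(200, 3.28, 0.15))
  res2 <- prepare_phenotype(ph2)
  for (sx in c("male", "female")) {
    sub <- res2[res2$stratum == sx, ]
    lnb <- log(ph2$bmi[match(sub$sample_id, ph2$sample_id)])
    expect_gt(cor(sub$residual, lnb), 0.98)
  }
})

test_that("residualization matches an independent normal-equations solve", {
  set.seed(53)
  ph <- random_phenotypes(6)
  ph$sex <- "female"  # single stratum (empty male stratum warns)
  suppressWarnings(res <- prepare_phenotype(ph))
  X <- cbind(1, ph$age)
  y <- log(ph$bmi)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- as.numeric(y - X %*% beta)
  r <- (r - mean(r)) / sd(r)
  expect_equal(res$residual[match(ph$sample_id, res$sample_id)], r,
               tolerance = 1e-10)
})

test_that("extra covariates are used and small strata are skipped", {
  set.seed(54)
  ph <- random_phenotypes(80)
  ph$mets <- rbinom(80, 1, 0.4)
  ph$bmi <- ph$bmi * exp(0.2 * ph$mets)
  res <- prepare_phenotype(ph, extra_covariates = "mets")
  # covariate effect is removed: residuals uncorrelated with mets
  for (sx in c("male", "female")) {
    sub <- res[res$stratum == sx, ]
    mets <- ph$mets[match(sub$sample_id, ph$sample_id)]
    expect_lt(abs(cor(sub$residual, mets)), 1e-10)
  }
  expect_error(prepare_phenotype(ph, extra_covariates = "nope"),
               "not in phenotype table")

  tiny <- random_phenotypes(30)
  tiny$sex <- c("female", rep("male", 29))
  expect_warning(res3 <- prepare_phenotype(tiny), "female.*skipped")
  expect_setequal(unique(res3$stratum), "male")
})

test_that("association flags degenerate SNPs and nails exact signals", {
  snps <- data.frame(snp_id = c("mono", "clean"), chrom = "chr1",
                     pos0 = c(0L, 10L), ref = "A", alt = "G")
  set.seed(55)
  n <- 50
  dose_clean <- rbinom(n, 2, 0.4)
  d <- rbind(rep(1, n), dose_clean)
  ids <- sprintf("s%03d", 1:n)
  g <- dosage_matrix(snps, d, ids)
  res <- fake_residuals(ids, 0.5 * dose_clean, stratum = "female")
  out <- associate_snps(g, res, stratum = "pooled")
  expect_equal(out$status, c("monomorphic", "ok"))
  expect_true(is.na(out$beta[1]))
  expect_equal(out$beta[2], 0.5, tolerance = 1e-12)
  expect_lt(out$p[2], 1e-100)
})

test_that("association equals an lm() oracle to 1e-10, dropping missing", {
  set.seed(56)
  for (case in 1:30) {
    n <- 30
    dose <- as.numeric(rbinom(n, 2, runif(1, 0.2, 0.5)))
    dose[sample.int(n, 3)] <- NA
    y <- rnorm(n)
    ids <- sprintf("s%03d", 1:n)
    g <- dosage_matrix(data.frame(snp_id = "rs1", chrom = "chr1",
                                  pos0 = 0L, ref = "A", alt = "G"),
                       matrix(dose, 1), ids)
    out <- associate_snps(g, fake_residuals(ids, y), stratum = "pooled",
                          maf_min = 0)
    if (out$status != "ok") next
    fit <- summary(lm(y ~ dose))$coefficients
    expect_equal(out$beta, fit["dose", "Estimate"], tolerance = 1e-10)
    expect_equal(out$se, fit["dose", "Std. Error"], tolerance = 1e-10)
    expect_equal(out$p, fit["dose", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(out$n, sum(!is.na(dose)))
  }
})

test_that("MAF floor and stratum selection behave", {
  set.seed(57)
  n <- 100
  ids <- sprintf("s%03d", 1:n)
  dose <- c(1, rep(0, n - 1))  # maf 0.005
  g <- dosage_matrix(data.frame(snp_id = "rare", chrom = "chr1", pos0 = 0L,
                                ref = "A", alt = "G"), matrix(dose, 1), ids)
  res <- rbind(fake_residuals(ids[1:50], rnorm(50), stratum = "female"),
               fake_residuals(ids[51:100], rnorm(50), stratum = "male"))
  expect_equal(associate_snps(g, res)$status, "low_maf")
  out_f <- associate_snps(g, res, stratum = "female", maf_min = 0)
  expect_equal(out_f$n, 50)
})

test_that("fixed-effects meta matches closed forms and metafor", {
  rec <- function(beta, se, stratum = "pooled", cohort = "c1", n = 100) {
    data.frame(snp_id = "rs1", cohort = cohort, stratum = stratum,
               beta = beta, se = se, t = beta / se, p = 0.5, n = n,
               maf = 0.3, status = "ok")
  }
  # single cohort: identity
  m1 <- meta_fixed_effects(rec(0.2, 0.1))
  expect_equal(m1$beta_meta, 0.2)
  expect_equal(m1$se_meta, 0.1)

  # two equal cohorts: se shrinks by sqrt(2)
  m2 <- meta_fixed_effects(rbind(rec(0.2, 0.1, cohort = "c1"),
                                 rec(0.2, 0.1, cohort = "c2")))
  expect_equal(m2$beta_meta, 0.2)
  expect_equal(m2$se_meta, 0.1 / sqrt(2))

  # hand-computed weighted mean: betas (0.1, 0.3), ses (0.1, 0.2)
  m3 <- meta_fixed_effects(rbind(rec(0.1, 0.1, cohort = "c1"),
                                 rec(0.3, 0.2, cohort = "c2")))
  expect_equal(m3$beta_meta, 0.14, tolerance = 1e-12)
  expect_equal(m3$se_meta, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(m3$p_overall, 2 * pnorm(-0.14 * sqrt(125)),
               tolerance = 1e-12)

  skip_if_not_installed("metafor")
  set.seed(58)
  for (case in 1:20) {
    k <- sample(2:6, 1)
    betas <- rnorm(k, 0.1, 0.2)
    ses <- runif(k, 0.05, 0.3)
    recs <- do.call(rbind, lapply(seq_len(k), function(i)
      rec(betas[i], ses[i], cohort = paste0("c", i))))
    m <- meta_fixed_effects(recs)
    ref <- metafor::rma(yi = betas, sei = ses, method = "FE")
    expect_equal(m$beta_meta, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(m$se_meta, ref$se, tolerance = 1e-10)
    expect_equal(m$p_overall, ref$pval, tolerance = 1e-10)
  }
})

test_that("meta of k replicated cohorts shrinks se by exactly 1/sqrt(k)
          and strata populate the sex-specific columns", {
  base <- data.frame(snp_id = "rs1", cohort = "c1", stratum = "pooled",
                     beta = 0.15, se = 0.05, t = 3, p = 0.01, n = 200,
                     maf = 0.3, status = "ok")
  for (k in c(2, 5, 9)) {
    recs <- do.call(rbind, lapply(1:k, function(i)
      transform(base, cohort = paste0("c", i))))
    m <- meta_fixed_effects(recs)
    expect_equal(m$se_meta, 0.05 / sqrt(k), tolerance = 1e-12)
    expect_equal(m$n, 200 * k)
  }
  recs <- rbind(base,
                transform(base, stratum = "female", beta = 0.2),
                transform(base, stratum = "male", beta = 0.05))
  m <- meta_fixed_effects(recs)
  expect_equal(m$p_women, 2 * pnorm(-0.2 / 0.05), tolerance = 1e-12)
  expect_equal(m$p_men, 2 * pnorm(-0.05 / 0.05), tolerance = 1e-12)
})
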