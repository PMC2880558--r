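# Shared generators for test inputs (all fixtures are built in code).

random_expression <- function(n_probes, n_samples, min = 1, max = 500) {
  m <- matrix(runif(n_probes * n_samples, min, max), nrow = n_probes,
              dimnames = list(sprintf("probe%04d", seq_len(n_probes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

random_phenotypes <- function(n, cohort = "c1") {
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             bmi = runif(n, 20, 38),
             sex = sample(c("male", "female"), n, replace = TRUE),
             age = runif(n, 25, 65),
             cohort = cohort)
}

# minimal VCF 4.2 text for a SNP x sample panel; `field` is "GT" or "DS"
write_test_vcf <- function(path, snps, values, sample_ids, field = "GT") {
  header <- c("##fileformat=VCFv4.2",
              paste0("##FORMAT=<ID=", field, ",Number=1,Type=",
                     if (field == "GT") "String" else "Float",
                     ",Description=\"x\">"),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", sample_ids),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(snps)), function(i) {
    paste(c(snps$chrom[i], snps$pos[i], snps$snp_id[i], snps$ref[i],
            snps$alt[i], ".", "PASS", ".", field, values[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# one standardized-residual data.frame usable by associate_snps()
fake_residuals <- function(sample_ids, values, cohort = "c1",
                           stratum = "female") {
  data.frame(sample_id = sample_ids, cohort = cohort, stratum = stratum,
             residual = values)
}
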