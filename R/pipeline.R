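# End-to-end orchestration: filter -> co-twin normalize -> classify ->
# map -> residualize -> associate -> meta-analyze -> enrichment, with every
# intermediate written as TSV plus a JSON manifest.  Inputs either come
# from the built-in simulator (default) or from files named in the config.

#' Default pipeline configuration
#'
#' Returns the full configuration list: analysis thresholds at their
#' published defaults, `simulate = TRUE`, and a [sim_config()] under `sim`.
#' Override any entry via `...` (or by editing the YAML written/read by
#' [run_pipeline()]).
#'
#' @param ... named overrides of the defaults.
#' @param seed integer seed applied to the simulator.
#' @return named list.
#' @export
pipeline_config <- function(..., seed = 1) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = TRUE,
    sim = NULL,                 # filled from seed below when NULL
    filter_threshold = 50,
    filter_min_fraction = 0.5,
    alpha_reactive = 0.05,
    alpha_corr = 1e-4,
    alpha_nominal = 0.05,
    flank = 1000,
    maf_min = 0.01,
    n_bins = 20,
    twin_test_mode = "log_ratio_one_sample",
    prune_best_snp = FALSE,
    # file-mode inputs (used when simulate = FALSE)
    twin_expression = NULL, twin_pairs = NULL,
    unrelated_expression = NULL, unrelated_phenotypes = NULL,
    probe_gene_map = NULL, annotation = NULL,
    cohort_genotypes = NULL, cohort_phenotypes = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (is.null(cfg$sim))
    cfg$sim <- sim_config(seed = cfg$seed)
  cfg
}

stage_stop <- function(stage, ...) {
  stop("[stage: ", stage, "] ", ..., call. = FALSE)
}

#' Run the whole pipeline
#'
#' Executes every stage in order, writes all intermediate tables under
#' `out_dir` and a `manifest.json` recording the configuration, package
#' version, seed and per-stage row counts.  Outputs are a pure function of
#' (inputs, config, seed): re-running with the same config yields
#' byte-identical TSVs.
#'
#' In simulate mode the gene universe, annotation and cohort panels come
#' from [simulate_unrelated()], [simulate_twin_pairs()] and
#' [simulate_cohort_panel()].  In file mode (`simulate = FALSE`) all input
#' paths must be supplied; `cohort_genotypes` / `cohort_phenotypes` are
#' parallel vectors of per-cohort files.
#'
#' The causative SNP set is compared against the control set of genes that
#' were BMI-correlated *and* twin-differential (the "reactive" control of
#' the study design).
#'
#' @param config list from [pipeline_config()], or a path to a YAML file
#'   with the same fields.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the classification, meta-analysis,
#'   enrichment and count results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- utils::modifyList(pipeline_config(),
                                yaml::read_yaml(config))
  if (is.list(config$sim) && !inherits(config$sim, "cotwin_config"))
    config$sim <- do.call(sim_config, config$sim)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  ## ---- inputs ----------------------------------------------------------
  if (isTRUE(config$simulate)) {
    unrel <- simulate_unrelated(config$sim)
    twins <- simulate_twin_pairs(config$sim, unrel$truth)
    panel <- simulate_cohort_panel(config$sim, unrel$truth)
    twin_expr <- twins$expression
    pairs <- twins$pairs
    unrel_expr <- unrel$expression
    unrel_phen <- unrel$phenotypes
    probe_map <- unrel$truth$genes[, c("probe_id", "gene_id")]
    annotation <- truth_annotation(unrel$truth)
    cohorts <- panel
    tsv(unrel$truth$genes[, c("gene_id", "class", "snp_id")], "truth.tsv")
  } else {
    need <- c("twin_expression", "twin_pairs", "unrelated_expression",
              "unrelated_phenotypes", "probe_gene_map", "annotation",
              "cohort_genotypes", "cohort_phenotypes")
    for (f in need)
      if (is.null(config[[f]]))
        stage_stop(if (f %in% c("twin_pairs", "twin_expression"))
          "classify" else "inputs", "missing input: ", f)
    twin_expr <- read_expression_matrix(config$twin_expression)
    pairs <- read_twin_pairs(config$twin_pairs)
    unrel_expr <- read_expression_matrix(config$unrelated_expression)
    unrel_phen <- read_phenotype_table(config$unrelated_phenotypes)
    probe_map <- read.delim(config$probe_gene_map, colClasses = "character")
    annotation <- read_gene_annotation(config$annotation)
    stopifnot(length(config$cohort_genotypes) ==
                length(config$cohort_phenotypes))
    cohorts <- Map(function(g, p) {
      phen <- read_phenotype_table(p)
      list(cohort = unique(phen$cohort)[1L],
           genotypes = read_genotypes(g), phenotypes = phen)
    }, config$cohort_genotypes, config$cohort_phenotypes)
  }

  ## ---- expression filter (each dataset independently) ------------------
  twin_f <- filter_by_expression(twin_expr, config$filter_threshold,
                                 config$filter_min_fraction)
  unrel_f <- filter_by_expression(unrel_expr, config$filter_threshold,
                                  config$filter_min_fraction)
  counts$probes_twin_filtered <- nrow(twin_f)
  counts$probes_unrelated_filtered <- nrow(unrel_f)
  # classification operates on the probes retained in both datasets
  universe <- intersect(rownames(twin_f), rownames(unrel_f))
  if (!length(universe))
    stage_stop("filter", "no probe passed the filter in both datasets")
  counts$probes_universe <- length(universe)

  ## ---- co-twin normalization + classification --------------------------
  ratios <- cotwin_normalize(twin_f[universe, , drop = FALSE], pairs)
  differential <- test_intrapair_difference(ratios,
                                            mode = config$twin_test_mode,
                                            matrix = twin_f, pairs = pairs)
  correlation <- correlate_with_bmi(unrel_f[universe, , drop = FALSE],
                                    unrel_phen)
  classification <- classify_transcripts(differential, correlation,
                                         config$alpha_reactive,
                                         config$alpha_corr)
  gene_table <- collapse_probes_to_genes(classification, probe_map)
  tsv(classification, "classification.tsv")
  tsv(gene_table, "genes.tsv")
  counts$probes_causative <- sum(classification$label == "causative")
  counts$probes_correlated_and_reactive <-
    sum(classification$label == "correlated_and_reactive")
  counts$genes_causative <- sum(gene_table$label == "causative")

  ## ---- SNP-to-gene mapping ---------------------------------------------
  sets <- data.frame(
    gene_id = gene_table$gene_id,
    gene_set = ifelse(gene_table$label == "causative", "causative",
                      ifelse(gene_table$label == "correlated_and_reactive",
                             "reactive", NA)))
  sets <- sets[!is.na(sets$gene_set), ]
  if (!nrow(sets))
    stage_stop("map", "no causative or reactive gene to map SNPs to")
  snps <- cohorts[[1L]]$genotypes$snps
  assignments <- map_snps_to_genes(annotation, snps, sets,
                                   flank = config$flank)
  tsv(assignments, "assignments.tsv")
  counts$snps_assigned <- length(unique(assignments$snp_id))

  ## ---- per-cohort association ------------------------------------------
  keep <- unique(assignments$snp_id)
  records <- list()
  for (co in cohorts) {
    g <- co$genotypes
    sel <- g$snps$snp_id %in% keep
    g <- dosage_matrix(g$snps[sel, ], g$dosages[sel, , drop = FALSE],
                       g$sample_ids)
    res <- prepare_phenotype(co$phenotypes)
    for (st in c("pooled", "female", "male"))
      records[[paste(co$cohort, st)]] <-
        associate_snps(g, res, stratum = st, cohort = co$cohort,
                       maf_min = config$maf_min)
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  tsv(records, "association.tsv")
  counts$association_records <- nrow(records)

  ## ---- meta-analysis ----------------------------------------------------
  meta <- meta_fixed_effects(records)
  set_of <- tapply(assignments$gene_set, assignments$snp_id,
                   function(s) paste(sort(unique(s)), collapse = "+"))
  meta$gene_set <- as.character(set_of[meta$snp_id])
  tsv(meta, "meta.tsv")
  counts$snps_meta <- nrow(meta)

  ## ---- enrichment -------------------------------------------------------
  meta_used <- meta
  if (isTRUE(config$prune_best_snp)) {
    pruned <- best_snp_per_gene(meta, assignments)
    tsv(pruned, "meta_best_per_gene.tsv")
    meta_used <- pruned
  }
  enr <- list(); qq <- list()
  for (s in c("causative", "reactive")) {
    ids <- unique(assignments$snp_id[assignments$gene_set == s])
    p <- meta_used$p_overall[meta_used$snp_id %in% ids]
    p <- p[!is.na(p)]
    if (length(p) >= 10L)
      enr[[s]] <- chisq_uniformity(p, n_bins = config$n_bins, label = s)
    if (length(p))
      qq[[s]] <- qq_series(p, label = s)
  }
  enrichment <- do.call(rbind, enr)
  if (!is.null(enrichment)) tsv(enrichment, "enrichment.tsv")
  qq_tab <- do.call(rbind, qq)
  if (!is.null(qq_tab)) tsv(qq_tab, "qq.tsv")

  caus_assign <- assignments[assignments$gene_set == "causative", ]
  hits <- count_nominal_hits(meta[meta$snp_id %in% caus_assign$snp_id, ],
                             caus_assign, alpha = config$alpha_nominal)
  counts$nominal_snps_causative <- hits$n_snps
  counts$nominal_genes_causative <- hits$n_genes

  ## ---- manifest ---------------------------------------------------------
  cfg_echo <- config
  cfg_echo$sim <- unclass(cfg_echo$sim)
  manifest <- list(package = "cotwin",
                   version = as.character(packageVersion("cotwin")),
                   seed = config$seed, config = cfg_echo, counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(classification = classification, genes = gene_table,
                 assignments = assignments, association = records,
                 meta = meta, enrichment = enrichment, qq = qq_tab,
                 nominal_hits = hits, counts = counts))
}
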