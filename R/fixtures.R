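# Published result tables shipped as machine-readable fixtures.  They are
# transcribed digit-for-digit from the printed source (a checksum of the
# shipped files is asserted in the test suite) and serve as inputs for
# counting operations: nominal-hit tallies, best-SNP-per-gene pruning and
# probe-to-gene collapse.

#' Load the packaged result-table fixtures
#'
#' Returns the three published tables as data.frames:
#' \describe{
#'   \item{table1}{28 probe rows relating adipose expression to BMI in the
#'     putatively causative set: `gene_symbol`, `probe_id`, `pearson_r`,
#'     `p_unrelated`, `fold_obese_lean`, `p_twin`.  Fold changes > 1 mean
#'     higher expression in the obese co-twin.}
#'   \item{table2}{23 SNP rows for the causative gene set: `gene_symbol`,
#'     `maf`, `snp_id`, `n`, `p_women`, `p_men`, `p_overall`.}
#'   \item{table3}{21 SNP rows for the reactive gene set, same columns.}
#' }
#' Gene symbols are kept exactly as printed (including the "PRDX8" spelling
#' in table2 versus "PRDX6" in table1 — no correction is applied).
#'
#' @return list with elements `table1`, `table2`, `table3`.
#' @export
load_fixture_tables <- function() {
  list(table1 = read_fixture("table1_expression_bmi.tsv"),
       table2 = read_fixture("table2_causative_snps.tsv"),
       table3 = read_fixture("table3_reactive_snps.tsv"))
}

read_fixture <- function(name) {
  path <- fixture_path(name)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (any(tab[[grep("^p_", names(tab))[1L]]] <= 0))
    stop("fixture ", name, " has a non-positive P-value")
  tab
}

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "cotwin")
  if (path == "")
    stop("fixture not found: ", name)
  path
}
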