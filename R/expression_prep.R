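# Expression-level filtering and the co-twin normalization that precede
# classification.  Both operate within one dataset at a time: the twin set
# and the unrelated set are filtered independently.

#' Filter probes by expression level
#'
#' Retains exactly the probes whose intensity is at least `threshold` in at
#' least `ceiling(min_fraction * n_samples)` samples ("at least" is
#' inclusive, so the half-of-samples rule uses the ceiling for odd sample
#' counts).  Sample set and probe order are preserved.
#'
#' @param matrix expression matrix (probes x samples).
#' @param threshold intensity cutoff (default 50).
#' @param min_fraction minimum fraction of samples at or above `threshold`
#'   (default 0.5).
#' @return the filtered expression matrix; a warning (not an error) is
#'   emitted when no probe survives.
#' @export
filter_by_expression <- function(matrix, threshold = 50, min_fraction = 0.5) {
  validate_expression_matrix(matrix)
  stopifnot(threshold >= 0, min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(matrix))
  keep <- rowSums(matrix >= threshold) >= need
  if (!any(keep))
    warning("no probe passed the expression filter (threshold ", threshold,
            ", min_fraction ", min_fraction, ")")
  matrix[keep, , drop = FALSE]
}

#' Co-twin normalization
#'
#' Divides the obese twin's expression value by the lean co-twin's, probe by
#' probe, yielding one ratio per probe per pair.  Ratios above 1 mean higher
#' expression in the obese twin.  Because monozygotic co-twins are
#' genetically identical, the ratio cancels sequence, sex, age and shared
#' environment, isolating the response to the discordant trait.
#'
#' @param matrix expression matrix containing all twin samples.
#' @param pairs twin pair table (`pair_id`, `obese_sample`, `lean_sample`).
#' @param pseudocount intensity added to numerator and denominator (default
#'   0; normalized intensities are strictly positive, so a zero denominator
#'   indicates an upstream problem and raises an error).
#' @return a `pair_ratio_matrix`: numeric matrix of obese/lean ratios with
#'   probe rownames and pair-id colnames.
#' @export
cotwin_normalize <- function(matrix, pairs, pseudocount = 0) {
  validate_expression_matrix(matrix)
  validate_twin_pairs(pairs)
  missing <- setdiff(c(pairs$obese_sample, pairs$lean_sample),
                     colnames(matrix))
  if (length(missing))
    stop("twin sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  obese <- matrix[, pairs$obese_sample, drop = FALSE] + pseudocount
  lean <- matrix[, pairs$lean_sample, drop = FALSE] + pseudocount
  if (any(lean <= 0)) {
    bad <- which(lean <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive lean-twin denominator for probe '",
         rownames(matrix)[bad[1L]], "' in pair '", pairs$pair_id[bad[2L]],
         "' (pseudocount ", pseudocount, ")")
  }
  ratios <- obese / lean
  colnames(ratios) <- pairs$pair_id
  class(ratios) <- c("pair_ratio_matrix", class(ratios))
  ratios
}
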