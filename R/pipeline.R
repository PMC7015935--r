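#' Run the full durable-response pipeline on a counts cohort
#'
#' Convenience wrapper chaining the stages: low-count filtering,
#' median-of-ratios size factors, the negative-binomial Wald test (DR vs
#' NR), stroma and proliferation signature derivation, FPKM conversion,
#' cohort-mean normalization, geometric-mean scoring and combination-score
#' classification with a threshold trained by Youden's J.
#'
#' @param counts an [expression_matrix()] of kind \code{"counts"}.
#' @param gene_lengths data frame (\code{gene_id}, \code{length_bp}).
#' @param samples metadata data frame (\code{sample_id},
#'   \code{response_label}).
#' @param caf_markers,g2m,e2f gene sets driving signature derivation.
#' @param responder_label,nonresponder_label the two-group contrast.
#' @param k,alpha stroma selection parameters (see
#'   [derive_stroma_signature()]).
#' @param min_abs_log2fc proliferation selection threshold.
#' @return list with \code{de} (differential-expression table),
#'   \code{stroma}, \code{proliferation} (signatures), \code{scores}
#'   (classified score table) and \code{threshold}.
#' @export
run_response_pipeline <- function(counts, gene_lengths, samples,
                                  caf_markers, g2m, e2f,
                                  responder_label = "DR", nonresponder_label = "NR",
                                  k = 10L, alpha = 0.05, min_abs_log2fc = 1) {
  filtered <- filter_low_expression(counts)
  sf <- estimate_size_factors(filtered)
  de <- nb_two_group_test(filtered, samples, sf,
                          responder_label = responder_label,
                          nonresponder_label = nonresponder_label)
  stroma <- derive_stroma_signature(de, caf_markers, k = k, alpha = alpha)
  prolif <- derive_proliferation_signature(de, g2m, e2f,
                                           min_abs_log2fc = min_abs_log2fc)
  fpkm <- counts_to_fpkm(filtered, gene_lengths)
  scored <- score_cohort(fpkm, stroma, prolif, labels = samples)
  classified <- combination_classify(scored, truth = scored$true_label,
                                     positive_label = responder_label)
  list(de = de, stroma = stroma, proliferation = prolif,
       scores = classified, threshold = attr(classified, "threshold"))
}

#' Score a new cohort with previously derived signatures
#'
#' Applies existing stroma/proliferation signatures and a fixed combination
#' threshold (e.g. trained on another cohort) to an independent cohort.
#' The cohort is normalized to its own mean, matching the per-cohort
#' normalization of the scoring procedure.
#'
#' @param counts counts matrix of the new cohort.
#' @param gene_lengths data frame (\code{gene_id}, \code{length_bp}).
#' @param stroma,proliferation [signature_set()] objects.
#' @param threshold fixed combination-score threshold.
#' @param samples optional metadata merged in as \code{true_label}.
#' @return classified score table.
#' @export
apply_signatures <- function(counts, gene_lengths, stroma, proliferation,
                             threshold, samples = NULL) {
  filtered <- filter_low_expression(counts)
  needed <- union(stroma$gene_ids, proliferation$gene_ids)
  dropped <- setdiff(needed, rownames(filtered))
  if (length(dropped)) {
    # signature genes must survive filtering in the new cohort; keep them
    filtered <- expression_matrix(
      unclass(counts)[union(rownames(filtered), needed), , drop = FALSE], "counts")
  }
  fpkm <- counts_to_fpkm(filtered, gene_lengths)
  scored <- score_cohort(fpkm, stroma, proliferation, labels = samples)
  combination_classify(scored, threshold = threshold)
}
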