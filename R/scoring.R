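#' Normalize expression to the cohort mean
#'
#' Divides each gene's values by its mean over the scoring cohort so that
#' every gene contributes on a common scale: for gene g and sample s,
#' \deqn{x'_{gs} = (x_{gs} + \epsilon) / \mathrm{mean}_{c \in cohort}(x_{gc} + \epsilon)}
#' with \eqn{\epsilon = 0.01} FPKM so the downstream geometric mean is
#' defined at zero expression. The per-gene arithmetic mean over the cohort
#' is exactly 1 by construction. Samples outside \code{cohort_samples} are
#' still returned, normalized against the cohort mean.
#'
#' @param fpkm an [expression_matrix()] of kind \code{"fpkm"}.
#' @param cohort_samples samples defining the per-gene mean (default: all
#'   samples in the matrix).
#' @param eps pseudocount added before normalization.
#' @return an [expression_matrix()] of kind \code{"normalized"}.
#' @export
mean_normalize <- function(fpkm, cohort_samples = colnames(fpkm), eps = 0.01) {
  assert_kind(fpkm, "fpkm")
  if (length(cohort_samples) == 0L) stop("cohort is empty", call. = FALSE)
  missing <- setdiff(cohort_samples, colnames(fpkm))
  if (length(missing))
    stop(sprintf("cohort sample(s) not in matrix: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  shifted <- unclass(fpkm) + eps
  gene_mean <- rowMeans(shifted[, cohort_samples, drop = FALSE])
  expression_matrix(shifted / gene_mean, "normalized")
}

#' Geometric-mean signature score
#'
#' Per-sample score of a signature on cohort-mean-normalized expression:
#' \deqn{score_s = \exp\left(\frac{1}{|S|}\sum_{g \in S} \ln x'_{gs}\right)}
#' Strictly positive for the normalized values produced by
#' [mean_normalize()].
#'
#' @param normalized an [expression_matrix()] of kind \code{"normalized"}.
#' @param sig a [signature_set()] whose genes must all be present.
#' @return named numeric vector of scores, one per sample.
#' @export
geometric_mean_score <- function(normalized, sig) {
  assert_kind(normalized, "normalized")
  stopifnot(inherits(sig, "signature_set"))
  missing <- setdiff(sig$gene_ids, rownames(normalized))
  if (length(missing))
    stop(sprintf("signature gene(s) missing from matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sub <- unclass(normalized)[sig$gene_ids, , drop = FALSE]
  if (any(sub <= 0))
    stop("normalized values must be strictly positive for geometric means", call. = FALSE)
  exp(colMeans(log(sub)))
}

#' Score a cohort with stroma and proliferation signatures
#'
#' Convenience wrapper: normalizes the cohort to its mean and returns a
#' score table with the stroma score, the proliferation score and the
#' combination score \eqn{\ln(stroma) - \ln(proliferation)} (high in
#' responders, which show high stroma and low proliferation).
#'
#' @param fpkm an [expression_matrix()] of kind \code{"fpkm"}.
#' @param stroma,proliferation [signature_set()] objects.
#' @param labels optional data frame (\code{sample_id},
#'   \code{response_label}) merged in as \code{true_label}.
#' @return data frame: \code{sample_id}, \code{stroma_score},
#'   \code{proliferation_score}, \code{combination_score}, and
#'   \code{true_label} when labels are given.
#' @export
score_cohort <- function(fpkm, stroma, proliferation, labels = NULL) {
  norm <- mean_normalize(fpkm)
  s <- geometric_mean_score(norm, stroma)
  p <- geometric_mean_score(norm, proliferation)
  out <- data.frame(sample_id = colnames(fpkm),
                    stroma_score = unname(s),
                    proliferation_score = unname(p),
                    combination_score = unname(log(s) - log(p)),
                    stringsAsFactors = FALSE)
  if (!is.null(labels))
    out$true_label <- labels$response_label[match(out$sample_id, labels$sample_id)]
  out
}

#' Classify response from the combination score
#'
#' A sample is predicted a responder when its combination score
#' \eqn{\ln(stroma) - \ln(proliferation)} is at least the threshold. The
#' threshold can be supplied directly or trained: training maximizes
#' Youden's J (sensitivity + specificity - 1) over candidate thresholds at
#' the midpoints between adjacent distinct combination scores, breaking
#' ties toward the smaller threshold. Alternatively \code{rule = "two_threshold"} predicts a
#' responder when stroma score >= \code{stroma_threshold} and proliferation
#' score <= \code{proliferation_threshold}.
#'
#' @param scores data frame from [score_cohort()] (needs
#'   \code{stroma_score}, \code{proliferation_score}; a missing
#'   \code{combination_score} is recomputed).
#' @param truth optional character vector of true labels (same order as
#'   \code{scores}) used to train the threshold; defaults to
#'   \code{scores$true_label}.
#' @param threshold fixed decision threshold on the combination score.
#' @param positive_label label counted as responder in \code{truth}.
#' @param rule \code{"combination"} (default) or \code{"two_threshold"}.
#' @param stroma_threshold,proliferation_threshold cutoffs for the
#'   two-threshold rule.
#' @return \code{scores} with \code{predicted_label}
#'   (\code{"responder"}/\code{"nonresponder"}) and, when trained, the
#'   chosen threshold in attribute \code{"threshold"}.
#' @export
combination_classify <- function(scores, truth = scores$true_label, threshold = NULL,
                                 positive_label = "DR",
                                 rule = c("combination", "two_threshold"),
                                 stroma_threshold = NULL, proliferation_threshold = NULL) {
  rule <- match.arg(rule)
  stopifnot(all(c("stroma_score", "proliferation_score") %in% names(scores)))
  if (is.null(scores$combination_score))
    scores$combination_score <- log(scores$stroma_score) - log(scores$proliferation_score)

  if (rule == "two_threshold") {
    if (is.null(stroma_threshold) || is.null(proliferation_threshold))
      stop("two_threshold rule needs stroma_threshold and proliferation_threshold",
           call. = FALSE)
    pred <- scores$stroma_score >= stroma_threshold &
      scores$proliferation_score <= proliferation_threshold
    scores$predicted_label <- ifelse(pred, "responder", "nonresponder")
    return(scores)
  }

  if (is.null(threshold)) {
    if (is.null(truth))
      stop("supply either a threshold or training labels", call. = FALSE)
    threshold <- train_combination_threshold(scores$combination_score,
                                             truth == positive_label)
  }
  scores$predicted_label <- ifelse(scores$combination_score >= threshold,
                                   "responder", "nonresponder")
  attr(scores, "threshold") <- threshold
  scores
}

# Youden-optimal threshold; candidates are the midpoints between adjacent
# distinct scores (plus the minimum score, which classifies everyone as a
# responder), so the decision boundary falls between training points rather
# than on one. Ties -> smaller threshold.
train_combination_threshold <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive), any(is_positive), any(!is_positive))
  u <- sort(unique(score))
  cand <- if (length(u) == 1L) u else c(u[1L], (u[-1L] + u[-length(u)]) / 2)
  j <- vapply(cand, function(t) {
    pred <- score >= t
    sens <- sum(pred & is_positive) / sum(is_positive)
    spec <- sum(!pred & !is_positive) / sum(!is_positive)
    sens + spec - 1
  }, numeric(1L))
  cand[which.max(j)]  # which.max takes the first, i.e. smallest, maximizer
}

#' Write a score table as TSV
#'
#' @param scores data frame from [score_cohort()] / [combination_classify()].
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
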