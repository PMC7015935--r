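#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed as in the median-of-ratios
#' method: for each sample, the median over reference genes (rows with all
#' counts positive) of the ratio of its count to the row's geometric mean.
#' Factors are rescaled to have geometric mean exactly 1, so normalized
#' counts stay on the raw-count scale.
#'
#' @param counts an [expression_matrix()] of kind \code{"counts"}.
#' @return named numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  assert_kind(counts, "counts")
  m <- unclass(counts)
  ref <- rowSums(m == 0) == 0L
  if (!any(ref))
    stop(paste("no gene has positive counts in every sample;",
               "filter low-count genes or add a pseudocount first"), call. = FALSE)
  logm <- log(m[ref, , drop = FALSE])
  row_gm <- exp(rowMeans(logm))
  sf <- apply(m[ref, , drop = FALSE], 2L, function(col) stats::median(col / row_gm))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Two-group negative-binomial Wald test
#'
#' Per-gene differential expression between two response groups on
#' size-factor-normalized counts. For each gene the group means \eqn{m_1}
#' (responders) and \eqn{m_2} are compared on the log scale with a Wald
#' statistic whose variance comes from the negative-binomial
#' mean-variance relation \eqn{Var = \mu + \alpha \mu^2}, with the
#' dispersion \eqn{\alpha} estimated by pooled method of moments and floored
#' at \code{1e-8} (sub-Poisson moment estimates are treated as Poisson).
#' The log2 fold change uses a pseudocount of 0.5 normalized counts,
#' \eqn{\log_2((m_1 + 0.5)/(m_2 + 0.5))}, positive when expression is higher
#' in responders. Two-sided p-values are taken from a t reference with
#' \eqn{n_1 + n_2 - 2} degrees of freedom, which keeps the test calibrated
#' at the small group sizes this design targets. Genes that are all zero
#' get \code{log2fc = 0}, \code{p_value = 1} and \code{flagged = TRUE}.
#'
#' @param counts an [expression_matrix()] of kind \code{"counts"}.
#' @param labels data frame with \code{sample_id} and \code{response_label}
#'   covering every sample in \code{counts}.
#' @param size_factors named vector from [estimate_size_factors()].
#' @param responder_label,nonresponder_label which labels form the contrast;
#'   each group needs at least 2 samples.
#' @return data frame: \code{gene_id}, \code{mean_expression} (overall mean
#'   of normalized counts), \code{log2fc}, \code{p_value}, \code{q_value}
#'   (Benjamini-Hochberg), \code{flagged}.
#' @export
nb_two_group_test <- function(counts, labels, size_factors,
                              responder_label = "DR", nonresponder_label = "NR") {
  assert_kind(counts, "counts")
  stopifnot(is.data.frame(labels), all(c("sample_id", "response_label") %in% names(labels)))
  lab <- labels$response_label[match(colnames(counts), labels$sample_id)]
  if (anyNA(lab)) stop("every sample in the matrix needs a response label", call. = FALSE)
  sf <- size_factors[colnames(counts)]
  if (anyNA(sf) || any(sf <= 0)) stop("size factors must be positive and cover all samples", call. = FALSE)

  i1 <- lab == responder_label
  i2 <- lab == nonresponder_label
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L)
    stop(sprintf("each group needs >= 2 samples (got %s=%d, %s=%d)",
                 responder_label, n1, nonresponder_label, n2), call. = FALSE)

  norm <- sweep(unclass(counts), 2L, sf, "/")
  x1 <- norm[, i1, drop = FALSE]
  x2 <- norm[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var)
  v2 <- apply(x2, 1L, stats::var)

  # pooled method-of-moments dispersion; normalized counts K/sf have
  # Var = mu/sf + alpha*mu^2, hence the mean(1/sf) terms
  inv1 <- mean(1 / sf[i1]); inv2 <- mean(1 / sf[i2])
  num <- (n1 - 1) * (v1 - m1 * inv1) + (n2 - 1) * (v2 - m2 * inv2)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  alpha <- pmax(ifelse(den > 0, num / den, 0), 1e-8)

  c0 <- 0.5
  log2fc <- log2((m1 + c0) / (m2 + c0))
  var_m1 <- (m1 * inv1 + alpha * m1^2) / n1
  var_m2 <- (m2 * inv2 + alpha * m2^2) / n2
  se_log <- sqrt(var_m1 / (m1 + c0)^2 + var_m2 / (m2 + c0)^2)
  wald <- (log(m1 + c0) - log(m2 + c0)) / se_log
  p <- 2 * stats::pt(-abs(wald), df = n1 + n2 - 2)

  flagged <- m1 + m2 == 0
  p[flagged | !is.finite(wald)] <- 1
  log2fc[flagged] <- 0

  res <- data.frame(
    gene_id = rownames(counts),
    mean_expression = rowMeans(norm[, i1 | i2, drop = FALSE]),
    log2fc = log2fc,
    p_value = p,
    q_value = bh_adjust(p),
    flagged = flagged | !is.finite(wald),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction: with sorted p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1, returned in
#' the input order.
#'
#' @param p_values numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes
#'
#' Genes with \code{q_value < max_fdr} and \code{|log2fc| > min_abs_log2fc}
#' (both strict): the defaults implement FDR < 0.05 with fold change > 2.
#'
#' @param results data frame from [nb_two_group_test()].
#' @param max_fdr FDR cutoff.
#' @param min_abs_log2fc absolute log2 fold-change cutoff.
#' @return character vector of selected gene identifiers.
#' @export
select_degs <- function(results, max_fdr = 0.05, min_abs_log2fc = 1) {
  stopifnot(all(c("gene_id", "log2fc", "q_value") %in% names(results)))
  results$gene_id[results$q_value < max_fdr & abs(results$log2fc) > min_abs_log2fc]
}

#' Write differential-expression results as TSV
#'
#' @param results data frame from [nb_two_group_test()].
#' @param path output file.
#' @export
write_de_results <- function(results, path) {
  cols <- c("gene_id", "mean_expression", "log2fc", "p_value", "q_value")
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
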