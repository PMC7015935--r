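#' Confusion counts and sensitivity/specificity
#'
#' Counts true/false positives and negatives of a predicted-label vector
#' against truth and reports sensitivity \eqn{100\,tp/(tp+fn)} and
#' specificity \eqn{100\,tn/(tn+fp)} as percentages, with one-decimal
#' rounding (half away from zero) alongside the exact values. With no true
#' positives in the input, sensitivity is undefined and reported as
#' \code{NA} (never 0); likewise specificity with no true negatives.
#'
#' @param truth,predicted equal-length label vectors.
#' @param positive_label the label in \code{truth} counted as positive.
#' @param positive_prediction the label in \code{predicted} meaning a
#'   positive call (default: same as \code{positive_label}).
#' @return list with \code{tp}, \code{fn}, \code{tn}, \code{fp},
#'   \code{sensitivity}, \code{specificity} (exact percentages) and
#'   \code{sensitivity_pct}, \code{specificity_pct} (one decimal).
#' @export
confusion_metrics <- function(truth, predicted, positive_label,
                              positive_prediction = positive_label) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  pos <- truth == positive_label
  pred_pos <- predicted == positive_prediction
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       positive_label = positive_label,
       sensitivity = sens, specificity = spec,
       sensitivity_pct = round_half_up(sens, 1L),
       specificity_pct = round_half_up(spec, 1L))
}

#' Response-rate summary from category counts
#'
#' Given tumor counts per response category (durable response DR,
#' short-lived response SR, nonresponder NR), returns the overall responding
#' percentage \eqn{100 (DR + SR) / total} and the per-category percentages.
#'
#' @param category_counts named numeric vector or list with entries
#'   \code{DR}, \code{SR}, \code{NR} (missing categories count as 0).
#' @return list with \code{total}, \code{responding_pct} and per-category
#'   percentages, all rounded to one decimal (exact values in
#'   \code{responding} / \code{per_category}).
#' @export
response_fractions <- function(category_counts) {
  cc <- unlist(category_counts)
  if (any(cc < 0)) stop("category counts must be non-negative", call. = FALSE)
  get <- function(k) if (k %in% names(cc)) cc[[k]] else 0
  dr <- get("DR"); sr <- get("SR"); nr <- get("NR")
  total <- dr + sr + nr
  if (total == 0) stop("total count is zero", call. = FALSE)
  responding <- 100 * (dr + sr) / total
  per <- 100 * c(DR = dr, SR = sr, NR = nr) / total
  list(total = total,
       responding = responding,
       responding_pct = round_half_up(responding, 1L),
       per_category = per,
       per_category_pct = round_half_up(per, 1L))
}

#' Two-sample Mann-Whitney U test
#'
#' Two-tailed rank-sum comparison of two independent groups. The p-value is
#' exact (full enumeration of rank arrangements) for small tie-free inputs
#' and uses the normal approximation with tie correction otherwise. The U
#' statistic is reported for \code{x} (number of (x, y) pairs with x > y,
#' ties counted 1/2).
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact_max use the exact distribution when
#'   \code{length(x) + length(y) <= exact_max} and there are no ties.
#' @return list with \code{U} and two-sided \code{p_value}.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(ht$statistic), p_value = ht$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed test for matched pre/on-treatment measurements, paired by
#' position. Zero differences are dropped before ranking; if every
#' difference is zero the p-value is reported as 1 with a warning. The
#' p-value is exact (sign-flip enumeration) for small tie-free inputs.
#'
#' @param pre,on equal-length numeric vectors.
#' @param exact_max use the exact distribution when the number of nonzero
#'   differences is at most this and their magnitudes are tie-free.
#' @return list with \code{V} (signed-rank statistic) and two-sided
#'   \code{p_value}.
#' @export
wilcoxon_signed_rank <- function(pre, on, exact_max = 12L) {
  if (length(pre) != length(on))
    stop("pre and on must have equal length (paired by position)", call. = FALSE)
  d <- on - pre
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; p-value reported as 1", call. = FALSE)
    return(list(V = 0, p_value = 1))
  }
  exact <- length(nz) <= exact_max && anyDuplicated(abs(nz)) == 0L
  ht <- suppressWarnings(stats::wilcox.test(on, pre, paired = TRUE,
                                            exact = exact, correct = !exact))
  list(V = unname(ht$statistic), p_value = ht$p.value)
}

#' Kaplan-Meier median survival
#'
#' Product-limit estimate of median survival: the smallest observed time at
#' which the survival function drops to 0.5 or below; \code{NA} when the
#' curve never reaches 0.5 (e.g. heavy censoring, a long-tail curve).
#'
#' @param records data frame with columns \code{time} (days, >= 0) and
#'   \code{event} (1 = death/endpoint, 0 = censored).
#' @return median survival time in days, or \code{NA}.
#' @export
km_median <- function(records) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)),
            nrow(records) >= 1L)
  if (any(records$time < 0)) stop("survival times must be non-negative", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  # smallest event time at which the product-limit curve reaches 0.5 or
  # below (no interpolation when S(t) equals 0.5 exactly)
  hit <- fit$time[fit$surv <= 0.5]
  if (length(hit) == 0L) NA_real_ else hit[1L]
}

#' Two-group log-rank test
#'
#' Standard observed-versus-expected log-rank statistic on one degree of
#' freedom, comparing two survival curves (e.g. anti-PD-1 vs control arm).
#'
#' @param records data frame with columns \code{time}, \code{event},
#'   \code{group} (exactly two groups, each with at least one event).
#' @return list with \code{chisq} and \code{p_value}.
#' @export
logrank_test <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event", "group") %in% names(records)))
  groups <- unique(records$group)
  if (length(groups) != 2L) stop("exactly two groups are required", call. = FALSE)
  ev <- tapply(records$event, records$group, sum)
  if (any(ev == 0))
    stop(sprintf("group '%s' has zero events", names(ev)[ev == 0][1L]), call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Write an evaluation report
#'
#' Writes confusion counts and percentages both as a two-column TSV and, if
#' jsonlite is available, as JSON next to it (\code{<path>.json}).
#'
#' @param metrics list from [confusion_metrics()].
#' @param path TSV output file.
#' @export
write_evaluation_report <- function(metrics, path) {
  flat <- unlist(metrics)
  utils::write.table(data.frame(metric = names(flat), value = unname(flat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(metrics, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
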