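#' Signature objects
#'
#' A signature is a named gene set with a direction (up- or down-regulated
#' in responders) and the differential-expression provenance of its members.
#'
#' @param name signature name.
#' @param gene_ids unique, non-empty character vector.
#' @param direction \code{"up_in_responders"} or \code{"down_in_responders"}.
#' @param provenance data frame with one row per member (at least
#'   \code{gene_id}, \code{log2fc}, \code{p_value}) plus any selection
#'   parameters as attributes.
#' @return an object of class \code{signature_set}.
#' @export
signature_set <- function(name, gene_ids,
                          direction = c("up_in_responders", "down_in_responders"),
                          provenance = NULL) {
  direction <- match.arg(direction)
  if (length(gene_ids) == 0L) stop("a signature must contain at least one gene", call. = FALSE)
  stop_if_duplicated(gene_ids, "signature gene")
  structure(list(name = name, gene_ids = gene_ids, direction = direction,
                 provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature '%s' (%s): %d genes\n  %s\n", x$name, x$direction,
              length(x$gene_ids), paste(x$gene_ids, collapse = ", ")))
  invisible(x)
}

#' Derive the stroma (CAF) signature
#'
#' From a differential-expression table and a set of cancer-associated
#' fibroblast marker genes, takes the markers significantly up-regulated in
#' responders (\code{log2fc > 0} and unadjusted \code{p_value < alpha}) and
#' keeps the top \code{k} by p-value. Ties are broken by larger
#' \code{|log2fc|}, then lexicographic gene id, so the selection is
#' deterministic. Fewer than \code{k} qualifying markers returns them all
#' with a warning; none is an error.
#'
#' @param de data frame from [nb_two_group_test()].
#' @param caf_markers character vector of CAF marker gene ids.
#' @param k signature size (default 10).
#' @param alpha unadjusted p-value cutoff (default 0.05).
#' @return a [signature_set()] with direction \code{"up_in_responders"}.
#' @export
derive_stroma_signature <- function(de, caf_markers, k = 10L, alpha = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "p_value") %in% names(de)))
  if (length(caf_markers) == 0L) stop("caf_markers must be non-empty", call. = FALSE)
  cand <- de[de$gene_id %in% caf_markers & de$log2fc > 0 & de$p_value < alpha, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no CAF marker is significantly up-regulated in responders", call. = FALSE)
  ord <- order(cand$p_value, -abs(cand$log2fc), cand$gene_id)
  cand <- cand[ord, , drop = FALSE]
  if (nrow(cand) < k)
    warning(sprintf("only %d qualifying CAF markers (requested %d)", nrow(cand), k),
            call. = FALSE)
  top <- utils::head(cand, k)
  prov <- top[, c("gene_id", "log2fc", "p_value")]
  attr(prov, "selection") <- list(k = k, alpha = alpha)
  signature_set("stroma", top$gene_id, "up_in_responders", prov)
}

#' Derive the proliferation signature
#'
#' Unique genes from the merged G2M-checkpoint and E2F-targets sets whose
#' expression is down-regulated in responders with
#' \code{log2fc <= -min_abs_log2fc} (the absolute-fold-change threshold is
#' inclusive). An empty result is an error.
#'
#' @param de data frame from [nb_two_group_test()].
#' @param g2m,e2f character vectors of cell-cycle gene ids.
#' @param min_abs_log2fc inclusive absolute log2 fold-change cutoff (default 1).
#' @return a [signature_set()] with direction \code{"down_in_responders"}.
#' @export
derive_proliferation_signature <- function(de, g2m, e2f, min_abs_log2fc = 1) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(de)))
  if (length(g2m) == 0L || length(e2f) == 0L)
    stop("g2m and e2f gene sets must be non-empty", call. = FALSE)
  pool <- unique(c(g2m, e2f))
  cand <- de[de$gene_id %in% pool & de$log2fc <= -min_abs_log2fc, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no cell-cycle gene is down-regulated at the fold-change threshold", call. = FALSE)
  cand <- cand[order(cand$log2fc, cand$gene_id), , drop = FALSE]
  prov <- cand[, c("gene_id", "log2fc", "p_value")]
  attr(prov, "selection") <- list(min_abs_log2fc = min_abs_log2fc)
  signature_set("proliferation", cand$gene_id, "down_in_responders", prov)
}

#' Write a signature as GMT plus a provenance side-car
#'
#' Writes the member list in GMT format and, when provenance is available,
#' a TSV of per-member log2 fold change and p-value next to it
#' (\code{<path>.provenance.tsv}).
#'
#' @param sig a [signature_set()].
#' @param path GMT output file.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_set"))
  sets <- stats::setNames(list(sig$gene_ids), sig$name)
  write_gmt(sets, path, descriptions = sig$direction)
  if (!is.null(sig$provenance)) {
    utils::write.table(sig$provenance, paste0(path, ".provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
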