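#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Duplicate members
#' within a line are dropped with a warning; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> unique members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)), call. = FALSE)
    name <- fields[1L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicate member(s) %s de-duplicated", name,
                      paste(unique(members[duplicated(members)]), collapse = ", ")),
              call. = FALSE)
      members <- unique(members)
    }
    if (name %in% names(sets))
      stop(sprintf("duplicate gene-set name '%s' (line %d)", name, i), call. = FALSE)
    sets[[name]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled \code{"na"} if omitted).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  stop_if_duplicated(names(sets), "gene-set")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(name, desc, members) {
    paste(c(name, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns \code{sample_id}, \code{response_label} and optionally
#' \code{timepoint}, \code{pair_id}, \code{cohort}. A pair identifier, when
#' present, must link exactly two samples with distinct timepoints (a
#' pre/on-treatment pair).
#'
#' @param path TSV file path.
#' @return data frame with the metadata columns.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (!all(c("sample_id", "response_label") %in% names(df)))
    stop("sample table needs columns sample_id and response_label", call. = FALSE)
  df$sample_id <- trimws(df$sample_id)
  stop_if_duplicated(df$sample_id, "sample")
  validate_pairing(df)
  df
}

validate_pairing <- function(df) {
  if (!"pair_id" %in% names(df)) return(invisible(df))
  has_pair <- !is.na(df$pair_id) & nzchar(df$pair_id)
  for (pid in unique(df$pair_id[has_pair])) {
    rows <- df[has_pair & df$pair_id == pid, , drop = FALSE]
    if (nrow(rows) != 2L)
      stop(sprintf("pair_id '%s' links %d sample(s); must link exactly 2",
                   pid, nrow(rows)), call. = FALSE)
    if (!"timepoint" %in% names(rows) || rows$timepoint[1L] == rows$timepoint[2L])
      stop(sprintf("pair_id '%s' must link two distinct timepoints", pid), call. = FALSE)
  }
  invisible(df)
}
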