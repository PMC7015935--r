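# Internal helpers shared across modules.

#' Geometric mean of a positive vector
#' @param x numeric vector, all values > 0
#' @return exp(mean(log(x)))
#' @keywords internal
#' @noRd
geom_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

# Round half away from zero (base round() is half-to-even); used for
# percentages reported to one decimal.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic sub-seed for a named component of a simulation, so each
# component draws from its own reproducible stream. Kept below 2^31.
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Evaluate expr under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_duplicated <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}
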