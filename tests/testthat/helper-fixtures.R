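# Shared fixtures and independent oracles used across test files.

make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, "counts")
}

make_fpkm <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, "fpkm")
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1, input order restored.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free inputs only): U for x counted as #{(i,j): x_i > y_j}.
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2L, function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  })
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p_value = p)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# assignments of the ranked absolute differences (tie-free, no zeros).
wsr_exact_oracle <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0L, 1L)), n))
  vs <- as.matrix(signs) %*% r
  p <- min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
  list(V = v_obs, p_value = p)
}

# Brute-force peptide window count: windows of length k in 1..n containing
# site `pos`, fully inside the protein.
window_count_oracle <- function(n, pos, lengths = 9:11) {
  total <- 0L
  for (k in lengths) {
    if (n < k) next
    for (st in 1:(n - k + 1L)) {
      if (st <= pos && pos <= st + k - 1L) total <- total + 1L
    }
  }
  total
}

random_protein <- function(n, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Small two-group NB cohort with optional planted log2 effects, used by the
# DE and signature tests (independent of the package's cohort generator).
simple_nb_cohort <- function(n_genes, n1, n2, mu, dispersion, effect_log2 = NULL,
                             seed = 1L) {
  set.seed(seed)
  base <- if (length(mu) == 1L) rep(mu, n_genes) else mu
  eff <- if (is.null(effect_log2)) rep(0, n_genes) else effect_log2
  m <- matrix(rep(base, n1 + n2), n_genes, n1 + n2)
  m[, seq_len(n1)] <- m[, seq_len(n1)] * 2^eff
  cnt <- matrix(rnbinom(n_genes * (n1 + n2), mu = m, size = 1 / dispersion),
                n_genes, n1 + n2)
  counts <- make_counts(cnt)
  labels <- data.frame(sample_id = colnames(counts),
                       response_label = rep(c("DR", "NR"), c(n1, n2)),
                       stringsAsFactors = FALSE)
  list(counts = counts, labels = labels)
}
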