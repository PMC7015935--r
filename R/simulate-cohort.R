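#' Simulation configuration for a synthetic expression cohort
#'
#' Defaults emulate the anti-PD-1 mouse study design: 6 durable responders
#' (DR) vs 8 nonresponders (NR), 2,000 genes with log-normal base means
#' (meanlog 4, sdlog 1.5, typical bulk RNA-seq shape), negative-binomial
#' counts with dispersion 0.2, log-normal library-size spread (sigma 0.25),
#' a 50-gene CAF-marker panel with 10 planted up-regulated genes
#' (log2 effect +1.5 in DR) and a 120-gene cell-cycle panel (G2M/E2F
#' stand-ins with a 20-gene overlap) with 7 planted down-regulated genes
#' (log2 effect -1.5 in DR). Gene lengths are uniform on 300-10,000 bp for
#' FPKM computation. Optional paired pre/on-treatment samples share a
#' per-pair random effect (sigma 0.1 on the log mean) so paired tests are
#' exercised.
#'
#' @param n_genes total number of genes.
#' @param n_dr,n_nr samples per response group.
#' @param n_caf_markers size of the CAF marker panel.
#' @param n_planted_stroma planted up-regulated CAF genes.
#' @param delta_up log2 effect of planted stroma genes in DR.
#' @param n_g2m,n_e2f,n_cellcycle_overlap sizes of the two cell-cycle sets
#'   and their overlap (union size is \code{n_g2m + n_e2f - overlap}).
#' @param n_planted_prolif planted down-regulated cell-cycle genes.
#' @param delta_down log2 effect magnitude of planted proliferation genes
#'   (applied with negative sign in DR).
#' @param base_meanlog,base_sdlog log-normal parameters of base means.
#' @param dispersion negative-binomial dispersion alpha (Var = mu + alpha mu^2).
#' @param libsize_sdlog log-normal sigma of library-size factors.
#' @param length_range gene-length range in bp.
#' @param paired_timepoints also generate paired pre-treatment samples.
#' @param pair_sdlog sigma of the shared per-pair log-mean random effect.
#' @param seed integer seed; all randomness derives from it.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 2000L, n_dr = 6L, n_nr = 8L,
                       n_caf_markers = 50L, n_planted_stroma = 10L, delta_up = 1.5,
                       n_g2m = 70L, n_e2f = 70L, n_cellcycle_overlap = 20L,
                       n_planted_prolif = 7L, delta_down = 1.5,
                       base_meanlog = 4, base_sdlog = 1.5,
                       dispersion = 0.2, libsize_sdlog = 0.25,
                       length_range = c(300L, 10000L),
                       paired_timepoints = FALSE, pair_sdlog = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_cellcycle <- n_g2m + n_e2f - n_cellcycle_overlap
  if (cfg$n_planted_stroma > cfg$n_caf_markers)
    stop("planted stroma genes must fit inside the CAF marker panel", call. = FALSE)
  if (cfg$n_planted_prolif > cfg$n_cellcycle)
    stop("planted proliferation genes must fit inside the cell-cycle union", call. = FALSE)
  if (cfg$n_caf_markers + cfg$n_cellcycle > cfg$n_genes)
    stop("marker panels exceed the gene universe", call. = FALSE)
  if (cfg$n_cellcycle_overlap > min(n_g2m, n_e2f))
    stop("overlap exceeds a cell-cycle set", call. = FALSE)
  if (cfg$dispersion <= 0 || cfg$libsize_sdlog < 0)
    stop("dispersion must be positive and libsize_sdlog non-negative", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic two-group expression cohort
#'
#' Draws counts \eqn{K_{gs} \sim NB(\mu = q_g \, f_s \, 2^{\delta_g I[s \in DR]},
#' \alpha)} with base means \eqn{q_g}, library-size factors \eqn{f_s} and
#' planted log2 effects \eqn{\delta_g} on the designated stroma
#' (up-regulated) and proliferation (down-regulated) genes. Deterministic
#' given the config seed; each stochastic component (means, lengths,
#' library sizes, counts) uses its own derived stream so partial
#' regeneration is reproducible.
#'
#' @param config a [sim_config()].
#' @return list with \code{counts} (an [expression_matrix()]),
#'   \code{gene_lengths} (data frame), \code{samples} (metadata data
#'   frame), \code{gene_sets} (list: \code{CAF_markers}, \code{G2M_checkpoint},
#'   \code{E2F_targets}), and \code{truth} (planted gene ids, effects,
#'   base means, dispersion, seed).
#' @export
generate_expression_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  caf <- genes[seq_len(cfg$n_caf_markers)]
  cc_pool <- genes[cfg$n_caf_markers + seq_len(cfg$n_cellcycle)]
  g2m <- cc_pool[seq_len(cfg$n_g2m)]
  e2f <- cc_pool[(cfg$n_g2m - cfg$n_cellcycle_overlap) + seq_len(cfg$n_e2f)]
  planted_up <- caf[seq_len(cfg$n_planted_stroma)]
  planted_down <- cc_pool[seq_len(cfg$n_planted_prolif)]

  n_on <- cfg$n_dr + cfg$n_nr
  on_ids <- sprintf("%s_on_%02d", rep(c("DR", "NR"), c(cfg$n_dr, cfg$n_nr)),
                    seq_len(n_on))
  resp <- rep(c("DR", "NR"), c(cfg$n_dr, cfg$n_nr))

  base_mu <- with_seed(derive_seed(cfg$seed, "base_means"),
                       stats::rlnorm(cfg$n_genes, cfg$base_meanlog, cfg$base_sdlog))
  lengths <- with_seed(derive_seed(cfg$seed, "gene_lengths"),
                       sample(cfg$length_range[1L]:cfg$length_range[2L],
                              cfg$n_genes, replace = TRUE))

  effect <- stats::setNames(rep(0, cfg$n_genes), genes)
  effect[planted_up] <- cfg$delta_up
  effect[planted_down] <- -cfg$delta_down

  n_total <- if (cfg$paired_timepoints) 2L * n_on else n_on
  sf <- with_seed(derive_seed(cfg$seed, "library_sizes"),
                  stats::rlnorm(n_total, 0, cfg$libsize_sdlog))

  if (cfg$paired_timepoints) {
    pre_ids <- sub("_on_", "_pre_", on_ids)
    sample_ids <- c(on_ids, pre_ids)
    pair_fx <- with_seed(derive_seed(cfg$seed, "pair_effects"),
                         stats::rnorm(n_on, 0, cfg$pair_sdlog))
    # planted effects act only on on-treatment DR samples; the pair random
    # effect is shared within each pre/on pair
    mu <- sweep(outer(base_mu, exp(rep(pair_fx, 2L))), 2L, sf, "*")
    is_dr_on <- c(resp == "DR", rep(FALSE, n_on))
    mu[, is_dr_on] <- mu[, is_dr_on] * 2^effect
    meta <- data.frame(
      sample_id = sample_ids,
      response_label = rep(resp, 2L),
      timepoint = rep(c("on", "pre"), each = n_on),
      pair_id = rep(sprintf("pair%02d", seq_len(n_on)), 2L),
      cohort = "synthetic", stringsAsFactors = FALSE)
  } else {
    sample_ids <- on_ids
    mu <- sweep(matrix(base_mu, cfg$n_genes, n_on), 2L, sf, "*")
    mu[, resp == "DR"] <- mu[, resp == "DR"] * 2^effect
    meta <- data.frame(sample_id = sample_ids, response_label = resp,
                       timepoint = "on", pair_id = NA_character_,
                       cohort = "synthetic", stringsAsFactors = FALSE)
  }

  cnt <- with_seed(derive_seed(cfg$seed, "counts"),
                   matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                          nrow = cfg$n_genes,
                          dimnames = list(genes, sample_ids)))

  list(
    counts = expression_matrix(cnt, "counts"),
    gene_lengths = data.frame(gene_id = genes, length_bp = lengths,
                              stringsAsFactors = FALSE),
    samples = meta,
    gene_sets = list(CAF_markers = caf, G2M_checkpoint = g2m, E2F_targets = e2f),
    truth = list(planted_stroma = planted_up, delta_up = cfg$delta_up,
                 planted_proliferation = planted_down, delta_down = -cfg$delta_down,
                 base_means = stats::setNames(base_mu, genes),
                 dispersion = cfg$dispersion, seed = cfg$seed)
  )
}

#' Write a simulated cohort to the formats the pipeline consumes
#'
#' Emits the counts matrix (TSV), gene lengths (TSV), sample metadata
#' (TSV) and the gene sets (GMT) under a directory.
#'
#' @param cohort list from [generate_expression_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.table(cohort$gene_lengths, file.path(dir, "gene_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
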