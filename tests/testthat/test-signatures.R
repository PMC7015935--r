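test_that("cohort-mean normalization has unit per-gene mean and handles toys", {
  fpkm <- make_fpkm(rbind(c(4, 8), c(5, 5), c(0, 0)))
  norm <- mean_normalize(fpkm)
  expect_equal(unname(rowMeans(unclass(norm))), rep(1, 3), tolerance = 1e-12)
  # values >> eps: 4 and 8 normalize to ~ 2/3 and 4/3
  expect_equal(unname(unclass(norm)["g1", ]), c(2 / 3, 4 / 3), tolerance = 1e-2)
  # constant gene -> all ones
  expect_equal(unname(unclass(norm)["g2", ]), c(1, 1), tolerance = 1e-12)
  # all-zero gene -> eps/eps = 1, keeping the geometric mean defined
  expect_equal(unname(unclass(norm)["g3", ]), c(1, 1), tolerance = 1e-12)
  expect_error(mean_normalize(fpkm, character(0)), "empty")
  expect_error(mean_normalize(fpkm, "nope"), "nope")
})

test_that("stroma signature takes the top-k CAF markers by p among significant up-genes", {
  set.seed(3)
  de <- data.frame(
    gene_id = sprintf("caf%02d", 1:12),
    log2fc = c(rep(2, 11), 2),          # all up
    p_value = c(sort(runif(11, 1e-6, 0.04)), 0.2),
    stringsAsFactors = FALSE)
  # add background genes that must never enter the signature
  bg <- data.frame(gene_id = sprintf("bg%02d", 1:5), log2fc = 3,
                   p_value = 1e-8, stringsAsFactors = FALSE)
  tab <- rbind(de, bg)
  sig <- derive_stroma_signature(tab, caf_markers = de$gene_id, k = 10)
  expect_s3_class(sig, "signature_set")
  expect_identical(sig$direction, "up_in_responders")
  # the 10 smallest qualifying p-values; caf12 (p = 0.2) excluded by alpha
  expect_identical(sort(sig$gene_ids),
                   sort(de$gene_id[order(de$p_value)][1:10]))
  expect_false("caf12" %in% sig$gene_ids)
  expect_false(any(grepl("^bg", sig$gene_ids)))

  # fewer than k candidates -> all returned with a warning
  few <- tab[tab$gene_id %in% sprintf("caf%02d", 1:6), ]
  expect_warning(s6 <- derive_stroma_signature(few, few$gene_id, k = 10), "6")
  expect_length(s6$gene_ids, 6)

  none <- data.frame(gene_id = "caf01", log2fc = -2, p_value = 0.001)
  expect_error(derive_stroma_signature(none, "caf01"), "no CAF marker")
})

test_that("stroma tie-breaking is deterministic: p, then |log2fc|, then gene id", {
  de <- data.frame(
    gene_id = c("b", "a", "c"),
    log2fc = c(1, 1, 2),
    p_value = c(0.01, 0.01, 0.01),
    stringsAsFactors = FALSE)
  sig <- derive_stroma_signature(de, de$gene_id, k = 2)
  expect_identical(sig$gene_ids, c("c", "a"))
})

test_that("proliferation signature merges G2M/E2F uniquely with inclusive threshold", {
  de <- data.frame(
    gene_id = c("shared", "g2m_only", "e2f_only", "weak", "up", "boundary"),
    log2fc = c(-2, -1.4, -1.8, -0.6, 1.5, -1.0),
    p_value = rep(0.01, 6),
    stringsAsFactors = FALSE)
  sig <- derive_proliferation_signature(
    de, g2m = c("shared", "g2m_only", "weak", "boundary"),
    e2f = c("shared", "e2f_only", "up"))
  expect_identical(sig$direction, "down_in_responders")
  # shared gene appears once; log2fc = -1.0 included (threshold inclusive)
  expect_setequal(sig$gene_ids, c("shared", "g2m_only", "e2f_only", "boundary"))
  expect_identical(sum(sig$gene_ids == "shared"), 1L)
  expect_false("weak" %in% sig$gene_ids)  # |lfc| < 1
  expect_false("up" %in% sig$gene_ids)    # up, not down

  allup <- data.frame(gene_id = "x", log2fc = 2, p_value = 0.5)
  expect_error(derive_proliferation_signature(allup, "x", "x"), "down-regulated")
})

test_that("geometric-mean score equals exp(mean(log)) and matches brute force", {
  vals <- rbind(g1 = c(0.5, 1, 1), g2 = c(2, 1, 2), g3 = c(1, 1, 4))
  colnames(vals) <- c("s1", "s2", "s3")
  norm <- expression_matrix(vals, "normalized")
  sig2 <- signature_set("toy", c("g1", "g2"), "up_in_responders")
  sc <- geometric_mean_score(norm, sig2)
  expect_equal(unname(sc["s1"]), 1)        # sqrt(0.5 * 2)
  expect_equal(unname(sc["s2"]), 1)        # all ones
  sig3 <- signature_set("toy3", c("g1", "g2", "g3"), "up_in_responders")
  expect_equal(unname(geometric_mean_score(norm, sig3)["s3"]), 2)  # (1*2*4)^(1/3)

  # brute-force product-then-root on random matrices
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(rlnorm(40), 8, 5,
                dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:5)))
    nm <- expression_matrix(m, "normalized")
    sig <- signature_set("r", sprintf("g%d", sample(8, 4)), "up_in_responders")
    brute <- apply(m[sig$gene_ids, ], 2, function(col) prod(col)^(1 / length(col)))
    expect_equal(geometric_mean_score(nm, sig), brute, tolerance = 1e-10)
  }

  expect_error(geometric_mean_score(norm, signature_set("m", "gX", "up_in_responders")),
               "gX")
})

test_that("scores are invariant to per-gene scaling and equivariant to sample permutation", {
  set.seed(12)
  fpkm <- make_fpkm(matrix(rlnorm(60, 2, 1), 10, 6))
  sig <- signature_set("s", rownames(fpkm)[1:4], "up_in_responders")
  base_score <- geometric_mean_score(mean_normalize(fpkm), sig)

  scaled <- unclass(fpkm)
  scaled[2, ] <- scaled[2, ] * 57.3   # any positive per-gene rescaling
  scaled[7, ] <- scaled[7, ] * 0.01
  # scale invariance is exact in the eps = 0 limit; with the pseudocount it
  # holds to the precision eps admits at these magnitudes
  sc2 <- geometric_mean_score(mean_normalize(expression_matrix(scaled, "fpkm")), sig)
  expect_equal(sc2, base_score, tolerance = 1e-2)

  perm <- sample(ncol(fpkm))
  fp <- expression_matrix(unclass(fpkm)[, perm], "fpkm")
  scp <- geometric_mean_score(mean_normalize(fp), sig)
  expect_equal(scp, base_score[perm], tolerance = 1e-12)

  # gene order within the signature does not matter
  sig_rev <- signature_set("s", rev(sig$gene_ids), "up_in_responders")
  expect_equal(geometric_mean_score(mean_normalize(fpkm), sig_rev), base_score)
})

test_that("combination classifier applies the log-ratio rule and trains by Youden's J", {
  scores <- data.frame(
    sample_id = c("a", "b"),
    stroma_score = c(2.0, 0.5),
    proliferation_score = c(0.5, 2.0))
  out <- combination_classify(scores, threshold = 0)
  expect_identical(out$predicted_label, c("responder", "nonresponder"))

  # perfectly separable training set -> 100/100 on training data
  sep <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    stroma_score = c(3, 2.5, 2.8, 3.2, 0.6, 0.5, 0.7, 0.9),
    proliferation_score = c(0.4, 0.5, 0.3, 0.6, 2.1, 1.8, 2.4, 1.5),
    true_label = rep(c("DR", "NR"), each = 4))
  cls <- combination_classify(sep)
  cm <- confusion_metrics(sep$true_label, cls$predicted_label, "DR", "responder")
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100)

  expect_error(combination_classify(scores, truth = NULL), "threshold or training")
})

test_that("trained threshold matches an exhaustive sweep on an overlapping 4+4 cohort", {
  scores <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    stroma_score = exp(c(1.0, 0.8, 0.9, 0.1, 0.2, 0.0, -0.1, 0.5)),
    proliferation_score = rep(1, 8),
    true_label = rep(c("DR", "NR"), each = 4))
  comb <- log(scores$stroma_score)
  is_pos <- scores$true_label == "DR"

  # brute-force sweep over every candidate threshold (midpoints between
  # adjacent distinct scores, plus the minimum)
  u <- sort(unique(comb))
  cand <- c(u[1], (u[-1] + u[-length(u)]) / 2)
  j <- sapply(cand, function(t) {
    pred <- comb >= t
    sum(pred & is_pos) / sum(is_pos) + sum(!pred & !is_pos) / sum(!is_pos) - 1
  })
  best <- min(cand[j == max(j)])

  cls <- combination_classify(scores)
  expect_equal(attr(cls, "threshold"), best)
  expect_identical(cls$predicted_label, ifelse(comb >= best, "responder", "nonresponder"))
})

test_that("the alternative two-threshold rule classifies each axis independently", {
  scores <- data.frame(
    sample_id = c("a", "b", "c"),
    stroma_score = c(2, 2, 0.5),
    proliferation_score = c(0.5, 2, 0.5))
  out <- combination_classify(scores, rule = "two_threshold",
                              stroma_threshold = 1, proliferation_threshold = 1)
  expect_identical(out$predicted_label,
                   c("responder", "nonresponder", "nonresponder"))
})

test_that("signatures round-trip through GMT with provenance side-car", {
  prov <- data.frame(gene_id = c("a", "b"), log2fc = c(2, 1.5),
                     p_value = c(0.001, 0.01))
  sig <- signature_set("stroma", c("a", "b"), "up_in_responders", prov)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_signature(sig, path)
  sets <- read_gmt(path)
  expect_identical(sets$stroma, c("a", "b"))
  side <- read.delim(paste0(path, ".provenance.tsv"))
  expect_equal(side$log2fc, prov$log2fc)
})

test_that("planted effects separate group score medians across seeds", {
  hits <- vapply(1:50, function(seed) {
    co <- generate_expression_cohort(sim_config(seed = seed))
    fpkm <- counts_to_fpkm(co$counts, co$gene_lengths)
    norm <- mean_normalize(fpkm)
    stroma <- signature_set("planted_stroma", co$truth$planted_stroma,
                            "up_in_responders")
    prolif <- signature_set("planted_prolif", co$truth$planted_proliferation,
                            "down_in_responders")
    s <- geometric_mean_score(norm, stroma)
    p <- geometric_mean_score(norm, prolif)
    dr <- co$samples$sample_id[co$samples$response_label == "DR"]
    nr <- co$samples$sample_id[co$samples$response_label == "NR"]
    ok_s <- median(s[dr]) > median(s[nr]) &&
      mann_whitney_u(s[dr], s[nr])$p_value < 0.05
    ok_p <- median(p[dr]) < median(p[nr]) &&
      mann_whitney_u(p[dr], p[nr])$p_value < 0.05
    ok_s && ok_p
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
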