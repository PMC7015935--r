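test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 300, seed = 42)
  a <- generate_expression_cohort(cfg)
  b <- generate_expression_cohort(cfg)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$gene_lengths, b$gene_lengths)
  expect_identical(a$truth$planted_stroma, b$truth$planted_stroma)
  c2 <- generate_expression_cohort(sim_config(n_genes = 300, seed = 43))
  expect_false(identical(unclass(a$counts), unclass(c2$counts)))
})

test_that("planted subsets sit inside their marker sets and config is validated", {
  co <- generate_expression_cohort(sim_config(n_genes = 500, seed = 1))
  expect_true(all(co$truth$planted_stroma %in% co$gene_sets$CAF_markers))
  cc <- union(co$gene_sets$G2M_checkpoint, co$gene_sets$E2F_targets)
  expect_true(all(co$truth$planted_proliferation %in% cc))
  expect_length(cc, 120)
  expect_length(intersect(co$gene_sets$G2M_checkpoint, co$gene_sets$E2F_targets), 20)
  expect_identical(ncol(co$counts), 14L)
  expect_identical(sum(co$samples$response_label == "DR"), 6L)

  expect_error(sim_config(n_caf_markers = 5, n_planted_stroma = 10), "planted stroma")
  expect_error(sim_config(n_genes = 100), "exceed")
  expect_error(sim_config(dispersion = 0), "positive")
})

test_that("empirical gene means track the configured means at large n", {
  cfg <- sim_config(n_genes = 60, n_dr = 100L, n_nr = 100L,
                    n_caf_markers = 10, n_planted_stroma = 0, delta_up = 0,
                    n_g2m = 10, n_e2f = 10, n_cellcycle_overlap = 5,
                    n_planted_prolif = 0, delta_down = 0,
                    libsize_sdlog = 0, dispersion = 0.2, seed = 7)
  co <- generate_expression_cohort(cfg)
  mu <- co$truth$base_means
  emp <- rowMeans(unclass(co$counts))
  se <- sqrt((mu + 0.2 * mu^2) / 200)
  z <- abs(emp - mu) / se
  # ~99.7% of genes expected inside 3 SE; allow the occasional tail draw
  expect_gte(mean(z <= 3), 0.95)
  expect_true(all(z <= 5))
})

test_that("null configuration yields uniform DE p-values at planted positions", {
  fracs <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_genes = 2000, delta_up = 0, delta_down = 0,
                      dispersion = 0.1, n_dr = 8L, n_nr = 8L, seed = seed)
    co <- generate_expression_cohort(cfg)
    filt <- filter_low_expression(co$counts)
    sf <- estimate_size_factors(filt)
    de <- nb_two_group_test(filt, co$samples, sf)
    mean(de$p_value < 0.05)
  }, numeric(1))
  expect_true(abs(mean(fracs) - 0.05) <= 0.02)
})

test_that("paired generation produces valid pre/on pairs sharing a random effect", {
  cfg <- sim_config(n_genes = 300, paired_timepoints = TRUE, seed = 3)
  co <- generate_expression_cohort(cfg)
  expect_identical(ncol(co$counts), 28L)
  tab <- table(co$samples$pair_id)
  expect_true(all(tab == 2))
  by_pair <- split(co$samples$timepoint, co$samples$pair_id)
  expect_true(all(vapply(by_pair, function(tp) setequal(tp, c("pre", "on")), logical(1))))
  # written files satisfy the reader's pairing validation
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_silent(read_sample_table(file.path(dir, "samples.tsv")))
})

test_that("written cohorts round-trip through the package readers", {
  co <- generate_expression_cohort(sim_config(n_genes = 200, seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  cnt <- read_expression_matrix(file.path(dir, "counts.tsv"), "counts")
  expect_equal(unclass(cnt), unclass(co$counts))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(sets$CAF_markers, co$gene_sets$CAF_markers)
})

test_that("tumor volume implements the ellipsoid formula and is symmetric", {
  expect_equal(tumor_volume(10, 10, 10), 1000 * pi / 6)
  expect_equal(round(tumor_volume(10, 10, 10), 3), 523.599)
  expect_equal(tumor_volume(5, 0, 3), 0)
  expect_error(tumor_volume(-1, 2, 3), "non-negative")

  set.seed(14)
  for (i in 1:1000) {
    d <- runif(3, 0, 20)
    p <- sample(3)
    expect_equal(tumor_volume(d[1], d[2], d[3]),
                 tumor_volume(d[p[1]], d[p[2]], d[p[3]]), tolerance = 1e-12)
  }
})

test_that("growth simulation labels archetypes sensibly and meets the endpoint rule", {
  sim <- simulate_growth_and_label(n_treated = 40, n_control = 10, seed = 8)
  g <- sim$growth
  s <- sim$survival
  expect_true(all(abs(g$volume - g$L * g$W * g$D * pi / 6) < 1e-9))
  expect_setequal(unique(s$group), c("anti-PD-1", "IgG"))
  expect_true(all(s$event %in% c(0L, 1L)))

  # events occur exactly when the trajectory reaches the 1500 mm^3 burden
  for (id in s$subject_id) {
    traj <- g[g$tumor_id == id, ]
    srow <- s[s$subject_id == id, ]
    if (srow$event == 1) {
      expect_gte(max(traj$volume), 1500)
      expect_equal(srow$time, traj$day[which(traj$volume >= 1500)[1]])
    } else {
      expect_lt(max(traj$volume), 1500)
    }
  }

  # monotone-decreasing trajectories label DR; monotone-increasing label NR
  treated <- unique(g$tumor_id[g$arm == "anti-PD-1"])
  for (id in treated) {
    traj <- g[g$tumor_id == id, ]
    if (all(diff(traj$volume) < 0)) expect_identical(traj$response_category[1], "DR")
    if (all(diff(traj$volume) > 0) && nrow(traj) > 3)
      expect_identical(traj$response_category[1], "NR")
  }
  # control arm never mounts a durable response under the rule set
  expect_false(any(s$response_category[s$group == "IgG"] == "DR"))
})
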