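test_that("config validation enforces the documented ranges", {
  expect_error(sim_config(planted_sign_prob = 0.4), "planted_sign_prob")
  expect_error(sim_config(planted_rank_geometric_p = 0), "geometric_p")
  expect_error(sim_config(n_genes = 10, n_planted_aad = 8,
                          n_planted_common = 8), "exceed the gene universe")
  expect_error(sim_config(n_planted_aad = 80, n_planted_common = 30,
                          list_depth = 100), "list capacity")
  expect_error(sim_config(noise_logfc_sd = 0), "noise_logfc_sd")
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  cfg <- sim_config(seed = 5, n_genes = 80, diseases = tiny_registry(),
                    n_planted_aad = 4, n_planted_common = 4, list_depth = 15)
  a <- gen_ranked_lists(cfg)
  b <- gen_ranked_lists(cfg)
  expect_identical(a, b)
  expect_identical(gen_comparisons(cfg, a$truth),
                   gen_comparisons(cfg, b$truth))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(cfg, d1)
  p2 <- write_simulation(cfg, d2)
  for (nm in names(p1))
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])))

  # a different seed changes the draw
  cfg2 <- sim_config(seed = 6, n_genes = 80, diseases = tiny_registry(),
                     n_planted_aad = 4, n_planted_common = 4,
                     list_depth = 15)
  expect_false(identical(gen_ranked_lists(cfg2)$ranked, a$ranked))
})

test_that("ground truth partitions the universe and is seed-stable", {
  cfg <- sim_config(seed = 9, n_genes = 50, diseases = tiny_registry(),
                    n_planted_aad = 5, n_planted_common = 5, list_depth = 12)
  tr <- ground_truth(cfg)
  all_genes <- c(tr$planted_aad$gene, tr$planted_common$gene, tr$null_genes)
  expect_equal(sort(all_genes), sprintf("G%05d", 1:50))
  expect_equal(anyDuplicated(all_genes), 0L)
  expect_true(all(tr$planted_aad$direction %in% c(-1L, 1L)))
  expect_identical(ground_truth(cfg), tr)
})

test_that("at the geometric limit planted genes occupy the top ranks", {
  cfg <- sim_config(seed = 2, n_genes = 100, diseases = tiny_registry(),
                    n_planted_aad = 4, n_planted_common = 4,
                    planted_rank_geometric_p = 1, list_depth = 20)
  sim <- gen_ranked_lists(cfg)
  planted_all <- c(sim$truth$planted_aad$gene, sim$truth$planted_common$gene)
  for (d in c("aad1", "aad2")) {
    top8 <- sim$ranked$gene[sim$ranked$disease == d & sim$ranked$rank <= 8]
    expect_setequal(top8, planted_all)
  }
  # in NAAD diseases only common-planted genes carry the advantage
  for (d in c("naad1", "naad2")) {
    top4 <- sim$ranked$gene[sim$ranked$disease == d & sim$ranked$rank <= 4]
    expect_setequal(top4, sim$truth$planted_common$gene)
  }
})

test_that("planted genes out-occur null genes across AAD lists", {
  occ_gap <- replicate(10, {
    seed <- sample.int(1e6, 1)
    cfg <- sim_config(seed = seed, n_genes = 300,
                      diseases = tiny_registry(),
                      n_planted_aad = 5, n_planted_common = 5,
                      list_depth = 30)
    sim <- gen_ranked_lists(cfg)
    aad <- sim$ranked[sim$ranked$disease %in% c("aad1", "aad2"), ]
    occ <- table(factor(aad$gene, levels = sprintf("G%05d", 1:300)))
    mean(occ[sim$truth$planted_aad$gene]) - mean(occ[sim$truth$null_genes])
  })
  expect_true(all(occ_gap > 0))
})

test_that("comparison counts follow the registry and planted signs are exact", {
  cfg <- sim_config(seed = 4, n_genes = 40, diseases = tiny_registry(),
                    n_planted_aad = 3, n_planted_common = 3,
                    planted_sign_prob = 1, list_depth = 10)
  sim <- gen_ranked_lists(cfg)
  rec <- gen_comparisons(cfg, sim$truth)
  cnt <- table(rec$disease) / 40
  expect_equal(as.numeric(cnt[tiny_registry()$disease]),
               as.numeric(tiny_registry()$n_comparisons))
  # sign_prob = 1: every planted comparison in the relevant category carries
  # the planted sign, so frac_up is exactly 0 or 1
  prof <- consistency_profiles(rec, genes = sim$truth$planted_aad$gene)
  dirs <- setNames(sim$truth$planted_aad$direction,
                   sim$truth$planted_aad$gene)
  expect_true(all(prof$frac_up[dirs[prof$gene] == 1L] == 1))
  expect_true(all(prof$frac_down[dirs[prof$gene] == -1L] == 1))
})

test_that("null-gene sign fractions follow the binomial null", {
  # one disease class with many comparisons; KS test of frac_up across null
  # genes against Binomial(n, 1/2)/n
  reg <- data.frame(disease = "aad1", category = "AAD",
                    disease_class = "neurological", n_comparisons = 20L,
                    stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 12, n_genes = 500, diseases = reg,
                    n_planted_aad = 0, n_planted_common = 0, list_depth = 50)
  rec <- gen_comparisons(cfg, ground_truth(cfg))
  prof <- consistency_profiles(rec, threshold = 0.6)
  expect_equal(nrow(prof), 500L)
  counts <- round(prof$frac_up * 20)
  expected <- dbinom(0:20, 20, 0.5) * 500
  observed <- tabulate(counts + 1, nbins = 21)
  # chi-squared on pooled tails to keep expected counts reasonable
  keep <- expected >= 5
  chi <- sum((observed[keep] - expected[keep])^2 / expected[keep]) +
    (sum(observed[!keep]) - sum(expected[!keep]))^2 / sum(expected[!keep])
  dfree <- sum(keep)  # bins - 1 (+1 pooled bin)
  expect_lt(chi, qchisq(0.999, dfree))
})

test_that("planted dual-purpose genes are recovered with high sensitivity", {
  # four AAD classes with eight comparisons each, 200 planted genes at the
  # default 0.9 sign-agreement probability
  reg <- data.frame(
    disease = paste0("aad", 1:4), category = "AAD",
    disease_class = c("neurological", "metabolic", "inflammatory",
                      "fibrotic"),
    n_comparisons = 8L, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 33, n_genes = 300, diseases = reg,
                    n_planted_aad = 200, n_planted_common = 0,
                    planted_sign_prob = 0.9, list_depth = 250)
  tr <- ground_truth(cfg)
  rec <- gen_comparisons(cfg, tr)
  prof <- consistency_profiles(rec, genes = tr$planted_aad$gene)
  dual <- dual_purpose_filter(prof, min_classes = 2L)
  sens <- length(intersect(dual$gene, tr$planted_aad$gene)) /
    nrow(tr$planted_aad)
  expect_gte(sens, 0.9)
  # recovered directions match the planted directions
  dirs <- setNames(ifelse(tr$planted_aad$direction == 1L, "up", "down"),
                   tr$planted_aad$gene)
  unambig <- dual[!dual$ambiguous, ]
  expect_true(all(unambig$direction == dirs[unambig$gene]))
})
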