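test_that("consistency calls follow the sign fractions, boundary inclusive", {
  m <- matrix(c(1, 2, 0.5, 0.1, 3), nrow = 1,
              dimnames = list("A", NULL))
  rec <- records_from_matrix(m, "aad1", "AAD", "neurological")
  prof <- consistency_profile(rec, "A", "neurological")
  expect_equal(prof$frac_up, 1)
  expect_equal(prof$call, "up")

  # 3 of 5 up is exactly 0.60 and meets the threshold (inclusive)
  m2 <- matrix(c(1, 1, 1, -1, -1), nrow = 1, dimnames = list("A", NULL))
  rec2 <- records_from_matrix(m2, "aad1", "AAD", "neurological")
  expect_equal(consistency_profile(rec2, "A", "neurological")$call, "up")

  # zero logFC counts toward neither direction
  m3 <- matrix(c(1, 1, -1, -1, 0), nrow = 1, dimnames = list("A", NULL))
  rec3 <- records_from_matrix(m3, "aad1", "AAD", "neurological")
  p3 <- consistency_profile(rec3, "A", "neurological")
  expect_equal(p3$frac_up, 0.4)
  expect_equal(p3$frac_down, 0.4)
  expect_equal(p3$call, "inconsistent")

  expect_error(consistency_profile(rec3, "A", "fibrotic"), "no AAD")
  expect_error(consistency_profiles(rec3, threshold = 0.5), "threshold")
})

test_that("profiles match a brute-force sign-counting oracle", {
  set.seed(21)
  classes <- c("neurological", "metabolic", "inflammatory", "fibrotic")
  for (i in 1:30) {
    recs <- do.call(rbind, lapply(seq_along(classes), function(ci) {
      m <- matrix(sample(c(-2, -1, 0, 1, 2), 4 * 5, replace = TRUE),
                  nrow = 4, dimnames = list(sprintf("g%d", 1:4), NULL))
      records_from_matrix(m, paste0("d", ci), "AAD", classes[ci])
    }))
    thr <- sample(c(0.6, 0.75, 1), 1)
    prof <- consistency_profiles(recs, threshold = thr)
    for (j in seq_len(nrow(prof))) {
      sub <- recs$logfc[recs$gene == prof$gene[j] &
                        recs$disease_class == prof$disease_class[j]]
      fu <- sum(sub > 0) / length(sub)
      fd <- sum(sub < 0) / length(sub)
      expect_equal(prof$frac_up[j], fu)
      expect_equal(prof$frac_down[j], fd)
      expect_equal(prof$call[j],
                   if (fu >= thr) "up" else if (fd >= thr) "down"
                   else "inconsistent")
    }
  }
})

test_that("profiles are order-invariant, scale-invariant, and threshold-monotone", {
  set.seed(8)
  m <- matrix(rnorm(6 * 7), nrow = 6, dimnames = list(sprintf("g%d", 1:6), NULL))
  rec <- records_from_matrix(m, "aad1", "AAD", "neurological")
  prof <- consistency_profiles(rec)
  expect_equal(consistency_profiles(rec[sample(nrow(rec)), ]), prof)
  rec_scaled <- rec
  rec_scaled$logfc <- rec$logfc * 17.3
  expect_equal(consistency_profiles(rec_scaled), prof)

  # raising the threshold never turns inconsistent into a direction call
  for (thr in c(0.6, 0.7, 0.8, 0.9, 1)) {
    p_lo <- consistency_profiles(rec, threshold = 0.6)
    p_hi <- consistency_profiles(rec, threshold = thr)
    was_inc <- p_lo$call == "inconsistent"
    expect_true(all(p_hi$call[was_inc] == "inconsistent"))
  }
})

test_that("dual-purpose filter equals exhaustive enumeration on small instances", {
  classes <- c("neurological", "metabolic", "inflammatory", "fibrotic")
  set.seed(31)
  for (i in 1:40) {
    ng <- sample(2:6, 1)
    prof <- expand.grid(gene = sprintf("g%d", seq_len(ng)),
                        disease_class = classes,
                        stringsAsFactors = FALSE)
    prof$n_comparisons <- 5L
    prof$call <- sample(c("up", "down", "inconsistent"), nrow(prof),
                        replace = TRUE)
    prof$frac_up <- ifelse(prof$call == "up", 0.8, 0.2)
    prof$frac_down <- ifelse(prof$call == "down", 0.8, 0.2)
    mc <- sample(1:3, 1)
    got <- dual_purpose_filter(prof, min_classes = mc)
    # oracle: enumerate every (gene, direction, class subset)
    for (g in unique(prof$gene)) {
      for (dir in c("up", "down")) {
        consistent <- prof$disease_class[prof$gene == g & prof$call == dir]
        expected_in <- length(consistent) >= mc
        row <- got[got$gene == g & got$direction == dir, ]
        expect_equal(nrow(row), as.integer(expected_in))
        if (expected_in) {
          expect_equal(row$n_classes_consistent, length(consistent))
          expect_equal(row$classes,
                       paste(sort(consistent), collapse = ";"))
        }
      }
    }
  }
})

test_that("dual-direction genes are emitted for both directions, flagged", {
  prof <- data.frame(
    gene = "g1",
    disease_class = c("neurological", "metabolic", "inflammatory",
                      "fibrotic"),
    n_comparisons = 5L,
    frac_up = c(0.9, 0.9, 0.1, 0.1), frac_down = c(0.1, 0.1, 0.9, 0.9),
    call = c("up", "up", "down", "down"), stringsAsFactors = FALSE)
  got <- dual_purpose_filter(prof, min_classes = 2L)
  expect_equal(nrow(got), 2L)
  expect_true(all(got$ambiguous))
  expect_setequal(got$direction, c("up", "down"))
  expect_error(dual_purpose_filter(prof, min_classes = 0L), "min_classes")
})

test_that("logFC group comparison reproduces the closed-form t CDF", {
  rec <- rbind(
    records_from_matrix(matrix(c(1.2, 0.8, 1.5, 0.9), nrow = 1,
                               dimnames = list("A", NULL)),
                        "aad1", "AAD", "neurological"),
    records_from_matrix(matrix(c(-0.3, 0.2, -0.6), nrow = 1,
                               dimnames = list("A", NULL)),
                        "naad1", "NAAD", "inflammatory"))
  got <- compare_logfc_groups(rec, "A")
  x <- c(1.2, 0.8, 1.5, 0.9); y <- c(-0.3, 0.2, -0.6)
  se <- sqrt(var(x) / 4 + var(y) / 3)
  tval <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  expect_equal(got$t_statistic, tval)
  expect_equal(got$df, df)
  expect_equal(got$p_value, 2 * pt(-abs(tval), df))

  # Student variant: pooled variance and n1 + n2 - 2 df
  got_s <- compare_logfc_groups(rec, "A", var.equal = TRUE)
  sp2 <- (3 * var(x) + 2 * var(y)) / 5
  t_s <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(got_s$t_statistic, t_s)
  expect_equal(got_s$df, 5)
  expect_equal(got_s$p_value, 2 * pt(-abs(t_s), 5))
})

test_that("logFC comparison handles degenerate separations and small n", {
  # identical AAD and NAAD vectors: t = 0, p = 1
  m_a <- matrix(c(0.5, -0.5, 1), nrow = 1, dimnames = list("A", NULL))
  m_n <- matrix(c(0.5, -0.5, 1), nrow = 1, dimnames = list("A", NULL))
  rec <- rbind(records_from_matrix(m_a, "aad1", "AAD", "neurological"),
               records_from_matrix(m_n, "naad1", "NAAD", "inflammatory"))
  got <- compare_logfc_groups(rec, "A")
  expect_equal(got$t_statistic, 0)
  expect_equal(got$p_value, 1)

  # near-complete separation drives p toward zero
  set.seed(2)
  m_a2 <- matrix(1 + rnorm(4, sd = 1e-3), nrow = 1, dimnames = list("B", NULL))
  m_n2 <- matrix(-1 + rnorm(4, sd = 1e-3), nrow = 1, dimnames = list("B", NULL))
  rec2 <- rbind(records_from_matrix(m_a2, "aad1", "AAD", "neurological"),
                records_from_matrix(m_n2, "naad1", "NAAD", "inflammatory"))
  expect_lt(compare_logfc_groups(rec2, "B")$p_value, 1e-6)

  rec3 <- rec2[c(1, 5:8), ]  # one AAD observation only
  expect_error(compare_logfc_groups(rec3, "B"), ">= 2")
})

test_that("the multi-gene comparison table adds a BH column", {
  set.seed(13)
  genes <- sprintf("g%d", 1:5)
  m_a <- matrix(rnorm(5 * 4), nrow = 5, dimnames = list(genes, NULL))
  m_n <- matrix(rnorm(5 * 4), nrow = 5, dimnames = list(genes, NULL))
  rec <- rbind(records_from_matrix(m_a, "aad1", "AAD", "neurological"),
               records_from_matrix(m_n, "naad1", "NAAD", "inflammatory"))
  tab <- compare_logfc_table(rec)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$p_bh, p.adjust(tab$p_value, "BH"))
  expect_true(!is.unsorted(tab$p_value))
})
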