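ann_row <- function(sample_id, patient_id, passage, dataset = "d1") {
  data.frame(sample_id = sample_id, patient_id = patient_id,
             dataset_id = dataset, passage_label = passage,
             cancer_type = "x", is_outlier = FALSE, stringsAsFactors = FALSE)
}

test_that("pair derivation enumerates biopsy and consecutive-passage pairs", {
  ann <- rbind(ann_row("s0", "p1", "F0"), ann_row("s1", "p1", "F1"),
               ann_row("s2", "p1", "F2"))
  p <- derive_pairs(ann)
  expect_identical(nrow(p), 3L)
  hx <- p[p$kind == "human_vs_xeno", ]
  expect_setequal(hx$sample_b, c("s1", "s2"))
  expect_true(all(hx$sample_a == "s0"))
  xx <- p[p$kind == "xeno_vs_xeno", ]
  expect_identical(xx$sample_a, "s1")
  expect_identical(xx$sample_b, "s2")

  # F0-only patient yields nothing; F? pairs only with F0
  expect_identical(nrow(derive_pairs(ann_row("s0", "p1", "F0"))), 0L)
  pq <- derive_pairs(rbind(ann_row("s0", "p1", "F0"), ann_row("sq", "p1", "F?")))
  expect_identical(pq$kind, "human_vs_xeno")
  expect_identical(pq$sample_b, "sq")

  # non-adjacent passages still chain in available order (F1 with F3)
  pg <- derive_pairs(rbind(ann_row("s0", "p1", "F0"), ann_row("s1", "p1", "F1"),
                           ann_row("s3", "p1", "F3")))
  xx <- pg[pg$kind == "xeno_vs_xeno", ]
  expect_identical(xx$sample_a, "s1"); expect_identical(xx$sample_b, "s3")

  # missing biopsy warns
  expect_warning(derive_pairs(rbind(ann_row("s1", "p1", "F1"),
                                    ann_row("s2", "p1", "F2"))), "no F0")
})

test_that("explicit pair files override derivation and are oriented", {
  ann <- rbind(ann_row("s0", "p1", "F0"), ann_row("s1", "p1", "F1"),
               ann_row("s2", "p1", "F2"))
  given <- data.frame(sample_a = c("s1", "s2"), sample_b = c("s0", "s1"))
  p <- derive_pairs(ann, pairs = given)
  # flipped so the biopsy / earlier passage is sample_a
  expect_identical(p$sample_a, c("s0", "s1"))
  expect_identical(p$kind, c("human_vs_xeno", "xeno_vs_xeno"))
  expect_error(derive_pairs(ann, pairs = data.frame(sample_a = "s0", sample_b = "zz")),
               "absent from sample sheet")
})

test_that("spearman_rcc matches hand example and rejects degenerate input", {
  expect_equal(spearman_rcc(1:5, 1:5), 1)
  expect_equal(spearman_rcc(1:5, 5:1), -1)
  expect_equal(spearman_rcc(c(1, 2, 2, 3), c(1, 3, 2, 4)), 0.9487, tolerance = 1e-4)
  expect_error(spearman_rcc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rcc(c(1, 2), c(1, 2)), "at least 3")
  expect_error(spearman_rcc(c(1, 2, NA), c(1, 2, 3)), "non-finite")
})

test_that("spearman_rcc equals the brute-force rank oracle and is monotone-invariant", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- sample(round(rnorm(n, 0, 2), 1))   # rounded -> frequent ties
    y <- round(x + rnorm(n, 0, 2), 1)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearman_rcc(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    # invariance under strictly increasing transforms of either argument
    expect_equal(spearman_rcc(exp(x / 2), y), spearman_rcc(x, y), tolerance = 1e-12)
    expect_equal(spearman_rcc(x, 3 * y + 10), spearman_rcc(x, y), tolerance = 1e-12)
  }
})

test_that("pair correlations score pairs over the gene vector", {
  m <- toy_expr(cbind(c(1, 5, 3, 4), c(1, 5, 3, 4), c(5, 1, 4, 2)),
                samples = c("s0", "s1", "s2"))
  ann <- rbind(ann_row("s0", "p1", "F0"), ann_row("s1", "p1", "F1"),
               ann_row("s2", "p1", "F2"))
  ct <- pair_correlations(m, derive_pairs(ann))
  # duplicate-column pair scores exactly 1
  expect_equal(ct$srcc[ct$sample_b == "s1" & ct$kind == "human_vs_xeno"], 1)
  expect_error(pair_correlations(m[, 1:2], derive_pairs(ann)), "missing from expression matrix")

  # empty pair table: empty result, undefined summary flagged by n = 0
  empty <- pair_correlations(m, derive_pairs(ann_row("s0", "p9", "F0")))
  expect_identical(nrow(empty), 0L)
  s <- correlation_summary(empty)
  expect_identical(s$n, 0L); expect_true(is.na(s$mean))
})

test_that("outlier rule uses mean minus k sample SDs with strict inequality", {
  # printed-summary arithmetic: mean 0.91, sd 0.10 -> threshold 0.76
  two <- 0.91 + c(-1, 1) * 0.10 / sqrt(2)
  expect_equal(mean(two), 0.91); expect_equal(sd(two), 0.10)
  expect_equal(outlier_threshold(two), 0.76, tolerance = 1e-12)

  # all values equal: sd 0, threshold = mean, nothing strictly below
  tbl <- data.frame(srcc = c(0.9, 0.9, 0.9))
  expect_false(any(flag_outliers(tbl, outlier_threshold(tbl$srcc))$outlier))

  # an unambiguous low pair is flagged; values at the threshold are not
  tbl2 <- data.frame(srcc = c(0.9, 0.92, 0.94, 0.91, 0.93, 0.2))
  th2 <- outlier_threshold(tbl2$srcc)   # 0.80 - 1.5 * 0.294 = 0.359
  fl <- flag_outliers(tbl2, th2)
  expect_identical(which(fl$outlier), 6L)
  expect_false(any(flag_outliers(data.frame(srcc = c(0.9, 0.9, 0.9, 0.9)), 0.9)$outlier))

  # flagged pairs all lie strictly below the threshold
  set.seed(42)
  v <- runif(50, 0.3, 1)
  th <- outlier_threshold(v)
  fl2 <- flag_outliers(data.frame(srcc = v), th)
  expect_true(all(fl2$srcc[fl2$outlier] < th))
  expect_true(all(fl2$srcc[!fl2$outlier] >= th))

  expect_error(outlier_threshold(0.9), ">= 2 correlations")
})

test_that("group comparison enumerates exactly for small samples and approximates for large", {
  # {1,2} vs {3,4}: two-sided exact p = 1/3
  expect_equal(suppressWarnings(compare_pair_groups(c(1, 2), c(3, 4)))$p.value,
               1 / 3, tolerance = 1e-12)
  # identical groups: p = 1
  expect_equal(suppressWarnings(compare_pair_groups(c(1, 2, 3), c(1, 2, 3)))$p.value, 1)
  # single-value group: warning, exact used
  expect_warning(compare_pair_groups(1.5, c(2, 3, 4)), "exact test used")

  # exact equals the full-permutation oracle for n <= 8
  set.seed(43)
  for (i in 1:10) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- sample(seq(0.1, 0.8, by = 0.01), n1)
    y <- sample(seq(0.81, 1.6, by = 0.01), n2) - runif(1, 0, 0.8)
    p_pkg <- compare_pair_groups(x, y)$p.value
    expect_equal(p_pkg, oracle_wilcox_p(x, y), tolerance = 1e-12)
  }

  # exact and approximate agree within 0.02 at n = 15 vs 15
  set.seed(44)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  approx_p <- compare_pair_groups(x, y)$p.value          # combined n > 20
  exact_p <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.02)
})

test_that("synthetic default cohort: engraftment pairs correlate lower than passage pairs", {
  coh <- default_cohort()
  pairs <- default_cohort_pairs()
  ct <- pair_correlations(coh$expr, pairs)
  ct <- flag_outliers(ct, outlier_threshold(ct$srcc))
  hx <- ct$srcc[ct$kind == "human_vs_xeno" & !ct$outlier]
  xx <- ct$srcc[ct$kind == "xeno_vs_xeno" & !ct$outlier]
  expect_lt(mean(hx), mean(xx))
  expect_lt(compare_pair_groups(hx, xx)$p.value, 0.05)
})
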