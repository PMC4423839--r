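pair_row <- function(a, b, kind = "human_vs_xeno", patient = "p1", ds = "d1") {
  data.frame(pair_id = paste(a, b, sep = "|"), sample_a = a, sample_b = b,
             kind = kind, patient_id = patient, dataset_id = ds,
             stringsAsFactors = FALSE)
}

test_that("fold-change screening thresholds log2 differences, boundary inclusive", {
  lfc <- log2(1.5)
  # g1 sits exactly on the log2(1.5) boundary (0 baseline keeps it exact)
  m <- toy_expr(cbind(c(0, 4, 2, 1, 2.5), c(lfc, 3, 2, 1.3, 2)),
                samples = c("h", "x"))
  de <- differential_genes(m, pair_row("h", "x"))
  expect_identical(de$up, "g1")                     # boundary inclusive
  expect_identical(de$down, "g2")                   # -1 change
  expect_false("g4" %in% c(de$up, de$down))         # |0.3| < lfc of ~0.585
  # a 0.3 shift stays non-differential
  m2 <- toy_expr(cbind(3, 3.3), samples = c("h", "x"))
  de2 <- differential_genes(m2, pair_row("h", "x"))
  expect_length(c(de2$up, de2$down), 0L)
  # 5-gene toy with deltas (+1, -1, 0, +0.6, -0.5): up {g1, g4}, down {g2}
  m3 <- toy_expr(cbind(rep(3, 5), 3 + c(1, -1, 0, 0.6, -0.5)),
                 samples = c("h", "x"))
  de3 <- differential_genes(m3, pair_row("h", "x"))
  expect_setequal(de3$up, c("g1", "g4"))
  expect_identical(de3$down, "g2")
  # linear-scale input refused
  lin <- toy_expr(cbind(3, 6), samples = c("h", "x"), scale = "linear")
  expect_error(differential_genes(lin, pair_row("h", "x")), "log2-scale")
})

test_that("consensus selection applies both thresholds with documented strictness", {
  # gene A: 3 datasets, 6/10 patients -> selected
  # gene B: 2 datasets only -> rejected; gene C: exactly half patients -> rejected
  mk <- function(gene, patient, ds)
    data.frame(pair_id = paste0(patient, "_pair"), kind = "human_vs_xeno",
               patient_id = patient, dataset_id = ds, gene_id = gene,
               direction = "up", stringsAsFactors = FALSE)
  patients <- sprintf("p%02d", 1:10)
  ds_of <- rep(c("d1", "d2", "d3", "d4", "d5"), each = 2)
  pairs <- do.call(rbind, lapply(1:10, function(i)
    pair_row(paste0(patients[i], "_F0"), paste0(patients[i], "_F1"),
             patient = patients[i], ds = ds_of[i])))
  de <- rbind(
    do.call(rbind, lapply(1:6, function(i) mk("A", patients[i], ds_of[i]))),
    do.call(rbind, lapply(1:6, function(i) mk("B", patients[i], rep(c("d1", "d2"), 3)[i]))),
    do.call(rbind, lapply(1:5, function(i) mk("C", patients[i], ds_of[i]))))
  de$pair_id <- paste0(de$patient_id, "_F0|", de$patient_id, "_F1")
  cons <- consensus_genes(de, pairs)
  expect_identical(cons$gene_id, "A")
  expect_identical(cons$n_datasets_hit, 3L)
  expect_equal(cons$patient_fraction, 0.6)
  # permutation invariance in row order
  perm <- sample(nrow(de))
  expect_identical(consensus_genes(de[perm, ], pairs[sample(nrow(pairs)), ])$gene_id, "A")
  # configurable thresholds
  expect_setequal(consensus_genes(de, pairs, min_datasets = 2L,
                                  min_patient_fraction = 0.4)$gene_id,
                  c("A", "B", "C"))
  # no human-vs-xeno pairs is an error
  xx <- pairs; xx$kind <- "xeno_vs_xeno"
  expect_error(consensus_genes(de, xx), "no human-vs-xeno pairs")
})

test_that("leave-one-out drops datasets one at a time and intersects", {
  patients <- sprintf("p%02d", 1:8)
  ds_of <- rep(c("d1", "d2", "d3", "d4"), each = 2)
  pairs <- do.call(rbind, lapply(1:8, function(i)
    pair_row(paste0(patients[i], "a"), paste0(patients[i], "b"),
             patient = patients[i], ds = ds_of[i])))
  # gene X hit by every patient, gene Y only via dataset d1's patients + d2 + d3
  de_all <- do.call(rbind, lapply(1:8, function(i)
    data.frame(pair_id = pairs$pair_id[i], kind = "human_vs_xeno",
               patient_id = patients[i], dataset_id = ds_of[i],
               gene_id = "X", direction = "down", stringsAsFactors = FALSE)))
  de_y <- do.call(rbind, lapply(c(1, 2, 3, 5), function(i)
    data.frame(pair_id = pairs$pair_id[i], kind = "human_vs_xeno",
               patient_id = patients[i], dataset_id = ds_of[i],
               gene_id = "Y", direction = "up", stringsAsFactors = FALSE)))
  de <- rbind(de_all, de_y)
  loo <- leave_one_out(de, pairs, min_datasets = 3L, min_patient_fraction = 0.4)
  expect_identical(sort(names(loo$per_drop)), c("d1", "d2", "d3", "d4"))
  # X survives every drop
  expect_true(all(vapply(loo$per_drop, function(g) "X" %in% g, logical(1))))
  expect_identical(loo$intersection, "X")
  # Y misses its 0.4 patient fraction once d1 (two of its patients) is gone
  expect_false("Y" %in% loo$per_drop$d1)
  expect_error(leave_one_out(de, pairs[pairs$dataset_id %in% c("d1", "d2"), ]),
               ">= 3 datasets")
})

test_that("identical dataset copies leave the consensus invariant under any drop", {
  patients <- sprintf("q%02d", 1:8)
  ds_of <- rep(c("d1", "d2", "d3", "d4"), times = 2)
  pairs <- do.call(rbind, lapply(1:8, function(i)
    pair_row(paste0(patients[i], "a"), paste0(patients[i], "b"),
             patient = patients[i], ds = ds_of[i])))
  de <- do.call(rbind, lapply(1:8, function(i)
    data.frame(pair_id = pairs$pair_id[i], kind = "human_vs_xeno",
               patient_id = patients[i], dataset_id = ds_of[i],
               gene_id = c("A", "B"), direction = "down",
               stringsAsFactors = FALSE)))
  loo <- leave_one_out(de, pairs, min_datasets = 3L, min_patient_fraction = 0.5)
  for (d in names(loo$per_drop)) expect_setequal(loo$per_drop[[d]], c("A", "B"))
  expect_setequal(loo$intersection, c("A", "B"))
})

test_that("hypergeometric enrichment matches exact enumeration and hand examples", {
  # universe 10, term 4, query 5, overlap 4 -> p = 6/252
  universe <- sprintf("u%02d", 1:10)
  term <- universe[1:4]
  query <- c(universe[1:4], universe[10])
  e <- enrich(query, universe, list(t = term))
  expect_equal(e$p_value, 6 / 252, tolerance = 1e-12)

  # enumeration oracle over all universes <= 12
  set.seed(51)
  for (i in 1:12) {
    nu <- sample(5:12, 1); nt <- sample(2:(nu - 1), 1); nq <- sample(2:(nu - 1), 1)
    u <- sprintf("v%02d", seq_len(nu))
    tset <- u[seq_len(nt)]
    q <- sample(u, nq)
    ov <- length(intersect(q, tset))
    e <- enrich(q, u, list(t = tset))
    expect_equal(e$p_value, oracle_hyper_p(nu, nt, nq, ov), tolerance = 1e-12)
  }

  # disjoint term: p is the full lower tail mass, never 0
  e2 <- enrich(universe[5:8], universe, list(t = universe[1:2]))
  expect_gt(e2$p_value, 0.1)
  expect_error(enrich(character(), universe, list(t = term)), "empty query")
  expect_error(enrich("zz", universe, list(t = term)), "outside the universe")
})

test_that("BH adjustment matches the hand step-up procedure", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.06), method = "BH"),
               c(0.03, 0.03, 0.06), tolerance = 1e-12)
  set.seed(52)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone nondecreasing along sorted raw p, bounded by 1
  p <- sort(runif(15))
  adj <- p.adjust(p, method = "BH")
  expect_true(all(diff(adj) >= -1e-15))
  expect_true(all(adj <= 1 & adj >= p))
})

test_that("robustness score is the fraction of pairs where the term is enriched", {
  # direct arithmetic: term enriched in the 4 pairs that carry the planted
  # genes, absent in the 1 pair that does not -> 4/5; empty pairs excluded
  universe <- sprintf("w%03d", 1:200)
  term <- universe[1:10]
  sets <- list(hit = term, other = universe[51:60])
  pairs <- do.call(rbind, lapply(1:6, function(i)
    pair_row(paste0("a", i), paste0("b", i), patient = paste0("p", i),
             ds = "d1")))
  de <- do.call(rbind, lapply(1:5, function(i) {
    genes <- if (i <= 4) term else universe[101:110]
    data.frame(pair_id = pairs$pair_id[i], kind = "human_vs_xeno",
               patient_id = pairs$patient_id[i], dataset_id = "d1",
               gene_id = genes, direction = "down", stringsAsFactors = FALSE)
  }))  # pair 6 has an empty differential set
  expect_equal(robustness_score("hit", de, pairs, universe, sets), 4 / 5)
  expect_equal(robustness_score("other", de, pairs, universe, sets), 0)
  expect_error(robustness_score("nope", de, pairs, universe, sets),
               "absent from the annotation")
})

test_that("planted engraftment term is robust on the synthetic cohort, decoys are not", {
  coh <- default_cohort()
  pairs <- default_cohort_pairs()
  ct <- pair_correlations(coh$expr, pairs)
  keep <- pairs[!flag_outliers(ct, outlier_threshold(ct$srcc))$outlier, ]
  de <- differential_table(coh$expr, keep)
  sets <- generate_gene_sets(coh$truth, n_decoy_terms = 10L, seed = 1L)
  rs <- robustness_scores(de, keep, rownames(coh$expr), sets)
  expect_gte(rs[["engraftment"]], 0.75)
  expect_true(all(rs[setdiff(names(rs), "engraftment")] <= 0.2))
})

test_that("drug interaction counts join both directions", {
  dm <- list(A = c("d1", "d2"), C = c("d1", "d3", "d4", "d5"))
  res <- count_interacting_drugs(c("A", "B"), dm)
  expect_equal(res$genes$n_drugs[res$genes$gene_id == "A"], 2L)
  expect_equal(res$genes$n_drugs[res$genes$gene_id == "B"], 0L)
  expect_setequal(res$drugs$drug_id, c("d1", "d2"))
  expect_true(all(res$drugs$n_genes == 1L))
  # empty map: all zeros
  res0 <- count_interacting_drugs(c("A", "B"), list())
  expect_true(all(res0$genes$n_drugs == 0L))
  expect_identical(nrow(res0$drugs), 0L)
  # a drug hitting 4 query genes counts 4
  dm4 <- list(G1 = "dx", G2 = "dx", G3 = "dx", G4 = "dx")
  res4 <- count_interacting_drugs(c("G1", "G2", "G3", "G4"), dm4)
  expect_identical(res4$drugs$n_genes, 4L)
})
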