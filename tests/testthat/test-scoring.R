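make_em <- function(values, gene_ids = rownames(values),
                    cell_ids = colnames(values)) {
  # ExpressionMatrix wrapper for matrices built directly in tests
  structure(list(values = values, source_total = rep(1, ncol(values)),
                 scale_factor = 1e4, gene_ids = gene_ids,
                 cell_ids = cell_ids,
                 cell_meta = data.frame(cell_id = cell_ids,
                                        sample_id = "S1", patient_id = "P1",
                                        population_label = NA)),
            class = "ExpressionMatrix")
}

test_that("module score is zero on a constant matrix and matches the exhaustive-control oracle", {
  v <- matrix(3, 10, 4, dimnames = list(sprintf("G%02d", 1:10),
                                        sprintf("c%d", 1:4)))
  em <- make_em(v)
  expect_equal(unname(module_score(em, c("G01", "G02"), seed = 1)),
               rep(0, 4))

  set.seed(31)
  v2 <- matrix(rexp(6 * 2), 6, 2, dimnames = list(sprintf("G%d", 1:6),
                                                  c("c1", "c2")))
  em2 <- make_em(v2)
  # one bin and n_ctrl = bin size: controls are exactly all non-set genes
  got <- module_score(em2, c("G1", "G4"), n_bins = 1, n_ctrl = 4, seed = 7)
  expect_equal(unname(got), bf_module_score_1bin(v2, c("G1", "G4")),
               tolerance = 1e-10)
  # invariant to gene order within the set
  expect_equal(module_score(em2, c("G4", "G1"), n_bins = 1, n_ctrl = 4, seed = 7),
               got)
})

test_that("module score errors when no set gene is present and warns-drops unmatched symbols", {
  em <- make_em(matrix(1:12, 4, 3,
                       dimnames = list(sprintf("G%d", 1:4), sprintf("c%d", 1:3))))
  expect_error(module_score(em, c("NOPE1", "NOPE2"), seed = 1),
               class = "missing_genes_error")
  expect_message(s <- module_score(em, c("G1", "NOPE"), n_bins = 1,
                                   n_ctrl = 3, seed = 1), "dropped 1/2")
  expect_length(s, 3)
})

test_that("random gene sets score near zero on average (null expectation)", {
  # needs a universe large enough for the quantile bins to hold genuine
  # expression-matched controls
  fx <- cohort_fixture()
  em <- log_normalize(apply_qc(fx$counts))
  set.seed(99)
  draw_means <- vapply(1:200, function(i) {
    s <- sample(em$gene_ids, 10)
    mean(module_score(em, s, seed = i))
  }, numeric(1))
  se <- stats::sd(draw_means) / sqrt(length(draw_means))
  expect_lt(abs(mean(draw_means)), 3 * se)
})

test_that("cycle scores: zeros on identical cells, equivariant to cell permutation, planted program detected", {
  cc <- default_cycle_genes()
  gene_ids <- c(cc$G1S, cc$G2M, sprintf("F%03d", 1:150))
  v <- matrix(2.5, length(gene_ids), 6,
              dimnames = list(gene_ids, sprintf("c%d", 1:6)))
  em <- make_em(v)
  cs <- cycle_scores(em, seed = 3)
  expect_equal(unname(cs$g1s), rep(0, 6))
  expect_equal(unname(cs$g2m), rep(0, 6))

  set.seed(17)
  n_cells <- 200
  v2 <- matrix(rexp(length(gene_ids) * n_cells), length(gene_ids), n_cells,
               dimnames = list(gene_ids, sprintf("c%03d", 1:n_cells)))
  planted <- 1:100
  v2[cc$G1S, planted] <- v2[cc$G1S, planted] + 2
  em2 <- make_em(v2)
  cs2 <- cycle_scores(em2, seed = 3)
  expect_lt(stats::wilcox.test(cs2$g1s[planted], cs2$g1s[-planted],
                               alternative = "greater")$p.value, 0.01)

  perm <- sample(n_cells)
  em_perm <- make_em(v2[, perm])
  cs_perm <- cycle_scores(em_perm, seed = 3)
  expect_equal(unname(cs_perm$g1s), unname(cs2$g1s[perm]), tolerance = 1e-12)
})

test_that("ssgsea score matches the brute-force weighted-ECDF oracle and is rank-invariant", {
  set.seed(41)
  v <- matrix(rexp(10 * 3), 10, 3,
              dimnames = list(sprintf("G%02d", 1:10), c("c1", "c2", "c3")))
  em <- make_em(v)
  set_genes <- c("G02", "G05", "G09")
  got <- ssgsea_score(em, set_genes, exponent = 0.25)
  is_set <- rownames(v) %in% set_genes
  for (ci in 1:3) {
    expect_equal(unname(got[ci]), bf_ssgsea_cell(v[, ci], is_set, 0.25),
                 tolerance = 1e-10)
  }
  # rank invariance: a monotone transform leaves scores unchanged
  em_t <- make_em(v^3)
  expect_equal(ssgsea_score(em_t, set_genes), got, tolerance = 1e-12)
})

test_that("ssgsea is maximal when set genes hold the top ranks", {
  n <- 12
  gene_ids <- sprintf("G%02d", seq_len(n))
  vals <- seq_len(n)  # distinct values to permute
  set_genes <- c("G01", "G02", "G03")
  is_set <- gene_ids %in% set_genes
  score_for <- function(assign) {
    v <- matrix(assign, n, 1, dimnames = list(gene_ids, "c1"))
    unname(ssgsea_score(make_em(v), set_genes))
  }
  top <- numeric(n)
  top[is_set] <- c(12, 11, 10)
  top[!is_set] <- 9:1
  best <- score_for(top)
  set.seed(13)
  for (i in 1:50) expect_lte(score_for(sample(vals)), best + 1e-12)
})

test_that("ssgsea null (random set assignment) has mean near zero", {
  # at exponent 0 the in/out-set exchangeability argument is exact; the
  # rank-weighted variant (exponent > 0) carries a small positive offset
  # that cancels in contrasts
  set.seed(57)
  n <- 100
  v <- matrix(rexp(n), n, 1, dimnames = list(sprintf("G%03d", 1:n), "c1"))
  em <- make_em(v)
  draws <- vapply(1:500, function(i) {
    unname(ssgsea_score(em, sample(rownames(v), 8), exponent = 0))
  }, numeric(1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("GSVA-like walk matches brute force, rescales to [0,1] with correct extremes, flips sign on reversal", {
  set.seed(23)
  v <- matrix(rexp(8 * 3), 8, 3,
              dimnames = list(sprintf("G%d", 1:8), c("c1", "c2", "c3")))
  em <- make_em(v)
  sets <- list(S = c("G2", "G5"))
  raw <- gsva_like_score(em, sets, rescale = FALSE)
  is_set <- rownames(v) %in% sets$S
  for (ci in 1:3) {
    expect_equal(unname(raw["S", ci]), bf_gsva_walk_cell(v[, ci], is_set),
                 tolerance = 1e-10)
  }
  # reversing the within-cell ranking flips the raw score sign
  raw_rev <- gsva_like_score(make_em(-v), sets, rescale = FALSE)
  expect_equal(unname(raw_rev["S", ]), -unname(raw["S", ]), tolerance = 1e-10)

  # extremes: all set genes top in one cell, bottom in another
  n <- 10
  gene_ids <- sprintf("G%02d", 1:n)
  top <- c(10, 9, 8:1); bottom <- c(1, 2, 10:3); mid <- c(5, 6, c(10, 9, 8, 7, 4, 3, 2, 1))
  v2 <- cbind(c1 = top, c2 = bottom, c3 = mid)
  rownames(v2) <- gene_ids
  sc <- gsva_like_score(make_em(v2), list(S = c("G01", "G02")))
  expect_equal(unname(sc["S", "c1"]), 1)
  expect_equal(unname(sc["S", "c2"]), 0)
  expect_true(all(sc >= 0 & sc <= 1))

  expect_error(gsva_like_score(make_em(v[, 1, drop = FALSE]), sets),
               class = "degenerate_input_error")
})

test_that("preranked GSEA: brute-force ES, bounds, determinism, and top-set significance", {
  set.seed(61)
  w <- sort(stats::rnorm(8), decreasing = TRUE)
  names(w) <- sprintf("G%d", 1:8)
  sets <- list(S = c("G2", "G3", "G7"))
  res <- preranked_gsea(w, sets, n_perm = 200, seed = 4)
  expect_equal(res$ES, bf_gsea_es(w, names(w) %in% sets$S), tolerance = 1e-10)

  # a set made of the top 5 genes of a 100-gene ranking is enriched
  w2 <- sort(stats::rnorm(100, sd = 2), decreasing = TRUE)
  names(w2) <- sprintf("R%03d", 1:100)
  res2 <- preranked_gsea(w2, list(top = names(w2)[1:5],
                                  rand = names(w2)[seq(10, 90, by = 10)]),
                         n_perm = 1000, seed = 9)
  top_row <- res2[res2$set == "top", ]
  expect_gt(top_row$ES, 0)
  expect_lt(top_row$p_nominal, 0.05)
  expect_true(all(abs(res2$ES) <= 1))
  expect_true(all(res2$p_nominal > 0 & res2$p_nominal <= 1))
  expect_true(all(res2$fdr_q >= 0 & res2$fdr_q <= 1))
  # leading edge is inside the set
  le <- strsplit(top_row$leading_edge, ",")[[1]]
  expect_true(all(le %in% names(w2)[1:5]))

  # bit-identical reproduction under the same seed
  res2b <- preranked_gsea(w2, list(top = names(w2)[1:5],
                                   rand = names(w2)[seq(10, 90, by = 10)]),
                          n_perm = 1000, seed = 9)
  expect_identical(res2, res2b)

  expect_warning(res3 <- preranked_gsea(w, list(S = "G2", none = "ZZZ"),
                                        n_perm = 50, seed = 1),
                 "skipped")
  expect_identical(res3$set, "S")
})

test_that("GSEA enrichment score agrees with an independent implementation", {
  set.seed(77)
  stats_vec <- sort(stats::rnorm(100), decreasing = TRUE)
  names(stats_vec) <- sprintf("R%03d", 1:100)
  for (size in c(5, 15, 40)) {
    sel <- sort(sample(100, size))
    ours <- preranked_gsea(stats_vec,
                           list(S = names(stats_vec)[sel]),
                           n_perm = 1, seed = 1)$ES
    ref <- fgsea::calcGseaStat(stats_vec, selectedStats = sel, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("immune score separates planted immune cells from CTCs", {
  fx <- cohort_fixture()
  cm <- apply_qc(fx$counts)
  em <- log_normalize(cm)
  truth <- fx$truth$cell$population[match(cm$cell_ids, fx$truth$cell$cell_id)]
  imm <- immune_score(em)
  is_immune <- truth %in% c("T", "B", "monocyte")
  is_ctc <- truth == "CTC"
  expect_gt(mean(imm[is_immune]), mean(imm[is_ctc]))
  expect_lt(stats::wilcox.test(imm[is_immune], imm[is_ctc],
                               alternative = "greater")$p.value, 1e-3)
})
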