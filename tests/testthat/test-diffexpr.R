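# homogeneous NB-with-dropout count matrix built directly
sim_nb_cm <- function(n_genes, n_cells, mu = 2, theta = 0.5, dropout = 0.3,
                      seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * n_cells, size = theta, mu = mu) *
                stats::rbinom(n_genes * n_cells, 1, 1 - dropout),
              n_genes, n_cells)
  count_matrix(m, sprintf("G%04d", seq_len(n_genes)),
               sprintf("c%04d", seq_len(n_cells)))
}

test_that("BH adjustment equals the brute-force step-up on the worked example and random vectors", {
  expect_equal(stats::p.adjust(c(.01, .02, .03, .04), "BH"),
               rep(.04, 4))
  expect_equal(bf_bh(c(.01, .02, .03, .04)), rep(.04, 4))
  set.seed(44)
  for (i in 1:1000) {
    p <- stats::runif(sample(3:20, 1))
    expect_equal(stats::p.adjust(p, "BH"), bf_bh(p), tolerance = 1e-12)
  }
})

test_that("group swap negates fold changes and preserves p-values; invalid groups error", {
  cm <- sim_nb_cm(60, 24, seed = 5)
  a <- cm$cell_ids[1:12]; b <- cm$cell_ids[13:24]
  de_ab <- de_two_group(cm, a, b)
  de_ba <- de_two_group(cm, b, a)
  expect_equal(de_ab$log2_fc, -de_ba$log2_fc, tolerance = 1e-12)
  expect_equal(de_ab$p_raw, de_ba$p_raw, tolerance = 1e-12)
  expect_equal(de_ab$mean_a, de_ba$mean_b, tolerance = 1e-12)

  expect_error(de_two_group(cm, a, c(b, a[1])), class = "validation_error")
  expect_error(de_two_group(cm, a[1:2], b), class = "degenerate_input_error")
})

test_that("rank-sum p-values match the statistic computed by hand on a tie-free toy", {
  set.seed(71)
  n <- 10
  m <- matrix(c(sample(1:60, n * 6)), n, 6)
  cm <- count_matrix(m, sprintf("G%d", 1:n), sprintf("c%d", 1:6))
  # equal library sizes are not guaranteed; check on the same normalized
  # values the implementation tests
  totals <- Matrix::colSums(cm$counts)
  vals <- log1p(sweep(as.matrix(cm$counts), 2, 1e4 / totals, "*"))
  de <- de_two_group(cm, cm$cell_ids[1:3], cm$cell_ids[4:6])
  for (g in 1:n) {
    W <- bf_ranksum_W(vals[g, 1:3], vals[g, 4:6])
    ref <- suppressWarnings(stats::wilcox.test(vals[g, 1:3], vals[g, 4:6],
                                               exact = TRUE))
    expect_equal(unname(ref$statistic), W, tolerance = 1e-10)
    expect_equal(de$p_raw[g], ref$p.value, tolerance = 1e-10)
  }
})

test_that("null comparisons call no genes and control type I error", {
  # two random halves of one homogeneous population, 20 seeded runs
  clean_runs <- vapply(1:20, function(s) {
    cm <- sim_nb_cm(300, 60, seed = 100 + s)
    set.seed(200 + s)
    idx <- sample(60)
    de <- de_two_group(cm, cm$cell_ids[idx[1:30]], cm$cell_ids[idx[31:60]])
    sum(de$p_adj < .05 & abs(de$log2_fc) > 1) == 0
  }, logical(1))
  expect_gte(mean(clean_runs), 0.95)

  # raw type-I rate within the binomial 99% CI of 0.05
  cm <- sim_nb_cm(2000, 200, seed = 7)
  de <- de_two_group(cm, cm$cell_ids[1:100], cm$cell_ids[101:200])
  rate <- mean(de$p_raw < .05)
  half <- 2.576 * sqrt(.05 * .95 / 2000)
  expect_lt(abs(rate - .05), half)
})

test_that("a planted 4x shift is detected with >=95% power and the expected fold change", {
  # balanced up/down planting keeps library sizes comparable between the
  # groups so normalization does not bias the fold-change estimate
  for (s in 1:3) {
    set.seed(700 + s)
    n_genes <- 500; n_per <- 100
    mu <- matrix(2, n_genes, 2 * n_per)
    up <- 1:25; down <- 26:50
    mu[up, 1:n_per] <- 8                 # 4x in group A
    mu[down, n_per + 1:n_per] <- 8       # 4x in group B
    m <- matrix(stats::rnbinom(length(mu), size = 0.5, mu = as.vector(mu)),
                n_genes, 2 * n_per)
    cm <- count_matrix(m, sprintf("G%03d", 1:n_genes),
                       sprintf("c%04d", 1:(2 * n_per)))
    de <- de_two_group(cm, cm$cell_ids[1:n_per], cm$cell_ids[n_per + 1:n_per])
    power <- mean(c(de$p_adj[up] < .05 & de$log2_fc[up] > 0,
                    de$p_adj[down] < .05 & de$log2_fc[down] < 0))
    expect_gte(power, 0.95)
    # the fold-change estimate is centered where a 4x shift puts it
    mean_abs_fc <- mean(abs(de$log2_fc[c(up, down)]))
    expect_gte(mean_abs_fc, 1.5)
    expect_lte(mean_abs_fc, 2.5)
    # stringent calls are nested inside lenient calls
    strict <- de$p_adj < .05 & de$log2_fc > 1
    lenient <- de$p_raw < .05 & de$log2_fc > log2(1.5)
    expect_true(all(lenient[strict]))
  }
})

test_that("patient signatures recover planted programs with little cross-assignment", {
  gen <- generate_synthetic(synthetic_config(
    n_patients = 5, cells_per_patient = 150, n_genes = 1000,
    n_patient_program_genes = 30, seed = 13))
  cm <- gen$counts
  sigs <- patient_signatures(cm)
  for (p in names(gen$truth$patient_programs)) {
    planted <- gen$truth$patient_programs[[p]]
    expect_gte(mean(planted %in% sigs[[p]]), 0.90)
    others <- unlist(gen$truth$patient_programs[setdiff(names(sigs), p)])
    expect_lte(mean(others %in% sigs[[p]]), 0.05)
  }
  expect_error(patient_signatures(subset_counts(
    cm, cells = cm$cell_meta$patient_id == "P1")),
    class = "validation_error")
})

test_that("identical patients yield only chance-level signatures", {
  gen <- generate_synthetic(synthetic_config(
    n_patients = 2, cells_per_patient = 80, n_genes = 700,
    n_patient_program_genes = 0, seed = 29))
  sigs <- patient_signatures(gen$counts)
  for (s in sigs) expect_lte(length(s), 0.05 * nrow(gen$counts$counts))
})

test_that("stage-biased genes are recovered with the correct sign", {
  gen <- generate_synthetic(synthetic_config(
    n_patients = 2, cells_per_patient = 100, n_genes = 700,
    n_patient_program_genes = 10, seed = 37))
  cm <- gen$counts
  stages <- stats::setNames(ifelse(cm$cell_meta$patient_id == "P1",
                                   "early", "late"), cm$cell_ids)
  res <- stage_biased_genes(cm, stages)
  up_late_planted <- gen$truth$patient_programs$P2
  up_early_planted <- gen$truth$patient_programs$P1
  expect_gte(mean(up_late_planted %in% res$up_late), 0.9)
  expect_gte(mean(up_early_planted %in% res$up_early), 0.9)
  expect_length(intersect(res$up_late, up_early_planted), 0)

  few <- stats::setNames(c("early", "early", rep("late", 10)),
                         cm$cell_ids[1:12])
  expect_error(stage_biased_genes(subset_counts(cm, cells = 1:12), few),
               class = "degenerate_input_error")
})

test_that("panel selection applies all four criteria with the documented ranking", {
  de <- data.frame(
    gene_id = c("A", "B", "C", "D", "E"),
    mean_a = c(50, 40, 30, 20, 10), mean_b = c(1, 1, 1, 25, 1),
    detect_frac_a = c(0.9, 0.8, 0.6, 0.9, 0.4),
    detect_frac_b = c(0.01, 0.02, 0.01, 0.01, 0.0),
    log2_fc = c(4, 3, 2, 0.5, 3),
    p_raw = c(1e-8, 1e-7, 1e-5, 0.2, 1e-4),
    p_adj = c(1e-6, 1e-5, 1e-3, 0.3, 1e-2))
  panel <- select_panel(de)
  # D fails log2_fc/p, E fails detect_frac_ctc; order by detection gap
  expect_identical(panel$gene_id, c("A", "B", "C"))
  expect_identical(select_panel(de, within.list(default_panel_criteria(),
                                                panel_size <- 1))$gene_id, "A")
  expect_warning(
    empty <- select_panel(de, within.list(default_panel_criteria(),
                                          max_p_adj <- 0)),
    "empty panel")
  expect_identical(nrow(empty), 0L)
})

test_that("panel criteria admit exactly a planted tumor program", {
  gen <- generate_synthetic(synthetic_config(
    n_patients = 1, cells_per_patient = 200, n_genes = 700,
    composition = c(T = 0.3, B = 0.05, monocyte = 0.15, CTC = 0.5),
    n_patient_program_genes = 0, seed = 41))
  cm <- gen$counts
  tr <- gen$truth$cell
  ctc <- tr$cell_id[tr$population == "CTC"]
  normal <- tr$cell_id[tr$population != "CTC"]
  de <- de_two_group(cm, ctc, normal)
  panel <- select_panel(de)
  planted <- gen$truth$programs$CTC
  expect_true(all(panel$gene_id %in% planted))
  expect_true(all(diff(panel$detection_gap) <= 1e-12))
})
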