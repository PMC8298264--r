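test_that("condition means average replicates per gene", {
  vals <- matrix(c(2, 0, 4, 0, 6, 0, 1, 0, 2, 0, 3, 0), 2, 6,
                 dimnames = list(c("a", "zero"), NULL))
  cm <- condition_means(toy_matrix(vals))
  expect_equal(cm$mean_wt, c(4, 0))
  expect_equal(cm$mean_ko, c(2, 0))
})

test_that("t-test matches the closed-form pooled and Welch oracles", {
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4), equal_variance = TRUE)
  o <- oracle_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r$df, 4)
  expect_equal(r$p, o$p, tolerance = 1e-9)

  w <- two_sample_t(c(0, 0.1), c(10, 10.1), equal_variance = FALSE)
  ow <- oracle_t(c(0, 0.1), c(10, 10.1), equal_variance = FALSE)
  expect_lt(w$p, 0.05)
  expect_equal(w$p, ow$p, tolerance = 1e-9)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("degenerate zero-variance groups are flagged, not errors", {
  r <- two_sample_t(c(2, 2), c(2, 2))
  expect_true(r$zero_variance)
  expect_equal(r$p, 1)
  r2 <- two_sample_t(c(2, 2), c(3, 3))
  expect_true(r2$zero_variance)
  expect_equal(r2$p, 0)
})

test_that("t-test agrees with the oracle on the exhaustive small grid", {
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3, e = 0:3, f = 0:3)
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    x <- as.numeric(grid[i, 1:3]); y <- as.numeric(grid[i, 4:6])
    r <- two_sample_t(x, y)
    if (r$zero_variance) {
      expect_true(var(x) == 0 && var(y) == 0)
      next
    }
    o <- oracle_t(x, y)
    worst <- max(worst, abs(r$p - o$p), abs(r$t - o$t))
  }
  expect_lt(worst, 1e-9)
})

test_that("log2 fold change uses the floor only for zero means", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(40, 5), 3)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_equal(log2_fold_change(0, 3, floor = 1), log2(1 / 4))
})

test_that("DE selection applies strict p and fold-change rules", {
  tab <- data.frame(gene_id = paste0("g", 1:5),
                    log2fc = c(3, 1, 5, -2.5, -1.9),
                    p = c(.01, .01, .2, .01, .04))
  sel <- select_de_genes(tab)
  expect_setequal(sel$gene_id, c("g1", "g4"))
  expect_equal(sel$direction[sel$gene_id == "g1"], "up")
  expect_equal(sel$direction[sel$gene_id == "g4"], "down")

  expect_equal(nrow(select_de_genes(tab[0, ])), 0L)

  boundary <- data.frame(gene_id = c("x", "y"), log2fc = c(2, -2),
                         p = c(.001, .001))
  expect_equal(nrow(select_de_genes(boundary)), 0L)  # strict bounds
})

test_that("DE selection count equals a brute-force recount on random tables", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    tab <- data.frame(gene_id = paste0("g", seq_len(n)),
                      log2fc = rnorm(n, 0, 3),
                      p = runif(n))
    sel <- select_de_genes(tab)
    brute <- sum(vapply(seq_len(n), function(i)
      tab$p[i] < 0.05 && (tab$log2fc[i] < -2 || tab$log2fc[i] > 2),
      logical(1)))
    expect_equal(nrow(sel), brute)
  }
})

test_that("planted 8-fold genes are recovered by the DE table", {
  cfg <- synth_config(seed = 301)
  ex <- gen_expression(cfg)
  sel <- select_de_genes(de_table(ex$matrix))
  planted <- ex$truth$de_genes
  nulls <- setdiff(rownames(ex$matrix$values),
                   c(planted, ex$truth$complements))
  expect_gte(mean(planted %in% sel$gene_id), 0.90)
  expect_lte(mean(nulls %in% sel$gene_id), 0.05)
})

test_that("ddCt fold changes follow 2^(-ddCt)", {
  ctrl <- qpcr_record(ct_target = c(20, 20.2, 19.8),
                      ct_reference = c(15, 15.1, 14.9), group = "WT")
  same <- ddct_fold_change(ctrl, ctrl)
  expect_equal(same$ddct, 0)
  expect_equal(same$fold, 1)

  test1 <- qpcr_record(ct_target = c(19, 19.2, 18.8),
                       ct_reference = c(15, 15.1, 14.9), group = "KO")
  expect_equal(ddct_fold_change(test1, ctrl)$fold, 2)

  # a ddCt of -log2(300) is a 300-fold induction
  test2 <- qpcr_record(ct_target = ctrl$ct_target - log2(300),
                       ct_reference = ctrl$ct_reference, group = "KO")
  r <- ddct_fold_change(test2, ctrl)
  expect_equal(r$fold, 300, tolerance = 1e-9)
  expect_equal(r$ddct, -8.2288, tolerance = 1e-4)
})

test_that("TAS normalisation equalises totals and preserves ratios", {
  areas <- matrix(c(10, 30, 20, 60), 2, 2,
                  dimnames = list(NULL, c("A", "B")))
  t0 <- protein_quant_table(c("p1", "p2"), c(3, 5), areas)
  t1 <- tas_normalize(t0)
  expect_equal(t1$areas[, "A"], c(p1 = 15, p2 = 45))     # scaled by 1.5
  expect_equal(t1$areas[, "B"], c(p1 = 15, p2 = 45))     # scaled by 0.75
  expect_equal(diff(colSums(t1$areas)), c(B = 0), tolerance = 1e-9)
  expect_equal(t1$areas[1, ] / t1$areas[2, ], t0$areas[1, ] / t0$areas[2, ],
               tolerance = 1e-12)

  equal <- protein_quant_table("p", 3, matrix(c(5, 5), 1, 2))
  expect_equal(tas_normalize(equal)$areas, equal$areas)
  one <- protein_quant_table("p", 3, matrix(7, 1, 1))
  expect_equal(tas_normalize(one)$areas, one$areas)

  zero <- protein_quant_table(c("p1"), 3, matrix(c(1, 0), 1, 2,
                              dimnames = list(NULL, c("A", "B"))))
  expect_error(tas_normalize(zero), "zero total")
})

test_that("TAS totals equalise on random tables", {
  set.seed(5)
  for (rep in 1:10) {
    areas <- matrix(rlnorm(8 * 6, 3, 1), 8, 6,
                    dimnames = list(paste0("p", 1:8), paste0("s", 1:6)))
    t1 <- tas_normalize(protein_quant_table(paste0("p", 1:8), rep(3, 8), areas))
    expect_lt(max(abs(colSums(t1$areas) - mean(colSums(areas)))), 1e-9)
    expect_equal(sweep(t1$areas, 2, colSums(t1$areas), "/"),
                 sweep(areas, 2, colSums(areas), "/"), tolerance = 1e-12)
  }
})

test_that("peptide-count filtering keeps proteins with enough support", {
  t0 <- protein_quant_table(paste0("p", 1:4), 1:4,
                            matrix(1, 4, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(filter_by_peptide_count(t0)$protein_id, c("p3", "p4"))
  expect_equal(length(filter_by_peptide_count(t0, 1)$protein_id), 4L)
  empty <- filter_by_peptide_count(t0, 99)
  expect_equal(length(empty$protein_id), 0L)
})
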