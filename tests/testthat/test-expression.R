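test_that("TPM normalizes by length and sums to one million", {
  counts <- tibble::tibble(feature_id = c("a", "b"), length = c(1000L, 2000L),
                           s1 = c(100, 100), s2 = c(0, 0))
  expect_warning(tpm <- compute_tpm(counts), "all-zero column s2")
  expect_equal(tpm$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_true(all(is.na(tpm$s2)))
  single <- compute_tpm(tibble::tibble(feature_id = "a", length = 500L, s1 = 7))
  expect_equal(single$s1, 1e6)
  expect_error(compute_tpm(tibble::tibble(feature_id = "a", length = 0L, s1 = 1)),
               "> 0")
  # columns sum to 1e6 for random matrices
  set.seed(2)
  rc <- tibble::tibble(feature_id = sprintf("g%d", 1:50),
                       length = sample(200:3000, 50),
                       s1 = rpois(50, 40), s2 = rpois(50, 40))
  tp <- compute_tpm(rc)
  expect_equal(sum(tp$s1), 1e6, tolerance = 1e-6)
  expect_equal(sum(tp$s2), 1e6, tolerance = 1e-6)
})

test_that("expressed mask requires replicate-mean TPM above 1 in some stage", {
  tpm <- tibble::tibble(feature_id = c("a", "b", "c"), length = 1L,
                        MY_1 = c(0.5, 0, 2), MY_2 = c(0.5, 0, 0),
                        FB_1 = c(0.99, 1.01, 0), FB_2 = c(0.99, 1.01, 0))
  smp <- tibble::tibble(sample = c("MY_1", "MY_2", "FB_1", "FB_2"),
                        stage = c("MY", "MY", "FB", "FB"))
  m <- expressed_mask(tpm, smp)
  expect_equal(m$expressed, c(FALSE, TRUE, FALSE))  # strict >1; means 0.5/1.01/1
})

test_that("NB Wald test is symmetric, calibrated and powerful", {
  set.seed(5)
  n <- 2000L
  mu <- rlnorm(n, log(200), 0.8)
  cnt <- tibble::tibble(feature_id = sprintf("g%04d", 1:n), length = 1000L)
  for (s in c("A_1", "A_2", "A_3")) cnt[[s]] <- rnbinom(n, mu = mu, size = 20)
  for (s in c("B_1", "B_2", "B_3")) cnt[[s]] <- rnbinom(n, mu = mu, size = 20)
  smp <- tibble::tibble(sample = c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3"),
                        stage = rep(c("A", "B"), each = 3))
  de <- de_test(cnt, smp, "A", "B")
  expect_lte(mean(de$status != "none"), 0.02)
  # label symmetry
  rev <- de_test(cnt, smp, "B", "A")
  expect_equal(rev$log2fc, -de$log2fc)
  expect_equal(rev$qvalue, de$qvalue)
  # identical replicate counts -> lfc 0, none
  same <- tibble::tibble(feature_id = "g", length = 1L,
                         A_1 = 10, A_2 = 20, A_3 = 30,
                         B_1 = 10, B_2 = 20, B_3 = 30)
  de_same <- de_test(same, smp, "A", "B")
  expect_equal(de_same$log2fc, 0)
  expect_equal(de_same$status, "none")
  # all-zero feature untested
  zero <- dplyr::mutate(cnt, dplyr::across(dplyr::starts_with(c("A_", "B_")),
                                           ~ ifelse(feature_id == "g0001", 0, .x)))
  expect_true(is.na(de_test(zero, smp, "A", "B")$qvalue[1]))
  # power on a planted 8-fold shift
  idx <- 1:100
  cnt8 <- cnt
  for (s in c("B_1", "B_2", "B_3")) {
    cnt8[[s]][idx] <- rnbinom(100, mu = mu[idx] * 8, size = 20)
  }
  de8 <- de_test(cnt8, smp, "A", "B")
  expect_gte(mean(de8$status[idx] == "up"), 0.95)
})

test_that("NB Wald fold changes agree with DESeq2 on a shared dataset", {
  set.seed(8)
  n <- 300L
  mu <- rlnorm(n, log(150), 1)
  mu_b <- mu * 2^(sample(c(-2, 0, 2), n, replace = TRUE, prob = c(0.1, 0.8, 0.1)))
  cnt <- tibble::tibble(feature_id = sprintf("g%03d", 1:n), length = 1000L)
  for (s in c("A_1", "A_2", "A_3")) cnt[[s]] <- rnbinom(n, mu = mu, size = 20)
  for (s in c("B_1", "B_2", "B_3")) cnt[[s]] <- rnbinom(n, mu = mu_b, size = 20)
  smp <- tibble::tibble(sample = c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3"),
                        stage = rep(c("A", "B"), each = 3))
  de <- de_test(cnt, smp, "A", "B")
  mat <- as.matrix(cnt[, smp$sample])
  rownames(mat) <- cnt$feature_id
  dds <- DESeq2::DESeqDataSetFromMatrix(
    mat, S4Vectors::DataFrame(condition = factor(smp$stage)), ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  keep <- !is.na(res$padj)
  expect_gt(cor(de$log2fc[keep], res$log2FoldChange[keep]), 0.95)
  # significance calls largely agree
  agree <- mean((de$qvalue[keep] < 0.01 & abs(de$log2fc[keep]) > 1) ==
                  (res$padj[keep] < 0.01 & abs(res$log2FoldChange[keep]) > 1))
  expect_gt(agree, 0.9)
})

test_that("ortholog filtering applies both strict thresholds", {
  pairs <- tibble::tibble(gene_a = c("a", "b", "c", "d"),
                          gene_b = c("A", "B", "C", "D"),
                          consensus_fraction = c(0.80, 0.60, 0.80, 0.70),
                          consensus_length_bp = c(400L, 400L, 250L, 400L))
  kept <- filter_orthologs(pairs)$kept
  expect_equal(kept, c(TRUE, FALSE, FALSE, FALSE))  # 0.70 is not > 0.70
})

test_that("divergence classification is total over the nine status pairs", {
  grid <- tidyr::expand_grid(a = c("up", "down", "none"),
                             b = c("up", "down", "none"))
  cls <- classify_divergence(grid$a, grid$b)
  expect_equal(length(cls), 9L)
  expect_setequal(unique(cls),
                  c("DE0", "DE1-Pt", "DE1-Pe", "DE2-identical", "DE2-opposite"))
  expect_equal(classify_divergence("up", "none"), "DE1-Pt")
  expect_equal(classify_divergence("down", "down"), "DE2-identical")
  expect_equal(classify_divergence("up", "down"), "DE2-opposite")
  expect_equal(classify_divergence("none", "up"), "DE1-Pe")
  expect_equal(classify_divergence("none", "none"), "DE0")
})

test_that("fold-change correlations recover planted structure", {
  d <- tibble::tibble(gene_a = sprintf("g%d", 1:50), gene_b = sprintf("h%d", 1:50),
                      phase = "phase1", status_a = "none", status_b = "none",
                      log2fc_a = seq(-2, 2, length.out = 50),
                      log2fc_b = seq(-2, 2, length.out = 50),
                      class = "DE0")
  expect_equal(foldchange_correlation(d, "phase1")$estimate, 1)
  d$log2fc_b <- -d$log2fc_a
  expect_equal(foldchange_correlation(d, "phase1")$estimate, -1)
  # uncorrelated planted effects -> r ~ 0
  set.seed(3)
  d$log2fc_a <- rnorm(50)
  d$log2fc_b <- rnorm(50)
  big <- dplyr::bind_rows(purrr::map(1:40, ~ dplyr::mutate(d, gene_a = paste0(gene_a, .x))))
  big$log2fc_a <- rnorm(2000)
  big$log2fc_b <- rnorm(2000)
  expect_lt(abs(foldchange_correlation(big, "phase1")$estimate), 0.1)
  expect_error(foldchange_correlation(d[1:2, ], "phase1"), "fewer than 3")
})

test_that("methylation-expression correlation handles subsets and degeneracy", {
  set.seed(6)
  lev <- runif(100)
  tpm <- 10^(2 - 3 * lev + rnorm(100, 0, 0.3))
  res <- methylation_expression_correlation(lev, tpm)
  expect_lt(res$estimate, -0.8)
  expect_lt(res$p.value, 1e-6)
  expect_warning(r0 <- methylation_expression_correlation(rep(0.5, 10), runif(10)),
                 "degenerate")
  expect_true(is.na(r0$estimate))
  # permutation: shuffled labels give weak correlation
  expect_lt(abs(methylation_expression_correlation(sample(lev), tpm)$estimate), 0.25)
})

test_that("TE expression summary counts expressed elements per class and stage", {
  tes <- tibble::tibble(id = sprintf("te%d", 1:4),
                        te_class = c("Gypsy", "Gypsy", "LINE", "DNA"))
  tpm <- tibble::tibble(feature_id = sprintf("te%d", 1:4), length = 500L,
                        MY_1 = c(0, 5, 0, 0), MY_2 = c(0, 7, 0, 0),
                        FB_1 = c(2, 0, 0, 0), FB_2 = c(2, 0, 0, 0))
  smp <- tibble::tibble(sample = c("MY_1", "MY_2", "FB_1", "FB_2"),
                        stage = c("MY", "MY", "FB", "FB"))
  s <- te_expression_summary(tes, tpm, smp)
  gy_my <- s[s$te_class == "Gypsy" & s$stage == "MY", ]
  expect_equal(gy_my$n_total, 2L)
  expect_equal(gy_my$n_expressed, 1L)
  expect_equal(gy_my$proportion, 0.5)
  expect_equal(s$n_expressed[s$te_class == "DNA"], c(0L, 0L))
  expect_false("Copia" %in% s$te_class)
})
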