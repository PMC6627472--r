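test_that("simulated annotation places non-overlapping features deterministically", {
  cfg <- sim_config(seed = 5, n_genes = 40L, n_tes = 30L, chrom_length_bp = 200000L,
                    class_counts = c(`DE1-Pt` = 8L, `DE1-Pe` = 8L,
                                     `DE2-identical` = 6L, `DE2-opposite` = 4L))
  ann <- simulate_annotation(cfg)
  placed <- dplyr::filter(ann$features, kind %in% c("gene", "TE")) |>
    dplyr::arrange(chrom, start)
  by_chrom <- split(placed, placed$chrom)
  for (tbl in by_chrom) {
    expect_true(all(tbl$start[-1] >= tbl$end[-nrow(tbl)]))
  }
  exons <- dplyr::filter(ann$features, kind == "exon")
  genes <- dplyr::filter(ann$features, kind == "gene")
  j <- dplyr::left_join(exons, genes, by = c("parent" = "id"),
                        suffix = c("", ".g"))
  expect_true(all(j$start >= j$start.g & j$end <= j$end.g))
  # determinism
  expect_identical(ann$features, simulate_annotation(cfg)$features)
  # degenerate settings
  only_te <- simulate_annotation(sim_config(seed = 2, n_genes = 0L, n_tes = 10L,
                                            class_counts = c(`DE1-Pt` = 0L, `DE1-Pe` = 0L,
                                                             `DE2-identical` = 0L,
                                                             `DE2-opposite` = 0L)))
  expect_equal(sum(only_te$features$kind == "gene"), 0L)
  all_gypsy <- simulate_annotation(sim_config(
    seed = 2, te_class_proportions = c(Gypsy = 1, Copia = 0, `LTR-other` = 0,
                                       LINE = 0, DNA = 0)))
  expect_equal(unique(all_gypsy$features$te_class[all_gypsy$features$kind == "TE"]),
               "Gypsy")
  # impossible density errors out
  expect_error(simulate_annotation(sim_config(seed = 1, chrom_length_bp = 10000L)),
               "density")
})

test_that("simulated methylome has the configured noise floor and bimodal structure", {
  cfg <- sim_config(seed = 9, n_planted_dmrs = 0L)
  ann <- simulate_annotation(cfg)
  m <- simulate_methylome(ann, cfg)
  ts <- m$truth_sites
  # mixture recovery against the configured per-site weights
  expect_equal(mean(ts$latent_MY < 0.10), mean(1 - ts$p_high), tolerance = 0.02)
  # latent levels shared across stages without planting
  expect_identical(ts$latent_MY, ts$latent_FB)
  # non-conversion noise: unmethylated sites read out at ~0.3%
  null_cfg <- sim_config(seed = 9, low_mode = 0, n_planted_dmrs = 0L,
                         low_weight = c(genic = 1, intergenic = 1, TE = 1),
                         te_spread_boost = 0, depth_mean = 30)
  nm <- simulate_methylome(ann, null_cfg)
  obs <- with(nm$stages$MY, sum(meth_reads) / sum(total_reads))
  expect_equal(obs, 0.003, tolerance = 0.15)
  # determinism of the full object
  expect_identical(m$stages$PR, simulate_methylome(ann, cfg)$stages$PR)
})

test_that("planted DMRs shift the later stage by the configured delta", {
  cfg <- sim_config(seed = 13, depth_mean = 30)
  ann <- simulate_annotation(cfg)
  m <- suppressWarnings(simulate_methylome(ann, cfg))
  truth <- dplyr::filter(m$truth_dmrs, transition == 1)
  expect_equal(nrow(truth), cfg$n_planted_dmrs)
  deltas <- purrr::pmap_dbl(truth, function(transition, chrom, start, end, direction, delta) {
    a <- m$stages$MY
    b <- m$stages$PR
    ia <- a$chrom == chrom & a$pos >= start & a$pos < end
    d <- mean(b$level[ia]) - mean(a$level[ia])
    if (direction == "hypo") -d else d
  })
  # mean observed shift approximates the planted magnitude (clamping and
  # binomial noise shrink it slightly)
  expect_true(all(deltas > 0.2))
  expect_equal(mean(deltas), 0.3, tolerance = 0.2)
  # every planted DMR has >= 15 CpGs
  n_sites <- purrr::pmap_int(truth, function(transition, chrom, start, end, ...) {
    sum(m$truth_sites$chrom == chrom & m$truth_sites$pos >= start &
          m$truth_sites$pos < end)
  })
  expect_true(all(n_sites >= 15L))
})

test_that("simulated expression has NB mean-variance structure and planted classes", {
  # NB identity: var = mu + disp * mu^2
  set.seed(77)
  draws <- rnbinom(10000, mu = 100, size = 1 / 0.1)
  expect_equal(var(draws), 100 + 0.1 * 100^2, tolerance = 0.08)

  cfg <- sim_config(seed = 4)
  ex <- simulate_expression(cfg)
  expect_error(simulate_expression(sim_config(seed = 1, nb_dispersion = 0)),
               "nb_dispersion")
  # all planted classes present with the configured counts
  tc <- dplyr::count(ex$truth_classes, phase, class)
  for (cl in names(cfg$class_counts)) {
    expect_equal(unique(tc$n[tc$class == cl]), unname(cfg$class_counts[cl]))
  }
  # DE2-opposite genes move in opposite directions in expectation
  opp <- dplyr::filter(ex$truth_classes, phase == "phase1", class == "DE2-opposite")
  fc <- function(cnt, sp) {
    my <- rowMeans(cnt[, paste0(sp, "_MY_", 1:3)])
    pr <- rowMeans(cnt[, paste0(sp, "_PR_", 1:3)])
    log2((pr + 0.5) / (my + 0.5))
  }
  i <- match(opp$gene_a, ex$counts$Pt$feature_id)
  expect_true(all(sign(fc(ex$counts$Pt, "Pt")[i]) != sign(fc(ex$counts$Pe, "Pe")[i])))
  # zero planted effect -> all DE0
  cfg0 <- sim_config(seed = 4, class_counts = c(`DE1-Pt` = 0L, `DE1-Pe` = 0L,
                                                `DE2-identical` = 0L,
                                                `DE2-opposite` = 0L))
  expect_true(all(simulate_expression(cfg0)$truth_classes$class == "DE0"))
  # determinism
  expect_identical(ex$counts$Pe, simulate_expression(cfg)$counts$Pe)
})
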