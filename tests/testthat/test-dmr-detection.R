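test_that("window tiling follows the size/step rule with truncation", {
  w <- make_windows(c(chr1 = 1400L), size = 1000L, step = 200L)
  expect_equal(w$start, seq(0L, 1200L, by = 200L))
  expect_equal(w$end, pmin(w$start + 1000L, 1400L))
  w2 <- make_windows(c(chr1 = 500L))
  expect_equal(nrow(w2), 3L)  # starts 0, 200, 400, all truncated at 500
  expect_equal(w2$end, c(500L, 500L, 500L))
  w3 <- make_windows(c(chr1 = 3000L), size = 1000L, step = 1000L)
  expect_true(all(w3$start[-1] == w3$end[-nrow(w3)]))  # non-overlapping tiling
})

test_that("Fisher 2x2 equals enumeration for all small-margin tables", {
  for (r1 in 0:8) {
    for (r2 in 0:8) {
      if (r1 == 0 && r2 == 0) next
      for (a in 0:r1) {
        for (c in 0:r2) {
          b <- r1 - a; d <- r2 - c
          if ((a + c) == 0 || (b + d) == 0 || r1 == 0 || r2 == 0) next
          expect_equal(fisher_exact_2x2(a, b, c, d), oracle_fisher_2x2(a, b, c, d),
                       tolerance = 1e-10)
        }
      }
    }
  }
  # larger margins against stats::fisher.test as a second, independent route
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 12), 2)
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(3, 7, 3, 7), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10))
  expect_warning(p <- fisher_exact_2x2(0, 0, 3, 7), "degenerate")
  expect_equal(p, 1)
})

test_that("window eligibility needs 10 mCGs in at least one stage", {
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  mk <- function(n_mcg, n_other = 0) {
    s <- make_sites(pos = seq_len(n_mcg + n_other) * 10,
                    meth = 5, total = 10)
    s$is_mcg <- c(rep(TRUE, n_mcg), rep(FALSE, n_other))
    s
  }
  expect_true(window_eligibility(w, mk(10), mk(0, 5)))
  expect_false(window_eligibility(w, mk(9), mk(9)))
  expect_false(window_eligibility(w, mk(0), mk(0)))
})

# deterministic two-stage site set: block [1000, 3000) changes level
two_stage_sites <- function(level_a, level_b, depth = 40L, spacing = 50L,
                            chrom_len = 20000L) {
  pos <- seq(25L, chrom_len - 25L, by = spacing)
  in_block <- pos >= 1000 & pos < 3000
  base <- ifelse(in_block, NA, 0.5)
  mk <- function(lv) {
    p <- ifelse(in_block, lv, 0.5)
    make_sites(pos = pos, meth = round(p * depth), total = depth)
  }
  list(a = mk(level_a), b = mk(level_b))
}

test_that("DMR calling finds the changed block, merges windows and is symmetric", {
  s <- two_stage_sites(0.10, 0.60)
  params <- dmr_params()
  ca <- call_mcgs(s$a)
  cb <- call_mcgs(s$b)
  res <- call_dmrs(ca, cb, c(chr1 = 20000L), params)
  expect_s3_class(res, "dmr_result")
  expect_equal(nrow(res$dmrs), 1L)
  expect_equal(res$dmrs$status, "hyper")
  # merged span covers the block (window granularity: 1 kb windows, 200 bp step)
  expect_lte(res$dmrs$start, 1000L)
  expect_gte(res$dmrs$end, 3000L)
  expect_true(all(res$windows$qvalue[res$windows$status != "none"] < params$q_threshold))
  expect_true(all(abs(res$windows$delta[res$windows$status != "none"]) >= 0.15))

  # symmetry: swapping stages maps hyper <-> hypo with identical p-values
  rev <- call_dmrs(cb, ca, c(chr1 = 20000L), params)
  expect_equal(rev$windows$pvalue, res$windows$pvalue)
  expect_equal(rev$dmrs$status, "hypo")
  expect_equal(rev$dmrs[, c("chrom", "start", "end")],
               res$dmrs[, c("chrom", "start", "end")])

  # sub-threshold delta is not called even when significant
  s2 <- two_stage_sites(0.50, 0.60)
  res2 <- call_dmrs(call_mcgs(s2$a), call_mcgs(s2$b), c(chr1 = 20000L), params)
  w_sig <- dplyr::filter(res2$windows, qvalue < 0.01)
  expect_true(all(w_sig$status == "none"))
  expect_equal(nrow(res2$dmrs), 0L)
})

test_that("window merging respects status and strict overlap", {
  w <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 200L, 2000L, 3000L),
    end = c(1000L, 1200L, 3000L, 4000L),
    status = c("hyper", "hyper", "hyper", "hyper"),
    delta = 0.3, qvalue = 1e-5
  )
  m <- merge_windows(w)
  # book-ended [2000,3000) + [3000,4000) do not merge
  expect_equal(nrow(m), 3L)
  expect_equal(m$start, c(0L, 2000L, 3000L))
  expect_equal(m$end, c(1200L, 3000L, 4000L))
  expect_equal(m$n_windows, c(2L, 1L, 1L))
  # opposite status never merges
  w$status <- c("hyper", "hypo", "hyper", "hyper")
  m2 <- merge_windows(w)
  expect_equal(nrow(m2), 4L)
  # merged DMRs of one status never overlap; every significant window covered
  for (st in c("hyper", "hypo")) {
    ms <- dplyr::arrange(dplyr::filter(m2, status == st), start)
    if (nrow(ms) > 1) expect_true(all(ms$start[-1] >= ms$end[-nrow(ms)]))
  }
  covered <- purrr::map_lgl(seq_len(nrow(w)), function(i) {
    any(m2$chrom == w$chrom[i] & m2$status == w$status[i] &
          m2$start <= w$start[i] & m2$end >= w$end[i])
  })
  expect_true(all(covered))
})

test_that("MP/MGB differential testing uses density eligibility, no merging", {
  regions <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                            end = c(1000L, 11000L), id = c("p1", "p2"))
  # region 1: strong change with dense mCGs; region 2: only 9 mCGs -> untested
  pos1 <- seq(10L, 990L, by = 50L)
  pos2 <- seq(10010L, 10410L, by = 50L)
  mk <- function(lv1) {
    s <- make_sites(pos = c(pos1, pos2),
                    meth = round(c(rep(lv1, length(pos1)), rep(0.5, length(pos2))) * 40),
                    total = 40L)
    s$is_mcg <- TRUE
    s
  }
  res <- call_differential_mp_mgb(regions, mk(0.2), mk(0.6))
  expect_true(res$eligible[1])
  expect_false(res$eligible[2])
  expect_equal(res$status, c("hyper", "none"))
  expect_true(is.na(res$pvalue[2]))
  # identical pooled counts -> p = 1, none
  same <- call_differential_mp_mgb(regions[1, ], mk(0.5), mk(0.5))
  expect_equal(same$pvalue, 1)
  expect_equal(same$status, "none")
})

test_that("null methylomes produce essentially no DMRs", {
  cfg <- sim_config(seed = 31, low_mode = 0, n_planted_dmrs = 0L,
                    low_weight = c(genic = 1, intergenic = 1, TE = 1),
                    te_spread_boost = 0, n_genes = 20L, n_tes = 10L,
                    chrom_length_bp = 150000L,
                    class_counts = c(`DE1-Pt` = 0L, `DE1-Pe` = 0L,
                                     `DE2-identical` = 0L, `DE2-opposite` = 0L))
  ann <- simulate_annotation(cfg)
  counts <- vapply(1:3, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    m <- simulate_methylome(ann, cfg_i)
    res <- suppressWarnings(call_dmrs(call_mcgs(m$stages$MY), call_mcgs(m$stages$PR),
                                      ann$chrom_lengths))
    nrow(res$dmrs)
  }, numeric(1))
  expect_lt(mean(counts), 1)
})
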