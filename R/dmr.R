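#' Sliding windows over a genome
#'
#' Windows `[k*step, k*step + size)` for every `k` with start inside the
#' chromosome; the final windows are truncated at the chromosome end.
#'
#' @param chrom_lengths Tibble (`chrom`, `length`) or named vector.
#' @param size Window size in bp (default 1000).
#' @param step Step in bp (default 200).
#' @return A tibble with `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size = 1000L, step = 200L) {
  stopifnot(size >= step, step > 0)
  cl <- as_chrom_lengths(chrom_lengths)
  purrr::map2_dfr(cl$chrom, cl$length, function(ch, L) {
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    starts <- starts[starts < L]
    tibble::tibble(chrom = ch, start = as.integer(starts),
                   end = as.integer(pmin(starts + size, L)))
  })
}

# Pooled per-window sums of site columns via cumulative sums on sorted
# positions; count in [s, e) for integer positions.
pool_in_windows <- function(windows, sites, cols) {
  out <- matrix(0, nrow = nrow(windows), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) next
    ord <- order(s$pos)
    pos <- s$pos[ord]
    lo <- findInterval(windows$start[wi] - 0.5, pos)
    hi <- findInterval(windows$end[wi] - 0.5, pos)
    for (cc in cols) {
      cs <- c(0, cumsum(as.numeric(s[[cc]][ord])))
      out[wi, cc] <- cs[hi + 1L] - cs[lo + 1L]
    }
  }
  out
}

#' Two-sided Fisher's exact test for 2x2 tables
#'
#' Exact conditional test: the p-value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of tables no more
#' probable than the observed one. Vectorised over tables. The table is
#' `[[a, b], [c, d]]`, e.g. methylated/unmethylated reads in two stages.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectors).
#' @return Numeric vector of two-sided p-values. A table with an all-zero
#'   margin yields `p = 1` with a warning.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative", call. = FALSE)
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 == 0L || m2 == 0L || k == 0L || (b[i] + d[i]) == 0L) {
      warning("fisher_exact_2x2: degenerate table with an all-zero margin; p = 1")
      p[i] <- 1
      next
    }
    support <- max(0L, k - m2):min(k, m1)
    dens <- dhyper(support, m1, m2, k)
    obs <- dhyper(a[i], m1, m2, k)
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Window eligibility for DMR testing
#'
#' A window is eligible when it contains at least `min_mcg` mCG sites in at
#' least one of the two stages.
#'
#' @param windows Window tibble (`chrom`, `start`, `end`).
#' @param sites_a,sites_b Called site tibbles (with `is_mcg`) for the two stages.
#' @param min_mcg Minimum mCG count (default 10).
#' @return Logical vector aligned with `windows`.
#' @export
window_eligibility <- function(windows, sites_a, sites_b, min_mcg = 10L) {
  na <- pool_in_windows(windows, dplyr::mutate(sites_a, mcg = as.integer(.data$is_mcg)), "mcg")
  nb <- pool_in_windows(windows, dplyr::mutate(sites_b, mcg = as.integer(.data$is_mcg)), "mcg")
  na[, "mcg"] >= min_mcg | nb[, "mcg"] >= min_mcg
}

#' Parameters of the DMR caller
#'
#' @param size,step Sliding-window geometry in bp (defaults 1000 / 200).
#' @param min_mcg Window eligibility: minimum mCG count in at least one stage.
#' @param q_threshold BH q-value threshold (default 0.01).
#' @param delta_threshold Minimum absolute change of pooled methylation level
#'   (default 0.15).
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(size = 1000L, step = 200L, min_mcg = 10L,
                       q_threshold = 0.01, delta_threshold = 0.15) {
  stopifnot(size >= step, step > 0, min_mcg >= 0,
            q_threshold > 0, delta_threshold >= 0)
  structure(list(size = size, step = step, min_mcg = min_mcg,
                 q_threshold = q_threshold, delta_threshold = delta_threshold),
            class = "dmr_params")
}

#' Call differentially methylated regions between two stages
#'
#' Sliding 1 kb windows at 200 bp steps; windows with at least `min_mcg` mCGs
#' in at least one stage are tested by Fisher's exact test on the pooled
#' methylated/unmethylated read counts of all covered CG sites; p-values are
#' BH-adjusted over the eligible windows of this transition; windows with
#' `q < q_threshold` and `|delta| >= delta_threshold` become hyper (level
#' higher in the later stage B) or hypo windows; overlapping same-status
#' windows are merged into maximal DMRs.
#'
#' @param sites_a Called sites of the earlier stage.
#' @param sites_b Called sites of the later stage.
#' @param chrom_lengths Tibble (`chrom`, `length`) or named vector.
#' @param params A [dmr_params()].
#' @return A list of class `dmr_result`: `windows` (all windows with pooled
#'   counts, eligibility, `pvalue`, `qvalue`, `delta`, `status`), `dmrs`
#'   (merged regions) and `params`.
#' @export
call_dmrs <- function(sites_a, sites_b, chrom_lengths, params = dmr_params()) {
  windows <- make_windows(chrom_lengths, params$size, params$step)
  wa <- pool_in_windows(windows,
                        dplyr::mutate(sites_a, mcg = as.integer(.data$is_mcg)),
                        c("meth_reads", "total_reads", "mcg"))
  wb <- pool_in_windows(windows,
                        dplyr::mutate(sites_b, mcg = as.integer(.data$is_mcg)),
                        c("meth_reads", "total_reads", "mcg"))
  windows <- windows |>
    dplyr::mutate(
      n_mcg_a = as.integer(wa[, "mcg"]), n_mcg_b = as.integer(wb[, "mcg"]),
      meth_a = wa[, "meth_reads"], total_a = wa[, "total_reads"],
      meth_b = wb[, "meth_reads"], total_b = wb[, "total_reads"],
      level_a = ifelse(.data$total_a > 0, .data$meth_a / .data$total_a, NA_real_),
      level_b = ifelse(.data$total_b > 0, .data$meth_b / .data$total_b, NA_real_),
      delta = .data$level_b - .data$level_a,
      eligible = .data$n_mcg_a >= params$min_mcg | .data$n_mcg_b >= params$min_mcg,
      pvalue = NA_real_, qvalue = NA_real_, status = "none"
    )
  el <- which(windows$eligible)
  if (length(el) == 0L) {
    warning("call_dmrs: no eligible windows")
    dmrs <- merge_windows(windows[0, ])
    return(structure(list(windows = windows, dmrs = dmrs, params = params),
                     class = "dmr_result"))
  }
  windows$pvalue[el] <- fisher_exact_2x2(
    windows$meth_a[el], windows$total_a[el] - windows$meth_a[el],
    windows$meth_b[el], windows$total_b[el] - windows$meth_b[el])
  windows$qvalue[el] <- bh_adjust(windows$pvalue[el])
  sig <- el[windows$qvalue[el] < params$q_threshold &
              abs(windows$delta[el]) >= params$delta_threshold &
              !is.na(windows$delta[el])]
  windows$status[sig] <- ifelse(windows$delta[sig] > 0, "hyper", "hypo")
  dmrs <- merge_windows(windows)
  structure(list(windows = windows, dmrs = dmrs, params = params),
            class = "dmr_result")
}

#' Merge overlapping same-status significant windows into DMRs
#'
#' Windows with identical status (hyper or hypo) overlapping by at least 1 bp
#' merge into one region (book-ended windows do not merge); the merged span
#' runs from the minimum start to the maximum end, and bookkeeping fields
#' (`n_windows`, `max_abs_delta`, `min_qvalue`) are aggregated.
#'
#' @param windows Window tibble from [call_dmrs()] (only rows with status
#'   hyper/hypo are used).
#' @return A tibble of merged DMRs.
#' @export
merge_windows <- function(windows) {
  sig <- windows |>
    dplyr::filter(.data$status %in% c("hyper", "hypo")) |>
    dplyr::arrange(.data$chrom, .data$start)
  if (nrow(sig) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          status = character(), n_windows = integer(),
                          max_abs_delta = double(), min_qvalue = double(),
                          delta = double()))
  }
  sig |>
    dplyr::group_by(.data$chrom, .data$status) |>
    dplyr::mutate(
      new_run = .data$start >= dplyr::lag(cummax(.data$end), default = -1L),
      run = cumsum(.data$new_run)
    ) |>
    dplyr::group_by(.data$chrom, .data$status, .data$run) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(),
      max_abs_delta = max(abs(.data$delta)),
      min_qvalue = min(.data$qvalue),
      delta = .data$delta[which.max(abs(.data$delta))],
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "start", "end", "status", "n_windows",
                  "max_abs_delta", "min_qvalue", "delta") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Differential methylation of promoters and gene bodies
#'
#' Applies the DMR machinery with fixed regions (methylated promoters or gene
#' bodies) as the testing unit, with no merging. Eligibility reuses the MP/MGB
#' density definition: at least `min_density` mCGs per kb in at least one
#' stage.
#'
#' @param regions Region tibble with `chrom`, `start`, `end` and an `id`.
#' @param sites_a,sites_b Called site tibbles for the two stages.
#' @param min_density Minimum mCG density per kb (default 10).
#' @param q_threshold,delta_threshold Significance thresholds (0.01 / 0.15).
#' @return The region tibble with pooled counts, mCG counts, levels, `delta`,
#'   `pvalue`, `qvalue` and `status`.
#' @export
call_differential_mp_mgb <- function(regions, sites_a, sites_b,
                                     min_density = 10, q_threshold = 0.01,
                                     delta_threshold = 0.15) {
  assert_columns(regions, c("chrom", "start", "end"))
  wa <- pool_in_windows(regions,
                        dplyr::mutate(sites_a, mcg = as.integer(.data$is_mcg)),
                        c("meth_reads", "total_reads", "mcg"))
  wb <- pool_in_windows(regions,
                        dplyr::mutate(sites_b, mcg = as.integer(.data$is_mcg)),
                        c("meth_reads", "total_reads", "mcg"))
  kb <- (regions$end - regions$start) / 1000
  out <- regions |>
    dplyr::mutate(
      n_mcg_a = as.integer(wa[, "mcg"]), n_mcg_b = as.integer(wb[, "mcg"]),
      meth_a = wa[, "meth_reads"], total_a = wa[, "total_reads"],
      meth_b = wb[, "meth_reads"], total_b = wb[, "total_reads"],
      level_a = ifelse(.data$total_a > 0, .data$meth_a / .data$total_a, NA_real_),
      level_b = ifelse(.data$total_b > 0, .data$meth_b / .data$total_b, NA_real_),
      delta = .data$level_b - .data$level_a,
      eligible = pmax(.data$n_mcg_a, .data$n_mcg_b) / kb >= min_density,
      pvalue = NA_real_, qvalue = NA_real_, status = "none"
    )
  el <- which(out$eligible)
  if (length(el) > 0L) {
    out$pvalue[el] <- fisher_exact_2x2(
      out$meth_a[el], out$total_a[el] - out$meth_a[el],
      out$meth_b[el], out$total_b[el] - out$meth_b[el])
    out$qvalue[el] <- bh_adjust(out$pvalue[el])
    sig <- el[out$qvalue[el] < q_threshold &
                abs(out$delta[el]) >= delta_threshold & !is.na(out$delta[el])]
    out$status[sig] <- ifelse(out$delta[sig] > 0, "hyper", "hypo")
  }
  out
}

#' Compare called DMRs with a planted-truth table
#'
#' Sensitivity: fraction of planted DMRs overlapped by a called DMR of the
#' same direction. Precision: fraction of called DMRs overlapping a planted
#' DMR of the same direction.
#'
#' @param dmrs Merged DMR tibble (from [call_dmrs()]`$dmrs`).
#' @param truth Planted-truth tibble (`chrom`, `start`, `end`, `direction`).
#' @return A one-row tibble with `n_truth`, `n_called`, `sensitivity`,
#'   `precision`.
#' @export
evaluate_dmrs <- function(dmrs, truth) {
  overlap_dir <- function(x, y) {
    if (nrow(x) == 0L) return(logical(0))
    if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
    vapply(seq_len(nrow(x)), function(i) {
      any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i] &
            y$dir == x$dir[i])
    }, logical(1))
  }
  xt <- truth |> dplyr::mutate(dir = .data$direction)
  xc <- dmrs |> dplyr::mutate(dir = .data$status)
  tibble::tibble(
    n_truth = nrow(truth),
    n_called = nrow(dmrs),
    sensitivity = if (nrow(truth) > 0) mean(overlap_dir(xt, xc)) else NA_real_,
    precision = if (nrow(dmrs) > 0) mean(overlap_dir(xc, xt)) else NA_real_
  )
}
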