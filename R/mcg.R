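#' Parameters of the mCG caller
#'
#' @param p0 Background methylation rate: the bisulfite non-conversion rate
#'   (default 0.003, estimated in the study design from unmethylated lambda
#'   DNA), the null success probability of the binomial test.
#' @param min_reads Minimum total read depth per site (default 5, i.e. "more
#'   than four" uniquely mapped reads).
#' @param q_threshold BH q-value threshold (strict `<`, default 0.01).
#' @param level_threshold Methylation-level threshold (strict `>`, default 0.05).
#' @return A list of class `mcg_params`.
#' @export
mcg_params <- function(p0 = 0.003, min_reads = 5L, q_threshold = 0.01,
                       level_threshold = 0.05) {
  stopifnot(p0 > 0, p0 < level_threshold, level_threshold < 1, min_reads >= 1)
  structure(list(p0 = p0, min_reads = min_reads, q_threshold = q_threshold,
                 level_threshold = level_threshold), class = "mcg_params")
}

#' Depth-filter cytosine sites
#'
#' Retains sites with `total_reads >= min_reads`.
#'
#' @param sites Cytosine site tibble.
#' @param min_reads Minimum depth (default 5).
#' @return The filtered tibble.
#' @export
depth_filter <- function(sites, min_reads = 5L) {
  assert_columns(sites, "total_reads")
  dplyr::filter(sites, .data$total_reads >= min_reads)
}

#' Upper-tail binomial p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, by exact summation of the mass
#' function (no normal approximation). Vectorised over `k` and `n`.
#'
#' @param k Observed successes (methylated reads).
#' @param n Trials (total reads).
#' @param p0 Null success probability.
#' @return Numeric vector of p-values.
#' @export
binomial_tail_p <- function(k, n, p0) {
  if (any(k < 0 | n < 0 | k > n)) stop("need 0 <= k <= n", call. = FALSE)
  stopifnot(p0 > 0, p0 < 1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Call methylated CG sites
#'
#' Applies the depth filter, tests every retained site against the
#' non-conversion background with a one-sided binomial test, adjusts p-values
#' by Benjamini-Hochberg jointly over all tested sites of the sample, and
#' flags sites with `q < q_threshold` and raw level `> level_threshold` as
#' mCG. Output rows are ordered by (chrom, pos, strand) for reproducibility.
#'
#' @param sites Cytosine site tibble (one sample: one species x stage).
#' @param params An [mcg_params()].
#' @return The site tibble with `pvalue`, `qvalue` and `is_mcg` columns.
#' @export
call_mcgs <- function(sites, params = mcg_params()) {
  assert_columns(sites, c("chrom", "pos", "strand", "meth_reads", "total_reads", "level"))
  sites <- depth_filter(sites, params$min_reads)
  if (nrow(sites) == 0L) {
    warning("call_mcgs: no sites pass the depth filter")
    sites$pvalue <- double()
    sites$qvalue <- double()
    sites$is_mcg <- logical()
    return(sites)
  }
  sites |>
    dplyr::mutate(
      pvalue = binomial_tail_p(.data$meth_reads, .data$total_reads, params$p0),
      qvalue = bh_adjust(.data$pvalue),
      is_mcg = .data$qvalue < params$q_threshold & .data$level > params$level_threshold
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
}

#' Summarise a called methylome
#'
#' Global mCG fraction and, among mCGs, the bimodality fractions with level
#' below 10% and above 70%. When an annotation is supplied, per-feature mCG
#' counts (exon/intron/promoter/downstream1kb/TE/intergenic precedence
#' assignment) are attached as an attribute `by_category`.
#'
#' @param sites Called site tibble (with `is_mcg`).
#' @param annotation Optional derived `genome_annotation` for the
#'   per-category breakdown.
#' @return A one-row tibble with `n_sites`, `n_mcg`, `mcg_fraction`,
#'   `frac_low` (level < 0.10 among mCGs), `frac_high` (level > 0.70);
#'   bimodality fractions are `NA` when there are no mCGs.
#' @export
methylome_summary <- function(sites, annotation = NULL) {
  assert_columns(sites, c("level", "is_mcg"))
  n <- nrow(sites)
  m <- sum(sites$is_mcg)
  lev <- sites$level[sites$is_mcg]
  out <- tibble::tibble(
    n_sites = n,
    n_mcg = m,
    mcg_fraction = if (n > 0) m / n else NA_real_,
    frac_low = if (m > 0) mean(lev < 0.10) else NA_real_,
    frac_high = if (m > 0) mean(lev > 0.70) else NA_real_
  )
  if (!is.null(annotation)) {
    assigned <- assign_sites_to_features(dplyr::filter(sites, .data$is_mcg), annotation)
    attr(out, "by_category") <- dplyr::count(assigned, .data$category, name = "n_mcg")
  }
  out
}
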