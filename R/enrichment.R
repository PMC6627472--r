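# Inferential statistics: hypergeometric over-representation, Games-Howell
# post-hoc comparisons, Mann-Whitney, two-count binomial comparison, Pearson.

#' Hypergeometric GO over-representation
#'
#' Upper-tail hypergeometric test of the overlap between a gene set and each
#' term's annotated genes within a universe, BH-adjusted over all tested
#' terms. A term is enriched when `q < q_threshold` and the overlap contains
#' at least `min_genes` genes.
#'
#' @param gene_set Character vector of genes (subset of the universe; genes
#'   outside the universe are dropped).
#' @param universe Character vector: the enrichment universe (by default the
#'   expressed ortholog set of the relevant comparison; any universe can be
#'   supplied).
#' @param term_map Two-column tibble (`gene`, `term`); an optional third
#'   column `term_name` is carried through.
#' @param q_threshold,min_genes Enrichment thresholds (defaults 0.05 / 5).
#' @return A tibble with `term`, `n_universe`, `n_term`, `n_set`, `n_overlap`,
#'   `pvalue`, `qvalue`, `enriched`, sorted by p-value.
#' @export
hypergeom_enrichment <- function(gene_set, universe, term_map,
                                 q_threshold = 0.05, min_genes = 5L) {
  assert_columns(term_map, c("gene", "term"))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty enrichment universe", call. = FALSE)
  gene_set <- unique(intersect(gene_set, universe))
  term_map <- term_map |> dplyr::filter(.data$gene %in% universe) |> dplyr::distinct()
  if (nrow(term_map) == 0L) {
    return(tibble::tibble(term = character(), n_universe = integer(),
                          n_term = integer(), n_set = integer(),
                          n_overlap = integer(), pvalue = double(),
                          qvalue = double(), enriched = logical()))
  }
  N <- length(universe)
  K <- length(gene_set)
  out <- term_map |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_term = dplyr::n_distinct(.data$gene),
      n_overlap = sum(unique(.data$gene) %in% gene_set),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_universe = N, n_set = K,
      pvalue = phyper(.data$n_overlap - 1L, .data$n_term, N - .data$n_term,
                      K, lower.tail = FALSE),
      qvalue = bh_adjust(.data$pvalue),
      enriched = .data$qvalue < q_threshold & .data$n_overlap >= min_genes
    ) |>
    dplyr::select("term", "n_universe", "n_term", "n_set", "n_overlap",
                  "pvalue", "qvalue", "enriched") |>
    dplyr::arrange(.data$pvalue, .data$term)
  if ("term_name" %in% names(term_map)) {
    out <- dplyr::left_join(out,
                            dplyr::distinct(term_map, .data$term, .data$term_name),
                            by = "term")
  }
  out
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Welch-type t statistics for every group pair with Welch-Satterthwaite
#' degrees of freedom, referred to the studentized-range distribution
#' (`q = t * sqrt(2)`) with the number of groups as the range parameter.
#' Appropriate for unequal variances and group sizes.
#'
#' @param groups Named list of numeric vectors (each `n >= 2`), or a data
#'   frame with `value` and `group` columns.
#' @return A tibble with one row per pair: `group1`, `group2`, `diff`
#'   (mean2 - mean1), `statistic` (t), `df`, `p.value` (Games-Howell
#'   adjusted). Pairs with zero pooled variance yield `NA` with a warning.
#' @export
games_howell <- function(groups) {
  if (is.data.frame(groups)) {
    assert_columns(groups, c("value", "group"))
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  stopifnot(k >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, var, numeric(1))
  pairs <- utils::combn(k, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se2 <- vars[i1] / ns[i1] + vars[i2] / ns[i2]
    if (se2 == 0) {
      warning("games_howell: zero-variance pair; p = NA")
      return(tibble::tibble(group1 = names(groups)[i1], group2 = names(groups)[i2],
                            diff = means[i2] - means[i1], statistic = NA_real_,
                            df = NA_real_, p.value = NA_real_))
    }
    t_stat <- unname((means[i2] - means[i1]) / sqrt(se2))
    df <- unname(se2^2 / ((vars[i1] / ns[i1])^2 / (ns[i1] - 1) +
                            (vars[i2] / ns[i2])^2 / (ns[i2] - 1)))
    p <- ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    tibble::tibble(group1 = names(groups)[i1], group2 = names(groups)[i2],
                   diff = unname(means[i2] - means[i1]), statistic = t_stat,
                   df = df, p.value = p)
  })
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided test of a location difference: exact p-value by enumeration when
#' `length(x) + length(y) <= 12` and there are no ties, otherwise the normal
#' approximation with tie correction (and continuity correction).
#'
#' @param x,y Numeric samples (`n >= 1` each).
#' @return One-row tibble `statistic` (the U statistic of `x`), `p.value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  tibble::tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
                 method = if (use_exact) "exact" else "normal")
}

#' Two-sided binomial comparison of two counts
#'
#' Exact two-sided binomial test of `k1` successes in `k1 + k2` trials against
#' `p = 0.5`: the standard comparison of two Poisson-like counts (e.g. DMR
#' counts between two transitions).
#'
#' @param k1,k2 Non-negative counts with `k1 + k2 > 0`.
#' @return One-row tibble `k1`, `k2`, `p.value`.
#' @export
binomial_count_comparison <- function(k1, k2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 + k2 > 0)
  tibble::tibble(k1 = k1, k2 = k2,
                 p.value = binom.test(k1, k1 + k2, p = 0.5)$p.value)
}

#' Pearson product-moment correlation test
#'
#' @param x,y Numeric vectors (`n >= 3`, positive variances; degenerate input
#'   yields `NA` with a warning).
#' @return One-row tibble `estimate` (r), `statistic` (t), `p.value`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
    warning("pearson_test: degenerate input")
    return(tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                          p.value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
                 p.value = ct$p.value, n = length(x))
}
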