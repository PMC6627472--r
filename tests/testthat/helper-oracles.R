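# Independent brute-force oracles, deliberately naive: direct summation and
# enumeration, no distribution functions shared with the implementation paths
# under test.

# P(X >= k), X ~ Binomial(n, p), by summing explicit products.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

# Two-sided conditional Fisher p for [[a, b], [c, d]]: enumerate all tables
# with the observed margins, table probability from factorials.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  tab_prob <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k))
  }
  support <- max(0, k - r2):min(k, r1)
  probs <- vapply(support, tab_prob, numeric(1))
  obs <- tab_prob(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of ranks.
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Step-up BH from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    min(1, min(vapply(which(p >= p[i] - 1e-15), function(j) {
      m * p[j] / sum(p <= p[j] + 1e-15)
    }, numeric(1))))
  }, numeric(1))
}

# Small deterministic site tibble builder for caller tests.
make_sites <- function(chrom = "chr1", pos, meth, total, strand = "+") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand, context = "CG",
    meth_reads = as.integer(meth), total_reads = as.integer(total),
    level = ifelse(total > 0, meth / total, NA_real_)
  )
}

# A tiny deterministic annotation: two genes (one per strand) and two TEs on
# one 20 kb chromosome.
make_tiny_annotation <- function() {
  features <- tibble::tibble(
    chrom = "chr1",
    start = c(5000L, 12000L, 5000L, 6500L, 12000L, 2000L, 16000L),
    end   = c(8000L, 15000L, 6000L, 8000L, 15000L, 3000L, 17000L),
    strand = c("+", "-", "+", "+", "-", ".", "."),
    kind = c("gene", "gene", "exon", "exon", "exon", "TE", "TE"),
    id = c("g1", "g2", "g1_e1", "g1_e2", "g2_e1", "te1", "te2"),
    parent = c(NA, NA, "g1", "g1", "g2", NA, NA),
    te_class = c(NA, NA, NA, NA, NA, "Gypsy", "LINE")
  )
  methdev:::new_genome_annotation(
    features, tibble::tibble(chrom = "chr1", length = 20000L))
}
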