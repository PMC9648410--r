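# Independent oracles used across the suite. These deliberately use
# naive O(N) / exhaustive formulations, not the package's condensed
# implementations.

# Full running-sum GSEA enrichment score over every position.
brute_es <- function(ranked, set, exponent = 1) {
  hit <- names(ranked) %in% set
  stopifnot(any(hit), !all(hit))
  w <- abs(ranked)^exponent * hit
  inc <- if (sum(w) > 0) w / sum(w) else hit / sum(hit)
  dec <- (!hit) / sum(!hit)
  rs <- unname(cumsum(inc - dec))
  i <- which.max(abs(round(rs, 12)))
  # tie between +max and -max resolves positive, as documented
  if (abs(max(rs) + min(rs)) < 1e-12 && max(rs) > 0) return(max(rs))
  rs[i]
}

# Direct per-position ssGSEA summation.
direct_ssgsea <- function(x, set, exponent = 0.25) {
  rk <- rank(x, ties.method = "average")
  ord <- order(-x, names(x), method = "radix")
  hit <- names(x)[ord] %in% set
  w <- rk[ord]^exponent
  p_hit <- cumsum(w * hit) / sum(w * hit)
  p_miss <- cumsum(!hit) / sum(!hit)
  sum(p_hit - p_miss) / (length(x) - 1)
}

# BH step-up by the textbook route: sort, scale by m/rank, cumulative
# minimum from the largest rank.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings.
enum_mw_p <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  u_of <- function(idx) {
    a <- all_v[idx]
    b <- all_v[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(all_v), n1)
  u_all <- apply(combos, 2, u_of)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by enumerating sign flips.
enum_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Small deterministic expression fixture: named genes x samples.
tiny_expr <- function(n_genes = 20, n_samples = 8, seed = 11) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}
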