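#' Build a ranked gene list
#'
#' Orders a per-gene metric non-increasingly, breaking ties by gene
#' identifier so the ordering is deterministic. The result is the input
#' expected by [gsea_es()] and [gsea_leading_edge()].
#'
#' @param metric Named numeric vector; names are unique gene identifiers.
#' @return Named numeric vector sorted in non-increasing order.
#' @export
ranked_list <- function(metric) {
  if (is.null(names(metric)) || anyNA(names(metric)) || any(names(metric) == ""))
    stop("metric must be named by gene identifiers")
  if (anyDuplicated(names(metric)))
    stop("gene identifiers must be unique")
  if (length(metric) < 2L)
    stop("ranked list needs at least 2 genes")
  if (anyNA(metric))
    stop("metric contains NA")
  metric[order(-metric, names(metric), method = "radix")]
}

# Condensed running-sum for a weighted Kolmogorov-Smirnov enrichment
# statistic. Extrema of the running sum can only occur just after a hit
# (candidate maxima) or just before a hit (candidate minima), so only hit
# positions are visited.
#
# pos: sorted positions of set members in the ranked list (1-based)
# w:   non-negative hit weights, same length/order as pos
# n:   length of the ranked list
.gsea_runsum <- function(pos, w, n) {
  k <- length(pos)
  if (k == 0L) stop("empty gene set on list")
  if (k == n) stop("no complement")
  wsum <- sum(w)
  hit <- if (wsum > 0) cumsum(w) / wsum else seq_len(k) / k
  miss_step <- 1 / (n - k)
  i <- seq_len(k)
  after <- hit - (pos - i) * miss_step                    # just after hit i
  before <- c(0, hit[-k]) - (pos - 1 - (i - 1)) * miss_step # just before hit i
  max_pos <- max(after)
  min_neg <- min(before)
  # tie between the extrema (within numerical error) resolves positive
  if (max_pos + min_neg >= -1e-12) {
    es <- max_pos
    peak <- which.max(after)
    le_idx <- seq_len(peak)
  } else {
    es <- min_neg
    trough <- which.min(before)
    le_idx <- seq(trough, k)
  }
  list(es = es, leading_idx = le_idx)
}

# Resolve a gene set against a ranked list: positions and hit weights.
.gsea_resolve <- function(ranked, members, exponent) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  inset <- names(ranked) %in% members
  pos <- which(inset)
  if (length(pos) == 0L) stop("empty gene set on list")
  if (length(pos) == length(ranked)) stop("no complement")
  list(pos = pos, w = abs(ranked[pos])^exponent)
}

#' GSEA enrichment score
#'
#' Signed maximum deviation of the weighted Kolmogorov-Smirnov running
#' sum: walking down the ranked list, set members increment the sum by
#' `|metric|^exponent` (normalised so the hits total 1) and non-members
#' decrement it by `1/(N - k)`. The score is the deviation of largest
#' magnitude; ties between the positive and negative extremum resolve to
#' the positive one. If all hit weights are zero the hits fall back to
#' equal increments.
#'
#' @param ranked Named numeric vector from [ranked_list()] (sorted
#'   non-increasing, unique gene names).
#' @param set Character vector of member gene identifiers.
#' @param exponent Weighting exponent for hit increments (default 1, the
#'   classic weighted statistic; 0 gives the unweighted KS form).
#' @return Enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, set, exponent = 1) {
  r <- .gsea_resolve(ranked, set, exponent)
  .gsea_runsum(r$pos, r$w, length(ranked))$es
}

#' GSEA leading-edge genes
#'
#' Set members that drive the enrichment signal: for a positive score,
#' members ranked at or before the running-sum peak; for a negative
#' score, members at or after the trough.
#'
#' @inheritParams gsea_es
#' @return Character vector of gene identifiers (subset of `set`), in
#'   ranked order.
#' @export
gsea_leading_edge <- function(ranked, set, exponent = 1) {
  r <- .gsea_resolve(ranked, set, exponent)
  rs <- .gsea_runsum(r$pos, r$w, length(ranked))
  names(ranked)[r$pos[rs$leading_idx]]
}

#' Two-group ranking metric
#'
#' Per-gene metric contrasting samples with a characteristic (`labels`
#' TRUE) against those without. The default is signal-to-noise,
#' `(m1 - m0) / (s1 + s0)`, with each group standard deviation floored
#' at `0.1 * |group mean|` (and a tiny absolute floor) for stability in
#' small groups; `"diffmean"` uses the plain difference of means.
#'
#' @param expr Numeric matrix, genes x samples, rownames = genes.
#' @param labels Logical/binary vector, one per sample.
#' @param method `"s2n"` (default) or `"diffmean"`.
#' @return Named numeric vector of per-gene metric values (unsorted).
#' @export
gsea_rank_metric <- function(expr, labels, method = c("s2n", "diffmean")) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  if (ncol(expr) != length(labels)) stop("labels must match samples")
  if (!any(labels) || !any(!labels)) stop("both label groups must be non-empty")
  m1 <- rowMeans(expr[, labels, drop = FALSE])
  m0 <- rowMeans(expr[, !labels, drop = FALSE])
  if (method == "diffmean") return(m1 - m0)
  s1 <- apply(expr[, labels, drop = FALSE], 1, stats::sd)
  s0 <- apply(expr[, !labels, drop = FALSE], 1, stats::sd)
  floor1 <- pmax(0.1 * abs(m1), .Machine$double.eps^0.5)
  floor0 <- pmax(0.1 * abs(m0), .Machine$double.eps^0.5)
  s1 <- pmax(s1, floor1, na.rm = TRUE)
  s0 <- pmax(s0, floor0, na.rm = TRUE)
  (m1 - m0) / (s1 + s0)
}

#' GSEA with permutation significance over a gene-set collection
#'
#' Computes the two-group enrichment score per set, a permutation p-value
#' and a Benjamini-Hochberg adjusted p-value across sets, plus the
#' leading-edge genes. Under the `gene_set` scheme the null redraws
#' random sets of the same size from the ranked list; under `phenotype`
#' it permutes the sample labels and recomputes the ranking metric.
#' `p_raw = (1 + #\{|ES*| >= |ES|\}) / (1 + n_perm)`. The normalised
#' score divides ES by the mean magnitude of same-sign null scores.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Logical/binary per-sample characteristic indicator.
#' @param sets Named list of character vectors (a gene-set collection).
#' @param n_perm Number of permutations (>= 1).
#' @param scheme `"gene_set"` (default) or `"phenotype"`.
#' @param seed Integer seed; required for reproducibility.
#' @param exponent Hit-weight exponent (default 1).
#' @param metric Ranking metric, see [gsea_rank_metric()].
#' @param exhaustive If TRUE (gene_set scheme only), enumerate all
#'   same-size sets instead of sampling; only allowed when the number of
#'   combinations is small.
#' @return A data.frame with one row per set: `set_name`, `size`, `es`,
#'   `nes`, `p_raw`, `p_adj`, and a list-column `leading_edge`.
#' @export
gsea_significance <- function(expr, labels, sets, n_perm = 1000,
                              scheme = c("gene_set", "phenotype"),
                              seed, exponent = 1,
                              metric = c("s2n", "diffmean"),
                              exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  metric <- match.arg(metric)
  if (missing(seed)) stop("seed is required")
  labels <- as.logical(labels)
  if (!exhaustive && (length(n_perm) != 1L || n_perm < 1))
    stop("n_perm must be >= 1")
  if (scheme == "phenotype" && (sum(labels) < 2L || sum(!labels) < 2L))
    stop("phenotype permutation needs >= 2 samples per group")
  if (length(sets) == 0L || is.null(names(sets)))
    stop("sets must be a non-empty named list")
  set.seed(as.integer(seed))

  ranked <- ranked_list(gsea_rank_metric(expr, labels, metric))
  n <- length(ranked)
  obs <- lapply(sets, function(s) {
    r <- .gsea_resolve(ranked, s, exponent)
    rs <- .gsea_runsum(r$pos, r$w, n)
    list(es = rs$es, k = length(r$pos),
         le = names(ranked)[r$pos[rs$leading_idx]])
  })

  null_for_size <- function(k) {
    if (exhaustive) {
      if (choose(n, k) > 1e5) stop("exhaustive null too large")
      combs <- utils::combn(n, k)
      apply(combs, 2, function(pos)
        .gsea_runsum(pos, abs(ranked[pos])^exponent, n)$es)
    } else {
      vapply(seq_len(n_perm), function(i) {
        pos <- sort.int(sample.int(n, k))
        .gsea_runsum(pos, abs(ranked[pos])^exponent, n)$es
      }, numeric(1))
    }
  }

  if (scheme == "gene_set") {
    sizes <- vapply(obs, function(o) o$k, integer(1))
    nulls <- lapply(unique(sizes), null_for_size)
    names(nulls) <- as.character(unique(sizes))
    null_of <- function(o) nulls[[as.character(o$k)]]
  } else {
    # one shared label permutation per iteration; recompute metric + rank
    perm_ranked <- lapply(seq_len(n_perm), function(i) {
      ranked_list(gsea_rank_metric(expr, sample(labels), metric))
    })
    null_mat <- vapply(perm_ranked, function(rk) {
      vapply(sets, function(s) {
        r <- .gsea_resolve(rk, s, exponent)
        .gsea_runsum(r$pos, r$w, n)$es
      }, numeric(1))
    }, numeric(length(sets)))
    if (length(sets) == 1L) null_mat <- matrix(null_mat, nrow = 1L)
    null_of <- local({
      i <- 0L
      function(o) {
        i <<- i + 1L
        null_mat[i, ]
      }
    })
  }

  es <- vapply(obs, function(o) o$es, numeric(1))
  p_raw <- numeric(length(obs))
  nes <- numeric(length(obs))
  for (i in seq_along(obs)) {
    nul <- null_of(obs[[i]])
    p_raw[i] <- (1 + sum(abs(nul) >= abs(es[i]))) / (1 + length(nul))
    same <- if (es[i] >= 0) nul[nul > 0] else nul[nul < 0]
    nes[i] <- if (length(same)) es[i] / mean(abs(same)) else NA_real_
  }
  out <- data.frame(
    set_name = names(sets),
    size = vapply(obs, function(o) o$k, integer(1)),
    es = es, nes = nes, p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$leading_edge <- I(lapply(obs, function(o) o$le))
  out
}

#' Single-sample GSEA enrichment score
#'
#' Rank-based per-sample enrichment of a gene set: genes are ranked by
#' expression within the sample (average ranks for ties), and the score
#' is the sum over ranked positions of the difference between the
#' weighted hit ECDF (hits weighted by rank value to the `exponent`) and
#' the miss ECDF, normalised by `N - 1` so it lies in `[-1, 1]`. The
#' score depends on expression only through ranks, so it is invariant to
#' strictly increasing transforms.
#'
#' @param sample_expr Named numeric vector, expression of one sample.
#' @param set Character vector of member gene identifiers.
#' @param exponent Rank-weight exponent (default 0.25).
#' @return Enrichment score in `[-1, 1]`.
#' @export
ssgsea_es <- function(sample_expr, set, exponent = 0.25) {
  if (is.null(names(sample_expr))) stop("sample_expr must be named by gene")
  if (anyDuplicated(names(sample_expr))) stop("gene identifiers must be unique")
  if (anyNA(sample_expr)) stop("sample_expr contains NA")
  n <- length(sample_expr)
  if (n < 2L) stop("need at least 2 genes")
  if (length(unique(sample_expr)) == 1L) stop("degenerate ranks")
  rk <- rank(sample_expr, ties.method = "average")
  ord <- order(-sample_expr, names(sample_expr), method = "radix")
  hit <- names(sample_expr)[ord] %in% set
  if (!any(hit)) stop("empty gene set on list")
  if (all(hit)) stop("no complement")
  w <- rk[ord]^exponent * hit
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / sum(!hit)
  sum(p_hit - p_miss) / (n - 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at
#' 1), with input validation.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
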