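#' Within-sample z-scoring of an expression matrix
#'
#' Standardises each sample (column) to mean 0, sd 1 (n-1 denominator)
#' across all genes in the matrix — not only signature genes — so that
#' downstream weighted sums are comparable between samples regardless
#' of per-sample location/scale shifts.
#'
#' @param expr Numeric matrix, genes x samples.
#' @return Matrix of the same shape, each column standardised.
#' @export
zscore_within_sample <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes per sample")
  if (anyNA(expr)) stop("expression contains NA")
  mu <- colMeans(expr)
  sdv <- apply(expr, 2, stats::sd)
  if (any(sdv == 0))
    stop("degenerate sample: constant expression in ",
         paste(colnames(expr)[sdv == 0], collapse = ", "))
  sweep(sweep(expr, 2, mu, "-"), 2, sdv, "/")
}

#' Raw repstress score
#'
#' Weighted sum of within-sample z-scored expression over the signature
#' genes: `score_j = sum_g w_g * z_gj`.
#'
#' @param zexpr Genes x samples matrix, already within-sample z-scored
#'   (see [zscore_within_sample()]).
#' @param sig A [repstress_signature()].
#' @param missing_policy `"error"` (default): any signature gene absent
#'   from the matrix is an error naming the missing genes;
#'   `"renormalize"`: weights of present genes are rescaled so their
#'   total absolute weight equals that of the full signature, with a
#'   warning.
#' @return Named numeric vector of raw scores, one per sample.
#' @export
repstress_raw <- function(zexpr, sig,
                          missing_policy = c("error", "renormalize")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(sig, "repstress_signature"))
  w <- sig$weights
  absent <- setdiff(names(w), rownames(zexpr))
  if (length(absent)) {
    if (missing_policy == "error")
      stop("signature genes absent from matrix: ",
           paste(absent, collapse = ", "))
    w <- w[setdiff(names(w), absent)]
    if (length(w) == 0L) stop("no signature gene present")
    if (sum(abs(w)) > 0)
      w <- w * sum(abs(sig$weights)) / sum(abs(w))
    warning(length(absent), " signature gene(s) absent; ",
            "weights renormalized over ", length(w), " present gene(s)")
  }
  drop(crossprod(zexpr[names(w), , drop = FALSE], w))
}

#' Z-normalise scores across analysis samples
#'
#' Standardises raw scores to mean 0, sd 1 (n-1 denominator) across the
#' samples used in the analysis.
#'
#' @param raw Numeric vector of raw scores (length >= 2).
#' @return Standardised scores, names preserved.
#' @export
normalize_scores <- function(raw) {
  if (length(raw) < 2L) stop("need at least 2 samples")
  s <- stats::sd(raw)
  if (s == 0) stop("all scores equal")
  (raw - mean(raw)) / s
}

#' Classify score extremes by percentiles
#'
#' Labels each sample `high` when its score is at or above the upper
#' percentile, `low` when strictly below the lower percentile, and
#' `mid` otherwise. Percentiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param scores Numeric vector, length >= 4.
#' @param hi_pct Upper percentile (default 75; inclusive `>=`).
#' @param lo_pct Lower percentile (default 25; strict `<`).
#' @return Character vector in `{high, low, mid}`, names preserved.
#' @export
classify_extremes <- function(scores, hi_pct = 75, lo_pct = 25) {
  if (length(scores) < 4L) stop("need at least 4 samples")
  qs <- stats::quantile(scores, c(lo_pct, hi_pct) / 100,
                        names = FALSE, type = 7)
  if (qs[2] <= qs[1]) stop("degenerate score distribution")
  out <- rep("mid", length(scores))
  out[scores >= qs[2]] <- "high"
  out[scores < qs[1]] <- "low"
  names(out) <- names(scores)
  out
}

#' Subgroup enrichment beyond the cohort confidence interval
#'
#' Counts how many subgroup samples lie beyond the 95% confidence bound
#' of the full cohort's score. With `ci_mode = "mean"` (default) the
#' bound is the CI of the cohort mean, `mean +/- 1.96 * sd / sqrt(n)`;
#' with `"reference"` it is a 95% reference interval of the score
#' distribution, `mean +/- 1.96 * sd`.
#'
#' @param scores Named numeric vector over the whole cohort (n >= 3).
#' @param subgroup Sample identifiers, a subset of `names(scores)`.
#' @param side `"above"` (upper bound) or `"below"` (lower bound).
#' @param ci_mode `"mean"` or `"reference"`.
#' @return List with `count`, `n` (subgroup size), `fraction`, `bound`.
#' @export
ci_enrichment_fraction <- function(scores, subgroup,
                                   side = c("above", "below"),
                                   ci_mode = c("mean", "reference")) {
  side <- match.arg(side)
  ci_mode <- match.arg(ci_mode)
  if (length(scores) < 3L) stop("cohort too small")
  if (is.null(names(scores))) stop("scores must be named by sample")
  if (length(subgroup) == 0L) stop("empty subgroup")
  if (!all(subgroup %in% names(scores)))
    stop("subgroup must be a subset of the cohort")
  half <- if (ci_mode == "mean")
    1.96 * stats::sd(scores) / sqrt(length(scores))
  else 1.96 * stats::sd(scores)
  bound <- mean(scores) + if (side == "above") half else -half
  v <- scores[subgroup]
  count <- if (side == "above") sum(v >= bound) else sum(v < bound)
  list(count = count, n = length(subgroup),
       fraction = count / length(subgroup), bound = bound)
}
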