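#' Spearman correlation panel with clustering order
#'
#' Correlates each feature (row) with a per-sample target by Spearman
#' rank correlation (average ranks for ties), adjusts p-values by
#' Benjamini-Hochberg across features, and orders the features by
#' complete-linkage hierarchical clustering of the Euclidean distances
#' between their pairwise correlation profiles.
#'
#' @param features Numeric matrix, features x samples.
#' @param target Numeric vector, one value per sample.
#' @return data.frame (one row per feature, in cluster order): feature,
#'   rho, p_raw, p_adj, cluster_order. Constant features get NA rho and
#'   p values and sort last.
#' @export
spearman_panel <- function(features, target) {
  features <- as.matrix(features)
  if (ncol(features) != length(target)) stop("target must match samples")
  if (ncol(features) < 3L) stop("need >= 3 paired observations")
  const <- apply(features, 1, function(x) stats::sd(x) == 0)
  rho <- rep(NA_real_, nrow(features))
  p <- rep(NA_real_, nrow(features))
  for (i in which(!const)) {
    ct <- suppressWarnings(
      stats::cor.test(features[i, ], target, method = "spearman"))
    rho[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  p_adj <- rep(NA_real_, length(p))
  p_adj[!const] <- bh_adjust(p[!const])
  ord <- seq_len(nrow(features))
  ok <- which(!const)
  if (length(ok) > 2L) {
    cm <- suppressWarnings(stats::cor(t(features[ok, , drop = FALSE]),
                                      method = "spearman"))
    cm[is.na(cm)] <- 0
    hc <- stats::hclust(stats::dist(cm), method = "complete")
    ord <- c(ok[hc$order], which(const))
  }
  out <- data.frame(feature = rownames(features), rho = rho,
                    p_raw = p, p_adj = p_adj,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[ord, , drop = FALSE]
  out$cluster_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Quartile drug-sensitivity contrast
#'
#' For each drug, compares activity between the score-high and
#' score-low groups by a two-sided Mann-Whitney U test (exact for small
#' groups without ties, normal approximation with tie correction
#' otherwise), adjusts across drugs by Benjamini-Hochberg, and reports
#' the median difference (high - low) as the effect.
#'
#' @param activity Numeric matrix, drugs x samples.
#' @param groups Character vector per sample with levels `"high"` and
#'   `"low"` (others ignored), e.g. from [classify_extremes()].
#' @param fdr Significance cutoff on adjusted p (default 0.05).
#' @return data.frame per tested drug: drug, effect, direction, p_raw,
#'   p_adj, significant. Drugs observed in fewer than 2 samples of
#'   either group are skipped with a message.
#' @export
drug_contrast <- function(activity, groups, fdr = 0.05) {
  activity <- as.matrix(activity)
  if (ncol(activity) != length(groups)) stop("groups must match samples")
  hi <- groups == "high"
  lo <- groups == "low"
  keep <- logical(nrow(activity))
  eff <- p <- numeric(nrow(activity))
  for (i in seq_len(nrow(activity))) {
    a_hi <- activity[i, hi]
    a_lo <- activity[i, lo]
    a_hi <- a_hi[!is.na(a_hi)]
    a_lo <- a_lo[!is.na(a_lo)]
    if (length(a_hi) < 2L || length(a_lo) < 2L) next
    keep[i] <- TRUE
    eff[i] <- stats::median(a_hi) - stats::median(a_lo)
    p[i] <- suppressWarnings(stats::wilcox.test(a_hi, a_lo)$p.value)
  }
  if (any(!keep))
    message(sum(!keep), " drug(s) skipped: < 2 observations in a group")
  drugs <- rownames(activity)
  if (is.null(drugs)) drugs <- as.character(seq_len(nrow(activity)))
  out <- data.frame(drug = drugs[keep], effect = eff[keep],
                    direction = ifelse(eff[keep] > 0, "more_active_high",
                                       ifelse(eff[keep] < 0,
                                              "more_active_low", "none")),
                    p_raw = p[keep], p_adj = bh_adjust(p[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p_adj < fdr
  out
}

#' Paired pre/post score dynamics
#'
#' Two-sided Wilcoxon signed-rank test of post versus pre (exact for
#' 25 or fewer nonzero pairs without ties, zeros dropped) plus the
#' median paired difference.
#'
#' @param pre,post Numeric vectors, paired by position (or by names
#'   when both are named).
#' @return List with `median_delta`, `p_value`, `n_pairs` (nonzero).
#' @export
paired_dynamics <- function(pre, post) {
  if (!is.null(names(pre)) && !is.null(names(post))) {
    common <- intersect(names(pre), names(post))
    pre <- pre[common]
    post <- post[common]
  }
  if (length(pre) != length(post)) stop("unpaired inputs")
  d <- post - pre
  nz <- sum(d != 0)
  if (nz < 3L) {
    if (all(d == 0)) stop("no signal: all paired differences are zero")
    stop("need >= 3 pairs with nonzero differences")
  }
  wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
  list(median_delta = stats::median(d), p_value = wt$p.value, n_pairs = nz)
}

#' Group comparisons: omnibus ANOVA, pairwise tests, or linear trend
#'
#' `omnibus`: one-way ANOVA F test. `pairwise`: all pairwise Welch
#' t-tests with Holm adjustment (an approximation to the Tukey
#' multiple-comparison procedure). `trend`: least-squares regression of
#' the values on the ordinal group index (1, 2, ...) with the slope's
#' two-sided t-test.
#'
#' @param values Numeric vector per sample.
#' @param groups Factor or character vector per sample; for `trend` the
#'   factor level order defines the ordinal index.
#' @param mode `"omnibus"`, `"pairwise"` or `"trend"`.
#' @return `omnibus`: list(F, df, p_value). `pairwise`: data.frame
#'   (group1, group2, diff, p_raw, p_adj). `trend`: list(slope,
#'   p_value).
#' @export
group_compare <- function(values, groups,
                          mode = c("omnibus", "pairwise", "trend")) {
  mode <- match.arg(mode)
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  tab <- table(g)
  if (mode %in% c("omnibus", "pairwise")) {
    if (nlevels(g) < 2L) stop("need at least 2 groups")
    if (any(tab < 2L)) stop("each group needs >= 2 samples")
  }
  if (mode == "omnibus") {
    fit <- stats::anova(stats::lm(values ~ g))
    if (!is.finite(fit$`F value`[1])) stop("F undefined")
    return(list(F = fit$`F value`[1], df = fit$Df,
                p_value = fit$`Pr(>F)`[1]))
  }
  if (mode == "pairwise") {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2)
    res <- apply(pairs, 2, function(pr) {
      a <- values[g == pr[1]]
      b <- values[g == pr[2]]
      tt <- stats::t.test(b, a)     # Welch
      c(diff = mean(b) - mean(a), p = tt$p.value)
    })
    return(data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      diff = res["diff", ], p_raw = res["p", ],
                      p_adj = stats::p.adjust(res["p", ], "holm"),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  if (nlevels(g) < 3L) stop("trend test needs >= 3 ordered groups")
  idx <- as.numeric(g)
  fit <- summary(stats::lm(values ~ idx))$coefficients
  list(slope = fit["idx", "Estimate"], p_value = fit["idx", "Pr(>|t|)"])
}

#' Jonckheere-Terpstra trend test
#'
#' Nonparametric test for an ordered alternative across ordinal groups
#' (normal approximation, two-sided). Provided as an alternative to the
#' regression-based trend in [group_compare()].
#'
#' @param values Numeric vector per sample.
#' @param groups Factor with ordered levels.
#' @return List with `statistic` (JT), `z`, `p_value`.
#' @export
jonckheere_trend <- function(values, groups) {
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  k <- nlevels(g)
  if (k < 3L) stop("trend test needs >= 3 ordered groups")
  jt <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- values[g == levels(g)[i]]
      b <- values[g == levels(g)[j]]
      cmp <- outer(a, b, "<")
      jt <- jt + sum(cmp) + 0.5 * sum(outer(a, b, "=="))
    }
  }
  ns <- as.numeric(table(g))
  n <- sum(ns)
  mu <- (n^2 - sum(ns^2)) / 4
  sig2 <- (n^2 * (2 * n + 3) - sum(ns^2 * (2 * ns + 3))) / 72
  z <- (jt - mu) / sqrt(sig2)
  list(statistic = jt, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimate per group and the two-sided log-rank
#' chi-square (1 df) comparing them, via the survival package.
#'
#' @param surv data.frame with columns `time` (nonnegative), `event`
#'   (0/1) and `group` (exactly 2 levels).
#' @return List with `curves` (data.frame: group, time, n_risk,
#'   n_event, surv), `chisq`, `p_value`.
#' @export
km_logrank <- function(surv) {
  stopifnot(all(c("time", "event", "group") %in% names(surv)))
  if (any(surv$time < 0)) stop("negative time")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  g <- factor(surv$group)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(tapply(surv$event, g, sum) == 0))
    stop("each group needs at least one event")
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = surv)
  strata <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(curves = curves, chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
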