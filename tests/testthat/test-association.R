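test_that("Spearman panel reports rho, BH p and a clustering order", {
  set.seed(21)
  target <- rnorm(12)
  features <- rbind(same = target,
                    rev = -target,
                    noise = rnorm(12),
                    flat = rep(1, 12))
  out <- suppressWarnings(spearman_panel(features, target))
  expect_equal(out$rho[out$feature == "same"], 1)
  expect_equal(out$rho[out$feature == "rev"], -1)
  expect_true(is.na(out$rho[out$feature == "flat"]))
  expect_equal(sort(out$cluster_order), 1:4)
  # the textbook 4-point example
  out2 <- spearman_panel(rbind(f = c(1, 3, 2, 4)), c(1, 2, 3, 4))
  expect_equal(out2$rho, 0.8)
  # rank-based: invariant under monotone transforms
  out3 <- suppressWarnings(spearman_panel(exp(features), exp(target)))
  expect_equal(out3$rho, out$rho)
  expect_error(spearman_panel(features[, 1:2], target[1:2]), ">= 3")
})

test_that("drug contrast uses exact Mann-Whitney and BH across drugs", {
  act <- rbind(d1 = c(1, 2, 3, 4),
               d2 = c(5, 6, 5, 6))
  groups <- c("high", "high", "low", "low")
  out <- suppressMessages(drug_contrast(act, groups))
  expect_equal(out$p_raw[out$drug == "d1"], 1 / 3)
  expect_equal(out$effect[out$drug == "d1"], 1.5 - 3.5)
  expect_equal(out$direction[out$drug == "d1"], "more_active_low")
  # identical distributions: zero effect, not significant
  expect_equal(out$effect[out$drug == "d2"], 0)
  expect_false(out$significant[out$drug == "d2"])
  # a drug observed in one group only is skipped
  act2 <- rbind(d1 = c(1, 2, 3, 4), d3 = c(1, 2, NA, NA))
  expect_message(out2 <- drug_contrast(act2, groups), "skipped")
  expect_equal(out2$drug, "d1")
})

test_that("planted drug classes separate by score group with FDR control", {
  co <- simulate_cohort(cohort_config(seed = 6))
  grp <- classify_extremes(co$truth$factor)
  out <- suppressMessages(drug_contrast(t(co$drug), grp, fdr = 0.05))
  rs <- out[grep("^RSDRUG", out$drug), ]
  mapk <- out[grep("^MAPKDRUG", out$drug), ]
  expect_true(all(rs$significant))
  expect_true(all(rs$effect > 0))
  expect_true(all(mapk$effect < 0))
})

test_that("Mann-Whitney exact p matches exhaustive enumeration up to n = 8", {
  set.seed(33)
  for (n1 in 2:8) {
    for (n2 in 2:8) {
      x <- rnorm(n1)
      y <- rnorm(n2)
      p_pkg <- suppressMessages(drug_contrast(
        rbind(d = c(x, y)),
        c(rep("high", n1), rep("low", n2))))$p_raw
      expect_equal(p_pkg, enum_mw_p(x, y), tolerance = 1e-12,
                   label = sprintf("MW n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("paired dynamics uses the exact signed-rank distribution", {
  pre <- c(0, 0, 0)
  post <- c(1, 2, 3)
  out <- paired_dynamics(pre, post)
  expect_equal(out$p_value, 0.25)
  expect_equal(out$median_delta, 2)
  # uniform positive shift: maximal delta; all differences tie, so the
  # tie-corrected approximation applies, still far below any threshold
  set.seed(44)
  pre2 <- rnorm(10)
  out2 <- paired_dynamics(pre2, pre2 + 1)
  expect_equal(out2$median_delta, 1)
  expect_lt(out2$p_value, 0.01)
  # sign flip: same p, negated delta
  out3 <- paired_dynamics(pre2 + 1, pre2)
  expect_equal(out3$p_value, out2$p_value)
  expect_equal(out3$median_delta, -1)
  expect_error(paired_dynamics(c(1, 2, 3), c(1, 2, 3)), "no signal")
})

test_that("signed-rank exact p matches enumeration up to 8 pairs", {
  set.seed(34)
  for (n in 3:8) {
    d <- rnorm(n)
    out <- paired_dynamics(rep(0, n), d)
    expect_equal(out$p_value, enum_wsr_p(d), tolerance = 1e-12,
                 label = sprintf("WSR n=%d", n))
  }
})

test_that("group comparisons: omnibus F, pairwise Holm, linear trend", {
  set.seed(50)
  # identical groups -> F = 0
  v <- rep(c(1, 2, 3), 4)
  g <- rep(c("a", "b"), each = 6)
  expect_equal(group_compare(rep(v[1:6], 2), g, "omnibus")$F, 0)
  # two groups: F equals the squared pooled-variance t statistic
  x <- rnorm(7)
  y <- rnorm(8) + 1
  om <- group_compare(c(x, y), rep(c("a", "b"), c(7, 8)), "omnibus")
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(om$F, unname(tt$statistic)^2)
  expect_equal(om$p_value, tt$p.value)
  # ordered means with tiny noise: trend slope about 1
  vals <- rep(c(0, 1, 2), each = 10) + rnorm(30, sd = 0.01)
  grp <- factor(rep(c("lo", "mid", "hi"), each = 10),
                levels = c("lo", "mid", "hi"))
  tr <- group_compare(vals, grp, "trend")
  expect_equal(tr$slope, 1, tolerance = 0.02)
  expect_lt(tr$p_value, 1e-10)
  pw <- group_compare(vals, grp, "pairwise")
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-15))
  jt <- jonckheere_trend(vals, grp)
  expect_lt(jt$p_value, 1e-6)
  expect_gt(jt$z, 0)
  expect_error(group_compare(vals, rep("a", 30), "omnibus"), "2 groups")
  expect_error(group_compare(vals[1:20], grp[1:20], "trend"), "3 ordered")
})

test_that("log-rank chi-square matches the hand-computed 4-subject value", {
  surv <- data.frame(time = c(1, 2, 3, 4), event = 1,
                     group = c("A", "A", "B", "B"))
  out <- km_logrank(surv)
  expect_equal(out$chisq, 49 / 17, tolerance = 1e-6)
  # identical groups: chi-square 0
  s2 <- data.frame(time = rep(c(1, 2, 3), 2), event = 1,
                   group = rep(c("A", "B"), each = 3))
  expect_equal(km_logrank(s2)$chisq, 0, tolerance = 1e-12)
  # invariant to time-unit rescaling
  s3 <- surv
  s3$time <- s3$time * 365.25
  expect_equal(km_logrank(s3)$chisq, out$chisq)
})

test_that("KM curves are valid product-limit estimates", {
  set.seed(61)
  surv <- data.frame(time = rexp(40), event = rbinom(40, 1, 0.7),
                     group = rep(c("A", "B"), each = 20))
  out <- km_logrank(surv)
  for (g in c("A", "B")) {
    s <- out$curves$surv[out$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  # censoring all of one group before the first event of the other:
  # the censored group contributes no events
  s4 <- data.frame(time = c(1, 2, 0.5, 0.6), event = c(1, 1, 0, 0),
                   group = c("A", "A", "B", "B"))
  expect_error(km_logrank(s4), "at least one event")
  expect_error(km_logrank(data.frame(time = 1:4, event = 1,
                                     group = "A")), "two groups")
})

test_that("null drug contrasts control the per-test type-I error", {
  set.seed(71)
  n <- 40
  act <- matrix(rnorm(500 * n), 500, n,
                dimnames = list(sprintf("d%03d", 1:500), NULL))
  grp <- sample(rep(c("high", "low"), each = n / 2))
  out <- suppressMessages(drug_contrast(act, grp))
  frac <- mean(out$p_raw < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
  expect_lte(mean(out$significant), 0.05 + 0.02)
})
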