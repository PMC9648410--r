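# Minimal hand-built enrichment-result tables for the set/leading-edge
# intersection logic.
mk_result <- function(sets, p_adj, es, le) {
  data.frame(set_name = sets, size = lengths(le), es = es,
             nes = es, p_raw = p_adj, p_adj = p_adj,
             leading_edge = I(le), stringsAsFactors = FALSE)
}

test_that("shared enriched sets require significance and es > 0 in every contrast", {
  le <- list(c("a", "b"), c("c"))
  r_sig <- mk_result(c("S1", "S2"), c(0.01, 0.2), c(0.5, 0.4), le)
  r_all <- mk_result(c("S1", "S2"), c(0.01, 0.01), c(0.5, 0.4), le)
  expect_equal(shared_enriched_sets(list(r_all, r_all, r_all, r_all)),
               c("S1", "S2"))
  # significant in 3/4 contrasts only -> dropped
  expect_equal(shared_enriched_sets(list(r_all, r_all, r_all, r_sig)), "S1")
  # negative enrichment never qualifies
  r_neg <- mk_result(c("S1", "S2"), c(0.01, 0.01), c(0.5, -0.4), le)
  expect_equal(shared_enriched_sets(list(r_all, r_neg)), "S1")
  # cutoff 1 retains every positively enriched set
  expect_equal(shared_enriched_sets(list(r_sig), adj_p_cutoff = 1),
               c("S1", "S2"))
  r_other <- mk_result(c("S1", "S3"), c(0.01, 0.01), c(1, 1), le)
  expect_error(shared_enriched_sets(list(r_all, r_other)), "different")
})

test_that("shared leading-edge genes are the strict intersection", {
  r1 <- mk_result(c("S1", "S2"), c(0.01, 0.01), c(1, 1),
                  list(c("a", "b", "x"), c("a", "b", "y")))
  r2 <- mk_result(c("S1", "S2"), c(0.01, 0.01), c(1, 1),
                  list(c("a", "b", "z"), c("a", "b")))
  expect_equal(shared_leading_edge_genes(list(r1, r2), c("S1", "S2")),
               c("a", "b"))
  # min_support relaxation: x appears in 1 of 4 edges
  expect_true("x" %in% shared_leading_edge_genes(list(r1, r2),
                                                 c("S1", "S2"),
                                                 min_support = 1))
  expect_error(shared_leading_edge_genes(list(r1, r2), "S1"),
               "nothing to intersect")
})

test_that("NE differential expression keeps DDR genes up in NE-high in all cohorts", {
  set.seed(77)
  n_genes <- 120
  genes <- sprintf("g%03d", seq_len(n_genes))
  mk_cohort <- function(planted_shift) {
    m <- matrix(rnorm(n_genes * 24), n_genes, 24,
                dimnames = list(genes, sprintf("c%02d", 1:24)))
    lab <- rep(c(TRUE, FALSE), each = 12)
    m["g001", lab] <- m["g001", lab] + planted_shift
    m["g002", lab] <- m["g002", lab] + planted_shift
    list(m = m, lab = lab)
  }
  c1 <- mk_cohort(2.5)
  c2 <- mk_cohort(2.5)
  ddr <- c("g001", "g003")
  got <- suppressMessages(
    ne_de_genes(list(c1$m, c2$m), list(c1$lab, c2$lab), 0.10, ddr))
  # g001: planted and in the DDR list; g002: planted but not DDR
  expect_equal(got, "g001")
  # significant in one cohort only -> dropped
  c3 <- mk_cohort(0)
  got2 <- suppressMessages(
    ne_de_genes(list(c1$m, c3$m), list(c1$lab, c3$lab), 0.10, ddr))
  expect_equal(got2, character(0))
  # identical class distributions: nothing passes
  got3 <- suppressMessages(
    ne_de_genes(list(c3$m), list(c3$lab), 0.10, genes))
  expect_equal(got3, character(0))
  expect_error(ne_de_genes(list(c1$m), list(rep(TRUE, 24)), 0.1, ddr),
               "NE class")
})

test_that("label shuffling yields an empty NE gene list in most replicates", {
  set.seed(88)
  n_empty <- 0
  for (i in 1:10) {
    m <- matrix(rnorm(100 * 20), 100, 20,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
    lab <- sample(rep(c(TRUE, FALSE), each = 10))
    got <- suppressMessages(
      ne_de_genes(list(m), list(lab), 0.10, rownames(m)))
    n_empty <- n_empty + (length(got) == 0)
  }
  expect_gte(n_empty, 9)
})

test_that("prevalence filter drops genes rarely expressed outside the derivation lineage", {
  set.seed(12)
  mk_panel <- function(vals) {
    m <- matrix(vals, nrow = 2, ncol = 20, byrow = TRUE,
                dimnames = list(c("common", "rare"), NULL))
    m
  }
  panels <- list(
    SCLC = mk_panel(c(5, 5)),
    lungAd = rbind(common = rnorm(20, 5), rare = c(rep(5, 1), rep(0, 19))),
    breast = rbind(common = rnorm(20, 5), rare = rep(0, 20))
  )
  out <- suppressMessages(
    prevalence_filter(panels, c("common", "rare"), floor = 1,
                      min_fraction = 0.10, derivation_lineage = "SCLC"))
  expect_equal(out$retained, "common")   # rare: 1/40 = 2.5% < 10%
  expect_false(out$report$retained[out$report$gene == "rare"])
  # min_fraction 0 retains everything
  out0 <- suppressMessages(
    prevalence_filter(panels, c("common", "rare"), floor = 1,
                      min_fraction = 0, derivation_lineage = "SCLC"))
  expect_equal(out0$retained, c("common", "rare"))
  expect_error(prevalence_filter(panels["SCLC"], "common",
                                 derivation_lineage = "SCLC"),
               "non-derivation")
})

test_that("PC1 weights recover planted structure and orientation", {
  set.seed(55)
  n <- 50
  f <- rnorm(n)
  chars <- matrix(f + rnorm(4 * n, sd = 0.3), n, 4,
                  dimnames = list(sprintf("s%02d", 1:n),
                                  paste0("c", 1:4)))
  # two perfectly correlated variables: loadings 1/sqrt(2) each
  pw2 <- derive_pca_weights(chars[, 1, drop = FALSE],
                            chars[, 1, drop = FALSE] * 3 + 2)
  expect_equal(unname(pw2$char_loadings), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(pw2$weights), 1 / sqrt(2), tolerance = 1e-8)
  # genes loading positively/negatively on the factor get signed weights
  genes <- cbind(gp = f + rnorm(n, sd = 0.4),
                 gn = -f + rnorm(n, sd = 0.4))
  rownames(genes) <- rownames(chars)
  pw <- derive_pca_weights(chars, genes)
  expect_gt(pw$weights["gp"], 0)
  expect_lt(pw$weights["gn"], 0)
  expect_true(sum(pw$char_loadings) > 0)
  # affine rescaling of any input column changes nothing
  genes2 <- genes
  genes2[, 1] <- 100 - 5 * genes[, 1] * -1
  chars2 <- chars
  chars2[, 2] <- chars[, 2] / 7 + 3
  pw_b <- derive_pca_weights(chars2, genes2)
  expect_equal(pw_b$weights, pw$weights, tolerance = 1e-8)
  # sample order is irrelevant
  perm <- sample(n)
  pw_c <- derive_pca_weights(chars[perm, ], genes[perm, ])
  expect_equal(pw_c$weights, pw$weights, tolerance = 1e-8)
  # supplementary mode agrees on signs
  pw_s <- derive_pca_weights(chars, genes, pca_mode = "supplementary")
  expect_gt(pw_s$weights["gp"], 0)
  expect_lt(pw_s$weights["gn"], 0)
  const <- cbind(const = rep(1, n))
  rownames(const) <- rownames(chars)
  expect_error(derive_pca_weights(chars, const), "constant")
  expect_error(derive_pca_weights(chars[1:2, ], genes[1:2, ]), "3")
})

test_that("signature assembly is union minus exclusions with weights attached", {
  lists <- repstress_gene_lists()
  w <- setNames(rep(1, 18), union(lists$leading_edge, lists$ne_repair))
  w[c("POLD4", "POLE4")] <- -1
  sig <- assemble_signature(lists$leading_edge, lists$ne_repair,
                            exclusions = "KPNA2", weights = w)
  expect_length(sig$genes, 17)
  expect_setequal(sig$genes, lists$signature)
  # duplicates collapse
  sig2 <- assemble_signature(c("A", "B"), c("B", "C"), character(),
                             setNames(1:3, c("A", "B", "C")))
  expect_equal(sig2$genes, c("A", "B", "C"))
  # empty NE list: leading edge minus exclusions
  sig3 <- assemble_signature(c("A", "B"), character(), "B",
                             c(A = 1, B = 2))
  expect_equal(sig3$genes, "A")
  expect_error(assemble_signature(c("A", "B"), character(), character(),
                                  c(A = 1)), "without weight")
})

test_that("the derivation pipeline recovers the planted sets and genes", {
  # reduced collection and permutations relative to the headline
  # reproduction run; recovery must be exact at every seed
  for (seed in c(3, 14, 15)) {
    co <- simulate_cohort(cohort_config(n_sets = 20, seed = seed))
    sig <- suppressMessages(derive_signature(
      co$expr, co$cn, co$drug, co$rppa, co$sets,
      co$ne_high_set, co$ne_low_set,
      ddr_genes = repstress_gene_lists()$ne_repair,
      config = derivation_config(seed = seed, n_perm = 400)))
    expect_setequal(sig$provenance$shared_sets, co$truth$signal_sets)
    expect_setequal(sig$provenance$leading_edge, co$truth$signal_genes)
    expect_true(all(coef(sig)[intersect(sig$genes,
                                        co$truth$signal_genes)] > 0))
  }
})
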