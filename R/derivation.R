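#' Derivation configuration
#'
#' Bundles the tunable parameters of the signature derivation with
#' validation. Defaults follow the published procedure: adjusted
#' P < 0.05 for shared enriched sets, FDR < 10% for the NE differential
#' expression step, and a prevalence rule (expressed above 1.0 log2
#' units in at least 10% of non-derivation-lineage samples) mirroring
#' the KPNA2 exclusion rationale.
#'
#' @param adj_p_cutoff Adjusted-P cutoff for shared enriched sets.
#' @param de_fdr_cutoff BH FDR cutoff for NE differential expression.
#' @param prevalence_floor Expression floor (log2 units) defining
#'   "expressed" in the prevalence filter.
#' @param prevalence_min_fraction Minimum fraction of non-derivation
#'   samples expressing a gene for it to be retained.
#' @param exclusions Gene identifiers removed from the final signature.
#' @param seed Integer seed for the permutation tests (required).
#' @param n_perm Permutations for [gsea_significance()].
#' @param scheme Permutation scheme, `"gene_set"` or `"phenotype"`.
#' @param exponent Classic-GSEA hit-weight exponent.
#' @param ssgsea_exponent ssGSEA rank-weight exponent.
#' @param metric Two-group ranking metric (see [gsea_rank_metric()]).
#' @param pca_mode `"joint"` or `"supplementary"`
#'   (see [derive_pca_weights()]).
#' @param min_support Leading-edge intersection relaxation: minimum
#'   number of (set x contrast) leading edges a gene must appear in;
#'   `NULL` (default) requires all of them.
#' @return List of class `derivation_config`.
#' @export
derivation_config <- function(adj_p_cutoff = 0.05, de_fdr_cutoff = 0.10,
                              prevalence_floor = 1.0,
                              prevalence_min_fraction = 0.10,
                              exclusions = character(), seed,
                              n_perm = 1000,
                              scheme = c("gene_set", "phenotype"),
                              exponent = 1, ssgsea_exponent = 0.25,
                              metric = c("s2n", "diffmean"),
                              pca_mode = c("joint", "supplementary"),
                              min_support = NULL) {
  if (missing(seed)) stop("seed is required")
  stopifnot(adj_p_cutoff > 0, adj_p_cutoff <= 1,
            de_fdr_cutoff > 0, de_fdr_cutoff <= 1,
            prevalence_min_fraction >= 0, prevalence_min_fraction <= 1)
  structure(list(adj_p_cutoff = adj_p_cutoff,
                 de_fdr_cutoff = de_fdr_cutoff,
                 prevalence_floor = prevalence_floor,
                 prevalence_min_fraction = prevalence_min_fraction,
                 exclusions = exclusions, seed = as.integer(seed),
                 n_perm = n_perm, scheme = match.arg(scheme),
                 exponent = exponent, ssgsea_exponent = ssgsea_exponent,
                 metric = match.arg(metric),
                 pca_mode = match.arg(pca_mode),
                 min_support = min_support),
            class = "derivation_config")
}

#' Gene sets commonly enriched across all characteristic contrasts
#'
#' Retains the sets that are positively enriched (`es > 0`) with
#' adjusted P below the cutoff in every contrast.
#'
#' @param results Named list of [gsea_significance()] data.frames, one
#'   per characteristic contrast, all over the same set collection.
#' @param adj_p_cutoff Adjusted-P cutoff (default 0.05).
#' @return Character vector of set names.
#' @export
shared_enriched_sets <- function(results, adj_p_cutoff = 0.05) {
  if (length(results) < 1L) stop("need at least one contrast")
  namesets <- lapply(results, function(r) sort(r$set_name))
  if (length(unique(namesets)) != 1L)
    stop("contrasts cover different set collections")
  hits <- lapply(results, function(r)
    r$set_name[r$p_adj < adj_p_cutoff & r$es > 0])
  Reduce(intersect, hits)
}

#' Shared leading-edge genes of the commonly enriched sets
#'
#' Genes present in the leading edge of every shared set in every
#' contrast (strict intersection). `min_support` relaxes the rule to
#' presence in at least that many of the (set x contrast) leading
#' edges.
#'
#' @param results Named list of [gsea_significance()] data.frames.
#' @param shared_sets Set names from [shared_enriched_sets()]
#'   (at least 2).
#' @param min_support Optional integer; `NULL` means all.
#' @return Character vector of gene identifiers.
#' @export
shared_leading_edge_genes <- function(results, shared_sets,
                                      min_support = NULL) {
  if (length(shared_sets) < 2L) stop("nothing to intersect")
  edges <- list()
  for (r in results) {
    for (s in shared_sets) {
      i <- match(s, r$set_name)
      if (is.na(i)) stop("shared set missing from a contrast: ", s)
      edges[[length(edges) + 1L]] <- r$leading_edge[[i]]
    }
  }
  need <- if (is.null(min_support)) length(edges)
          else min(min_support, length(edges))
  tab <- table(unlist(edges))
  sort(names(tab)[tab >= need])
}

#' DNA-repair genes up in neuroendocrine-high samples across cohorts
#'
#' Per cohort, each gene is tested NE-high versus NE-low by two-sided
#' Mann-Whitney U test with Benjamini-Hochberg adjustment across genes;
#' a gene is called in a cohort when adjusted p is below the FDR cutoff
#' and its median is higher in NE-high. Genes called in every cohort
#' are intersected with the DNA-damage-repair list.
#'
#' @param expr_cohorts List of genes x samples matrices (>= 1 cohort).
#' @param ne_labels List of logical vectors (TRUE = NE-high), parallel
#'   to `expr_cohorts`.
#' @param fdr_cutoff BH FDR cutoff (default 0.10).
#' @param ddr_genes Character vector of DNA-repair pathway genes.
#' @return Character vector of gene identifiers.
#' @export
ne_de_genes <- function(expr_cohorts, ne_labels, fdr_cutoff = 0.10,
                        ddr_genes) {
  if (length(expr_cohorts) < 1L) stop("need at least one cohort")
  if (length(expr_cohorts) != length(ne_labels))
    stop("one label vector per cohort required")
  per_cohort <- vector("list", length(expr_cohorts))
  for (c in seq_along(expr_cohorts)) {
    expr <- as.matrix(expr_cohorts[[c]])
    lab <- as.logical(ne_labels[[c]])
    if (sum(lab) < 2L || sum(!lab) < 2L)
      stop("cohort ", c, " needs >= 2 samples per NE class")
    hi <- expr[, lab, drop = FALSE]
    lo <- expr[, !lab, drop = FALSE]
    p <- vapply(seq_len(nrow(expr)), function(g)
      suppressWarnings(stats::wilcox.test(hi[g, ], lo[g, ],
                                          exact = NULL)$p.value),
      numeric(1))
    up <- apply(hi, 1, stats::median) > apply(lo, 1, stats::median)
    padj <- bh_adjust(p)
    per_cohort[[c]] <- rownames(expr)[padj < fdr_cutoff & up]
    message("NE DE cohort ", c, ": ", length(per_cohort[[c]]),
            " gene(s) up in NE-high at FDR ", fdr_cutoff)
  }
  sort(intersect(Reduce(intersect, per_cohort), ddr_genes))
}

#' Prevalence filter against non-derivation lineages
#'
#' Retains a candidate gene only when it is expressed (strictly above
#' `floor`) in at least `min_fraction` of samples pooled over the
#' lineages other than the derivation lineage. Mirrors the exclusion of
#' genes rarely expressed outside the derivation disease.
#'
#' @param expr_panels Named list of genes x samples matrices, one per
#'   lineage.
#' @param candidates Candidate gene identifiers.
#' @param floor Expression floor (default 1.0, log2 units).
#' @param min_fraction Minimum expressing fraction (default 0.10).
#' @param derivation_lineage Name of the lineage the signature was
#'   derived in (excluded from the assessment).
#' @return List with `retained` (character) and `report` (data.frame:
#'   gene, fraction_expressed, retained).
#' @export
prevalence_filter <- function(expr_panels, candidates, floor = 1.0,
                              min_fraction = 0.10, derivation_lineage) {
  others <- setdiff(names(expr_panels), derivation_lineage)
  if (length(others) == 0L) stop("no non-derivation lineage present")
  pooled <- do.call(cbind, lapply(expr_panels[others], function(m)
    as.matrix(m)[candidates, , drop = FALSE]))
  frac <- rowMeans(pooled > floor)
  report <- data.frame(gene = candidates, fraction_expressed = frac,
                       retained = frac >= min_fraction,
                       stringsAsFactors = FALSE, row.names = NULL)
  message("prevalence filter: ", sum(report$retained), "/",
          length(candidates), " candidate(s) retained")
  list(retained = report$gene[report$retained], report = report)
}

#' First-principal-component gene weights
#'
#' Joint mode (default): z-scores the four characteristic scores and
#' the candidate gene expression over the shared samples, takes the
#' first right singular vector of the combined samples x (4 + G)
#' matrix, orients it so the characteristic loadings sum positive, and
#' returns the gene loadings as weights. Supplementary mode runs the
#' PCA on the characteristics alone and projects each gene as the
#' correlation of its expression with the PC1 sample scores.
#'
#' @param char_scores Samples x characteristics numeric matrix
#'   (rownames = sample ids), e.g. from [characteristic_scores()].
#' @param candidate_expr Samples x genes numeric matrix over the same
#'   samples.
#' @param pca_mode `"joint"` (default) or `"supplementary"`.
#' @return List with `weights` (named per gene), `char_loadings`, and
#'   `mode`.
#' @export
derive_pca_weights <- function(char_scores, candidate_expr,
                               pca_mode = c("joint", "supplementary")) {
  pca_mode <- match.arg(pca_mode)
  char_scores <- as.matrix(char_scores)
  candidate_expr <- as.matrix(candidate_expr)
  common <- intersect(rownames(char_scores), rownames(candidate_expr))
  if (length(common) < 3L) stop("need at least 3 shared samples")
  ch <- char_scores[common, , drop = FALSE]
  ge <- candidate_expr[common, , drop = FALSE]
  if (any(apply(ch, 2, stats::sd) == 0) || any(apply(ge, 2, stats::sd) == 0))
    stop("constant variable")
  chz <- scale(ch)
  gez <- scale(ge)
  if (pca_mode == "joint") {
    x <- cbind(chz, gez)
    sv <- svd(x, nu = 0, nv = 1)
    v <- drop(sv$v)
    if (sum(v[seq_len(ncol(ch))]) < 0) v <- -v
    char_loadings <- stats::setNames(v[seq_len(ncol(ch))], colnames(ch))
    weights <- stats::setNames(v[-seq_len(ncol(ch))], colnames(ge))
  } else {
    sv <- svd(chz, nu = 1, nv = 1)
    v1 <- drop(sv$v)
    if (sum(v1) < 0) {
      v1 <- -v1
      sv$u <- -sv$u
    }
    scores1 <- drop(chz %*% v1)
    char_loadings <- stats::setNames(v1, colnames(ch))
    weights <- apply(gez, 2, function(g) stats::cor(g, scores1))
  }
  list(weights = weights, char_loadings = char_loadings, mode = pca_mode)
}

#' Assemble a signature from its component gene lists
#'
#' Ordered union of the shared leading-edge genes and the NE-associated
#' repair genes, with duplicates collapsed, exclusions removed and
#' weights attached. Every retained gene must have a weight.
#'
#' @param leading_edge Character vector of shared leading-edge genes.
#' @param ne_repair Character vector of NE-associated repair genes.
#' @param exclusions Gene identifiers to drop (e.g. `"KPNA2"`).
#' @param weights Named numeric weights covering all retained genes.
#' @param provenance Optional provenance list stored on the object.
#' @return A [repstress_signature()].
#' @export
assemble_signature <- function(leading_edge, ne_repair,
                               exclusions = character(), weights,
                               provenance = list()) {
  genes <- setdiff(union(leading_edge, ne_repair), exclusions)
  if (length(genes) == 0L) stop("no gene survives assembly")
  absent <- setdiff(genes, names(weights))
  if (length(absent))
    stop("retained gene(s) without weight: ", paste(absent, collapse = ", "))
  provenance$leading_edge <- leading_edge
  provenance$ne_repair <- ne_repair
  provenance$exclusions <- exclusions
  repstress_signature(genes, weights[genes], provenance)
}

#' Derive a repstress signature from a characterized cohort
#'
#' The end-to-end discovery pipeline. Samples are stratified by the
#' four replication-stress characteristics (MYC-paralog amplification,
#' checkpoint-inhibitor sensitivity, high p-Chk1, NE differentiation);
#' each characteristic defines a two-group GSEA contrast over the gene
#' set collection; sets positively enriched in all four contrasts at
#' the adjusted-P cutoff are intersected and their shared leading-edge
#' genes extracted; DNA-repair genes up in NE-high samples (BH FDR) in
#' every NE cohort are added; an optional prevalence filter and
#' explicit exclusions are applied; finally each retained gene is
#' weighted by its first-principal-component loading alongside the
#' characteristic scores.
#'
#' @param expr Genes x samples log-scale expression matrix of the
#'   derivation cohort.
#' @param cn Samples x genes copy-number score table (MYC paralogs).
#' @param drug Samples x drugs activity score table.
#' @param rppa Samples x antibodies RPPA table.
#' @param gene_sets Named list of gene sets (the enrichment universe).
#' @param ne_high_set,ne_low_set The 25-gene high/low NE sets.
#' @param ddr_genes DNA-damage-repair pathway gene list.
#' @param config A [derivation_config()].
#' @param ne_cohorts Optional list of extra NE differential-expression
#'   cohorts, each a list with elements `expr` and `ne_high`; the
#'   derivation cohort with its own NE calls is always included first.
#' @param prevalence_panels Optional named list of genes x samples
#'   matrices per lineage for [prevalence_filter()].
#' @param derivation_lineage Lineage name of the derivation cohort in
#'   `prevalence_panels`.
#' @return A [repstress_signature()] whose provenance records the
#'   shared sets, component gene lists, filter counts and parameters.
#' @export
derive_signature <- function(expr, cn, drug, rppa, gene_sets,
                             ne_high_set, ne_low_set, ddr_genes, config,
                             ne_cohorts = NULL,
                             prevalence_panels = NULL,
                             derivation_lineage = NULL) {
  stopifnot(inherits(config, "derivation_config"))
  expr <- as.matrix(expr)

  chars <- characteristic_table(
    call_myc_amplified(cn),
    call_checkpoint_sensitive(drug),
    call_pchk1_high(rppa),
    ne_status(expr, ne_high_set, ne_low_set,
              exponent = config$ssgsea_exponent))
  calls <- c("myc_amp", "cpi_sensitive", "pchk1_high", "ne_high")
  complete <- chars[stats::complete.cases(chars[, calls]), , drop = FALSE]
  complete <- complete[complete$sample_id %in% colnames(expr), , drop = FALSE]
  message("derivation cohort: ", nrow(complete), "/", nrow(chars),
          " sample(s) complete in all four characteristics")
  ex <- expr[, complete$sample_id, drop = FALSE]

  contrasts <- lapply(stats::setNames(calls, calls), function(cc)
    gsea_significance(ex, complete[[cc]], gene_sets,
                      n_perm = config$n_perm, scheme = config$scheme,
                      seed = config$seed, exponent = config$exponent,
                      metric = config$metric))
  shared <- shared_enriched_sets(contrasts, config$adj_p_cutoff)
  message("shared enriched sets: ", length(shared), " (",
          paste(shared, collapse = ", "), ")")
  le_genes <- shared_leading_edge_genes(contrasts, shared,
                                        min_support = config$min_support)
  message("shared leading-edge genes: ", length(le_genes))

  de_exprs <- c(list(ex), lapply(ne_cohorts, `[[`, "expr"))
  de_labels <- c(list(complete$ne_high), lapply(ne_cohorts, `[[`, "ne_high"))
  ne_genes <- ne_de_genes(de_exprs, de_labels,
                          fdr_cutoff = config$de_fdr_cutoff,
                          ddr_genes = ddr_genes)
  message("NE-associated repair genes: ", length(ne_genes))

  candidates <- union(le_genes, ne_genes)
  prevalence_report <- NULL
  exclusions <- config$exclusions
  if (!is.null(prevalence_panels)) {
    pf <- prevalence_filter(prevalence_panels, candidates,
                            floor = config$prevalence_floor,
                            min_fraction = config$prevalence_min_fraction,
                            derivation_lineage = derivation_lineage)
    exclusions <- union(exclusions, setdiff(candidates, pf$retained))
    prevalence_report <- pf$report
  }
  retained <- setdiff(candidates, exclusions)
  if (length(retained) == 0L) stop("no candidate gene survives filtering")

  cs <- characteristic_scores(complete)
  pw <- derive_pca_weights(cs, t(ex[retained, , drop = FALSE]),
                           pca_mode = config$pca_mode)
  assemble_signature(le_genes, ne_genes, exclusions, pw$weights,
                     provenance = list(
                       derived_from = "derive_signature",
                       shared_sets = shared,
                       n_samples = nrow(complete),
                       char_loadings = pw$char_loadings,
                       pca_mode = pw$mode,
                       prevalence_report = prevalence_report,
                       config = unclass(config)))
}
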