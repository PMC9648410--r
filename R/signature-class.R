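#' Construct a repstress signature object
#'
#' A signature is an ordered set of genes with real-valued weights plus
#' a provenance record of how it was derived. Scoring a cohort with a
#' signature is the weighted sum of within-sample z-scored expression
#' of its genes (see [predict.repstress_signature()]).
#'
#' @param genes Character vector of unique gene identifiers.
#' @param weights Numeric weights, one per gene.
#' @param provenance Optional list of derivation parameters (cutoffs,
#'   seeds, cohort identifiers, filter counts).
#' @return An object of class `repstress_signature`.
#' @export
repstress_signature <- function(genes, weights, provenance = list()) {
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  if (length(genes) != length(weights))
    stop("genes and weights differ in length")
  if (length(genes) == 0L) stop("empty signature")
  if (anyNA(weights) || all(weights == 0))
    stop("signature needs at least one nonzero finite weight")
  structure(list(genes = as.character(genes),
                 weights = stats::setNames(as.numeric(weights),
                                           as.character(genes)),
                 provenance = provenance),
            class = "repstress_signature")
}

#' @export
print.repstress_signature <- function(x, ...) {
  cat("repstress signature:", length(x$genes), "genes\n")
  neg <- names(x$weights)[x$weights < 0]
  cat("  negative-weight genes:",
      if (length(neg)) paste(neg, collapse = ", ") else "none", "\n")
  if (!is.null(x$provenance$derived_from))
    cat("  derived from:", x$provenance$derived_from, "\n")
  invisible(x)
}

#' @export
summary.repstress_signature <- function(object, ...) {
  w <- sort(object$weights, decreasing = TRUE)
  cat("repstress signature with", length(w), "genes\n\n")
  print(round(w, 4))
  prov <- object$provenance
  if (length(prov)) {
    cat("\nprovenance:\n")
    for (k in names(prov))
      if (is.atomic(prov[[k]]) && length(prov[[k]]) <= 8)
        cat(" ", k, "=", paste(prov[[k]], collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.repstress_signature <- function(object, ...) object$weights

#' @export
plot.repstress_signature <- function(x, ...) {
  w <- sort(x$weights)
  graphics::barplot(w, horiz = TRUE, las = 1,
                    xlab = "PC1 loading (gene weight)",
                    col = ifelse(w < 0, "firebrick", "grey35"), ...)
  invisible(x)
}

#' Score a cohort with a repstress signature
#'
#' The full scoring path: within-sample z-scoring of the expression
#' matrix across all genes, weighted sum over signature genes (the raw
#' repstress score), z-normalisation of raw scores across the analysis
#' samples, and percentile-based extreme-group classification.
#'
#' @param object A `repstress_signature`.
#' @param newdata Numeric matrix, genes x samples, log-scale expression.
#' @param missing One of `"error"` (default; any absent signature gene
#'   is an error) or `"renormalize"` (weights rescaled over present
#'   genes to preserve the total absolute weight, with a warning).
#' @param groups If TRUE (default), classify samples into
#'   high/low/mid groups with [classify_extremes()]; needs >= 4 samples.
#' @param hi_pct,lo_pct Percentile cutoffs passed to
#'   [classify_extremes()].
#' @param ... Unused.
#' @return data.frame with `sample_id`, `raw_score`, `norm_score` and,
#'   when `groups` is TRUE, `group`.
#' @export
predict.repstress_signature <- function(object, newdata,
                                        missing = c("error", "renormalize"),
                                        groups = TRUE,
                                        hi_pct = 75, lo_pct = 25, ...) {
  missing <- match.arg(missing)
  z <- zscore_within_sample(newdata)
  raw <- repstress_raw(z, object, missing_policy = missing)
  norm <- normalize_scores(raw)
  out <- data.frame(sample_id = names(raw), raw_score = unname(raw),
                    norm_score = unname(norm),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (groups) out$group <- unname(classify_extremes(norm, hi_pct, lo_pct))
  out
}

#' The packaged 17-gene repstress signature
#'
#' Gene list of the published replication-stress signature: the 10
#' retained shared leading-edge genes of the E2F-target and G2-M
#' checkpoint enrichments (KPNA2 was excluded for sparse expression
#' outside small cell lung cancer) plus the 7 DNA-repair genes
#' associated with neuroendocrine differentiation. The numeric weights
#' are synthetic: the published loadings live in external supplementary
#' data, so the packaged weights are equal-magnitude placeholders that
#' carry only the published sign pattern (negative for POLD4 and POLE4,
#' positive otherwise). Re-derive weights on your own cohort with
#' [derive_signature()] for any quantitative use.
#'
#' @return A `repstress_signature` with 17 genes and synthetic weights.
#' @export
default_signature <- function() {
  repstress_signature(
    genes = repstress_gene_lists()$signature,
    weights = ifelse(repstress_gene_lists()$signature %in%
                       c("POLD4", "POLE4"), -1, 1),
    provenance = list(derived_from = "packaged gene list",
                      weights = "synthetic sign-only placeholders")
  )
}

#' Published repstress derivation gene lists
#'
#' The component gene lists of the published signature: the 11 shared
#' leading-edge genes of the two commonly enriched hallmark sets, the 7
#' neuroendocrine-associated DNA-repair genes, the exclusion (KPNA2,
#' rarely expressed outside small cell lung cancer), and the resulting
#' 17-gene signature.
#'
#' @return Named list with `leading_edge`, `ne_repair`, `excluded`,
#'   `signature`.
#' @export
repstress_gene_lists <- function() {
  le <- c("AURKB", "CCNA2", "GINS1", "KPNA2", "LIG3", "MTF2", "ORC6",
          "PRPS1", "SRSF1", "SUV39H1", "TNPO2")
  ne <- c("GADD45G", "POLA1", "POLD4", "POLE4", "RFC5", "RMI1", "RRM1")
  excl <- "KPNA2"
  list(leading_edge = le, ne_repair = ne, excluded = excl,
       signature = setdiff(union(le, ne), excl))
}
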