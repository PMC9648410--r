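#' MYC-paralog amplification call
#'
#' A sample is called MYC-amplified when the maximum copy-number score
#' over the MYC paralogs (MYC, MYCL, MYCN by default) is at or above the
#' 0.7 cutoff. The copy-number score is the average log2 probe-intensity
#' ratio of the gene's segment relative to normal DNA.
#'
#' @param cn Numeric matrix or data.frame, samples x genes, with gene
#'   column names and sample rownames.
#' @param paralogs Gene identifiers to scan (default the MYC family).
#' @param cutoff Amplification cutoff, called with `>=` (default 0.7).
#' @return data.frame with `sample_id`, `myc_cn_score` (max over
#'   paralogs, NA propagated when all are missing) and logical `myc_amp`.
#' @export
call_myc_amplified <- function(cn, paralogs = c("MYC", "MYCL", "MYCN"),
                               cutoff = 0.7) {
  cn <- as.matrix(cn)
  present <- intersect(paralogs, colnames(cn))
  if (length(present) == 0L) stop("no MYC paralog column present")
  score <- apply(cn[, present, drop = FALSE], 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  data.frame(sample_id = rownames(cn), myc_cn_score = score,
             myc_amp = score >= cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Checkpoint-inhibitor sensitivity call
#'
#' A sample is called sensitive when its drug activity score (a
#' z-standardised potency measure) strictly exceeds the cutoff for at
#' least one of the configured cell-cycle checkpoint inhibitors — by
#' default the CHK1 inhibitor AZD-7762 (NSC 754352) and the WEE1
#' inhibitor MK-1775 (NSC 757148).
#'
#' @param activity Numeric matrix or data.frame, samples x drugs, drug
#'   identifiers as column names.
#' @param drugs Drug identifiers to scan.
#' @param cutoff Sensitivity cutoff, strict `>` (default 6).
#' @return data.frame with `sample_id`, `cpi_activity` (max over drugs)
#'   and logical `cpi_sensitive`; both NA when all activities are
#'   missing for a sample (missingness is propagated, never imputed).
#' @export
call_checkpoint_sensitive <- function(activity,
                                      drugs = c("AZD-7762", "MK-1775"),
                                      cutoff = 6) {
  activity <- as.matrix(activity)
  present <- intersect(drugs, colnames(activity))
  if (length(present) == 0L) stop("none of the checkpoint drugs present")
  score <- apply(activity[, present, drop = FALSE], 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  data.frame(sample_id = rownames(activity), cpi_activity = score,
             cpi_sensitive = score > cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Phosphorylated-Chk1 high call
#'
#' High p-Chk1 is a reverse-phase protein array (RPPA) value for the
#' Chk1_pS345 antibody strictly above the cutoff.
#'
#' @param rppa Numeric matrix or data.frame, samples x antibodies.
#' @param antibody Antibody column to use (default `"Chk1_pS345"`).
#' @param cutoff Strict `>` cutoff (default 0.15).
#' @return data.frame with `sample_id`, `pchk1_value`, logical
#'   `pchk1_high`.
#' @export
call_pchk1_high <- function(rppa, antibody = "Chk1_pS345", cutoff = 0.15) {
  rppa <- as.matrix(rppa)
  if (!antibody %in% colnames(rppa))
    stop("antibody column absent: ", antibody)
  v <- rppa[, antibody]
  data.frame(sample_id = rownames(rppa), pchk1_value = as.numeric(v),
             pchk1_high = as.numeric(v) > cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Neuroendocrine differentiation status
#'
#' Scores each sample by single-sample GSEA of the 25-gene high-NE set
#' and the 25-gene low-NE set separately; the difference
#' (`high - low`) is the NE delta, and a sample is NE-high when the
#' delta is strictly positive (a tie classifies as low).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param ne_high_set,ne_low_set Disjoint character vectors of gene
#'   identifiers.
#' @param exponent ssGSEA rank-weight exponent (default 0.25).
#' @return data.frame with `sample_id`, `ne_delta`, logical `ne_high`.
#' @export
ne_status <- function(expr, ne_high_set, ne_low_set, exponent = 0.25) {
  if (length(intersect(ne_high_set, ne_low_set)) > 0L)
    stop("NE gene sets must be disjoint")
  if (!any(rownames(expr) %in% ne_high_set) ||
      !any(rownames(expr) %in% ne_low_set))
    stop("NE gene sets do not overlap the expression matrix")
  delta <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    names(x) <- rownames(expr)
    ssgsea_es(x, ne_high_set, exponent) - ssgsea_es(x, ne_low_set, exponent)
  }, numeric(1))
  data.frame(sample_id = colnames(expr), ne_delta = delta,
             ne_high = delta > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the four-characteristic table
#'
#' Joins the four per-characteristic calls on `sample_id` into one
#' table, one row per sample. Samples missing any characteristic are
#' kept (with NA); downstream derivation excludes them with a message.
#'
#' @param myc,cpi,pchk1,ne data.frames from [call_myc_amplified()],
#'   [call_checkpoint_sensitive()], [call_pchk1_high()], [ne_status()].
#' @return data.frame keyed by `sample_id` with all continuous scores
#'   and binary calls.
#' @export
characteristic_table <- function(myc, cpi, pchk1, ne) {
  out <- Reduce(function(a, b) merge(a, b, by = "sample_id", all = TRUE),
                list(myc, cpi, pchk1, ne))
  out[order(out$sample_id), , drop = FALSE]
}

#' Continuous characteristic score matrix
#'
#' Extracts the four continuous characteristic scores (MYC copy-number,
#' checkpoint-inhibitor activity, p-Chk1 RPPA value, NE delta) for
#' samples complete in all four, and z-scores each column across
#' samples (n-1 denominator). This matrix seeds the PCA weighting.
#'
#' @param table data.frame from [characteristic_table()].
#' @return Numeric matrix, samples x 4, rownames = sample ids, columns
#'   `myc_cn_score`, `cpi_activity`, `pchk1_value`, `ne_delta`.
#' @export
characteristic_scores <- function(table) {
  cols <- c("myc_cn_score", "cpi_activity", "pchk1_value", "ne_delta")
  if (!all(cols %in% names(table)))
    stop("characteristic table lacks continuous fields")
  m <- as.matrix(table[, cols])
  rownames(m) <- table$sample_id
  keep <- stats::complete.cases(m)
  if (sum(!keep) > 0L)
    message(sum(!keep), " sample(s) dropped for missing characteristics")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate characteristic: zero variance")
  scale(m)[, , drop = FALSE]
}
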