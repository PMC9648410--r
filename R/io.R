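#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, ds, members)
    paste(c(nm, ds, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV: first column gene identifiers, remaining columns samples.
#' GCT (version 1.2): two header lines then the same layout with a
#' Description column, which is dropped.
#'
#' @param path Path to a `.tsv`/`.txt` or `.gct` file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) {
    df <- utils::read.delim(path, skip = 2, check.names = FALSE)
    rn <- df[[1]]
    df <- df[, -(1:2), drop = FALSE]
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- rn
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Genes x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample annotation table
#'
#' TSV keyed by a `sample_id` column; remaining columns become a
#' numeric matrix with sample rownames (the layout consumed by the
#' characteristic calls).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, samples x variables.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("annotation needs a sample_id column")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Write a signature to JSON
#'
#' Layout: `{genes: [{symbol, weight}, ...], provenance: {...}}`.
#'
#' @param sig A [repstress_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_json <- function(sig, path) {
  stopifnot(inherits(sig, "repstress_signature"))
  prov <- sig$provenance
  prov <- prov[vapply(prov, function(x)
    is.atomic(x) || is.list(x) && !is.data.frame(x), logical(1))]
  obj <- list(genes = data.frame(symbol = sig$genes,
                                 weight = unname(sig$weights)),
              provenance = prov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a signature from JSON
#'
#' @param path Path written by [write_signature_json()].
#' @return A [repstress_signature()].
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  repstress_signature(obj$genes$symbol, obj$genes$weight,
                      provenance = as.list(obj$provenance))
}
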