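#' Construct a validated expression matrix
#'
#' The cohort container used throughout the package: a numeric matrix of
#' log2 expression values (genes in rows, samples in columns) plus a
#' per-gene biotype label distinguishing lncRNA from mRNA rows.
#'
#' @param values Numeric matrix, rows = gene ids, columns = sample ids.
#' @param biotype Character vector, one of `"lncRNA"`/`"mRNA"` per gene;
#'   may be named by gene id.
#' @return A list of class `"expr_matrix"` with elements `values` and
#'   `biotype` (named by gene id).
#' @export
expression_matrix <- function(values, biotype) {
  if (!is.matrix(values) || !is.numeric(values))
    .fail("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .fail("'values' must have gene row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) .fail("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) .fail("duplicate sample id: ", paste(unique(dup), collapse = ", "))
  if (ncol(values) < 2L) .fail("expression matrix needs at least 2 samples")
  if (any(!is.finite(values))) .fail("expression values must all be finite")
  if (length(biotype) != nrow(values))
    .fail("'biotype' must have one label per gene")
  if (!all(biotype %in% c("lncRNA", "mRNA")))
    .fail("biotype labels must be 'lncRNA' or 'mRNA'")
  biotype <- stats::setNames(as.character(biotype), rownames(values))
  structure(list(values = values, biotype = biotype), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes (%d lncRNA, %d mRNA) x %d samples\n",
              nrow(x$values), sum(x$biotype == "lncRNA"),
              sum(x$biotype == "mRNA"), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset lncRNA or mRNA rows of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param biotype `"lncRNA"` or `"mRNA"`.
#' @return The numeric sub-matrix of the requested biotype.
#' @export
expr_rows <- function(x, biotype = c("lncRNA", "mRNA")) {
  biotype <- match.arg(biotype)
  x$values[x$biotype == biotype, , drop = FALSE]
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids, gene ids in the first column, and an
#' optional `biotype` column (`lncRNA`/`mRNA`); all remaining cells numeric.
#' Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (ncol(df) < 3L) .fail("expression TSV needs a gene column and >= 2 samples")
  genes <- df[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) .fail("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  df <- df[, -1L, drop = FALSE]
  if ("biotype" %in% names(df)) {
    biotype <- df[["biotype"]]
    df <- df[, names(df) != "biotype", drop = FALSE]
  } else {
    biotype <- rep("lncRNA", length(genes))
  }
  vals <- suppressWarnings(vapply(df, as.numeric, numeric(length(genes))))
  if (length(genes) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(df)))
  bad <- which(is.na(vals) & df != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    .fail(sprintf("non-numeric expression cell at gene '%s', sample '%s'",
                  genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  rownames(vals) <- genes
  expression_matrix(vals, biotype)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; emits gene id, biotype, then one
#' column per sample, at full precision.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), biotype = unname(x$biotype),
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

.clinical_columns <- c("sample", "location", "mmr", "cimp", "cin", "braf",
                       "kras", "tp53", "subtype", "rfs_time", "rfs_event",
                       "stage")

#' Read a clinical annotation table from TSV
#'
#' Requires the columns `sample`, `location` (distal/proximal), `mmr`
#' (dMMR/pMMR), `cimp` (pos/neg), `cin` (high/low), `braf`/`kras`/`tp53`
#' (mut/wt), `subtype` (C1--C6), `rfs_time` (years), `rfs_event` (0/1) and
#' `stage`; any value may be NA, but an `rfs_time` without an `rfs_event`
#' is rejected.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with validated columns.
#' @export
read_clinical_table <- function(path) {
  df <- .read_tsv(path)
  validate_clinical(df)
}

#' @rdname read_clinical_table
#' @param clinical A data frame to validate in place.
#' @export
validate_clinical <- function(clinical) {
  missing_cols <- setdiff(.clinical_columns, names(clinical))
  if (length(missing_cols))
    .fail("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(clinical$sample))
    .fail("duplicate sample id in clinical table")
  if (!all(is.na(clinical$rfs_event) | clinical$rfs_event %in% c(0, 1)))
    .fail("rfs_event must be 0, 1 or NA")
  bad <- !is.na(clinical$rfs_time) & is.na(clinical$rfs_event)
  if (any(bad))
    .fail("rfs_event missing for sample(s) with rfs_time: ",
          paste(utils::head(clinical$sample[bad], 3L), collapse = ", "))
  if (any(!is.na(clinical$rfs_time) & clinical$rfs_time < 0))
    .fail("rfs_time must be nonnegative")
  clinical
}

#' @rdname read_clinical_table
#' @param path Output path.
#' @export
write_clinical_table <- function(clinical, path) {
  .write_tsv(clinical[, .clinical_columns], path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene ids. Duplicate genes within a set are
#' stored once (with a warning); empty sets and duplicate set names are
#' errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `"descriptions"`
#'   attribute (named character vector).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    .fail("duplicate gene-set name: ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- vector("list", length(parts))
  desc <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L) .fail("gene set '", nm[i], "' is empty")
    desc[i] <- p[2L]
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) .fail("gene set '", nm[i], "' is empty")
    if (anyDuplicated(genes)) {
      warning("gene set '", nm[i], "' lists duplicate genes; stored once",
              call. = FALSE)
      genes <- unique(genes)
    }
    sets[[i]] <- genes
  }
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
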