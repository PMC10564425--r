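#' Construct an expression matrix
#'
#' The core container of the package: a numeric genes x samples matrix with
#' unique gene symbols as rownames and unique sample identifiers as colnames.
#' Samples are always columns. The scale of the values (log2 intensities vs
#' raw counts) is recorded explicitly because downstream scoring assumes
#' log-scale input while the single-cell QC filter assumes counts; callers
#' must declare which they have.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Rownames
#'   and colnames are required and must be unique after whitespace trimming.
#' @param scale_tag one of `"log2"` or `"counts"`.
#' @return a matrix of class `"expr_matrix"` with a `scale_tag` attribute.
#' @export
expression_matrix <- function(values, scale_tag = c("log2", "counts")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)", call. = FALSE)
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale_tag")))
  invisible(x)
}

#' Read an expression table
#'
#' Reads a delimited gene x sample table (first column gene ids, header row
#' sample ids). Duplicate gene rows are collapsed by their arithmetic mean
#' with a warning; non-numeric cells or missing values are an error rather
#' than being imputed.
#'
#' @param path path to a TSV/CSV file.
#' @param scale_tag declared scale of the values, `"log2"` or `"counts"`.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale_tag = c("log2", "counts"), sep = NULL) {
  scale_tag <- match.arg(scale_tag)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (ncol(tab) < 2L || nrow(tab) < 1L)
    stop("malformed expression table: need a gene id column plus >= 1 sample",
         call. = FALSE)
  genes <- trimws(as.character(tab[[1L]]))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]))
      stop("non-numeric expression values in column '", names(vals)[j], "'",
           call. = FALSE)
  }
  m <- as.matrix(vals)
  if (anyNA(m)) stop("missing expression values are not permitted", call. = FALSE)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(length(dup), " duplicated gene id(s) collapsed by mean: ",
            paste(utils::head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) ", ..." else "", call. = FALSE)
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(m) <- genes
  expression_matrix(m, scale_tag)
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample, full double precision.
#'
#' @param expr an [expression_matrix()].
#' @param path output path; `.csv` extension writes comma-separated.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' A named list of character vectors of gene symbols, one per set, with an
#' optional description per set. Set names must be unique, sets non-empty,
#' members unique within a set.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @return object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a fully named list", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, function(g) {
    g <- trimws(as.character(g))
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("`descriptions` must match `sets` in length", call. = FALSE)
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions,
            class = c("gene_set_collection", "list"))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (%s genes/set)\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], attr(x, "descriptions")[i])
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Blank member fields are dropped;
#' a line with fewer than three fields or a duplicated set name is an error.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 tab-separated fields",
         call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct cohort annotations
#'
#' Per-sample clinical annotations: a group label (e.g. tumor/normal or an
#' FPI stratum), survival time in days, an event indicator (1 = death,
#' 0 = censored), and any further covariate columns.
#'
#' @param df data.frame with at least columns `sample_id`, `group`, `time`,
#'   `event`. Additional columns are kept as covariates.
#' @return a data.frame of class `"cohort_annotations"`.
#' @export
cohort_annotations <- function(df) {
  req <- c("sample_id", "group", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotations missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in annotations", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("`event` must be 0 (censored) or 1 (death)", call. = FALSE)
  df$event <- as.integer(df$event)
  if (!is.numeric(df$time) || any(!is.na(df$time) & df$time <= 0))
    stop("`time` must be numeric and > 0 where present", call. = FALSE)
  df$group <- as.character(df$group)
  class(df) <- c("cohort_annotations", "data.frame")
  df
}

#' Read a sample-annotation TSV
#'
#' @param path TSV with header; required columns `sample_id`, `group`,
#'   `time`, `event`.
#' @return a [cohort_annotations()] data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  cohort_annotations(df)
}

#' Write cohort annotations as TSV
#'
#' @param ann a [cohort_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix and annotations on shared samples
#'
#' Restricts both objects to the intersection of their sample ids, in the
#' expression matrix's order, and reports how many samples were dropped from
#' each side. Idempotent.
#'
#' @param expr an [expression_matrix()].
#' @param ann a [cohort_annotations()].
#' @return list with elements `expr` and `ann`, both restricted to shared
#'   samples in matching order.
#' @export
align_cohort <- function(expr, ann) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(ann, "cohort_annotations"))
  shared <- intersect(colnames(expr), ann$sample_id)
  if (length(shared) == 0L)
    stop("no shared samples between expression matrix and annotations",
         call. = FALSE)
  d_expr <- ncol(expr) - length(shared)
  d_ann <- nrow(ann) - length(shared)
  if (d_expr > 0L || d_ann > 0L)
    message("align_cohort: dropped ", d_expr, " expression sample(s) and ",
            d_ann, " annotation row(s) outside the intersection")
  expr2 <- expression_matrix(unclass(expr)[, shared, drop = FALSE],
                             attr(expr, "scale_tag"))
  ann2 <- ann[match(shared, ann$sample_id), , drop = FALSE]
  rownames(ann2) <- NULL
  list(expr = expr2, ann = ann2)
}
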