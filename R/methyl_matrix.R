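#' Construct a methylation matrix
#'
#' A `methyl_matrix` is a numeric features x samples matrix carrying its
#' measurement scale: `"M"` (log2 methylated/unmethylated ratios) or `"beta"`
#' (methylation proportions in \[0,1\]). All statistical testing in this
#' package is performed on the M scale, where methylation data are closer to
#' homoscedastic; beta-scale input is accepted everywhere and logit-transformed
#' on entry.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param scale `"M"` or `"beta"`.
#' @param probe_ids optional feature identifiers; defaults to existing
#'   rownames or `probe1..probeG`.
#' @param sample_ids optional sample identifiers; defaults to existing
#'   colnames or `sample1..sampleN`.
#' @return A numeric matrix of class `methyl_matrix` with a `scale` attribute.
#' @examples
#' m <- methyl_matrix(matrix(rnorm(12), 3, 4), scale = "M")
#' methyl_scale(m)
#' @export
methyl_matrix <- function(values, scale = c("M", "beta"),
                          probe_ids = NULL, sample_ids = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("need at least 1 feature and 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite values are not allowed; filter features first")
  if (is.null(probe_ids))
    probe_ids <- rownames(values)
  if (is.null(probe_ids))
    probe_ids <- paste0("probe", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- colnames(values)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(ncol(values)))
  if (anyDuplicated(probe_ids))
    stop("duplicate probe IDs: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (scale == "beta" && (any(values < 0) || any(values > 1)))
    stop("beta values must lie in [0, 1]")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, scale = scale, class = c("methyl_matrix", class(values)))
}

#' @rdname methyl_matrix
#' @param x a `methyl_matrix`.
#' @export
methyl_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) stop("not a methyl_matrix: no scale attribute")
  sc
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d features x %d samples, scale = %s\n",
              nrow(x), ncol(x), methyl_scale(x)))
  n <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

as_plain_matrix <- function(x) {
  attr(x, "scale") <- NULL
  class(x) <- "matrix"
  unclass(as.matrix(x))
}

#' Build a design specification from group labels or a design matrix
#'
#' Encodes the mean model under test. Group labels become a group-means design
#' (one indicator column per group); with exactly two groups the tested
#' contrast defaults to the second-minus-first group difference, so a positive
#' effect means "larger in group 2". Arbitrary full-rank design matrices are
#' supported; then `coef` (a column index) or `contrast` must name the tested
#' effect.
#'
#' @param groups a factor or vector of group labels, one per sample.
#' @param design alternatively, an N x p numeric design matrix of full column
#'   rank.
#' @param coef column index of the tested coefficient (design-matrix input).
#' @param contrast numeric contrast vector of length p; overrides `coef`.
#' @param sample_ids optional sample identifiers used for alignment checks
#'   against the data matrix.
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(groups = rep(c("normal", "cancer"), each = 3))
#' @export
design_spec <- function(groups = NULL, design = NULL, coef = NULL,
                        contrast = NULL, sample_ids = NULL) {
  if (is.null(groups) && is.null(design))
    stop("supply 'groups' or 'design'")
  if (!is.null(groups)) {
    groups <- as_groups(groups)
    if (any(table(groups) < 2L))
      stop("every group needs at least 2 samples for variability testing; ",
           "offending group(s): ",
           paste(names(which(table(groups) < 2L)), collapse = ", "))
    if (is.null(design)) {
      design <- stats::model.matrix(~ 0 + groups)
      colnames(design) <- levels(groups)
      if (nlevels(groups) == 2L && is.null(contrast) && is.null(coef))
        contrast <- c(-1, 1)
    }
  }
  design <- as.matrix(design)
  p <- ncol(design)
  if (qr(design)$rank < p)
    stop("design matrix is rank deficient")
  if (nrow(design) - p < 1L)
    stop("no residual degrees of freedom: N - p must be >= 1")
  if (!is.null(contrast)) {
    if (length(contrast) != p) stop("contrast must have length ncol(design)")
  } else if (!is.null(coef)) {
    if (coef < 1L || coef > p) stop("'coef' out of range")
    contrast <- as.numeric(seq_len(p) == coef)
  }
  structure(list(design = design, contrast = contrast, groups = groups,
                 sample_ids = sample_ids),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design_spec: N = %d samples, p = %d coefficients\n",
              nrow(x$design), ncol(x$design)))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                                 table(x$groups)), collapse = ", "), "\n")
  if (!is.null(x$contrast))
    cat("tested contrast:", paste(format(x$contrast), collapse = " "), "\n")
  invisible(x)
}

# Resolve (design | groups) arguments into a validated design_spec aligned
# with the data matrix. Misaligned sample IDs are an error, never reordered.
resolve_design <- function(x, design, groups) {
  if (inherits(design, "design_spec")) {
    spec <- design
  } else if (!is.null(design)) {
    spec <- design_spec(design = design, groups = groups)
  } else if (!is.null(groups)) {
    spec <- design_spec(groups = groups)
  } else {
    stop("supply 'design' or 'groups'")
  }
  if (nrow(spec$design) != ncol(x))
    stop(sprintf("design has %d rows but the matrix has %d samples",
                 nrow(spec$design), ncol(x)))
  ids <- spec$sample_ids
  if (!is.null(ids) && !is.null(colnames(x)) &&
      !identical(as.character(ids), colnames(x))) {
    bad <- which(as.character(ids) != colnames(x))
    stop("sample sheet and matrix sample IDs are misaligned at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; reorder explicitly, alignment is never silent")
  }
  spec
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a methylation matrix from delimited text
#'
#' Expects a header row of sample identifiers and feature identifiers in the
#' first column. The delimiter is auto-detected (tab vs comma) unless given.
#' Non-numeric cells, missing values, duplicate probe IDs and out-of-range
#' beta values are rejected with informative errors.
#'
#' @param path path to a TSV/CSV file.
#' @param scale measurement scale of the stored values, `"M"` or `"beta"`.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @return A [methyl_matrix].
#' @export
read_methyl_matrix <- function(path, scale = c("M", "beta"), sep = NULL) {
  scale <- match.arg(scale)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 3L)
    stop("matrix file needs a probe-ID column plus at least 2 samples")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at row %s (probe %s), column %s",
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing value at row %s (probe %s), column %s",
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  methyl_matrix(num, scale = scale, probe_ids = ids,
                sample_ids = colnames(vals))
}

#' Read a sample sheet and build a group-means design
#'
#' The sheet must contain a `sample_id` column and a group column. Groups are
#' encoded as a group-means design (one indicator column per group); with two
#' groups the tested contrast is set to the group difference (-1, +1). With
#' more than two groups the contrast is left unset and must be supplied to the
#' fitting functions.
#'
#' @param path path to a TSV/CSV sample sheet.
#' @param group_column name of the column holding group labels.
#' @param sep field delimiter; `NULL` auto-detects.
#' @param sample_column name of the sample-identifier column.
#' @return A [design_spec] carrying sample IDs for alignment checks.
#' @export
read_sample_sheet <- function(path, group_column = "group", sep = NULL,
                              sample_column = "sample_id") {
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!sample_column %in% names(df))
    stop("sample sheet lacks a '", sample_column, "' column")
  if (!group_column %in% names(df))
    stop("sample sheet lacks the group column '", group_column, "'")
  ids <- as.character(df[[sample_column]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in sheet: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  design_spec(groups = df[[group_column]], sample_ids = ids)
}

#' Write a per-feature result table to tab-separated text
#'
#' Writes one row per feature with deterministic column order and full double
#' precision (17 significant digits), so that a write/read round trip is exact
#' to within one ulp.
#'
#' @param table a data frame of per-feature results (e.g. from
#'   [as.data.frame.varfit]).
#' @param path output file path.
#' @export
write_results <- function(table, path) {
  table <- as.data.frame(table)
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
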