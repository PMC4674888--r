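#' Construct an ExpressionMatrix
#'
#' The central expression container: a genes x samples matrix of intensities
#' plus a group label for every sample.  Intensities are expected on the
#' linear scale (nonnegative); log-scale input with negative values is
#' admitted with `allow_negative = TRUE`.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.  Row and
#'   column names are required and must be unique.
#' @param groups Named character vector or factor mapping every sample id
#'   (names) to a group label.
#' @param allow_negative Permit negative intensities (e.g. already
#'   log-transformed data).  Default `FALSE`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `groups` (a factor aligned with the columns).
#' @export
expression_matrix <- function(values, groups, allow_negative = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must carry gene row names and sample column names")
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite expression value(s) present")
  if (!allow_negative && any(values < 0))
    stop("negative intensities found; pass allow_negative = TRUE for log-scale input")
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)) || !all(sid %in% names(groups)))
    stop("`groups` must be named and cover every sample id")
  grp <- factor(groups[sid])
  if (anyNA(grp)) stop("missing group label for some sample(s)")
  structure(list(values = values, groups = stats::setNames(grp, sid)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tb <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix to one or more sample groups
#' @param x An `ExpressionMatrix`.
#' @param groups Character vector of group labels to keep.
#' @return An `ExpressionMatrix` restricted to those samples.
#' @export
subset_groups <- function(x, groups) {
  keep <- x$groups %in% groups
  if (!any(keep)) stop("no samples in group(s): ", paste(groups, collapse = ", "))
  expression_matrix(x$values[, keep, drop = FALSE],
                    droplevels(x$groups[keep]), allow_negative = TRUE)
}
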