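#' Differential protein pool by one-way ANOVA
#'
#' Screens every gene with a classical one-way fixed-effects ANOVA across the
#' sample groups (equal-variance F test).  By default intensities are
#' variance-stabilized as `log2(x + 1)` before testing; fold changes
#' elsewhere always use the raw scale.  Genes with zero total variance are
#' assigned p = 1 and excluded.
#'
#' @param expr An [expression_matrix()] with >= 2 groups of >= 2 samples.
#' @param alpha Significance threshold on the (corrected) p-value.
#' @param correction `"benjamini_hochberg"` or `"none"`.
#' @param groups Optional subset of group labels to test (default: all);
#'   lets the screen run per time point (condition vs control) instead of
#'   across all groups.
#' @param log_transform Apply `log2(x + 1)` before testing.
#' @return A data.frame of class `ScreenResult` with columns `gene`, `F`,
#'   `p`, `p_adj`, `pass`, ordered by p; the passing pool is in
#'   `attr(, "pool")` (genes ordered by p, ties by id).
#' @export
anova_screen <- function(expr, alpha = 0.05,
                         correction = c("benjamini_hochberg", "none"),
                         groups = NULL, log_transform = TRUE) {
  correction <- match.arg(correction)
  if (!is.null(groups)) expr <- subset_groups(expr, groups)
  g <- droplevels(expr$groups)
  sizes <- table(g)
  if (length(sizes) < 2) stop("need >= 2 groups to screen")
  if (any(sizes < 2))
    stop("group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  v <- expr$values
  if (log_transform) v <- log2(v + 1)

  res <- t(apply(v, 1L, function(y) {
    if (stats::var(y) == 0) return(c(NA_real_, 1))
    ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
    p <- ft$p.value
    if (is.nan(p)) p <- 1  # within-group variance zero and means equal
    c(unname(ft$statistic), p)
  }))
  out <- data.frame(gene = rownames(v), F = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE)
  out$p_adj <- if (correction == "benjamini_hochberg")
    stats::p.adjust(out$p, "BH") else out$p
  out$pass <- out$p_adj <= alpha
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ScreenResult", "data.frame")
  attr(out, "pool") <- out$gene[out$pass]
  out
}
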