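# Ranked biomarker table per time point: protein, SRV, p, raw group means
# and log2 fold change.  Means are always on the raw intensity scale,
# independent of the standardized scale used for model fitting.

#' Raw group mean intensities for one protein
#'
#' @param expr_raw [expression_matrix()] on the raw (linear) intensity scale.
#' @param protein Gene id.
#' @param case_group,control_group Group labels.
#' @return Named numeric vector `c(case, control)` of arithmetic means.
#' @export
group_means <- function(expr_raw, protein, case_group, control_group) {
  if (!protein %in% rownames(expr_raw$values))
    stop("protein absent from expression matrix: ", protein)
  v <- expr_raw$values[protein, ]
  c(case = mean(v[expr_raw$groups == case_group]),
    control = mean(v[expr_raw$groups == control_group]))
}

#' Log2 fold change of case over control mean
#'
#' @param case_mean,control_mean Positive mean intensities.
#' @return `log2(case_mean / control_mean)` at full precision (round for
#'   display).
#' @export
log2fc <- function(case_mean, control_mean) {
  if (any(case_mean <= 0) || any(control_mean <= 0))
    stop("group means must be positive to form a log2 fold change")
  log2(case_mean / control_mean)
}

#' Compile the ranked biomarker table for one time point
#'
#' One record per screened protein, sorted by SRV descending (ties by id):
#' protein, SRV, permutation p, case and control raw mean intensities, and
#' log2 fold change.
#'
#' @param diff A `DifferenceNetwork` with SRV and p-values.
#' @param expr_raw Raw-scale [expression_matrix()].
#' @param case_group,control_group Group labels for the mean columns.
#' @param threshold Inclusive p cutoff passed to [screen_srv()].
#' @return data.frame of class `BiomarkerTable` with columns `Protein`,
#'   `SRV`, `p_value`, `Case_AvgExp`, `Control_AvgExp`, `Log2FC`.
#' @export
compile_table <- function(diff, expr_raw, case_group,
                          control_group, threshold = 0.01) {
  prot <- screen_srv(diff, threshold)
  rows <- lapply(prot, function(g) {
    m <- group_means(expr_raw, g, case_group, control_group)
    data.frame(Protein = g, SRV = unname(diff$srv[g]),
               p_value = unname(diff$p[g]),
               Case_AvgExp = unname(m["case"]),
               Control_AvgExp = unname(m["control"]),
               Log2FC = log2fc(m["case"], m["control"]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Protein = character(), SRV = numeric(), p_value = numeric(),
               Case_AvgExp = numeric(), Control_AvgExp = numeric(),
               Log2FC = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("BiomarkerTable", "data.frame")
  out
}

#' Write a biomarker table as TSV
#'
#' Display formatting: SRV and Log2FC to 2 decimals, p in scientific
#' notation when below 1e-4.
#'
#' @param tab A [compile_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biomarker_table <- function(tab, path) {
  fmt <- data.frame(
    Protein = tab$Protein,
    SRV = sprintf("%.2f", tab$SRV),
    p_value = ifelse(tab$p_value < 1e-4,
                     sprintf("%.2e", tab$p_value),
                     sprintf("%.6g", tab$p_value)),
    Case_AvgExp = sprintf("%.6g", tab$Case_AvgExp),
    Control_AvgExp = sprintf("%.6g", tab$Control_AvgExp),
    Log2FC = sprintf("%.2f", tab$Log2FC),
    stringsAsFactors = FALSE)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
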