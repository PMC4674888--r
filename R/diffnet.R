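# Differential network: elementwise difference of the condition and control
# coefficient matrices, the per-protein rewiring score (SRV), and its
# label-permutation significance.

#' Difference matrix between a condition and the control model
#'
#' Elementwise `d_ij = alpha_ij(condition) - alpha_ij(control)` on the union
#' support of the two models; an edge absent from one model contributes 0
#' there.  The sign of `d_ij` is retained for export (rewiring up vs down).
#'
#' @param model_condition,model_control `AssociationModel`s over the same
#'   gene list.
#' @param k Label for the comparison (e.g. the post-event time point).
#' @return Object of class `DifferenceNetwork` with the matrix `D`; SRV and
#'   p-values are filled in by [srv()] / [srv_pvalues()].
#' @export
difference_matrix <- function(model_condition, model_control,
                              k = model_condition$condition) {
  ga <- rownames(model_condition$coef)
  gb <- rownames(model_control$coef)
  if (!identical(ga, gb)) {
    d1 <- setdiff(ga, gb); d2 <- setdiff(gb, ga)
    stop("models are over different gene lists; condition-only: {",
         paste(d1, collapse = ", "), "}, control-only: {",
         paste(d2, collapse = ", "), "}")
  }
  D <- model_condition$coef - model_control$coef
  structure(list(k = k, D = D, srv = NULL, p = NULL, B = NULL, seed = NULL),
            class = "DifferenceNetwork")
}

#' @export
print.DifferenceNetwork <- function(x, ...) {
  cat(sprintf("DifferenceNetwork [%s]: %d genes, %d nonzero d_ij\n",
              x$k, nrow(x$D), sum(x$D != 0)))
  if (!is.null(x$srv))
    cat(sprintf("SRV range: %.3g .. %.3g\n", min(x$srv), max(x$srv)))
  invisible(x)
}

#' Per-protein rewiring score (SRV)
#'
#' The stroke relevance value of protein i is the row-wise aggregate of its
#' coefficient differences, `SRV_i = sum_j |d_ij|` by default.  The plain
#' signed sum `sum_j d_ij` (which can cancel opposite rewiring) is available
#' with `abs = FALSE`.
#'
#' @param diff A [difference_matrix()] result.
#' @param abs Use absolute values (default) or the literal signed sum.
#' @return The `DifferenceNetwork` with `srv` (named vector) filled in.
#' @export
srv <- function(diff, abs = TRUE) {
  diff$srv <- if (abs) rowSums(base::abs(diff$D)) else rowSums(diff$D)
  diff
}

#' Permutation p-values for the SRV
#'
#' Null model: the condition and control samples are pooled and their two
#' labels reshuffled `B` times preserving the group sizes; both networks are
#' refit and the SRV recomputed for every draw.  The p-value of protein i is
#' `(1 + #\{b : SRV_i^(b) >= SRV_i\}) / (B + 1)`, so the smallest attainable
#' p is `1/(B+1)`.
#'
#' @param expr Full [expression_matrix()] (both groups present).
#' @param cnet [candidate_network()] over the pool.
#' @param k Condition group label.
#' @param config A [dppin_config()]; `control_group`, `srv_abs`, fitting
#'   thresholds and `B`/`perm_seed` defaults are read from it.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param fit_control Optional pre-computed control `AssociationModel`
#'   (reused across the time-point comparisons by the pipeline).
#' @return A `DifferenceNetwork` with `D`, `srv`, `p`, `B`, `seed` set.
#' @export
srv_pvalues <- function(expr, cnet, k, config = dppin_config(),
                        B = config$B, seed = config$perm_seed,
                        fit_control = NULL) {
  if (B < 100) stop("B must be >= 100")
  if (1 / (B + 1) > config$srv_threshold)
    stop(sprintf(
      "B = %d cannot resolve the screen threshold %.4g (min p = %.4g); increase B",
      B, config$srv_threshold, 1 / (B + 1)))
  ctrl <- config$control_group
  fit_k <- fit_condition_network(expr, k, cnet, config)
  fit_n <- if (is.null(fit_control)) {
    fit_condition_network(expr, ctrl, cnet, config)
  } else fit_control
  diff <- srv(difference_matrix(fit_k, fit_n, k = k), abs = config$srv_abs)

  idx_k <- which(expr$groups == k)
  idx_n <- which(expr$groups == ctrl)
  pooled <- expr$values[cnet$genes, c(idx_k, idx_n), drop = FALSE]
  n_k <- length(idx_k)
  n_tot <- ncol(pooled)

  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  count <- numeric(length(cnet$genes))
  for (b in seq_len(B)) {
    perm <- sample.int(n_tot)
    Ak <- .fit_network_core(pooled[, perm[seq_len(n_k)], drop = FALSE],
                            cnet, config)$coef
    An <- .fit_network_core(pooled[, perm[(n_k + 1L):n_tot], drop = FALSE],
                            cnet, config)$coef
    Db <- Ak - An
    sb <- if (config$srv_abs) rowSums(abs(Db)) else rowSums(Db)
    count <- count + (sb >= diff$srv)
  }
  diff$p <- stats::setNames((1 + count) / (B + 1), cnet$genes)
  diff$B <- B
  diff$seed <- seed
  diff
}

#' Screen proteins by SRV significance
#'
#' @param diff A `DifferenceNetwork` with p-values.
#' @param threshold Inclusive p-value cutoff (default 0.01).
#' @return Character vector of significant proteins, sorted by SRV
#'   descending, ties broken by gene id.
#' @export
screen_srv <- function(diff, threshold = 0.01) {
  if (is.null(diff$p)) stop("p-values not computed; run srv_pvalues() first")
  hit <- names(diff$p)[diff$p <= threshold]
  hit[order(-diff$srv[hit], hit)]
}
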