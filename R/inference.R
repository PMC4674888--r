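# PPI-constrained linear association model, fit per condition:
# per-target OLS (Gaussian ML) on standardized expression without intercept,
# greedy forward AIC model-order selection along the |marginal correlation|
# path, and Student's t-test pruning of non-significant edges.

#' Restrict a candidate edge list to the differential pool
#'
#' @param pool Character vector of pool gene ids (from [anova_screen()]).
#' @param edges An [edge_list()] of candidate PPIs.
#' @return Object of class `CandidateNetwork`: `genes`, symmetric logical
#'   `adj` over pool x pool, and per-gene `degree` (the candidate model
#'   order M_i of each target).
#' @export
candidate_network <- function(pool, edges) {
  pool <- as.character(pool)
  if (anyDuplicated(pool)) stop("duplicate gene in pool")
  adj <- matrix(FALSE, length(pool), length(pool), dimnames = list(pool, pool))
  keep <- edges$a %in% pool & edges$b %in% pool
  ea <- edges$a[keep]; eb <- edges$b[keep]
  adj[cbind(ea, eb)] <- TRUE
  adj[cbind(eb, ea)] <- TRUE
  diag(adj) <- FALSE
  structure(list(genes = pool, adj = adj, degree = rowSums(adj)),
            class = "CandidateNetwork")
}

#' @export
print.CandidateNetwork <- function(x, ...) {
  cat(sprintf("CandidateNetwork: %d genes, %d candidate edges\n",
              length(x$genes), sum(x$adj) / 2))
  invisible(x)
}

# Default fitting configuration; every threshold is a config key.
#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default.  Arguments
#' override defaults; unknown names are an error.
#'
#' @param ... Name-value overrides.  Keys: `alpha_screen` (0.05),
#'   `screen_correction` ("benjamini_hochberg"), `screen_log` (TRUE),
#'   `alpha_edge` (0.05, two-sided t-test on edges), `max_order`
#'   (NULL = per-condition `n - 3`), `iterate_prune` (FALSE = refit once),
#'   `srv_abs` (TRUE = absolute row sums), `B` (200 permutations),
#'   `perm_seed` (1), `srv_threshold` (0.01, inclusive), `control_group`
#'   ("normal"), `collapse_policy` ("max_mean"), `taxon` (9606).
#' @return A named list of class `dppin_config`.
#' @export
dppin_config <- function(...) {
  cfg <- list(alpha_screen = 0.05, screen_correction = "benjamini_hochberg",
              screen_log = TRUE, alpha_edge = 0.05, max_order = NULL,
              iterate_prune = FALSE, srv_abs = TRUE, B = 200L,
              perm_seed = 1L, srv_threshold = 0.01,
              control_group = "normal", collapse_policy = "max_mean",
              taxon = 9606)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  for (k in c("alpha_screen", "alpha_edge", "srv_threshold"))
    if (!(cfg[[k]] > 0 && cfg[[k]] <= 1)) stop(k, " must be in (0, 1]")
  if (cfg$B < 100) stop("B must be >= 100 when permutation is enabled")
  structure(cfg, class = "dppin_config")
}

# Standardize rows (genes) of a matrix to zero mean / unit variance within
# one condition; zero-variance rows are flagged and left as all-zero.
.standardize_rows <- function(v) {
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  degenerate <- sd == 0
  sd[degenerate] <- 1
  z <- (v - mu) / sd
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- rownames(v)[degenerate]
  z
}

# AIC of a no-intercept Gaussian model at order m, additive constants
# dropped: n * log(RSS/n) + 2m.  RSS is floored at 1e-12 * TSS so that
# numerically-zero residuals at different orders tie and the 2m penalty
# picks the smaller model (raw float noise ~1e-28 would otherwise dominate).
.aic <- function(rss, n, m, tss) n * log(max(rss, 1e-12 * tss) / n) + 2 * m

#' Fit one target's association coefficients
#'
#' Gaussian-noise maximum-likelihood (equivalently ordinary least squares)
#' estimate of the association strengths of `target` on `neighbors`, without
#' intercept, on per-gene standardized expression of a single condition.
#' Rank-deficient designs drop collinear columns deterministically (in
#' decreasing |correlation with target| order) with a message.
#'
#' @param expr_condition `ExpressionMatrix` holding samples of one condition.
#' @param target Gene id of the regression target.
#' @param neighbors Character vector of candidate interactor gene ids.
#' @return List: `coef` (named alpha-hat), `se`, `t`, `p` (two-sided,
#'   df = n - m), `df`, `rss`, `n`, `dropped` (collinear columns).
#' @export
fit_target <- function(expr_condition, target, neighbors) {
  if (!length(neighbors)) stop("`neighbors` must be nonempty")
  v <- expr_condition$values[c(target, neighbors), , drop = FALSE]
  z <- .standardize_rows(v)
  y <- z[1L, ]
  X <- t(z[-1L, , drop = FALSE])
  ord <- order(-abs(stats::cor(y, X)[1L, ]), colnames(X))
  .ols_stats(y, X[, ord, drop = FALSE])
}

# Core no-intercept OLS with deterministic collinear-column dropping.
# Columns are assumed pre-ordered by selection priority; a column whose
# residual after projection on earlier kept columns has norm^2 below
# tol * its norm^2 is dropped.
.ols_stats <- function(y, X, tol = 1e-10) {
  n <- length(y)
  keep <- logical(ncol(X))
  Q <- matrix(0, n, 0L)
  dropped <- character()
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    r <- x - Q %*% crossprod(Q, x)
    if (sum(r^2) <= tol * max(sum(x^2), .Machine$double.eps)) {
      dropped <- c(dropped, colnames(X)[j])
      next
    }
    Q <- cbind(Q, r / sqrt(sum(r^2)))
    keep[j] <- TRUE
  }
  if (length(dropped))
    message("dropped collinear column(s): ", paste(dropped, collapse = ", "))
  Xk <- X[, keep, drop = FALSE]
  m <- ncol(Xk)
  if (m == 0L) {
    return(list(coef = stats::setNames(numeric(0), character(0)),
                se = numeric(0), t = numeric(0), p = numeric(0),
                df = n, rss = sum(y^2), n = n, dropped = dropped))
  }
  fit <- stats::lm.fit(Xk, y)
  co <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - m
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  tstat <- ifelse(se > 0, co / se, ifelse(co == 0, 0, sign(co) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = max(df, 1L))
  p[is.infinite(tstat)] <- 0
  list(coef = co, se = stats::setNames(se, names(co)),
       t = stats::setNames(tstat, names(co)),
       p = stats::setNames(p, names(co)),
       df = df, rss = rss, n = n, dropped = dropped)
}

#' AIC model-order selection along the correlation-ordered forward path
#'
#' Candidates enter in decreasing |marginal correlation with the target|
#' (ties broken lexicographically).  At each order m along this greedy path
#' the no-intercept residual sum of squares RSS_m is computed and scored as
#' `AIC(m) = n log(RSS_m / n) + 2 m`; the subset minimizing AIC over
#' m = 0..max_order is returned (order 0 is always admissible).
#'
#' @inheritParams fit_target
#' @param max_order Largest model order searched; capped at `n - 2`.
#' @return List: `selected` (gene ids, possibly empty), `order` (m), `aic`
#'   (AIC at the selected order), `path` (data.frame of m, gene, rss, aic
#'   along the search path).
#' @export
aic_select <- function(expr_condition, target, neighbors, max_order = NULL) {
  v <- expr_condition$values[c(target, neighbors), , drop = FALSE]
  z <- .standardize_rows(v)
  y <- z[1L, ]
  X <- t(z[-1L, , drop = FALSE])
  n <- length(y)
  cap <- n - 2L
  if (is.null(max_order)) max_order <- n - 3L
  max_order <- min(max_order, length(neighbors), cap)
  ord <- order(-abs(stats::cor(y, X)[1L, ]), colnames(X))
  .aic_path(y, X[, ord, drop = FALSE], max_order)
}

# Nested-model RSS along a fixed column order via incremental Gram-Schmidt;
# collinear columns are skipped (they cannot lower RSS).  Hot path: no
# data.frame allocation inside the loop.
.aic_path <- function(y, X, max_order, record = TRUE) {
  n <- length(y)
  tss <- sum(y^2)
  nmax <- min(max_order, ncol(X))
  Q <- matrix(0, n, nmax)
  taken <- character(nmax)
  rss_v <- numeric(nmax)
  aic_v <- numeric(nmax)
  rss <- tss
  aic0 <- .aic(rss, n, 0L, tss)
  best_aic <- aic0; best_m <- 0L
  m <- 0L; j <- 1L
  while (m < nmax && j <= ncol(X)) {
    x <- X[, j]; gene <- colnames(X)[j]; j <- j + 1L
    r <- if (m > 0L)
      x - Q[, seq_len(m), drop = FALSE] %*%
        crossprod(Q[, seq_len(m), drop = FALSE], x)
    else x
    r2 <- sum(r^2)
    if (r2 <= 1e-10 * max(sum(x^2), .Machine$double.eps)) next
    m <- m + 1L
    Q[, m] <- r / sqrt(r2)
    taken[m] <- gene
    rss <- max(rss - sum(Q[, m] * y)^2, 0)
    rss_v[m] <- rss
    aic_v[m] <- .aic(rss, n, m, tss)
    if (aic_v[m] < best_aic) { best_aic <- aic_v[m]; best_m <- m }
  }
  list(selected = taken[seq_len(best_m)], order = best_m, aic = best_aic,
       path = if (record)
         data.frame(m = 0:m, gene = c(NA_character_, taken[seq_len(m)]),
                    rss = c(tss, rss_v[seq_len(m)]),
                    aic = c(aic0, aic_v[seq_len(m)]),
                    stringsAsFactors = FALSE))
}

#' Prune non-significant edges by Student's t-test
#'
#' Removes edges whose two-sided p exceeds `alpha_edge`, then refits once on
#' the survivors (the refit-once policy); with `iterate = TRUE` pruning and
#' refitting repeat until every surviving edge is significant.  If every
#' edge is pruned the target keeps an empty coefficient row.
#'
#' @param est A [fit_target()] result.
#' @param y,X The standardized response and (ordered) design used for the
#'   fit; needed for refitting.
#' @param alpha_edge Two-sided significance threshold.
#' @param iterate Repeat prune/refit until stable.
#' @return A [fit_target()]-shaped list on the surviving edges.
#' @export
prune_by_ttest <- function(est, y, X, alpha_edge = 0.05, iterate = FALSE) {
  repeat {
    drop <- names(est$coef)[est$p > alpha_edge]
    if (!length(drop) || !length(est$coef)) return(est)
    keep <- setdiff(names(est$coef), drop)
    est <- .ols_stats(y, X[, keep, drop = FALSE])
    if (!iterate) return(est)
    if (all(est$p <= alpha_edge)) return(est)
  }
}

#' Fit the condition-specific association network
#'
#' Runs, for every pool gene i: marginal-correlation ordering of its
#' candidate interactors, greedy forward AIC order selection, OLS fit at the
#' selected order, and t-test pruning with one refit.  Rows are independent
#' regressions, so the assembled coefficient matrix need not be symmetric.
#' Degenerate targets (zero variance within the condition) keep a zero row.
#'
#' Fitting runs on per-gene standardized data (no intercept needed), but the
#' assembled coefficients are mapped back to the raw expression scale
#' (`alpha_std * sd_target / sd_neighbor`), so that matrices fitted under
#' different conditions are commensurable when differenced; t statistics and
#' p-values are scale-invariant.
#'
#' @param expr An [expression_matrix()] containing the condition's samples.
#' @param condition Group label to fit.
#' @param cnet A [candidate_network()] over the pool.
#' @param config A [dppin_config()].
#' @return Object of class `AssociationModel`: `condition`, `coef` (pool x
#'   pool matrix, zero off support), `edges` (per-edge estimates), `targets`
#'   (per-target diagnostics M, M_prime, rss, aic).
#' @export
fit_condition_network <- function(expr, condition, cnet,
                                  config = dppin_config()) {
  if (!condition %in% levels(expr$groups))
    stop("condition absent from sample groups: ", condition)
  sub <- subset_groups(expr, condition)
  core <- .fit_network_core(sub$values, cnet, config, stats = TRUE)
  structure(list(condition = condition, coef = core$coef,
                 edges = core$edges, targets = core$targets),
            class = "AssociationModel")
}

#' @export
print.AssociationModel <- function(x, ...) {
  cat(sprintf("AssociationModel [%s]: %d genes, %d retained edges\n",
              x$condition, nrow(x$coef), nrow(x$edges)))
  invisible(x)
}

# Hot path shared by fit_condition_network and the permutation null.
# `values`: raw genes x samples matrix restricted to one condition.
# With stats = FALSE only the coefficient matrix is assembled.
.fit_network_core <- function(values, cnet, config, stats = FALSE) {
  pool <- cnet$genes
  miss <- setdiff(pool, rownames(values))
  if (length(miss)) stop("pool gene(s) missing from expression: ",
                         paste(miss, collapse = ", "))
  raw <- values[pool, , drop = FALSE]
  z <- .standardize_rows(raw)
  degenerate <- attr(z, "degenerate")
  # fitting happens on per-gene standardized data (numerically safe, no
  # intercept needed); coefficients are mapped back to the raw expression
  # scale so that models fitted under different conditions are commensurable
  # when differenced
  sds <- apply(raw, 1L, stats::sd)
  sds[sds == 0] <- 1
  n <- ncol(z)
  max_order <- if (is.null(config$max_order)) n - 3L else config$max_order
  max_order <- min(max_order, n - 2L)
  A <- matrix(0, length(pool), length(pool), dimnames = list(pool, pool))
  edges <- if (stats) vector("list", length(pool)) else NULL
  targets <- if (stats) vector("list", length(pool)) else NULL

  zt <- t(z)
  for (i in seq_along(pool)) {
    g <- pool[i]
    nb <- pool[cnet$adj[i, ]]
    nb <- setdiff(nb, degenerate)
    Mi <- length(nb)
    if (g %in% degenerate || Mi == 0L) {
      if (stats) targets[[i]] <- data.frame(
        target = g, M = cnet$degree[[i]], M_prime = 0L,
        rss = NA_real_, aic = NA_real_, stringsAsFactors = FALSE)
      next
    }
    y <- z[g, ]
    X <- zt[, nb, drop = FALSE]
    cr <- abs(crossprod(y, X))[1L, ] # |cor| up to the common (n-1) factor
    ord <- order(-cr, nb)
    Xo <- X[, ord, drop = FALSE]
    sel <- .aic_path(y, Xo, min(max_order, Mi), record = FALSE)
    if (sel$order == 0L) {
      if (stats) targets[[i]] <- data.frame(
        target = g, M = Mi, M_prime = 0L, rss = sum(y^2), aic = sel$aic,
        stringsAsFactors = FALSE)
      next
    }
    Xs <- Xo[, sel$selected, drop = FALSE]
    est <- .ols_stats(y, Xs)
    est <- prune_by_ttest(est, y, Xs, alpha_edge = config$alpha_edge,
                          iterate = isTRUE(config$iterate_prune))
    if (length(est$coef))
      A[g, names(est$coef)] <- est$coef * sds[g] / sds[names(est$coef)]
    if (stats) {
      if (length(est$coef))
        edges[[i]] <- data.frame(target = g, neighbor = names(est$coef),
                                 alpha = unname(A[g, names(est$coef)]),
                                 se = unname(est$se * sds[g] /
                                               sds[names(est$coef)]),
                                 t = unname(est$t),
                                 p = unname(est$p),
                                 stringsAsFactors = FALSE)
      targets[[i]] <- data.frame(target = g, M = Mi,
                                 M_prime = length(est$coef),
                                 rss = est$rss,
                                 aic = .aic(est$rss, n, length(est$coef),
                                            sum(y^2)),
                                 stringsAsFactors = FALSE)
    }
  }
  out <- list(coef = A)
  if (stats) {
    out$edges <- if (length(ed <- Filter(Negate(is.null), edges)))
      do.call(rbind, ed) else
        data.frame(target = character(), neighbor = character(),
                   alpha = numeric(), se = numeric(), t = numeric(),
                   p = numeric(), stringsAsFactors = FALSE)
    out$targets <- do.call(rbind, targets)
    rownames(out$edges) <- rownames(out$targets) <- NULL
  }
  out
}
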