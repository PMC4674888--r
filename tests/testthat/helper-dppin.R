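# Shared fixture builders: everything is generated in code at test time.

# A small ExpressionMatrix with explicit values and group labels.
make_expr <- function(values, groups, allow_negative = TRUE) {
  expression_matrix(values, groups, allow_negative = allow_negative)
}

# Random genes x samples matrix with named dims and a group vector of
# equal-sized groups.
random_expr <- function(n_genes, groups_sizes, seed = 1, base = 100) {
  set.seed(seed)
  n <- sum(groups_sizes)
  v <- matrix(base + rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n))))
  grp <- setNames(rep(names(groups_sizes), groups_sizes), colnames(v))
  expression_matrix(v, grp)
}

# Write a plain expression TSV and return its path.
write_tsv_fixture <- function(expr) {
  path <- tempfile("expr", fileext = ".tsv")
  write_expression_tsv(expr, path)
  path
}

# Hand-built AssociationModel over `genes` from a coefficient matrix.
model_from_matrix <- function(A, condition = "cond") {
  idx <- which(A != 0, arr.ind = TRUE)
  g <- rownames(A)
  edges <- data.frame(target = g[idx[, 1]], neighbor = g[idx[, 2]],
                      alpha = if (nrow(idx)) A[idx] else numeric(0),
                      se = rep(NA_real_, nrow(idx)),
                      t = rep(NA_real_, nrow(idx)),
                      p = rep(NA_real_, nrow(idx)), stringsAsFactors = FALSE)
  structure(list(condition = condition, coef = A, edges = edges,
                 targets = NULL),
            class = "AssociationModel")
}

# Hand-built DifferenceNetwork (optionally with SRV/p filled).
diff_from_matrix <- function(D, k = "case", p = NULL) {
  d <- structure(list(k = k, D = D, srv = NULL, p = p, B = NULL, seed = NULL),
                 class = "DifferenceNetwork")
  d <- srv(d)
  if (!is.null(p)) d$p <- setNames(p, rownames(D))
  d
}

# Two-group ExpressionMatrix simulated from a GroundTruth condition pair.
simulate_pair <- function(truth, condition, n_samples, seed,
                          control_label = "normal", base_mean = 100) {
  ec <- simulate_expression(truth, "control", n_samples, base_mean,
                            seed = seed, group_label = control_label)
  ek <- simulate_expression(truth, condition, n_samples, base_mean,
                            seed = seed + 1L, group_label = condition)
  vals <- cbind(ec$values, ek$values)
  grp <- setNames(c(as.character(ec$groups), as.character(ek$groups)),
                  colnames(vals))
  expression_matrix(vals, grp, allow_negative = TRUE)
}
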