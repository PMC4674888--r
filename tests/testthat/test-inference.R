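# Independent oracle: no-intercept OLS by explicit normal equations.
ne_solve <- function(y, X) solve(crossprod(X), crossprod(X, y))[, 1]

test_that("single-target fits recover exact and null relationships", {
  set.seed(10)
  xj <- rnorm(30)
  v <- rbind(tgt = 2 * xj, nb = xj)
  colnames(v) <- paste0("s", 1:30)
  e <- make_expr(v, setNames(rep("a", 30), colnames(v)))
  est <- fit_target(e, "tgt", "nb")
  # on standardized data an exact proportionality has coefficient 1, RSS 0
  expect_equal(unname(est$coef["nb"]), 1, tolerance = 1e-10)
  expect_lt(est$rss, 1e-20)
  expect_equal(unname(est$p["nb"]), 0)

  # uncorrelated pure-noise neighbor: small coefficient, small |t|
  set.seed(11)
  v2 <- rbind(tgt = rnorm(2000), nb = rnorm(2000))
  colnames(v2) <- paste0("s", 1:2000)
  e2 <- make_expr(v2, setNames(rep("a", 2000), colnames(v2)))
  est2 <- fit_target(e2, "tgt", "nb")
  expect_lt(abs(est2$coef["nb"]), 0.1)
  expect_lt(abs(est2$t["nb"]), 3)
})

test_that("OLS equals the normal-equations oracle on random instances", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    n <- sample(15:40, 1)
    p <- sample(1:8, 1)
    v <- matrix(rnorm((p + 1) * n), p + 1, n,
                dimnames = list(c("tgt", paste0("nb", 1:p)),
                                paste0("s", 1:n)))
    e <- make_expr(v, setNames(rep("a", n), colnames(v)))
    est <- fit_target(e, "tgt", paste0("nb", 1:p))
    z <- scale(t(v))
    oracle <- ne_solve(z[, "tgt"], z[, names(est$coef), drop = FALSE])
    worst <- max(worst, max(abs(est$coef - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("rank-deficient designs drop collinear columns deterministically", {
  set.seed(3)
  x <- rnorm(25)
  v <- rbind(tgt = x + rnorm(25, sd = 0.1), nb1 = x, nb2 = x, nb3 = rnorm(25))
  colnames(v) <- paste0("s", 1:25)
  e <- make_expr(v, setNames(rep("a", 25), colnames(v)))
  expect_message(est <- fit_target(e, "tgt", c("nb1", "nb2", "nb3")),
                 "collinear")
  # the duplicated predictor entering second is the one dropped
  expect_false("nb2" %in% names(est$coef))
  expect_true("nb1" %in% names(est$coef))
})

test_that("AIC selection recovers exact supports and rejects null ones", {
  # noise-free target built from 2 of 6 candidates
  set.seed(7)
  n <- 60
  X <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("nb", 1:6), paste0("s", 1:n)))
  y <- 1.1 * X["nb2", ] - 0.9 * X["nb5", ]
  e <- make_expr(rbind(tgt = y, X), setNames(rep("a", n), colnames(X)))
  sel <- aic_select(e, "tgt", paste0("nb", 1:6))
  expect_setequal(sel$selected, c("nb2", "nb5"))
  expect_equal(sel$order, 2L)

  # independent target: order 0 wins at large n
  set.seed(8)
  n2 <- 500
  X2 <- matrix(rnorm(4 * n2), 4, n2,
               dimnames = list(paste0("nb", 1:4), paste0("s", 1:n2)))
  e2 <- make_expr(rbind(tgt = rnorm(n2), X2),
                  setNames(rep("a", n2), colnames(X2)))
  sel2 <- aic_select(e2, "tgt", paste0("nb", 1:4))
  expect_equal(sel2$order, 0L)
  expect_length(sel2$selected, 0)
})

test_that("greedy-path AIC matches an independent enumeration oracle", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 40
    p <- 7
    X <- matrix(rnorm(p * n), p, n,
                dimnames = list(paste0("nb", 1:p), paste0("s", 1:n)))
    y <- 0.8 * X["nb1", ] + 0.5 * X["nb3", ] + rnorm(n, sd = 0.5)
    e <- make_expr(rbind(tgt = y, X), setNames(rep("a", n), colnames(X)))
    sel <- aic_select(e, "tgt", paste0("nb", 1:p))

    # oracle: recompute RSS of every prefix of the same correlation-ordered
    # path with lm(), and the AIC formula from scratch
    z <- scale(t(rbind(tgt = y, X)))
    ord <- order(-abs(cor(z[, "tgt"], z[, -1]))[1, ], colnames(z)[-1])
    genes <- colnames(z)[-1][ord]
    aics <- vapply(0:length(genes), function(m) {
      rss <- if (m == 0) sum(z[, "tgt"]^2) else
        sum(lm.fit(z[, genes[1:m], drop = FALSE], z[, "tgt"])$residuals^2)
      n * log(rss / n) + 2 * m
    }, numeric(1))
    expect_equal(sel$order, which.min(aics) - 1L)
    expect_equal(sel$aic, min(aics), tolerance = 1e-8)
    expect_equal(sel$selected, genes[seq_len(sel$order)])
  }
})

test_that("for orthogonal designs greedy selection equals exhaustive search", {
  set.seed(23)
  n <- 32
  p <- 5
  # orthogonal polynomial columns: mean zero and mutually orthogonal, so
  # per-column standardization preserves orthogonality exactly
  Q <- unclass(poly(seq_len(n), p)) * sqrt(n - 1)
  rownames(Q) <- paste0("s", 1:n)
  colnames(Q) <- paste0("nb", 1:p)
  y <- 0.9 * Q[, "nb2"] + 0.6 * Q[, "nb4"] + rnorm(n, sd = 0.4)
  e <- make_expr(rbind(tgt = y, t(Q)), setNames(rep("a", n), rownames(Q)))
  sel <- aic_select(e, "tgt", colnames(Q))

  z <- scale(cbind(tgt = y, Q))
  subsets <- unlist(lapply(0:p, function(m)
    combn(colnames(Q), m, simplify = FALSE)), recursive = FALSE)
  aic_of <- vapply(subsets, function(s) {
    rss <- if (!length(s)) sum(z[, "tgt"]^2) else
      sum(lm.fit(z[, s, drop = FALSE], z[, "tgt"])$residuals^2)
    n * log(rss / n) + 2 * length(s)
  }, numeric(1))
  best <- subsets[[which.min(aic_of)]]
  expect_setequal(sel$selected, best)
})

test_that("AIC values along the path match the formula on hand fits", {
  set.seed(5)
  n <- 20
  v <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(c("tgt", "nb1", "nb2"), paste0("s", 1:n)))
  e <- make_expr(v, setNames(rep("a", n), colnames(v)))
  sel <- aic_select(e, "tgt", c("nb1", "nb2"))
  z <- scale(t(v))
  for (r in seq_len(nrow(sel$path))) {
    m <- sel$path$m[r]
    genes <- sel$path$gene[seq_len(r)][-1]
    rss <- if (m == 0) sum(z[, "tgt"]^2) else
      sum(lm.fit(z[, genes, drop = FALSE], z[, "tgt"])$residuals^2)
    expect_equal(sel$path$rss[r], rss, tolerance = 1e-10)
    expect_equal(sel$path$aic[r], n * log(rss / n) + 2 * m, tolerance = 1e-10)
  }
})

test_that("t-test pruning removes null edges and keeps exact ones", {
  # an exactly zero coefficient has t = 0 and is always pruned
  set.seed(9)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1 + rnorm(n, sd = 0.2)
  z <- scale(cbind(y = y, x1 = x1, x2 = x2))
  est <- dppin:::.ols_stats(z[, "y"], z[, c("x1", "x2")])
  est$p["x2"] <- 1  # force the null edge over threshold
  pruned <- prune_by_ttest(est, z[, "y"], z[, c("x1", "x2")],
                           alpha_edge = 0.05)
  expect_false("x2" %in% names(pruned$coef))
  expect_true("x1" %in% names(pruned$coef))
  expect_lt(pruned$p["x1"], 1e-6)

  # all edges pruned leaves an empty estimate, not an error
  yn <- scale(rnorm(n))[, 1]
  estn <- dppin:::.ols_stats(yn, z[, c("x1", "x2"), drop = FALSE])
  prunedn <- prune_by_ttest(estn, yn, z[, c("x1", "x2")], alpha_edge = 1e-6)
  expect_length(prunedn$coef, 0)
  expect_equal(prunedn$rss, sum(yn^2))
})

test_that("decoy edges are retained at no more than the nominal rate", {
  # 3 true + 3 decoy candidate neighbors per target, many seeds
  set.seed(77)
  n <- 200
  kept_decoy <- 0; total_decoy <- 0
  for (s in 1:200) {
    Xt <- matrix(rnorm(6 * n), 6, n,
                 dimnames = list(paste0("nb", 1:6), paste0("s", 1:n)))
    y <- 0.5 * Xt[1, ] - 0.4 * Xt[2, ] + 0.3 * Xt[3, ] + rnorm(n)
    e <- make_expr(rbind(tgt = y, Xt), setNames(rep("a", n), colnames(Xt)))
    est <- fit_target(e, "tgt", paste0("nb", 1:6))
    pruned_names <- names(est$coef)[est$p <= 0.05]
    kept_decoy <- kept_decoy + sum(pruned_names %in% paste0("nb", 4:6))
    total_decoy <- total_decoy + 3
  }
  rate <- kept_decoy / total_decoy
  se <- sqrt(0.05 * 0.95 / total_decoy)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("condition networks assemble, respect support, and are deterministic", {
  tr <- generate_truth(10, 0.25, 0, 0, seed = 31)
  expr <- simulate_pair(tr, "case", 40, seed = 100)
  cand <- make_candidate_edges(tr, 0.5, seed = 32)
  cn <- candidate_network(tr$genes, cand)
  cfg <- dppin_config()
  fit1 <- fit_condition_network(expr, "case", cn, cfg)
  fit2 <- fit_condition_network(expr, "case", cn, cfg)
  expect_identical(fit1$coef, fit2$coef)

  # support never exceeds the candidate adjacency; zero diagonal
  expect_true(all(fit1$coef[!cn$adj] == 0))
  expect_true(all(diag(fit1$coef) == 0))
  # every retained edge is significant at the pruning threshold or kept
  # after a single refit
  expect_true(all(fit1$edges$p <= 0.25))
  expect_true(all(fit1$targets$M_prime <= pmin(fit1$targets$M, 40 - 2)))

  # empty candidate network gives the zero matrix
  cn0 <- candidate_network(tr$genes, edge_list(character(), character()))
  fit0 <- fit_condition_network(expr, "case", cn0, cfg)
  expect_true(all(fit0$coef == 0))
  expect_equal(nrow(fit0$edges), 0L)

  # unknown condition label is a hard error
  expect_error(fit_condition_network(expr, "nope", cn, cfg), "nope")
})

test_that("fitted coefficients converge to the population linear predictor", {
  # independent oracle: for data x = (I-A)^-1 w the population covariance is
  # proportional to S = (I-A)^-1 (I-A)^-T, and the raw-scale OLS of target i
  # on a retained neighbor set R converges to the best-linear-predictor
  # coefficients solve(S[R,R], S[R,i])
  tr <- generate_truth(12, 0.2, 0, 0, sigma = 0.3, de_shift = c(0, 0),
                       seed = 61)
  expr <- simulate_pair(tr, "case", 500, seed = 200)
  cn <- candidate_network(tr$genes, make_candidate_edges(tr, 0.5, seed = 62))
  fit <- fit_condition_network(expr, "case", cn, dppin_config())
  IA <- solve(diag(12) - tr$control)
  S <- IA %*% t(IA)
  dimnames(S) <- dimnames(tr$control)
  est <- c(); oracle <- c()
  for (g in rownames(fit$coef)) {
    R <- names(which(fit$coef[g, ] != 0))
    if (!length(R)) next
    blp <- solve(S[R, R, drop = FALSE], S[R, g])
    est <- c(est, fit$coef[g, R])
    oracle <- c(oracle, blp)
  }
  expect_gt(length(est), 10)
  expect_gt(cor(est, oracle), 0.98)
  expect_lt(max(abs(est - oracle)), 0.2)  # sampling error at n = 500
})

test_that("edge-recovery F1 improves with sample size", {
  f1_at <- function(n, seeds = 1:4) {
    mean(vapply(seeds, function(s) {
      tr <- generate_truth(10, 0.2, 0, 0, de_shift = c(0, 0), seed = s)
      expr <- simulate_pair(tr, "case", n, seed = 500 + s)
      cn <- candidate_network(tr$genes,
                              make_candidate_edges(tr, 0.5, seed = s + 40))
      fit <- fit_condition_network(expr, "case", cn, dppin_config())
      est <- fit$coef != 0
      tru <- tr$control != 0
      tp <- sum(est & tru)
      if (sum(est) == 0 || tp == 0) return(0)
      prec <- tp / sum(est); rec <- tp / sum(tru)
      2 * prec * rec / (prec + rec)
    }, numeric(1)))
  }
  f1 <- vapply(c(20, 50, 200, 500), f1_at, numeric(1))
  expect_true(all(diff(f1) > -0.02))   # monotone up to seed noise
  expect_gt(f1[4], f1[1])
})
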