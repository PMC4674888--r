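# Ground-truth simulator for benchmarking the full pipeline: a sparse
# coefficient matrix over a random PPI graph, per-condition rewiring of a
# chosen node subset, linear generation x = (I - A)^-1 w with Gaussian
# noise, and decoy (false-positive) candidate edges.

#' Generate a ground-truth network with condition-specific rewiring
#'
#' Draws an undirected support graph (each of the `choose(n_genes, 2)` pairs
#' an edge with probability `edge_density`), assigns every directed
#' coefficient on the support a value uniform on +/-\[0.2, 0.6\], and rescales
#' the control matrix so its spectral radius is at most 0.8 (keeping
#' `x = A x + w` well-defined).  Each condition matrix equals the control
#' except on edges incident to the `n_perturbed` perturbed nodes, whose
#' coefficients are shifted away from zero by exactly `effect_size`.
#'
#' @param n_genes Number of genes/proteins.
#' @param edge_density Bernoulli edge probability over unordered pairs.
#' @param n_perturbed Number of rewired nodes per condition.
#' @param effect_size Absolute coefficient shift on perturbed edges.
#' @param conditions Character vector of condition labels (one perturbed
#'   matrix each); the control matrix is labeled `"control"`.
#' @param sigma Noise standard deviation used at simulation time.
#' @param de_shift Range (in units of `sigma`) of the per-gene differential
#'   mean offset each condition adds on top of `base_mean`; the simulated
#'   genes emulate the ANOVA-screened differential pool, so by default every
#'   gene's condition mean is shifted by a uniform 2--4 sigma with random
#'   sign.  Set to `c(0, 0)` for groups that differ only in their network.
#' @param seed Integer seed; the same seed reproduces the truth exactly.
#' @return Object of class `GroundTruth`: gene ids, `control` matrix, one
#'   matrix per condition, `perturbed` node sets, `offsets` (per-condition
#'   mean shifts), `edges` (true support as an [edge_list()]), `sigma`, and
#'   the seed.
#' @export
generate_truth <- function(n_genes, edge_density, n_perturbed, effect_size,
                           conditions = "case", sigma = 1,
                           de_shift = c(2, 4), seed = 1L) {
  stopifnot(n_genes >= 2, edge_density > 0, edge_density < 1,
            n_perturbed >= 0, n_perturbed <= n_genes, effect_size >= 0)
  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  pairs <- utils::combn(n_genes, 2)
  on_edge <- stats::runif(ncol(pairs)) < edge_density
  if (!any(on_edge)) stop("edge_density yielded zero edges; increase it")
  ii <- pairs[1, on_edge]; jj <- pairs[2, on_edge]

  A <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  draw <- function(k) stats::runif(k, 0.2, 0.6) * sample(c(-1, 1), k, TRUE)
  for (e in seq_along(ii)) {
    A[ii[e], jj[e]] <- draw(1L)
    A[jj[e], ii[e]] <- draw(1L)
  }
  rho <- .spectral_radius(A)
  if (rho > 0.8) A <- A * (0.8 / rho)

  perturbed <- list()
  cond_mats <- list()
  offsets <- list(control = stats::setNames(numeric(n_genes), genes))
  for (k in conditions) {
    Ak <- A
    # only connected nodes can be rewired: a perturbed node must actually
    # change the coefficient matrix
    connected <- genes[rowSums(A != 0) + colSums(A != 0) > 0]
    if (n_perturbed > length(connected))
      stop("n_perturbed exceeds the ", length(connected),
           " connected nodes of the true graph")
    pert <- sort(sample(connected, n_perturbed))
    if (n_perturbed > 0) {
      hit <- (rownames(A) %in% pert | rep(colnames(A) %in% pert,
                                          each = n_genes)) & A != 0
      # shift each perturbed coefficient by +/- effect_size, so that
      # |condition - control| = effect_size exactly on every hit entry;
      # signs are redrawn (up to 20 times) until the perturbed matrix
      # stays safely inside the stability region
      ok <- FALSE
      for (try in 1:20) {
        Ak <- A
        Ak[hit] <- A[hit] + sample(c(-1, 1), sum(hit), TRUE) * effect_size
        if (.spectral_radius(Ak) < 0.95) { ok <- TRUE; break }
      }
      if (!ok)
        stop("perturbed coefficient matrix too close to instability; ",
             "lower effect_size or edge_density")
    }
    perturbed[[k]] <- if (n_perturbed > 0) pert else character()
    cond_mats[[k]] <- Ak
    offsets[[k]] <- stats::setNames(
      sample(c(-1, 1), n_genes, TRUE) *
        stats::runif(n_genes, de_shift[1], de_shift[2]) * sigma,
      genes)
  }

  structure(list(genes = genes, control = A, condition = cond_mats,
                 perturbed = perturbed, offsets = offsets,
                 edges = edge_list(genes[ii], genes[jj],
                                   source = rep("true", length(ii))),
                 sigma = sigma, seed = seed),
            class = "GroundTruth")
}

.spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d genes, %d true edges, conditions: %s\n",
              length(x$genes), nrow(x$edges),
              paste(names(x$condition), collapse = ", ")))
  invisible(x)
}

#' Simulate expression under the linear association model
#'
#' Each sample is an exact solution of `x = A x + w` with
#' `w ~ N(0, sigma^2 I)`, i.e. `x = (I - A)^-1 w`, shifted by `base_mean`
#' to positive intensities.  Any residual negative value is clamped to zero
#' with a message (with the default `base_mean` this should never trigger).
#'
#' @param truth A [generate_truth()] object.
#' @param condition `"control"` or one of the truth's condition labels.
#' @param n_samples Samples to draw (study groups have 23).
#' @param base_mean Intensity offset added to every gene.
#' @param seed Integer seed.
#' @param group_label Group label attached to the samples; defaults to
#'   `condition`.
#' @return An [expression_matrix()] with `n_samples` columns.
#' @export
simulate_expression <- function(truth, condition = "control", n_samples = 23,
                                base_mean = 100, seed = 1L,
                                group_label = condition) {
  stopifnot(n_samples >= 2)
  A <- if (condition == "control") truth$control else truth$condition[[condition]]
  if (is.null(A)) stop("unknown condition: ", condition)
  M <- length(truth$genes)
  IA <- diag(M) - A
  if (abs(det(IA)) < 1e-12) stop("(I - A) is singular; cannot simulate")
  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  W <- matrix(stats::rnorm(M * n_samples, sd = truth$sigma), M, n_samples)
  off <- if (!is.null(truth$offsets)) truth$offsets[[condition]] else 0
  X <- solve(IA, W) + base_mean + off
  neg <- X < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative intensity value(s) to zero")
    X[neg] <- 0
  }
  dimnames(X) <- list(truth$genes,
                      sprintf("%s_S%03d", group_label, seq_len(n_samples)))
  expression_matrix(X, stats::setNames(rep(group_label, n_samples), colnames(X)))
}

#' Candidate edge list with decoy (false-positive) edges
#'
#' Returns the union of the true support edges and `round(decoy_fraction *
#' n_true)` decoys sampled uniformly from the non-edges.  The `source`
#' column (`"true"` / `"decoy"`) is scoring metadata for benchmark
#' harnesses; the inference pipeline never reads it.
#'
#' @param truth A [generate_truth()] object.
#' @param decoy_fraction Decoys as a fraction of the true edge count.
#' @param seed Integer seed.
#' @return An [edge_list()] with a `source` annotation.
#' @export
make_candidate_edges <- function(truth, decoy_fraction = 0.5, seed = 1L) {
  stopifnot(decoy_fraction >= 0, decoy_fraction <= 1)
  true <- truth$edges
  n_decoy <- round(decoy_fraction * nrow(true))
  if (n_decoy == 0) return(true)
  genes <- truth$genes
  pairs <- utils::combn(length(genes), 2)
  key <- paste(genes[pairs[1, ]], genes[pairs[2, ]], sep = "\r")
  free <- which(!(key %in% paste(true$a, true$b, sep = "\r")))
  if (length(free) < n_decoy)
    stop("not enough non-edges to place ", n_decoy, " decoys")
  old <- .hold_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  pick <- sort(sample(free, n_decoy))
  edge_list(c(true$a, genes[pairs[1, pick]]),
            c(true$b, genes[pairs[2, pick]]),
            source = c(true$source, rep("decoy", n_decoy)))
}

.hold_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
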