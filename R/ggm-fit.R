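#' Per-condition sample statistics
#'
#' Computes the sample mean, the mean-centered scatter matrix
#' \eqn{W = \sum_j (y_j - \bar y)(y_j - \bar y)^T} and the unbiased
#' sample covariance \eqn{S = W / (n - 1)} of one condition's expression
#' matrix.
#'
#' @param x Numeric matrix, samples in rows, genes in columns (column
#'   names are gene labels).
#' @return An object of class `sample_stats`: list with `mean`, `S`, `W`,
#'   `n`, `p`.
#' @export
sample_stats <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 samples are required to estimate a covariance")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  W <- crossprod(xc)
  S <- W / (n - 1)
  if (any(diag(S) <= .Machine$double.eps))
    warning("constant column(s) detected; sample covariance is singular")
  structure(list(mean = mu, S = S, W = W, n = n, p = ncol(x)),
            class = "sample_stats")
}

#' Pooled sample covariance of two conditions
#'
#' \eqn{S = \{(n_1-1) S_1 + (n_2-1) S_2\} / (n_1 + n_2 - 2)}, the input to
#' the constrained fit under the null hypothesis of equal covariances.
#'
#' @param s1,s2 `sample_stats` for the two conditions (matching genes).
#' @return A p x p matrix.
#' @export
pooled_covariance <- function(s1, s2) {
  if (s1$p != s2$p || !identical(colnames(s1$S), colnames(s2$S)))
    stop("the two conditions have mismatched gene sets")
  ((s1$n - 1) * s1$S + (s2$n - 1) * s2$S) / (s1$n + s2$n - 2)
}

# positive-definiteness by relative eigenvalue threshold
.is_pd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] > nrow(S) * .Machine$double.eps * max(ev[1L], 0)
}

.logdet <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e)
    stop("singular or non-positive-definite ", what, call. = FALSE))
  2 * sum(log(diag(ch)))
}

.check_alignment <- function(S, graph) {
  nms <- igraph::V(graph)$name
  if (nrow(S) != length(nms))
    stop("matrix dimension does not match the graph's vertex count")
  if (!is.null(colnames(S)) && !identical(colnames(S), nms))
    stop("matrix column order must equal the graph vertex order")
  nms
}

#' Fit a graphical Gaussian model by iterative proportional scaling
#'
#' Estimates the covariance of a Gaussian model whose concentration matrix
#' is constrained to have zeros at the non-edges of `graph`
#' (\eqn{\Sigma^{-1} \in S^+(G)}).  IPS cycles over the maximal cliques of
#' the graph, matching the fitted clique-marginal covariances to those of
#' the input matrix `S`; at convergence the fit equals `S` on every clique
#' (edges and diagonal) while the concentration is exactly zero elsewhere.
#'
#' @param S Symmetric positive definite input matrix (a sample or shrinkage
#'   covariance), columns ordered as the graph vertices.
#' @param graph Undirected [igraph::graph].
#' @param tol Convergence tolerance: maximum absolute change of any fitted
#'   covariance entry between sweeps.
#' @param max_iter Maximum number of full sweeps over the cliques.
#' @return An object of class `ggm_fit`: list with `graph`, `sigma`, `K`
#'   (concentration), `converged`, `iterations`, `cliques`.
#' @seealso [decomposable_mle()] for the closed form on chordal graphs,
#'   [shrinkage_covariance()] for non-positive-definite inputs.
#' @export
ips_fit <- function(S, graph, tol = 1e-8, max_iter = 5000L) {
  S <- as.matrix(S)
  nms <- .check_alignment(S, graph)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("input matrix is not symmetric")
  S <- (S + t(S)) / 2
  if (!.is_pd(S))
    stop("input matrix is not positive definite; for n < p use ",
         "shrinkage_covariance() as the IPS input")
  p <- nrow(S)
  cliques <- graph_cliques(graph)
  idx <- lapply(cliques, function(cc) match(cc, nms))
  K <- diag(1 / diag(S), p)
  sigma_prev <- diag(diag(S), p)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (ci in idx) {
      sigma <- chol2inv(chol(K))
      K[ci, ci] <- K[ci, ci] + solve(S[ci, ci, drop = FALSE]) -
        solve(sigma[ci, ci, drop = FALSE])
    }
    sigma <- chol2inv(chol(K))
    if (max(abs(sigma - sigma_prev)) < tol) { converged <- TRUE; break }
    sigma_prev <- sigma
  }
  if (!converged)
    warning("IPS did not converge within ", max_iter, " sweeps")
  dimnames(sigma) <- dimnames(K) <- list(nms, nms)
  structure(list(graph = graph, sigma = sigma, K = K, converged = converged,
                 iterations = it, cliques = cliques),
            class = "ggm_fit")
}

#' Closed-form constrained MLE on a decomposable graph
#'
#' For chordal graphs the graph-constrained concentration estimate has a
#' junction-tree closed form: the sum of padded inverses of the clique
#' submatrices of `S` minus padded inverses of the separator submatrices.
#' Serves as an independent check of [ips_fit()].
#'
#' @param S Symmetric positive definite matrix aligned to the graph.
#' @param graph A chordal undirected [igraph::graph].
#' @return The p x p concentration matrix estimate.
#' @export
decomposable_mle <- function(S, graph) {
  S <- as.matrix(S)
  nms <- .check_alignment(S, graph)
  if (!is_triangulated(graph))
    stop("decomposable_mle() requires a triangulated (chordal) graph")
  if (!.is_pd(S)) stop("input matrix is not positive definite")
  rip <- .rip_cliques(graph)
  p <- nrow(S)
  K <- matrix(0, p, p, dimnames = list(nms, nms))
  for (j in seq_along(rip$cliques)) {
    ci <- match(rip$cliques[[j]], nms)
    K[ci, ci] <- K[ci, ci] + solve(S[ci, ci, drop = FALSE])
    sp <- rip$separators[[j]]
    if (length(sp)) {
      si <- match(sp, nms)
      K[si, si] <- K[si, si] - solve(S[si, si, drop = FALSE])
    }
  }
  K
}

#' Shrinkage covariance estimate
#'
#' Analytic shrinkage of the sample covariance toward its diagonal
#' (variances preserved, off-diagonal entries shrunk), with the
#' Ledoit-Wolf/Schafer-Strimmer data-driven intensity
#' \eqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(s_{ij}) / \sum_{i \ne j}
#' s_{ij}^2} truncated to \[0, 1\].  Guarantees a positive definite matrix
#' usable as IPS input when n < p.
#'
#' @param x Samples x genes matrix.
#' @return A p x p positive definite matrix with attribute `lambda`, the
#'   shrinkage intensity used.
#' @export
shrinkage_covariance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 samples are required")
  xc <- sweep(x, 2L, colMeans(x))
  S <- crossprod(xc) / (n - 1)
  lambda <- .shrink_intensity(xc)
  .shrink_apply(S, lambda)
}

# analytic off-diagonal shrinkage intensity from a column-centered matrix:
# lambda* = sum_{i<j} Var-hat(s_ij) / sum_{i<j} s_ij^2, with
# Var-hat(s_ij) = n/(n-1)^3 sum_k (w_kij - mean_k w_kij)^2, w_kij = xc_ki xc_kj
.shrink_intensity <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  if (p < 2L) return(0)
  S <- crossprod(xc) / (n - 1)
  num <- 0; den <- 0
  for (i in seq_len(p - 1L)) {
    w <- xc[, (i + 1L):p, drop = FALSE] * xc[, i]
    wbar <- colMeans(w)
    num <- num + sum(colSums(sweep(w, 2L, wbar)^2)) * n / (n - 1)^3
    den <- den + sum(S[i, (i + 1L):p]^2)
  }
  if (den > 0) min(1, max(0, num / den)) else 1
}

# convex combination with the diagonal target; lambda* is derived for risk,
# not conditioning, so nudge further toward the target in the rare case the
# combination is still not numerically positive definite
.shrink_apply <- function(S, lambda) {
  target <- diag(diag(S), nrow(S))
  Sstar <- (1 - lambda) * S + lambda * target
  while (!.is_pd(Sstar) && lambda < 1) {
    lambda <- min(1, lambda + 0.05)
    Sstar <- (1 - lambda) * S + lambda * target
  }
  dimnames(Sstar) <- dimnames(S)
  attr(Sstar, "lambda") <- lambda
  Sstar
}

#' Gaussian profile log-likelihood of a fitted GGM
#'
#' \eqn{\ell = n\{-p \log(2\pi) + \log\det K - tr(K W)/n\}/2} with the
#' mean-centered scatter `W` of `stats`.  At an IPS fit of `W/n` the trace
#' term equals `n p`.
#'
#' @param fit A `ggm_fit`.
#' @param stats A `sample_stats` for the same variables.
#' @return Scalar log-likelihood.
#' @export
ggm_loglik <- function(fit, stats) {
  K <- fit$K
  if (nrow(K) != stats$p) stop("dimension mismatch between fit and stats")
  ld <- .logdet(K, "concentration matrix")
  n <- stats$n
  0.5 * n * (-stats$p * log(2 * pi) + ld) - 0.5 * sum(K * stats$W)
}

#' Fit a graphical Gaussian model to one condition's data
#'
#' Convenience wrapper: computes [sample_stats()], chooses the sample or
#' shrinkage covariance as IPS input, and returns the fit annotated with
#' the condition's mean, sample size and log-likelihood.
#'
#' @param x Samples x genes matrix aligned to the graph vertex order.
#' @param graph Undirected [igraph::graph].
#' @param shrinkage Use [shrinkage_covariance()] instead of the sample
#'   covariance as IPS input.
#' @param ... Passed to [ips_fit()].
#' @return A `ggm_fit` with additional fields `mean`, `n`, `loglik`.
#' @export
fit_ggm <- function(x, graph, shrinkage = FALSE, ...) {
  st <- sample_stats(x)
  .check_alignment(st$S, graph)
  S <- if (shrinkage) shrinkage_covariance(x) else st$S
  fit <- ips_fit(S, graph, ...)
  fit$mean <- st$mean
  fit$n <- st$n
  fit$loglik <- ggm_loglik(fit, st)
  fit
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat("Graphical Gaussian model fit\n")
  cat("  vertices:", nrow(x$sigma), " cliques:", length(x$cliques), "\n")
  cat("  IPS sweeps:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$loglik)) cat("  log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}
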