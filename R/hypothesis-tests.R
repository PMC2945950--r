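#' @keywords internal
new_test_result <- function(statistic, df = NA_real_, p.value, method,
                            n_perm = NA_integer_, note = NULL) {
  structure(list(statistic = statistic, df = df, p.value = p.value,
                 method = method, n_perm = n_perm, note = note),
            class = "ggm_test")
}

#' @export
print.ggm_test <- function(x, ...) {
  cat("Two-sample GGM test (", x$method, ")\n", sep = "")
  cat("  statistic =", format(x$statistic),
      if (!is.na(x$df)) paste0(" df = ", x$df) else "",
      " p-value =", format.pval(x$p.value, digits = 4), "\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

# reorder sample x gene matrices to the graph's vertex order
.align_data <- function(x, graph) {
  nms <- igraph::V(graph)$name
  if (is.null(colnames(x))) {
    if (ncol(x) != length(nms))
      stop("data has ", ncol(x), " columns but the graph has ", length(nms),
           " vertices")
    colnames(x) <- nms
    return(x)
  }
  missing <- setdiff(nms, colnames(x))
  if (length(missing))
    stop("expression data lacks graph vertices: ",
         paste(missing, collapse = ", "))
  as.matrix(x)[, nms, drop = FALSE]
}

.fit_named <- function(S, graph, label, ...) {
  tryCatch(ips_fit(S, graph, ...),
           error = function(e) stop(label, " fit failed: ",
                                    conditionMessage(e), call. = FALSE))
}

# -2 log lambda for equality of graph-constrained concentration matrices
.conc_stat <- function(x1, x2, graph, shrinkage = FALSE, ...) {
  s1 <- sample_stats(x1); s2 <- sample_stats(x2)
  if (shrinkage) {
    S1 <- shrinkage_covariance(x1)
    S2 <- shrinkage_covariance(x2)
    Sp <- ((s1$n - 1) * S1 + (s2$n - 1) * S2) / (s1$n + s2$n - 2)
  } else {
    S1 <- s1$S; S2 <- s2$S
    Sp <- pooled_covariance(s1, s2)
  }
  f1 <- .fit_named(S1, graph, "condition-1", ...)
  f2 <- .fit_named(S2, graph, "condition-2", ...)
  f0 <- .fit_named(Sp, graph, "pooled", ...)
  ld0 <- .logdet(f0$K)
  s1$n * (.logdet(f1$K) - ld0) + s2$n * (.logdet(f2$K) - ld0)
}

#' Test equality of the graph-constrained concentration matrices
#'
#' Likelihood-ratio test of \eqn{H_0 : K_1 = K_2} for two graphical
#' Gaussian models sharing the undirected graph `G`, i.e. of whether the
#' strength of the relations among the genes differs between conditions.
#' The statistic is \eqn{-2\log\lambda = \sum_i n_i \log(\det\hat K_i /
#' \det\hat K)}, with the three constrained estimates obtained by IPS from
#' the per-condition sample covariances and their pooled combination; its
#' asymptotic null distribution is chi-squared with \eqn{p + r} degrees of
#' freedom (`p` vertices, `r` edges of `G`).
#'
#' With `shrinkage = TRUE` (the n < p path) the IPS inputs are shrinkage
#' covariance estimates and the null distribution is obtained by permuting
#' condition labels instead of the chi-squared asymptotics.
#'
#' @param x1,x2 Samples x genes matrices for the two conditions, columns
#'   aligned (or alignable by name) to the graph vertices.
#' @param graph Undirected [igraph::graph] (typically the moral graph).
#' @param shrinkage Use the shrinkage/permutation path.
#' @param n_perm Number of label permutations when `shrinkage = TRUE`.
#' @param seed Optional RNG seed for the permutations.
#' @param ... Passed to [ips_fit()].
#' @return A `ggm_test` result.
#' @export
test_concentration_equality <- function(x1, x2, graph, shrinkage = FALSE,
                                        n_perm = 999L, seed = NULL, ...) {
  x1 <- .align_data(x1, graph); x2 <- .align_data(x2, graph)
  if (shrinkage) {
    return(permutation_null(x1, x2, graph,
                            function(a, b, g) .conc_stat(a, b, g, shrinkage = TRUE, ...),
                            n_perm = n_perm, seed = seed))
  }
  stat <- .conc_stat(x1, x2, graph, shrinkage = FALSE, ...)
  p <- igraph::vcount(graph); r <- igraph::ecount(graph)
  df <- p + r
  new_test_result(stat, df = df,
                  p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                  method = "asymptotic_chi2")
}

# MLE-divisor scatter about an arbitrary center
.scatter_about <- function(x, center) {
  xc <- sweep(x, 2L, center)
  crossprod(xc)
}

#' Test equality of the two mean vectors
#'
#' Likelihood-ratio test of \eqn{H_0 : \mu_1 = \mu_2} for two graphical
#' Gaussian models on the graph `G`, with the covariance treated as common
#' (`homogeneous = TRUE`) or condition-specific (`homogeneous = FALSE`,
#' the graph-constrained Behrens-Fisher problem).  The choice between the
#' two variants is normally made from the outcome of
#' [test_concentration_equality()].
#'
#' Both variants maximize the Gaussian likelihood with IPS-constrained
#' covariances under each hypothesis and refer \eqn{2(\hat\ell_1 -
#' \hat\ell_0)} to a chi-squared distribution with `p` degrees of freedom.
#' In the heterogeneous case the common-mean fit alternates generalized
#' least squares updates of the mean with IPS updates of the two
#' covariances until the mean stabilizes.
#'
#' @inheritParams test_concentration_equality
#' @param homogeneous Assume a common covariance matrix under both
#'   hypotheses.
#' @param shrinkage Shrink every scatter-derived IPS input toward its
#'   diagonal with the analytic intensity estimated from the data (the
#'   n < p path); pair with [permutation_null()] since the chi-squared
#'   reference is then no longer justified.
#' @param mean_tol Convergence tolerance on the common-mean iteration
#'   (heterogeneous case).
#' @param max_mean_iter Iteration cap for the common-mean alternation.
#' @return A `ggm_test` result (df = p).
#' @export
test_mean_equality <- function(x1, x2, graph, homogeneous = TRUE,
                               shrinkage = FALSE, mean_tol = 1e-7,
                               max_mean_iter = 100L, ...) {
  x1 <- .align_data(x1, graph); x2 <- .align_data(x2, graph)
  n1 <- nrow(x1); n2 <- nrow(x2); N <- n1 + n2
  p <- igraph::vcount(graph)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  W1 <- .scatter_about(x1, m1); W2 <- .scatter_about(x2, m2)
  if (shrinkage) {
    lam1 <- .shrink_intensity(sweep(x1, 2L, m1))
    lam2 <- .shrink_intensity(sweep(x2, 2L, m2))
    lamp <- .shrink_intensity(rbind(sweep(x1, 2L, m1), sweep(x2, 2L, m2)))
    prep <- function(M, lam) .shrink_apply(M, lam)
  } else {
    lam1 <- lam2 <- lamp <- 0
    prep <- function(M, lam) M
  }
  if (homogeneous) {
    f1 <- .fit_named(prep((W1 + W2) / N, lamp), graph,
                     "alternative (pooled-covariance)", ...)
    grand <- (n1 * m1 + n2 * m2) / N
    W0 <- .scatter_about(x1, grand) + .scatter_about(x2, grand)
    f0 <- .fit_named(prep(W0 / N, lamp), graph, "null (common-mean)", ...)
    stat <- N * (.logdet(f1$K) - .logdet(f0$K))
  } else {
    f1a <- .fit_named(prep(W1 / n1, lam1), graph, "condition-1", ...)
    f2a <- .fit_named(prep(W2 / n2, lam2), graph, "condition-2", ...)
    mu <- (n1 * m1 + n2 * m2) / N
    K1 <- f1a$K; K2 <- f2a$K
    for (it in seq_len(max_mean_iter)) {
      g1 <- .fit_named(prep(.scatter_about(x1, mu) / n1, lam1), graph,
                       "null condition-1", ...)
      g2 <- .fit_named(prep(.scatter_about(x2, mu) / n2, lam2), graph,
                       "null condition-2", ...)
      A <- n1 * g1$K + n2 * g2$K
      b <- n1 * g1$K %*% m1 + n2 * g2$K %*% m2
      mu_new <- drop(solve(A, b))
      done <- max(abs(mu_new - mu)) < mean_tol
      mu <- mu_new
      if (done) break
    }
    stat <- n1 * (.logdet(K1) - .logdet(g1$K)) +
      n2 * (.logdet(K2) - .logdet(g2$K))
  }
  new_test_result(stat, df = p,
                  p.value = stats::pchisq(stat, p, lower.tail = FALSE),
                  method = "asymptotic_chi2",
                  note = if (homogeneous) "homogeneous covariances"
                         else "heterogeneous covariances (Behrens-Fisher)")
}

#' Exact Hotelling T-squared mean test on one clique
#'
#' On a clique the graph-constrained model is saturated, so when the two
#' covariance matrices are homogeneous the classical exact two-sample
#' Hotelling test applies: \eqn{T^2 = \frac{n_1 n_2}{n_1+n_2}
#' (\bar y_1 - \bar y_2)^T S_p^{-1} (\bar y_1 - \bar y_2)} with
#' \eqn{\frac{N - c - 1}{(N-2)c} T^2 \sim F_{c,\,N-c-1}}.
#'
#' @param x1,x2 Samples x genes matrices (columns named by gene).
#' @param clique Character vector of clique member labels.
#' @return A `ggm_test` with `method = "exact"`; `statistic` is the
#'   T-squared value and `df` the pair of F degrees of freedom.
#' @export
exact_clique_mean_test <- function(x1, x2, clique) {
  x1 <- as.matrix(x1)[, clique, drop = FALSE]
  x2 <- as.matrix(x2)[, clique, drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2); N <- n1 + n2
  cs <- length(clique)
  if (cs >= N - 1L)
    stop("clique size ", cs, " too large for an exact test with ", N, " samples")
  s1 <- sample_stats(x1); s2 <- sample_stats(x2)
  Sp <- pooled_covariance(s1, s2)
  d <- s1$mean - s2$mean
  quad <- tryCatch(drop(crossprod(d, solve(Sp, d))),
                   error = function(e) stop("singular pooled clique covariance",
                                            call. = FALSE))
  T2 <- (n1 * n2 / N) * quad
  Fstat <- (N - cs - 1) / ((N - 2) * cs) * T2
  res <- new_test_result(T2, df = NA_real_,
                         p.value = stats::pf(Fstat, cs, N - cs - 1,
                                             lower.tail = FALSE),
                         method = "exact")
  res$df <- c(cs, N - cs - 1)
  res
}

# classical (unconstrained) two-sample covariance-equality LRT on a
# complete variable set; equals the graph-constrained test when the
# subgraph is complete
.classical_cov_test <- function(x1, x2) {
  s1 <- sample_stats(x1); s2 <- sample_stats(x2)
  Sp <- pooled_covariance(s1, s2)
  ldp <- .logdet(Sp, "pooled covariance")
  stat <- s1$n * (ldp - .logdet(s1$S, "condition-1 covariance")) +
    s2$n * (ldp - .logdet(s2$S, "condition-2 covariance"))
  cs <- s1$p
  df <- cs * (cs + 1) / 2
  new_test_result(stat, df = df,
                  p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                  method = "asymptotic_chi2")
}

.complete_graph <- function(labels) {
  g <- igraph::make_full_graph(length(labels))
  igraph::V(g)$name <- labels
  g
}

#' Clique-level two-sample analysis
#'
#' Repeats both tests on every maximal clique of a triangulated graph,
#' mirroring the per-clique report of the method: for each clique, the
#' covariance-equality test reduces to the classical unconstrained
#' two-sample likelihood-ratio test (the clique is complete, df =
#' c(c+1)/2); the mean test is the exact Hotelling test when clique-level
#' homogeneity is not rejected at `alpha_cov`, and the asymptotic
#' heterogeneous (Behrens-Fisher) test otherwise.
#'
#' @inheritParams test_concentration_equality
#' @param graph A chordal undirected [igraph::graph]; triangulate first if
#'   needed.
#' @param alpha_cov Level of the per-clique covariance test used to switch
#'   between the exact and asymptotic mean tests.
#' @return An object of class `clique_report`: a data frame with one row
#'   per clique (`clique`, `size`, `stat_cov`, `df_cov`, `p_cov`,
#'   `stat_mean`, `p_mean`, `mean_method`, `error`), with the full
#'   `ggm_test` objects in attribute `details`.
#' @export
clique_analysis <- function(x1, x2, graph, alpha_cov = 0.05) {
  if (!is_triangulated(graph))
    stop("clique_analysis() requires a triangulated graph; call triangulate()")
  x1 <- .align_data(x1, graph); x2 <- .align_data(x2, graph)
  cliques <- graph_cliques(graph)
  rows <- vector("list", length(cliques))
  details <- vector("list", length(cliques))
  for (j in seq_along(cliques)) {
    cc <- cliques[[j]]
    row <- data.frame(clique = paste(cc, collapse = ","), size = length(cc),
                      stat_cov = NA_real_, df_cov = NA_real_, p_cov = NA_real_,
                      stat_mean = NA_real_, p_mean = NA_real_,
                      mean_method = NA_character_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      ct <- .classical_cov_test(x1[, cc, drop = FALSE], x2[, cc, drop = FALSE])
      homogeneous <- ct$p.value > alpha_cov
      mt <- if (homogeneous) {
        exact_clique_mean_test(x1, x2, cc)
      } else {
        test_mean_equality(x1[, cc, drop = FALSE], x2[, cc, drop = FALSE],
                           .complete_graph(cc), homogeneous = FALSE)
      }
      list(ct = ct, mt = mt)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      row$error <- res
    } else {
      row$stat_cov <- res$ct$statistic
      row$df_cov <- res$ct$df
      row$p_cov <- res$ct$p.value
      row$stat_mean <- res$mt$statistic
      row$p_mean <- res$mt$p.value
      row$mean_method <- if (res$mt$method == "exact") "exact" else "asymptotic"
      details[[j]] <- res
    }
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  attr(out, "alpha_cov") <- alpha_cov
  class(out) <- c("clique_report", "data.frame")
  out
}

#' Count clique-level rejections
#'
#' The number m of cliques whose covariance (or mean) test rejects at
#' `alpha`; the quantity whose null distribution the simulation module
#' characterizes.
#'
#' @param report A `clique_report`.
#' @param alpha Rejection level.
#' @param which `"cov"` or `"mean"`.
#' @return Integer count.
#' @export
count_rejections <- function(report, alpha = 0.05, which = c("cov", "mean")) {
  which <- match.arg(which)
  p <- if (which == "cov") report$p_cov else report$p_mean
  sum(p <= alpha, na.rm = TRUE)
}

#' Permutation null distribution for a two-sample statistic
#'
#' Approximates the null distribution of an arbitrary two-sample statistic
#' by shuffling condition labels over the pooled samples, for use when the
#' chi-squared asymptotics do not apply (e.g. shrinkage-based fits with
#' n < p).  The p-value uses the add-one estimator
#' \eqn{(1 + \#\{stat_b \ge stat_{obs}\}) / (1 + B)}.
#'
#' @param x1,x2 Samples x genes matrices aligned to the graph.
#' @param graph Undirected [igraph::graph], passed through to
#'   `statistic_fn`.
#' @param statistic_fn Function `(x1, x2, graph) -> scalar`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional RNG seed; permutations are reproducible given it.
#' @return A `ggm_test` with `method = "permutation"`.
#' @export
permutation_null <- function(x1, x2, graph, statistic_fn, n_perm = 999L,
                             seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  x1 <- .align_data(x1, graph); x2 <- .align_data(x2, graph)
  obs <- statistic_fn(x1, x2, graph)
  pool <- rbind(x1, x2)
  n1 <- nrow(x1); N <- nrow(pool)
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(N, n1)
    stat_b <- statistic_fn(pool[idx, , drop = FALSE],
                           pool[-idx, , drop = FALSE], graph)
    if (stat_b >= obs) ge <- ge + 1L
  }
  new_test_result(obs, df = NA_real_, p.value = (1 + ge) / (1 + n_perm),
                  method = "permutation", n_perm = as.integer(n_perm))
}
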