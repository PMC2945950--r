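#' Random chordal graphical Gaussian model
#'
#' Generates a random chordal graph (an Erdos-Renyi draw, triangulated by
#' greedy min-fill) together with a covariance matrix whose inverse
#' respects it: edge entries of the concentration matrix receive random
#' partial-correlation-scale values, the diagonal is inflated to strict
#' diagonal dominance (hence positive definiteness), and the implied
#' covariance is rescaled to unit variances.  Used as the synthetic stand-in
#' for pathway-derived graphs in calibration studies.
#'
#' @param p Number of vertices.
#' @param edge_density Edge probability of the pre-triangulation graph.
#' @param seed Optional RNG seed.
#' @return List with `graph` (chordal, vertices `g01`, `g02`, ...),
#'   `sigma` (p x p covariance, unit diagonal) and `K` (its inverse).
#' @export
random_chordal_ggm <- function(p, edge_density = 0.15, seed = NULL) {
  stopifnot(p >= 1, edge_density >= 0, edge_density <= 1)
  if (!is.null(seed)) set.seed(seed)
  nms <- sprintf("g%02d", seq_len(p))
  g <- igraph::sample_gnp(p, edge_density)
  igraph::V(g)$name <- nms
  g <- triangulate(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  K <- diag(1, p)
  if (p > 1) {
    up <- which(upper.tri(K) & A[nms, nms], arr.ind = TRUE)
    if (nrow(up)) {
      vals <- stats::runif(nrow(up), 0.2, 0.4) *
        sample(c(-1, 1), nrow(up), replace = TRUE)
      K[up] <- vals
      K[up[, c(2, 1), drop = FALSE]] <- vals
    }
    diag(K) <- rowSums(abs(K)) - abs(diag(K)) + 1
  }
  sigma <- chol2inv(chol(K))
  d <- 1 / sqrt(diag(sigma))
  sigma <- sigma * tcrossprod(d)          # unit variances
  K <- chol2inv(chol(sigma))
  K[!A[nms, nms] & !diag(p)] <- 0         # exact structural zeros
  dimnames(sigma) <- dimnames(K) <- list(nms, nms)
  list(graph = g, sigma = sigma, K = K)
}

#' Sample from a multivariate normal (GGM) distribution
#'
#' @param n Number of observations.
#' @param mu Mean vector (recycled scalar allowed).
#' @param sigma Positive definite covariance matrix; column names become
#'   gene labels.
#' @param seed Optional RNG seed (bit-reproducible draws given it).
#' @return An n x p matrix, samples in rows.
#' @export
sample_ggm <- function(n, mu, sigma, seed = NULL) {
  sigma <- as.matrix(sigma)
  if (!.is_pd(sigma)) stop("sigma is not positive definite")
  p <- nrow(sigma)
  mu <- rep_len(mu, p)
  if (!is.null(seed)) set.seed(seed)
  x <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  if (n == 1L) x <- matrix(x, nrow = 1L)
  colnames(x) <- colnames(sigma)
  x
}

#' Type-I error study for the clique-level tests
#'
#' Draws both conditions from a single graphical Gaussian model (so every
#' clique-level null hypothesis is true by construction), runs
#' [clique_analysis()] on each replicate, and records the number m of
#' clique rejections per run for the covariance and the mean test.  The
#' distribution of m characterizes the joint type-I behaviour of the
#' uncorrected clique tests, whose statistics are dependent through shared
#' variables.
#'
#' @param graph Chordal undirected [igraph::graph].
#' @param sigma Covariance with inverse respecting `graph`.
#' @param mu Mean vector (default 0).
#' @param n1,n2 Per-condition sample sizes.
#' @param n_runs Number of simulation runs.
#' @param alpha Rejection level for counting.
#' @param seed Root seed; each run draws from its own derived substream so
#'   runs are independent and individually replayable.
#' @return Object of class `type1_study`: list with integer vectors
#'   `m_cov`, `m_mean`, the clique count, histogram tables, `mean_m_cov`,
#'   `mean_m_mean`, and `skipped` (runs lost to fit failures; the study
#'   errs if they exceed 1% of `n_runs`).
#' @export
type1_error_study <- function(graph, sigma, mu = 0, n1 = 37L, n2 = 41L,
                              n_runs = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(n_runs >= 1, alpha > 0, alpha < 1)
  if (!is_triangulated(graph))
    stop("the study design requires a chordal graph")
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  n_cliques <- length(graph_cliques(graph))
  m_cov <- m_mean <- rep(NA_integer_, n_runs)
  skipped <- 0L
  p <- nrow(sigma)
  mu <- rep_len(mu, p)
  for (run in seq_len(n_runs)) {
    set.seed(run_seeds[run])
    x1 <- MASS::mvrnorm(n1, mu, sigma)
    x2 <- MASS::mvrnorm(n2, mu, sigma)
    colnames(x1) <- colnames(x2) <- colnames(sigma)
    rep_run <- tryCatch(clique_analysis(x1, x2, graph, alpha_cov = alpha),
                        error = function(e) NULL)
    if (is.null(rep_run) || any(!is.na(rep_run$error))) {
      skipped <- skipped + 1L
      next
    }
    m_cov[run] <- count_rejections(rep_run, alpha, "cov")
    m_mean[run] <- count_rejections(rep_run, alpha, "mean")
  }
  if (skipped > 0.01 * n_runs)
    stop("more than 1% of runs (", skipped, "/", n_runs,
         ") failed to fit; the m distribution would be biased")
  ok_cov <- m_cov[!is.na(m_cov)]
  ok_mean <- m_mean[!is.na(m_mean)]
  structure(list(
    m_cov = ok_cov, m_mean = ok_mean, n_cliques = n_cliques,
    hist_cov = table(factor(ok_cov, levels = 0:n_cliques)) / length(ok_cov),
    hist_mean = table(factor(ok_mean, levels = 0:n_cliques)) / length(ok_mean),
    mean_m_cov = mean(ok_cov), mean_m_mean = mean(ok_mean),
    alpha = alpha, n_runs = n_runs, skipped = skipped, seed = seed
  ), class = "type1_study")
}

#' Tail probability of the rejection count m
#'
#' Proportion of runs with more than `threshold` rejections.
#'
#' @param study A `type1_study`.
#' @param threshold Integer threshold.
#' @param which `"cov"` or `"mean"`.
#' @return A proportion in \[0, 1\].
#' @export
tail_prob <- function(study, threshold, which = c("cov", "mean")) {
  which <- match.arg(which)
  m <- if (which == "cov") study$m_cov else study$m_mean
  mean(m > threshold)
}

#' @export
print.type1_study <- function(x, ...) {
  cat("Type-I error study:", x$n_runs, "runs,", x$n_cliques,
      "cliques, alpha =", x$alpha, "\n")
  cat("  mean m (covariance test):", format(x$mean_m_cov), "\n")
  cat("  mean m (mean test):      ", format(x$mean_m_mean), "\n")
  cat("  P(m_cov > 9):", format(tail_prob(x, 9, "cov")), "\n")
  if (x$skipped) cat("  skipped runs:", x$skipped, "\n")
  invisible(x)
}

#' Write a type-I study to tab-separated files
#'
#' Writes the histogram of m (both tests) plus a one-line summary.
#'
#' @param study A `type1_study`.
#' @param file Output path for the histogram table; the summary goes to
#'   `<file>.summary.tsv`.
#' @return Invisibly, the histogram file path.
#' @export
write_study <- function(study, file) {
  df <- data.frame(m = 0:study$n_cliques,
                   prop_cov = as.numeric(study$hist_cov),
                   prop_mean = as.numeric(study$hist_mean))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- data.frame(n_runs = study$n_runs, n_cliques = study$n_cliques,
                   alpha = study$alpha, mean_m_cov = study$mean_m_cov,
                   mean_m_mean = study$mean_m_mean,
                   p_m_cov_gt9 = tail_prob(study, 9, "cov"),
                   skipped = study$skipped, seed = study$seed)
  utils::write.table(sm, paste0(file, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
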