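test_that("identical samples give a zero concentration-equality statistic", {
  mod <- random_chordal_ggm(5, 0.4, seed = 71)
  x <- sample_ggm(30, 0, mod$sigma, seed = 72)
  res <- test_concentration_equality(x, x, mod$graph)
  expect_lt(abs(res$statistic), 1e-6)
  expect_equal(res$p.value, 1, tolerance = 1e-6)
})

test_that("on a complete graph the test reduces to the classical covariance LRT", {
  nms <- c("a", "b", "c")
  g <- complete_graph_named(nms)
  set.seed(73)
  x1 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, nms))
  x2 <- matrix(rnorm(75, sd = 1.3), 25, 3, dimnames = list(NULL, nms))
  res <- test_concentration_equality(x1, x2, g)
  # direct determinant formula with the same divisor convention
  S1 <- cov(x1); S2 <- cov(x2)
  Sp <- (19 * S1 + 24 * S2) / 43
  ldet <- function(M) determinant(M, logarithm = TRUE)$modulus
  classical <- 20 * (ldet(Sp) - ldet(S1)) + 25 * (ldet(Sp) - ldet(S2))
  expect_equal(res$statistic, as.numeric(classical), tolerance = 1e-8)
  expect_equal(res$df, 3 + 3)
})

test_that("the statistic is symmetric in the conditions and scale equivariant", {
  mod <- random_chordal_ggm(5, 0.4, seed = 81)
  x1 <- sample_ggm(25, 0, mod$sigma, seed = 82)
  x2 <- sample_ggm(35, 0, 1.4 * mod$sigma, seed = 83)
  a <- test_concentration_equality(x1, x2, mod$graph)
  b <- test_concentration_equality(x2, x1, mod$graph)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-8)

  cs <- test_concentration_equality(3.7 * x1, 3.7 * x2, mod$graph)
  expect_equal(a$statistic, cs$statistic, tolerance = 1e-6)
  ms1 <- test_mean_equality(x1, x2, mod$graph, homogeneous = TRUE)
  ms2 <- test_mean_equality(3.7 * x1, 3.7 * x2, mod$graph, homogeneous = TRUE)
  expect_equal(ms1$statistic, ms2$statistic, tolerance = 1e-6)
})

test_that("degrees of freedom equal p + r and grow by one per added edge", {
  mod <- random_chordal_ggm(6, 0.3, seed = 91)
  g <- mod$graph
  x1 <- sample_ggm(40, 0, mod$sigma, seed = 92)
  x2 <- sample_ggm(40, 0, mod$sigma, seed = 93)
  r0 <- test_concentration_equality(x1, x2, g)
  expect_equal(r0$df, igraph::vcount(g) + igraph::ecount(g))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  non <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  g2 <- igraph::add_edges(g, igraph::V(g)$name[non[1, ]])
  expect_equal(test_concentration_equality(x1, x2, g2)$df, r0$df + 1)
})

test_that("mean tests are near zero for identical arms and match Hotelling exactly", {
  mod <- random_chordal_ggm(4, 0.5, seed = 101)
  x <- sample_ggm(40, 0, mod$sigma, seed = 102)
  for (hom in c(TRUE, FALSE)) {
    res <- test_mean_equality(x, x, mod$graph, homogeneous = hom)
    expect_lt(abs(res$statistic), 1e-6)
    expect_equal(res$df, 4)
  }

  # clique of size 1: exact test squares the pooled-variance t statistic
  x1 <- matrix(rnorm(20, 0.5), 20, 1, dimnames = list(NULL, "g"))
  x2 <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "g"))
  h <- exact_clique_mean_test(x1, x2, "g")
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(h$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(h$p.value, tt$p.value, tolerance = 1e-10)

  # two-gene toy data: hand-evaluated T-squared
  y1 <- matrix(c(1, 2, 3, 2, 4, 1, 0, 3), 4, 2,
               dimnames = list(NULL, c("u", "v")))
  y2 <- matrix(c(2, 3, 4, 5, 1, 2, 2, 4, 3, 1), 5, 2,
               dimnames = list(NULL, c("u", "v")))
  d <- colMeans(y1) - colMeans(y2)
  Sp <- (3 * cov(y1) + 4 * cov(y2)) / 7
  T2 <- (4 * 5 / 9) * drop(t(d) %*% solve(Sp) %*% d)
  h2 <- exact_clique_mean_test(y1, y2, c("u", "v"))
  expect_equal(h2$statistic, T2, tolerance = 1e-10)
  Fs <- (9 - 2 - 1) / ((9 - 2) * 2) * T2
  expect_equal(h2$p.value, pf(Fs, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("homogeneous mean test agrees with the Hotelling decision on complete graphs", {
  nms <- c("a", "b", "c")
  g <- complete_graph_named(nms)
  agree <- 0L
  for (s in 1:60) {
    set.seed(1200 + s)
    delta <- sample(c(0, 0.25), 1)
    x1 <- matrix(rnorm(180), 60, 3, dimnames = list(NULL, nms))
    x2 <- matrix(rnorm(180, mean = delta), 60, 3, dimnames = list(NULL, nms))
    lrt <- test_mean_equality(x1, x2, g, homogeneous = TRUE)
    hot <- exact_clique_mean_test(x1, x2, nms)
    agree <- agree + ((lrt$p.value <= 0.05) == (hot$p.value <= 0.05))
    # the LRT statistic is a monotone function of T2; p-values are close
    expect_lt(abs(lrt$p.value - hot$p.value), 0.06)
  }
  expect_gte(agree / 60, 0.9)
})

test_that("exact clique mean test p-values are uniform under the null", {
  pv <- numeric(300)
  for (s in seq_along(pv)) {
    set.seed(1500 + s)
    x1 <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
    x2 <- matrix(rnorm(54), 18, 3, dimnames = list(NULL, c("a", "b", "c")))
    pv[s] <- exact_clique_mean_test(x1, x2, c("a", "b", "c"))$p.value
  }
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("clique analysis reduces to the global tests on a complete graph", {
  nms <- c("a", "b", "c")
  g <- complete_graph_named(nms)
  set.seed(111)
  x1 <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, nms))
  x2 <- matrix(rnorm(90, 0.3), 30, 3, dimnames = list(NULL, nms))
  rep1 <- clique_analysis(x1, x2, g)
  expect_equal(nrow(rep1), 1)
  glob <- test_concentration_equality(x1, x2, g)
  expect_equal(rep1$stat_cov, glob$statistic, tolerance = 1e-8)
  expect_equal(rep1$p_cov, glob$p.value, tolerance = 1e-8)

  # identical arms on a path graph: all p-values 1
  path3 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c")), directed = FALSE)
  rep2 <- clique_analysis(x1, x1, path3)
  expect_equal(nrow(rep2), 2)
  expect_true(all(rep2$p_cov > 0.999))
  expect_true(all(rep2$p_mean > 0.999))
})

test_that("per-clique failures are reported in the row, not thrown", {
  nms <- c("a", "b", "c", "d")
  g <- complete_graph_named(nms)
  set.seed(121)
  # n too small for a 4-variable covariance: singular S
  x1 <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, nms))
  x2 <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, nms))
  rep3 <- clique_analysis(x1, x2, g)
  expect_equal(nrow(rep3), 1)
  expect_false(is.na(rep3$error))
  expect_true(is.na(rep3$p_cov))
})

test_that("permutation p-values follow the add-one rule", {
  nms <- c("a", "b")
  g <- complete_graph_named(nms)
  set.seed(131)
  x1 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, nms))
  x2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, nms))
  const <- permutation_null(x1, x2, g, function(a, b, g) 1, n_perm = 50,
                            seed = 1)
  expect_equal(const$p.value, 1)
  # statistic that is maximal for the observed labelling by construction
  topstat <- local({
    first <- TRUE
    function(a, b, g) {
      if (first) { first <<- FALSE; return(1e9) }
      stats::runif(1)
    }
  })
  top <- permutation_null(x1, x2, g, topstat, n_perm = 99, seed = 2)
  expect_equal(top$p.value, 0.01)
  expect_error(permutation_null(x1, x2, g, function(a, b, g) 1, n_perm = 0),
               "n_perm")
})

test_that("shrinkage + permutation path runs when n < p", {
  mod <- random_chordal_ggm(12, 0.25, seed = 141)
  x1 <- sample_ggm(8, 0, mod$sigma, seed = 142)
  x2 <- sample_ggm(9, 0, mod$sigma, seed = 143)
  expect_error(test_concentration_equality(x1, x2, mod$graph),
               "shrinkage_covariance")
  res <- test_concentration_equality(x1, x2, mod$graph, shrinkage = TRUE,
                                     n_perm = 49, seed = 3)
  expect_equal(res$method, "permutation")
  expect_gte(res$p.value, 1 / 50)
  res2 <- test_concentration_equality(x1, x2, mod$graph, shrinkage = TRUE,
                                      n_perm = 49, seed = 3)
  expect_identical(res$p.value, res2$p.value)  # seed-reproducible
})
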