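# Generates the small synthetic demo dataset shipped under inst/extdata/.
# Run from the package root with the package installed:
#   Rscript data-raw/make_extdata.R
# The files are synthetic: a hand-crafted 12-node signaling-style pathway
# and expression values simulated from a graphical Gaussian model on its
# moral graph, with a mean shift on MAPK and TF1 in condition B and
# weakened MAPK-related edge strengths, so both tests have signal.

library(pathGGM)

set.seed(20260920)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

pw <- data.frame(
  source = c("LIG", "RTK", "SCAF", "ADAP", "KIN1", "GTP", "KIN2",
             "MAPK", "MAPK", "PHOS", "TF1", "TF2"),
  target = c("RTK", "ADAP", "ADAP", "GTP", "GTP", "MAPK", "MAPK",
             "TF1", "TF2", "RTK", "OUT", "OUT"),
  type = c("directed", "phospho_plus", "directed", "directed",
           "inhibition", "directed", "phospho_plus", "directed",
           "directed", "phospho_minus", "undirected", "directed"),
  orientation = c(rep("", 10), "forward", ""))
writeLines(c("# synthetic demo pathway (12 nodes, all edge types)",
             apply(pw, 1, paste, collapse = "\t")),
           "inst/extdata/synthetic_pathway.tsv")

dag <- build_dag(pathway_edges(pw))
moral <- moralize(dag)
nodes <- igraph::V(moral)$name
p <- length(nodes)
A <- igraph::as_adjacency_matrix(moral, sparse = FALSE) > 0

make_K <- function(scale_mapk = 1) {
  K <- diag(1, p); dimnames(K) <- list(nodes, nodes)
  set.seed(101)
  up <- which(upper.tri(K) & A, arr.ind = TRUE)
  vals <- runif(nrow(up), 0.2, 0.35) * sample(c(-1, 1), nrow(up), TRUE)
  K[up] <- vals; K[up[, c(2, 1)]] <- vals
  mapk <- which(nodes[up[, 1]] == "MAPK" | nodes[up[, 2]] == "MAPK")
  K[up[mapk, , drop = FALSE]] <- scale_mapk * K[up[mapk, , drop = FALSE]]
  K[up[mapk, c(2, 1), drop = FALSE]] <- K[up[mapk, , drop = FALSE]]
  diag(K) <- rowSums(abs(K)) - abs(diag(K)) + 1
  chol2inv(chol(K))
}
sigma1 <- make_K(1)
sigma2 <- make_K(-1)   # condition B: MAPK partial correlations flip sign
dimnames(sigma1) <- dimnames(sigma2) <- list(nodes, nodes)

n1 <- 30L; n2 <- 35L
mu2 <- setNames(rep(0, p), nodes)
mu2[c("MAPK", "TF1")] <- 0.9
set.seed(202)
x1 <- MASS::mvrnorm(n1, rep(0, p), sigma1)
x2 <- MASS::mvrnorm(n2, mu2, sigma2)
expr <- t(rbind(x1, x2))
rownames(expr) <- nodes
colnames(expr) <- sprintf("s%02d", seq_len(n1 + n2))

mk_members <- function(v, labels) {
  m <- rbind(v + rnorm(length(v), sd = 0.3), v + rnorm(length(v), sd = 0.3))
  rownames(m) <- labels
  m
}
expr <- rbind(expr[setdiff(nodes, c("KIN1", "TF2")), , drop = FALSE],
              mk_members(expr["KIN1", ], c("KIN1a", "KIN1b")),
              mk_members(expr["TF2", ], c("TF2a", "TF2b")))
expr <- round(expr, 4)

write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
            "inst/extdata/synthetic_expression.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = colnames(expr),
                       condition = rep(c("A", "B"), c(n1, n2))),
            "inst/extdata/synthetic_labels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
writeLines(c("KIN1\tKIN1a,KIN1b\tfirst_pc",
             "TF2\tTF2a,TF2b\trepresentative"),
           "inst/extdata/synthetic_mapping.tsv")
cat("wrote inst/extdata files\n")
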