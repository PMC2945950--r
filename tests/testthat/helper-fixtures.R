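# Writes a small synthetic pathway + expression dataset to `dir`.
# The pathway has 12 nodes with all edge types, a v-structure, and two
# multi-gene nodes (one first_pc, one representative).
make_demo_files <- function(dir, seed = 42L, n1 = 25L, n2 = 30L, shift = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pw <- data.frame(
    source = c("LIG", "RTK", "SCAF", "ADAP", "KIN1", "GTP", "KIN2",
               "MAPK", "MAPK", "PHOS", "TF1", "TF2"),
    target = c("RTK", "ADAP", "ADAP", "GTP", "GTP", "MAPK", "MAPK",
               "TF1", "TF2", "RTK", "OUT", "OUT"),
    type = c("directed", "phospho_plus", "directed", "directed",
             "inhibition", "directed", "phospho_plus", "directed",
             "directed", "phospho_minus", "undirected", "directed"),
    orientation = c(rep("", 10), "forward", ""))
  pw_file <- file.path(dir, "pathway.tsv")
  writeLines(c("# synthetic demo pathway",
               apply(pw, 1L, paste, collapse = "\t")), pw_file)

  dag <- pathGGM::build_dag(pathGGM::pathway_edges(pw))
  moral <- pathGGM::moralize(dag)
  nodes <- igraph::V(moral)$name
  p <- length(nodes)
  set.seed(seed)
  K <- diag(1, p)
  A <- igraph::as_adjacency_matrix(moral, sparse = FALSE) > 0
  up <- which(upper.tri(K) & A, arr.ind = TRUE)
  vals <- stats::runif(nrow(up), 0.2, 0.35) * sample(c(-1, 1), nrow(up), TRUE)
  K[up] <- vals; K[up[, c(2, 1)]] <- vals
  diag(K) <- rowSums(abs(K)) - abs(diag(K)) + 1
  sigma <- chol2inv(chol(K))
  dimnames(sigma) <- list(nodes, nodes)

  mu2 <- rep(0, p); mu2[match(c("MAPK", "TF1"), nodes)] <- shift
  x1 <- MASS::mvrnorm(n1, rep(0, p), sigma)
  x2 <- MASS::mvrnorm(n2, mu2, sigma)
  expr <- t(rbind(x1, x2))            # nodes x samples
  rownames(expr) <- nodes
  colnames(expr) <- sprintf("s%02d", seq_len(n1 + n2))

  # expand the two multi-gene nodes into member rows
  mk_members <- function(v, labels) {
    m <- rbind(v + stats::rnorm(length(v), sd = 0.3),
               v + stats::rnorm(length(v), sd = 0.3))
    rownames(m) <- labels
    m
  }
  expr <- rbind(expr[setdiff(nodes, c("KIN1", "TF2")), , drop = FALSE],
                mk_members(expr["KIN1", ], c("KIN1a", "KIN1b")),
                mk_members(expr["TF2", ], c("TF2a", "TF2b")))
  expr <- round(expr, 4)

  expr_file <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE),
                     expr_file, sep = "\t", quote = FALSE, row.names = FALSE)
  labels_file <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(sample = colnames(expr),
                                condition = rep(c("A", "B"), c(n1, n2))),
                     labels_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map_file <- file.path(dir, "mapping.tsv")
  writeLines(c("KIN1\tKIN1a,KIN1b\tfirst_pc",
               "TF2\tTF2a,TF2b\trepresentative"), map_file)
  list(pathway = pw_file, expression = expr_file, labels = labels_file,
       mapping = map_file, sigma = sigma, moral = moral)
}
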