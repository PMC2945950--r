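# Independent brute-force oracles for the graph and model operations.
# These deliberately avoid the package's own code paths (and igraph's
# chordality/clique routines) so agreement is a genuine cross-check.

adj_of <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  nms <- igraph::V(g)$name
  dimnames(A) <- list(nms, nms)
  A
}

# all maximal cliques by subset enumeration (p <= 12)
oracle_max_cliques <- function(g) {
  A <- adj_of(g)
  nms <- rownames(A)
  p <- length(nms)
  subsets <- list()
  for (mask in seq_len(2^p) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    if (!length(idx)) next
    sub <- A[idx, idx, drop = FALSE]
    if (all(sub[upper.tri(sub)])) subsets[[length(subsets) + 1L]] <- idx
  }
  keep <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))
  cl <- lapply(subsets[keep], function(s) sort(nms[s]))
  cl[order(vapply(cl, paste, character(1), collapse = ","))]
}

# chordal iff no vertex subset of size >= 4 induces a cycle
oracle_is_chordal <- function(g) {
  A <- adj_of(g)
  p <- nrow(A)
  if (p < 4L) return(TRUE)
  for (mask in seq_len(2^p) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    k <- length(idx)
    if (k < 4L) next
    sub <- A[idx, idx, drop = FALSE]
    deg <- rowSums(sub)
    if (all(deg == 2L)) {
      # connected 2-regular induced subgraph = induced (chordless) cycle
      seen <- 1L; frontier <- 1L
      while (length(frontier)) {
        nxt <- setdiff(which(apply(sub[frontier, , drop = FALSE], 2L, any)), seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      if (length(seen) == k) return(FALSE)
    }
  }
  TRUE
}

# definitional moral edge set: skeleton plus all parent pairs
oracle_moral_edges <- function(dag) {
  nms <- igraph::V(dag)$name
  ed <- igraph::as_edgelist(dag, names = TRUE)
  pairs <- apply(ed, 1L, function(e) paste(sort(e), collapse = "|"))
  for (v in nms) {
    pa <- ed[ed[, 2L] == v, 1L]
    if (length(pa) >= 2L) {
      cmb <- utils::combn(sort(pa), 2L)
      pairs <- c(pairs, apply(cmb, 2L, paste, collapse = "|"))
    }
  }
  sort(unique(pairs))
}

edge_keys <- function(g) {
  ed <- igraph::as_edgelist(g, names = TRUE)
  if (!nrow(ed)) return(character(0))
  sort(apply(ed, 1L, function(e) paste(sort(e), collapse = "|")))
}

# random DAG with edges following a random vertex permutation
random_dag <- function(p, prob = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- sprintf("v%02d", seq_len(p))
  ord <- sample(nms)
  from <- character(0); to <- character(0)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (stats::runif(1) < prob) { from <- c(from, ord[i]); to <- c(to, ord[j]) }
  }
  igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                directed = TRUE,
                                vertices = data.frame(name = sort(nms)))
}

random_ugraph <- function(p, prob = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(p, prob)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(p))
  g
}

random_pd <- function(p, seed = NULL, names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(p * p), p)
  S <- crossprod(M) / p + diag(p)
  if (!is.null(names)) dimnames(S) <- list(names, names)
  S
}

complete_graph_named <- function(labels) {
  g <- igraph::make_full_graph(length(labels))
  igraph::V(g)$name <- labels
  g
}

empty_graph_named <- function(labels) {
  igraph::make_empty_graph(length(labels), directed = FALSE) |>
    igraph::set_vertex_attr("name", value = labels)
}
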