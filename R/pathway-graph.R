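#' Read a pathway edge list
#'
#' Reads a tab-separated pathway description with columns
#' `source`, `target`, `type` and an optional fourth column `orientation`
#' (`forward` or `backward`, consulted only for `undirected` rows).
#' Lines starting with `#` are comments.  Recognised edge types are
#' `directed`, `undirected`, `inhibition`, `phospho_plus` and
#' `phospho_minus`; inhibition and (de)phosphorylation edges are treated
#' downstream as plain directed edges.
#'
#' @param file Path to the edge-list file.
#' @return A data frame of class `pathway_edges` with columns
#'   `source`, `target`, `type`, `orientation`.
#' @seealso [build_dag()]
#' @export
read_pathway <- function(file) {
  raw <- utils::read.delim(file, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 3L)
    stop("pathway file '", file, "' must have at least 3 tab-separated columns")
  edges <- data.frame(source = trimws(raw[[1L]]), target = trimws(raw[[2L]]),
                      type = trimws(raw[[3L]]),
                      orientation = if (ncol(raw) >= 4L) trimws(raw[[4L]]) else NA_character_,
                      stringsAsFactors = FALSE)
  edges$orientation[edges$orientation == ""] <- NA_character_
  pathway_edges(edges)
}

#' Construct a pathway edge list
#'
#' Validates and classes a data frame of typed pathway edges.
#'
#' @param edges Data frame with columns `source`, `target`, `type` and
#'   optionally `orientation`.
#' @return The validated `pathway_edges` data frame.
#' @export
pathway_edges <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$orientation)) edges$orientation <- NA_character_
  edges$orientation[!is.na(edges$orientation) & edges$orientation == ""] <-
    NA_character_
  types <- c("directed", "undirected", "inhibition", "phospho_plus", "phospho_minus")
  bad <- setdiff(unique(edges$type), types)
  if (length(bad))
    stop("unknown edge type(s): ", paste(bad, collapse = ", "))
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target)))
    stop("empty node labels are not allowed")
  loops <- edges$source == edges$target
  if (any(loops))
    stop("self-loop entries are not allowed: ",
         paste(unique(edges$source[loops]), collapse = ", "))
  ok_or <- is.na(edges$orientation) | edges$orientation %in% c("forward", "backward")
  if (!all(ok_or)) stop("orientation must be 'forward' or 'backward'")
  class(edges) <- c("pathway_edges", "data.frame")
  edges
}

#' Orient a pathway into a directed acyclic graph
#'
#' Applies the conversion rules: inhibition and (de)phosphorylation entries
#' become plain directed edges; undirected entries are oriented by their
#' `orientation` hint when present, otherwise by the chosen policy.  The
#' result is checked to be acyclic.
#'
#' @param edges A `pathway_edges` data frame (see [read_pathway()]).
#' @param orientation Policy for undirected entries without a hint:
#'   `"lexicographic"` orients from the lexicographically smaller to the
#'   larger label; `"strict"` raises an error instead.
#' @return A directed acyclic [igraph::graph] whose vertices are sorted by
#'   label.
#' @export
build_dag <- function(edges, orientation = c("lexicographic", "strict")) {
  orientation <- match.arg(orientation)
  edges <- pathway_edges(edges)
  from <- edges$source
  to <- edges$target
  und <- edges$type == "undirected"
  hinted <- und & !is.na(edges$orientation)
  back <- hinted & edges$orientation == "backward"
  tmp <- from[back]; from[back] <- to[back]; to[back] <- tmp
  open <- und & !hinted
  if (any(open)) {
    if (orientation == "strict")
      stop("undirected edge(s) without orientation hint under strict policy: ",
           paste(paste(from[open], to[open], sep = "--"), collapse = ", "))
    flip <- open & from > to
    tmp <- from[flip]; from[flip] <- to[flip]; to[flip] <- tmp
  }
  # deduplicate identical directed pairs; opposite pairs survive and are
  # reported below as a 2-cycle
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  from <- from[keep]; to <- to[keep]
  verts <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = TRUE,
                                     vertices = data.frame(name = verts))
  if (!igraph::is_dag(g)) {
    cyc <- .find_directed_cycle(g)
    stop("pathway orientation is cyclic: ", paste(cyc, collapse = " -> "))
  }
  g
}

# first directed cycle found by depth-first search, as a label sequence
.find_directed_cycle <- function(g) {
  adj <- igraph::as_adj_list(g, mode = "out")
  n <- igraph::vcount(g)
  state <- integer(n)  # 0 new, 1 on stack, 2 done
  parent <- integer(n)
  cyc <- NULL
  visit <- function(v) {
    state[v] <<- 1L
    for (w in as.integer(adj[[v]])) {
      if (!is.null(cyc)) return(invisible())
      if (state[w] == 1L) {
        path <- w
        u <- v
        while (u != w) { path <- c(path, u); u <- parent[u] }
        cyc <<- rev(c(path, w))
      } else if (state[w] == 0L) {
        parent[w] <<- v
        visit(w)
      }
    }
    state[v] <<- 2L
  }
  for (v in seq_len(n)) {
    if (state[v] == 0L && is.null(cyc)) { parent[v] <- 0L; visit(v) }
  }
  igraph::V(g)$name[cyc]
}

#' Moralize a directed acyclic graph
#'
#' Adds an undirected edge between every pair of vertices sharing a child
#' ("marrying" the parents) and drops edge directions, yielding the moral
#' graph on which the graphical Gaussian models are defined.
#'
#' @param dag A directed acyclic [igraph::graph], e.g. from [build_dag()].
#' @return An undirected [igraph::graph] with the same vertex set.
#' @export
moralize <- function(dag) {
  if (!igraph::is_directed(dag) || !igraph::is_dag(dag))
    stop("moralize() requires a directed acyclic graph")
  extra_from <- character(0); extra_to <- character(0)
  nms <- igraph::V(dag)$name
  parents <- igraph::as_adj_list(dag, mode = "in")
  for (v in seq_along(parents)) {
    pa <- sort(nms[as.integer(parents[[v]])])
    if (length(pa) >= 2L) {
      prs <- utils::combn(pa, 2L)
      extra_from <- c(extra_from, prs[1L, ])
      extra_to <- c(extra_to, prs[2L, ])
    }
  }
  ed <- igraph::as_edgelist(dag, names = TRUE)
  ed <- rbind(ed, cbind(extra_from, extra_to))
  g <- igraph::graph_from_data_frame(data.frame(from = ed[, 1L], to = ed[, 2L]),
                                     directed = FALSE,
                                     vertices = data.frame(name = nms))
  igraph::simplify(g)
}

#' Triangulate an undirected graph
#'
#' Adds fill-in edges so that every cycle of length four or more has a
#' chord, making the graph chordal and hence decomposable into cliques.
#' Uses deterministic greedy minimum-fill elimination: at each step the
#' vertex whose elimination requires the fewest fill edges is removed (ties
#' broken by label order) and its remaining neighbours are completed.
#' Already-chordal graphs are returned with an identical edge set.
#'
#' @param graph An undirected [igraph::graph].
#' @return An undirected chordal [igraph::graph] containing all input edges.
#'   Fill edges are recorded in the graph attributes `fill_edges` (two-column
#'   character matrix) and `triangulation` (heuristic tag).
#' @export
triangulate <- function(graph) {
  if (igraph::is_directed(graph)) stop("triangulate() requires an undirected graph")
  nms <- igraph::V(graph)$name
  p <- length(nms)
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  dimnames(adj) <- list(nms, nms)
  work <- adj
  alive <- rep(TRUE, p)
  fill_from <- character(0); fill_to <- character(0)
  for (step in seq_len(p)) {
    rem <- which(alive)
    fills <- vapply(rem, function(v) {
      nb <- rem[work[v, rem]]
      if (length(nb) < 2L) return(0L)
      sub <- work[nb, nb, drop = FALSE]
      as.integer((length(nb) * (length(nb) - 1L)) / 2L - sum(sub[upper.tri(sub)]))
    }, integer(1))
    cand <- rem[fills == min(fills)]
    v <- cand[order(nms[cand])][1L]
    nb <- rem[work[v, rem]]
    if (length(nb) >= 2L) {
      for (a in seq_along(nb)) for (b in seq_len(a - 1L)) {
        i <- nb[a]; j <- nb[b]
        if (!work[i, j]) {
          work[i, j] <- work[j, i] <- TRUE
          lo <- min(nms[i], nms[j]); hi <- max(nms[i], nms[j])
          fill_from <- c(fill_from, lo); fill_to <- c(fill_to, hi)
        }
      }
    }
    alive[v] <- FALSE
  }
  ed <- igraph::as_edgelist(graph, names = TRUE)
  ed <- rbind(ed, cbind(fill_from, fill_to))
  out <- igraph::graph_from_data_frame(
    data.frame(from = ed[, 1L], to = ed[, 2L]), directed = FALSE,
    vertices = data.frame(name = nms))
  out <- igraph::simplify(out)
  out <- igraph::set_graph_attr(out, "triangulation", "greedy-min-fill")
  igraph::set_graph_attr(out, "fill_edges",
                         matrix(c(fill_from, fill_to), ncol = 2L))
}

#' Test whether an undirected graph is triangulated (chordal)
#'
#' A graph is triangulated when every cycle of length at least four has two
#' non-consecutive adjacent vertices; this is equivalent to decomposability.
#'
#' @param graph An undirected [igraph::graph].
#' @return `TRUE` or `FALSE`.
#' @export
is_triangulated <- function(graph) {
  if (igraph::is_directed(graph)) stop("is_triangulated() requires an undirected graph")
  isTRUE(igraph::is_chordal(graph)$chordal)
}

#' Maximal cliques of an undirected graph
#'
#' Enumerates the maximal complete subgraphs, the unit at which the
#' two-sample tests are localized.  Each clique is returned as a sorted
#' character vector of vertex labels; cliques are ordered lexicographically
#' so results are reproducible.
#'
#' @param graph An undirected [igraph::graph].
#' @return A list of character vectors, one per maximal clique.  Isolated
#'   vertices appear as singleton cliques, so every vertex is covered.
#' @export
graph_cliques <- function(graph) {
  if (igraph::is_directed(graph)) stop("graph_cliques() requires an undirected graph")
  cl <- igraph::max_cliques(graph)
  cl <- lapply(cl, function(v) sort(igraph::V(graph)$name[as.integer(v)]))
  keys <- vapply(cl, paste, character(1), collapse = ",")
  cl[order(keys)]
}

# maximum cardinality search: a perfect elimination ordering for chordal
# graphs, used to order cliques so separators satisfy the running
# intersection property.  Returns vertex ranks (1 = first numbered).
.mcs_rank <- function(graph) {
  nms <- igraph::V(graph)$name
  p <- length(nms)
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  rank <- integer(p)
  weight <- integer(p)
  numbered <- rep(FALSE, p)
  for (k in seq_len(p)) {
    cand <- which(!numbered)
    cand <- cand[weight[cand] == max(weight[cand])]
    v <- cand[order(nms[cand])][1L]
    rank[v] <- k
    numbered[v] <- TRUE
    nb <- which(adj[v, ] & !numbered)
    weight[nb] <- weight[nb] + 1L
  }
  stats::setNames(rank, nms)
}

# cliques of a chordal graph in running-intersection order, with separators
.rip_cliques <- function(graph) {
  rk <- .mcs_rank(graph)
  cl <- graph_cliques(graph)
  hi <- vapply(cl, function(cc) max(rk[cc]), numeric(1))
  cl <- cl[order(hi)]
  seps <- vector("list", length(cl))
  seen <- character(0)
  for (j in seq_along(cl)) {
    seps[[j]] <- intersect(cl[[j]], seen)
    seen <- union(seen, cl[[j]])
  }
  list(cliques = cl, separators = seps)
}

#' Write a graph as a tab-separated edge list
#'
#' @param graph An [igraph::graph].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_edgelist <- function(graph, file) {
  ed <- igraph::as_edgelist(graph, names = TRUE)
  df <- data.frame(source = ed[, 1L], target = ed[, 2L])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
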