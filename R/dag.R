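#' Directed acyclic graph over labelled nodes
#'
#' Constructs a DAG from a node universe and a directed edge set.  The edge
#' set is stored dually: as parallel `from`/`to` character vectors (the
#' "edge matrix" of two lists that the perturbation operators manipulate)
#' and, implicitly, as the ordered-pair set they induce.  The constructor
#' enforces the structural invariants: known labels only, no self-loops, no
#' duplicate edges, at most one orientation per node pair, and acyclicity.
#'
#' @param nodes character vector of distinct node labels (the node universe;
#'   isolated nodes are allowed and preserved).
#' @param from,to parallel character vectors; `from[i] -> to[i]` is the i-th
#'   directed edge.
#' @return An object of class `dag` with fields `nodes`, `from`, `to`.
#' @examples
#' g <- dag(c("A", "B", "C"), from = c("A", "B"), to = c("B", "C"))
#' is_acyclic(g)
#' leaf_nodes(g)
#' @export
dag <- function(nodes, from = character(), to = character()) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a DAG needs at least one node")
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("from/to lists differ in length")
  unknown <- setdiff(c(from, to), nodes)
  if (length(unknown)) {
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  }
  if (any(from == to)) stop("self-loops are not allowed")
  key <- edge_keys(from, to)
  if (anyDuplicated(key)) stop("duplicate edges")
  if (any(key %in% edge_keys(to, from))) {
    stop("both orientations of the same edge are present")
  }
  g <- new_dag(nodes, from, to)
  if (!is_acyclic(g)) stop("edge set contains a directed cycle")
  g
}

# unvalidated constructor; used internally where invariants are guaranteed
# (or deliberately relaxed mid cycle-repair)
new_dag <- function(nodes, from, to) {
  structure(list(nodes = nodes, from = from, to = to), class = "dag")
}

edge_keys <- function(from, to) paste(from, to, sep = "\x1f")

#' @export
print.dag <- function(x, ...) {
  cat(sprintf("dag: %d nodes, %d edges\n", length(x$nodes), length(x$from)))
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (length(x$from)) {
    cat("  edges:", paste(x$from, "->", x$to, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Edge matrix of a DAG
#'
#' Returns the edge set as the two parallel lists the perturbation operators
#' work on.
#'
#' @param g a [dag].
#' @return A list with character vectors `from` and `to`.
#' @export
edge_lists <- function(g) list(from = g$from, to = g$to)

#' Number of edges in a DAG
#' @param g a [dag].
#' @export
n_edges <- function(g) length(g$from)

#' @rdname dag_queries
#' @export
has_edge <- function(g, from, to) any(g$from == from & g$to == to)

#' Parent, child, leaf and root queries
#'
#' `parents()`/`children()` return the direct neighbours of a node;
#' `leaf_nodes()` the nodes without children, `root_nodes()` the nodes
#' without parents (a fully isolated node is both).  `max_in_degree()` and
#' `max_out_degree()` return the largest parent and child counts over all
#' nodes (0 for an edgeless graph).
#'
#' @param g a [dag].
#' @param x a node label.
#' @param from,to node labels.
#' @name dag_queries
NULL

#' @rdname dag_queries
#' @export
parents <- function(g, x) {
  stop_unknown_node(g, x)
  g$from[g$to == x]
}

#' @rdname dag_queries
#' @export
children <- function(g, x) {
  stop_unknown_node(g, x)
  g$to[g$from == x]
}

#' @rdname dag_queries
#' @export
leaf_nodes <- function(g) g$nodes[!(g$nodes %in% g$from)]

#' @rdname dag_queries
#' @export
root_nodes <- function(g) g$nodes[!(g$nodes %in% g$to)]

#' @rdname dag_queries
#' @export
max_in_degree <- function(g) {
  if (!length(g$to)) return(0L)
  max(tabulate(match(g$to, g$nodes), nbins = length(g$nodes)))
}

#' @rdname dag_queries
#' @export
max_out_degree <- function(g) {
  if (!length(g$from)) return(0L)
  max(tabulate(match(g$from, g$nodes), nbins = length(g$nodes)))
}

stop_unknown_node <- function(g, x) {
  if (length(x) != 1L || !(x %in% g$nodes)) {
    stop("unknown node: ", paste(x, collapse = ", "))
  }
  invisible(x)
}

#' Topological sort and acyclicity test
#'
#' `topo_sort()` returns a topological order of the nodes (Kahn's
#' algorithm; ties broken by node-universe order so the result is
#' deterministic) or `NULL` if the edge set contains a directed cycle.
#' `is_acyclic()` is the corresponding predicate.  Both are pure.
#'
#' @param g a [dag] (possibly holding a non-acyclic edge set, as arises
#'   transiently inside cycle repair).
#' @return `topo_sort()`: character vector of node labels, or `NULL`;
#'   `is_acyclic()`: logical flag.
#' @export
topo_sort <- function(g) {
  n <- length(g$nodes)
  fi <- match(g$from, g$nodes)
  ti <- match(g$to, g$nodes)
  indeg <- tabulate(ti, nbins = n)
  adj <- split(ti, factor(fi, levels = seq_len(n)))
  avail <- which(indeg == 0L)
  ord <- integer(0)
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    ord <- c(ord, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(ord) < n) NULL else g$nodes[ord]
}

#' @rdname topo_sort
#' @export
is_acyclic <- function(g) !is.null(topo_sort(g))

# Is there a directed path src ~> dst?  Depth-first search over children.
path_exists <- function(g, src, dst) {
  if (src == dst) return(TRUE)
  n <- length(g$nodes)
  fi <- match(g$from, g$nodes)
  ti <- match(g$to, g$nodes)
  adj <- split(ti, factor(fi, levels = seq_len(n)))
  si <- match(src, g$nodes)
  di <- match(dst, g$nodes)
  seen <- logical(n)
  seen[si] <- TRUE
  stack <- si
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (w == di) return(TRUE)
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  FALSE
}

#' Incremental cycle query for a candidate edge
#'
#' Would adding the edge `from -> to` to `g` close a directed cycle?
#' Answered by a reachability search from `to` back to `from`, so the full
#' graph need not be re-sorted; the search loop relies on this form.
#'
#' @param g a [dag].
#' @param from,to node labels of the candidate edge.
#' @export
would_create_cycle <- function(g, from, to) {
  stop_unknown_node(g, from)
  stop_unknown_node(g, to)
  path_exists(g, to, from)
}

drop_edge <- function(g, from, to) {
  keep <- !(g$from == from & g$to == to)
  new_dag(g$nodes, g$from[keep], g$to[keep])
}

add_edge_unchecked <- function(g, from, to) {
  new_dag(g$nodes, c(g$from, from), c(g$to, to))
}

#' Structure equality
#'
#' Two DAGs are equal when they have the same node universe and the same
#' directed edge set (order of storage is irrelevant).
#'
#' @param a,b [dag] objects.
#' @export
dag_equal <- function(a, b) {
  setequal(a$nodes, b$nodes) &&
    length(a$from) == length(b$from) &&
    setequal(edge_keys(a$from, a$to), edge_keys(b$from, b$to))
}

#' Structural Hamming distance between two DAGs
#'
#' Counts the unordered node pairs adjacent in exactly one of the two
#' graphs (missing/extra edges) plus the pairs adjacent in both but with
#' opposite orientation (each reversal counts one).  Symmetric, zero iff
#' the edge sets are identical.
#'
#' @param a,b [dag] objects over the same node set.
#' @return Integer distance.
#' @export
shd_pair <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) stop("node sets differ")
  ua <- edge_keys(pmin(a$from, a$to), pmax(a$from, a$to))
  ub <- edge_keys(pmin(b$from, b$to), pmax(b$from, b$to))
  da <- edge_keys(a$from, a$to)
  db <- edge_keys(b$from, b$to)
  only_a <- sum(!(ua %in% ub))
  only_b <- sum(!(ub %in% ua))
  reversed <- sum(!(da[ua %in% ub] %in% db))
  as.integer(only_a + only_b + reversed)
}

#' Random DAG by permutation-and-Bernoulli sampling
#'
#' Draws a uniform random permutation of the nodes as a topological order
#' and includes each forward pair independently with probability
#' `edge_prob`.  Every draw is acyclic by construction.  The default
#' `edge_prob = 2/(n-1)` gives an expected `n` edges, a sparsity typical of
#' benchmark networks.  Randomness comes from the R session RNG, so results
#' are reproducible under `set.seed()`.
#'
#' @param nodes character vector of node labels.
#' @param edge_prob inclusion probability for each forward pair, in
#'   `[0, 1]`.
#' @return A [dag].
#' @export
random_dag <- function(nodes, edge_prob = NULL) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n < 1L) stop("a DAG needs at least one node")
  if (is.null(edge_prob)) edge_prob <- if (n > 1L) min(1, 2 / (n - 1)) else 0
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  perm <- sample(nodes)
  if (n == 1L || edge_prob == 0) return(dag(nodes))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < edge_prob
  dag(nodes, from = perm[idx[keep, 1L]], to = perm[idx[keep, 2L]])
}

#' Convenience constructors for common shapes
#'
#' `empty_dag()` has no edges; `chain_dag()` links the given labels in
#' order (`x1 -> x2 -> ...`); `star_dag()` points a hub at every other
#' node (out-degree `n - 1` at the hub); `collider_dag()` points every
#' other node at the hub (in-degree `n - 1` at the hub).
#'
#' @param nodes character vector of node labels; for `star_dag()` and
#'   `collider_dag()` the first label is the hub.
#' @name dag_shapes
#' @export
empty_dag <- function(nodes) dag(nodes)

#' @rdname dag_shapes
#' @export
chain_dag <- function(nodes) {
  n <- length(nodes)
  if (n < 2L) return(dag(nodes))
  dag(nodes, from = nodes[-n], to = nodes[-1L])
}

#' @rdname dag_shapes
#' @export
star_dag <- function(nodes) {
  if (length(nodes) < 2L) return(dag(nodes))
  dag(nodes, from = rep(nodes[1L], length(nodes) - 1L), to = nodes[-1L])
}

#' @rdname dag_shapes
#' @export
collider_dag <- function(nodes) {
  if (length(nodes) < 2L) return(dag(nodes))
  dag(nodes, from = nodes[-1L], to = rep(nodes[1L], length(nodes) - 1L))
}

#' The Asia benchmark structure
#'
#' The eight-node, eight-edge chest-clinic network widely used to
#' illustrate structure-learning operators: smoking influences lung cancer
#' and bronchitis, a trip to Asia influences tuberculosis, either lung
#' cancer or tuberculosis produce a positive X-ray and dyspnoea.
#'
#' @return A [dag] with nodes A, S, T, L, B, E, X, D and edges
#'   `A->T, S->L, S->B, T->E, L->E, E->X, E->D, B->D`.
#' @export
asia_dag <- function() {
  dag(c("A", "S", "T", "L", "B", "E", "X", "D"),
      from = c("A", "S", "S", "T", "L", "E", "E", "B"),
      to   = c("T", "L", "B", "E", "E", "X", "D", "D"))
}
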