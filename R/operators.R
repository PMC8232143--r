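#' Basic edge operations with cycle-repair conventions
#'
#' Applies one Add, Delete or Reverse operation under the repair
#' conventions used by the perturbation step:
#'
#' * **Add** `from -> to`: the pair must be non-adjacent; if the new edge
#'   would close a cycle, the opposite edge `to -> from` is added instead
#'   (which is always safe: if paths existed in both directions the graph
#'   would already be cyclic).
#' * **Delete** removes an existing edge (never creates cycles).
#' * **Reverse** `from -> to`: if the reversed edge would close a cycle
#'   the operation is dropped and the graph returned unchanged.
#'
#' @param g a [dag].
#' @param kind `"add"`, `"delete"` or `"reverse"`.
#' @param from,to node labels.
#' @return The resulting [dag] (always acyclic).
#' @export
apply_basic <- function(g, kind, from, to) {
  stop_unknown_node(g, from)
  stop_unknown_node(g, to)
  if (from == to) stop("self-loops are not allowed")
  switch(
    match.arg(kind, c("add", "delete", "reverse")),
    add = {
      if (has_edge(g, from, to) || has_edge(g, to, from)) {
        stop("cannot add: ", from, " and ", to, " are already adjacent")
      }
      if (would_create_cycle(g, from, to)) {
        add_edge_unchecked(g, to, from)
      } else {
        add_edge_unchecked(g, from, to)
      }
    },
    delete = {
      if (!has_edge(g, from, to)) stop("no such edge: ", from, " -> ", to)
      drop_edge(g, from, to)
    },
    reverse = {
      if (!has_edge(g, from, to)) stop("no such edge: ", from, " -> ", to)
      g2 <- drop_edge(g, from, to)
      if (path_exists(g2, from, to)) g else add_edge_unchecked(g2, to, from)
    }
  )
}

#' Leaf and Root operators
#'
#' `leaf_op()` converts a node into a leaf by reversing every edge whose
#' from-node is `x`; `root_op()` converts it into a root by reversing
#' every edge whose to-node is `x`.  Both preserve acyclicity: after the
#' operation a cycle through `x` would need an outgoing (resp. incoming)
#' edge at `x`, and there is none.  A node that already is a leaf (resp.
#' root) is returned unchanged, and applying the operator twice equals
#' applying it once.  The structural effect, measured in SHD against the
#' input, lies in `[1, u]` for Leaf (`u` = max out-degree) and `[1, k]`
#' for Root (`k` = max in-degree) whenever the node is eligible.
#'
#' @param g a [dag].
#' @param x a node label.
#' @return The resulting [dag].
#' @export
leaf_op <- function(g, x) {
  stop_unknown_node(g, x)
  out <- g$from == x
  if (!any(out)) return(g)
  from <- g$from
  to <- g$to
  from[out] <- g$to[out]
  to[out] <- x
  new_dag(g$nodes, from, to)
}

#' @rdname leaf_op
#' @export
root_op <- function(g, x) {
  stop_unknown_node(g, x)
  incoming <- g$to == x
  if (!any(incoming)) return(g)
  from <- g$from
  to <- g$to
  to[incoming] <- g$from[incoming]
  from[incoming] <- x
  new_dag(g$nodes, from, to)
}

# Is exchanging the incoming edges p -> x and q -> y (into p -> y, q -> x)
# neither meaningless nor illegal?  Screens the four failure categories:
# shared parent (no-op), parent/child coincidence (self-loop), creation of
# a bidirectional pair, duplication of an existing edge.
swap_pair_ok <- function(g, x, y, p, q) {
  p != q && p != y && q != x &&
    !has_edge(g, p, y) && !has_edge(g, y, p) &&
    !has_edge(g, q, x) && !has_edge(g, x, q)
}

swap_legal_pairs <- function(g, x, y) {
  px <- parents(g, x)
  py <- parents(g, y)
  out <- matrix(character(0), ncol = 2,
                dimnames = list(NULL, c("parent_x", "parent_y")))
  for (p in px) {
    for (q in py) {
      if (swap_pair_ok(g, x, y, p, q)) out <- rbind(out, c(p, q))
    }
  }
  out
}

#' Swap partner whitelist
#'
#' For a node `x` with at least one parent, lists the nodes `y` (also with
#' at least one parent) such that exchanging one incoming edge of `x` with
#' one incoming edge of `y` passes the legality screen (see
#' [swap_pair_ok][swap_op] categories).  An empty result signals that Swap
#' is inapplicable at `x`.
#'
#' @param g a [dag].
#' @param x a node label.
#' @return Character vector of candidate partner nodes, in node-universe
#'   order.
#' @export
swap_candidates <- function(g, x) {
  stop_unknown_node(g, x)
  if (!length(parents(g, x))) return(character(0))
  cand <- setdiff(g$nodes[g$nodes %in% g$to], x)
  cand[vapply(cand,
              function(y) nrow(swap_legal_pairs(g, x, y)) > 0L,
              logical(1))]
}

#' Swap operator
#'
#' Exchanges the to-nodes of one incoming edge of each of `x` and `y`:
#' edges `P -> x` and `Q -> y` become `P -> y` and `Q -> x`.  When either
#' node has several parents the exchanged edge is sampled uniformly among
#' the legal pairs (or fixed via `parent_x`/`parent_y`).  If the exchange
#' closes a cycle, the cycle is repaired by applying the Leaf operator to
#' the from-node of each cycle-generating new edge, in random order, until
#' the graph is acyclic; Leaf (rather than Root) is used because reversing
#' outgoing edges explores the larger neighbourhood.  The structural
#' effect is at least 4 SHD units (two adjacencies lost, two gained) and
#' at most `4 + 2u` where `u` is the max out-degree.
#'
#' @param g a [dag].
#' @param x,y node labels; `y` must come from [swap_candidates()].
#' @param parent_x,parent_y optional: pin the exchanged incoming edges
#'   instead of sampling them.
#' @return The resulting [dag] (acyclic).
#' @export
swap_op <- function(g, x, y, parent_x = NULL, parent_y = NULL) {
  stop_unknown_node(g, x)
  stop_unknown_node(g, y)
  if (x == y) stop("swap needs two distinct nodes")
  pairs <- swap_legal_pairs(g, x, y)
  if (!is.null(parent_x) || !is.null(parent_y)) {
    keep <- rep(TRUE, nrow(pairs))
    if (!is.null(parent_x)) keep <- keep & pairs[, 1L] == parent_x
    if (!is.null(parent_y)) keep <- keep & pairs[, 2L] == parent_y
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no legal swap between ", x, " and ", y)
  k <- if (nrow(pairs) > 1L) sample.int(nrow(pairs), 1L) else 1L
  p <- pairs[k, 1L]
  q <- pairs[k, 2L]

  g2 <- drop_edge(drop_edge(g, p, x), q, y)
  g2 <- add_edge_unchecked(add_edge_unchecked(g2, p, y), q, x)
  new_edges <- list(c(p, y), c(q, x))

  guard <- 0L
  while (!is_acyclic(g2)) {
    guard <- guard + 1L
    if (guard > 2L * length(g$nodes)) stop("cycle repair did not converge")
    repaired <- FALSE
    for (k in sample(length(new_edges))) {
      e <- new_edges[[k]]
      if (!has_edge(g2, e[1L], e[2L])) next
      # the edge generates a cycle iff the rest of the graph carries a
      # path from its to-node back to its from-node
      if (path_exists(drop_edge(g2, e[1L], e[2L]), e[2L], e[1L])) {
        g2 <- leaf_op(g2, e[1L])
        repaired <- TRUE
        break
      }
    }
    if (!repaired) stop("cyclic state with no repairable swap edge")
  }
  g2
}

#' Momentum compound perturbation
#'
#' Applies `m` randomly chosen structure operators: each iteration samples
#' a node uniformly and one of Leaf, Root, Swap uniformly, then applies it
#' (Swap additionally samples its partner from the whitelist).  Draws for
#' which the sampled operator is inapplicable at the sampled node (for
#' example Leaf at a node that is already a leaf) are resampled up to ten
#' times, after which the iteration is skipped; the number of skipped
#' iterations is attached as attribute `"momentum_skipped"`.  The result
#' is always acyclic.
#'
#' @param g a [dag].
#' @param m number of operator applications (>= 0).
#' @return The perturbed [dag].
#' @export
momentum <- function(g, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 0L) stop("m must be a nonnegative integer")
  skipped <- 0L
  for (i in seq_len(m)) {
    done <- FALSE
    for (attempt in 1:10) {
      x <- sample(g$nodes, 1L)
      op <- sample(c("leaf", "root", "swap"), 1L)
      if (op == "leaf") {
        if (any(g$from == x)) {
          g <- leaf_op(g, x)
          done <- TRUE
        }
      } else if (op == "root") {
        if (any(g$to == x)) {
          g <- root_op(g, x)
          done <- TRUE
        }
      } else {
        cand <- swap_candidates(g, x)
        if (length(cand)) {
          y <- if (length(cand) > 1L) sample(cand, 1L) else cand
          g <- swap_op(g, x, y)
          done <- TRUE
        }
      }
      if (done) break
    }
    if (!done) skipped <- skipped + 1L
  }
  attr(g, "momentum_skipped") <- skipped
  g
}

nonadjacent_ordered_pairs <- function(g) {
  n <- length(g$nodes)
  if (n < 2L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  all_from <- rep(g$nodes, each = n)
  all_to <- rep(g$nodes, times = n)
  keep <- all_from != all_to
  all_from <- all_from[keep]
  all_to <- all_to[keep]
  keys <- edge_keys(all_from, all_to)
  present <- c(edge_keys(g$from, g$to), edge_keys(g$to, g$from))
  keep <- !(keys %in% present)
  cbind(from = all_from[keep], to = all_to[keep])
}

#' Basic perturbation step
#'
#' Applies `pf` basic operations, each with a uniformly sampled kind
#' (Add/Delete/Reverse) and a uniformly sampled legal operand, under the
#' [apply_basic()] repair conventions (cycle-closing Adds are reversed,
#' cycle-closing Reverses dropped).  Kinds inapplicable in the current
#' graph (Delete/Reverse on an edgeless graph, Add on a complete one) are
#' resampled up to ten times, then the step is skipped.
#'
#' @param g a [dag].
#' @param pf number of basic operations (>= 0).
#' @return The perturbed [dag] (acyclic).
#' @export
perturb_basic <- function(g, pf) {
  pf <- as.integer(pf)
  if (is.na(pf) || pf < 0L) stop("pf must be a nonnegative integer")
  for (i in seq_len(pf)) {
    for (attempt in 1:10) {
      kind <- sample(c("add", "delete", "reverse"), 1L)
      if (kind == "add") {
        cand <- nonadjacent_ordered_pairs(g)
        if (!nrow(cand)) next
        k <- sample.int(nrow(cand), 1L)
        g <- apply_basic(g, "add", cand[k, 1L], cand[k, 2L])
      } else {
        if (!length(g$from)) next
        k <- sample.int(length(g$from), 1L)
        g <- apply_basic(g, kind, g$from[k], g$to[k])
      }
      break
    }
  }
  g
}

# One sampled application of a named operator, constrained to operands
# where it has an effect (mirrors how single-operator impact is measured:
# eligible nodes/edges are drawn, so Add/Delete/Reverse always move the
# structure by exactly one unit).
apply_effect_op <- function(g, op) {
  switch(
    op,
    add = {
      cand <- nonadjacent_ordered_pairs(g)
      if (!nrow(cand)) return(g)
      k <- sample.int(nrow(cand), 1L)
      apply_basic(g, "add", cand[k, 1L], cand[k, 2L])
    },
    delete = {
      if (!length(g$from)) return(g)
      k <- sample.int(length(g$from), 1L)
      apply_basic(g, "delete", g$from[k], g$to[k])
    },
    reverse = {
      if (!length(g$from)) return(g)
      for (k in sample.int(length(g$from))) {
        g2 <- apply_basic(g, "reverse", g$from[k], g$to[k])
        if (!dag_equal(g2, g)) return(g2)
      }
      g
    },
    leaf = {
      eligible <- setdiff(g$nodes, leaf_nodes(g))
      if (!length(eligible)) return(g)
      x <- if (length(eligible) > 1L) sample(eligible, 1L) else eligible
      leaf_op(g, x)
    },
    root = {
      eligible <- setdiff(g$nodes, root_nodes(g))
      if (!length(eligible)) return(g)
      x <- if (length(eligible) > 1L) sample(eligible, 1L) else eligible
      root_op(g, x)
    },
    swap = {
      with_parents <- g$nodes[g$nodes %in% g$to]
      for (attempt in 1:10) {
        if (!length(with_parents)) break
        x <- if (length(with_parents) > 1L) sample(with_parents, 1L) else
          with_parents
        cand <- swap_candidates(g, x)
        if (length(cand)) {
          y <- if (length(cand) > 1L) sample(cand, 1L) else cand
          return(swap_op(g, x, y))
        }
      }
      g
    },
    stop("unknown operator: ", op)
  )
}

#' Operator-effect trials
#'
#' Measures the structural impact of an operator: each trial starts from a
#' fresh copy of `true_dag`, applies the operator `m` times (for
#' `op = "momentum"`, one Momentum draw of `m` objects), and records the
#' SHD between the perturbed copy and the original.  Reports the maximum,
#' minimum and mean SHD over all trials — the summary used to compare the
#' reach of Add/Delete/Reverse (always exactly 1 per application), Leaf
#' (up to the max out-degree), Root (up to the max in-degree) and Swap
#' (at least 4 per application).
#'
#' @param true_dag the reference [dag].
#' @param op one of `"add"`, `"delete"`, `"reverse"`, `"leaf"`, `"root"`,
#'   `"swap"`, `"momentum"`.
#' @param trials number of trials (conventionally `5 * n`).
#' @param m applications per trial (objects for Momentum); non-integer
#'   values are rounded.
#' @return A list with `max`, `min`, `mean` and the per-trial `shd`
#'   vector.
#' @export
effect_trials <- function(true_dag, op, trials = 5L * length(true_dag$nodes),
                          m = 1L) {
  op <- match.arg(op, c("add", "delete", "reverse", "leaf", "root",
                        "swap", "momentum"))
  trials <- as.integer(trials)
  if (is.na(trials) || trials < 1L) stop("trials must be >= 1")
  m <- as.integer(round(m))
  shds <- integer(trials)
  for (t in seq_len(trials)) {
    g <- true_dag
    if (op == "momentum") {
      g <- momentum(g, m)
    } else {
      for (i in seq_len(m)) g <- apply_effect_op(g, op)
    }
    shds[t] <- shd_pair(g, true_dag)
  }
  list(max = max(shds), min = min(shds), mean = mean(shds), shd = shds)
}

#' Parse an operator spec string
#'
#' Turns a spec such as `"leaf(n/2)"`, `"momentum(2*n)"` or `"swap"` into
#' the operator name and a rounded object count, with `n` bound to the
#' number of nodes.  A bare operator name means one application.
#'
#' @param spec character scalar.
#' @param n number of nodes substituted for `n` in the count expression.
#' @return List with `op` and integer `m`.
#' @export
parse_op_spec <- function(spec, n) {
  spec <- trimws(spec)
  m <- regmatches(spec, regexec("^([a-z]+)\\s*(\\((.*)\\))?$", spec))[[1L]]
  if (!length(m) || !nzchar(m[2L])) stop("cannot parse operator spec: ", spec)
  op <- m[2L]
  count <- if (nzchar(m[4L])) {
    expr <- gsub("round", "", m[4L], fixed = TRUE)
    if (!grepl("^[0-9n+*/(). -]*$", expr)) {
      stop("count expression may only use numbers, n, and + - * / ( ): ", spec)
    }
    val <- eval(parse(text = m[4L])[[1L]], envir = list(n = n, round = round))
    as.integer(round(val))
  } else {
    1L
  }
  if (is.na(count) || count < 0L) stop("invalid object count in spec: ", spec)
  list(op = op, m = count)
}
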