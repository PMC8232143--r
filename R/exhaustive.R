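#' Exhaustive DAG enumeration (small n)
#'
#' Enumerates every DAG on `n` labelled nodes (2 to 6).  The enumeration
#' assigns one of none / forward / backward to each unordered node pair
#' and keeps the acyclic assignments, so each DAG is produced exactly
#' once; the counts are 25, 543, 29281 and 3781503 for n = 3..6.
#' `enumerate_dag_masks()` returns compact bitmask encodings (bit
#' `(i-1)*n + j - 1` set means edge `i -> j` in label order);
#' `enumerate_dags()` materialises [dag] objects and is meant for
#' `n <= 4`.
#'
#' @param n number of nodes (2 to 6; `enumerate_dags()` caps at 5).
#' @param labels node labels (defaults to `LETTERS[1:n]`).
#' @return `enumerate_dag_masks()`: a numeric vector of masks;
#'   `enumerate_dags()`: a list of [dag] objects.
#' @export
enumerate_dag_masks <- function(n) enumerate_dag_masks_cpp(as.integer(n))

#' @rdname enumerate_dag_masks
#' @export
enumerate_dags <- function(n, labels = LETTERS[seq_len(n)]) {
  if (n > 5) stop("materialising all DAGs is supported up to n = 5")
  lapply(enumerate_dag_masks(n), mask_to_dag, labels = labels)
}

#' Convert between DAGs and bitmask encodings
#'
#' @param mask a numeric bitmask as produced by [enumerate_dag_masks()].
#' @param labels node labels, in the order defining the bit layout.
#' @param g a [dag] whose node order defines the bit layout.
#' @export
mask_to_dag <- function(mask, labels) {
  n <- length(labels)
  from <- character(0)
  to <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && bit_set(mask, (i - 1L) * n + j - 1L)) {
        from <- c(from, labels[i])
        to <- c(to, labels[j])
      }
    }
  }
  new_dag(labels, from, to)
}

#' @rdname mask_to_dag
#' @export
dag_to_mask <- function(g) {
  n <- length(g$nodes)
  if (n > 6) stop("bitmask encoding supports up to 6 nodes")
  fi <- match(g$from, g$nodes) - 1L
  ti <- match(g$to, g$nodes) - 1L
  sum(2^(fi * n + ti))
}

bit_set <- function(mask, bit) (mask %/% 2^bit) %% 2 >= 1

#' Exhaustive acyclicity verification for Leaf and Root
#'
#' Applies the Leaf and the Root operator to every node of every DAG on
#' `n` labelled nodes and counts results that fail the acyclicity test.
#' Both counts are provably zero — converting a node into a leaf (root)
#' leaves it without outgoing (incoming) edges, so no cycle can pass
#' through it, and any cycle avoiding it existed before — and this sweep
#' verifies the implementation exhaustively.  Runs at bitmask level in
#' compiled code; see [leaf_mask_equiv()] for tying it to the R-level
#' operators.
#'
#' @param n number of nodes (2 to 6).
#' @return A list with `n_dags`, `leaf_violations`, `root_violations`.
#' @export
check_leaf_root_acyclicity <- function(n) leaf_root_exhaustive(as.integer(n))

#' Equivalence of R-level and bitmask-level operators
#'
#' For each supplied mask and every node, checks that [leaf_op()] and
#' [root_op()] produce exactly the structure the compiled bitmask kernel
#' produces.  Used to tie the exhaustive compiled sweep of
#' [check_leaf_root_acyclicity()] to the R implementation.
#'
#' @param masks numeric bitmasks (see [enumerate_dag_masks()]).
#' @param n number of nodes the masks are defined over.
#' @return `TRUE`, or stops at the first disagreement.
#' @export
leaf_mask_equiv <- function(masks, n) {
  labels <- paste0("v", seq_len(n))
  for (mask in masks) {
    g <- mask_to_dag(mask, labels)
    for (x in seq_len(n)) {
      if (dag_to_mask(leaf_op(g, labels[x])) !=
          leaf_mask_cpp(mask, n, x - 1L)) {
        stop("leaf_op disagrees with bitmask kernel at mask ", mask,
             ", node ", labels[x])
      }
      if (dag_to_mask(root_op(g, labels[x])) !=
          root_mask_cpp(mask, n, x - 1L)) {
        stop("root_op disagrees with bitmask kernel at mask ", mask,
             ", node ", labels[x])
      }
    }
  }
  TRUE
}
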