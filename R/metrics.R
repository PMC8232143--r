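#' Confusion counts of a learned structure against the truth
#'
#' Directed-edge matching: TP counts learned edges present (same
#' orientation) in the true graph, FP learned edges absent from it, FN
#' true edges absent from the learned graph; TN counts unordered node
#' pairs non-adjacent in both graphs.  A reversed edge therefore
#' contributes one FP and one FN.  Also reports `a`, the true edge count,
#' and `i = V(V-1)/2 - a`, the number of direct independencies in the
#' true graph.
#'
#' @param learned,truth [dag] objects over the same node set.
#' @return A list with `tp`, `tn`, `fp`, `fn`, `a`, `i`.
#' @export
confusion <- function(learned, truth) {
  if (!setequal(learned$nodes, truth$nodes)) stop("node sets differ")
  dl <- edge_keys(learned$from, learned$to)
  dt <- edge_keys(truth$from, truth$to)
  ul <- edge_keys(pmin(learned$from, learned$to),
                  pmax(learned$from, learned$to))
  ut <- edge_keys(pmin(truth$from, truth$to), pmax(truth$from, truth$to))
  v <- length(truth$nodes)
  a <- length(dt)
  pairs <- v * (v - 1) / 2
  list(
    tp = sum(dl %in% dt),
    tn = as.integer(pairs - length(union(ul, ut))),
    fp = sum(!(dl %in% dt)),
    fn = sum(!(dt %in% dl)),
    a = a,
    i = as.integer(pairs - a)
  )
}

#' Structural Hamming distance
#'
#' Missing edges + extra edges + incorrectly oriented edges between the
#' learned and the true graph; 0 indicates a perfect fit.
#'
#' @inheritParams confusion
#' @export
shd <- function(learned, truth) shd_pair(learned, truth)

#' Balanced scoring function
#'
#' `BSF = 0.5 * (TP/a + TN/i - FP/i - FN/a)` with the counts of
#' [confusion()].  1 for a perfect match, 0 for an empty learned graph,
#' and at most 1 always.  The nominal lower bound of -1 assumes
#' adjacency-based false positives; under the directed matching used here
#' a reversed true edge adds an FP on top of the `i` non-adjacent pairs,
#' so graphs with many reversals can score below -1.  Undefined when the
#' true graph is empty (`a = 0`) or complete (`i = 0`).
#'
#' @inheritParams confusion
#' @export
bsf <- function(learned, truth) {
  cc <- confusion(learned, truth)
  if (cc$a == 0L || cc$i == 0L) {
    stop("BSF is undefined for an empty or complete true graph")
  }
  0.5 * (cc$tp / cc$a + cc$tn / cc$i - cc$fp / cc$i - cc$fn / cc$a)
}
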