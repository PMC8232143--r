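#' Joint counts of a variable against a parent configuration
#'
#' Tallies `N(x, pi)`, the number of records in which the variable takes
#' state `x` while its parents jointly take configuration `pi`, over the
#' full cartesian grid of parent states (unobserved configurations get
#' zero counts).  Configurations are indexed with the first parent varying
#' fastest, parents taken in the canonical (dataset column) order.
#'
#' @param ds a [discrete_dataset].
#' @param var variable label.
#' @param parents character vector of parent labels (possibly empty).
#' @return A list: `counts` (matrix, states x configurations), `n_parent`
#'   (per-configuration totals `N(pi)`), `r` (cardinality of `var`), `q`
#'   (number of parent configurations; 1 for the empty set).
#' @export
count_table <- function(ds, var, parents = character()) {
  vi <- match(var, ds$vars)
  if (is.na(vi)) stop("unknown variable: ", var)
  if (var %in% parents) stop("variable cannot be its own parent: ", var)
  parents <- canonical_parents(ds, parents)
  pidx <- match(parents, ds$vars)
  r <- ds$card[[vi]]
  x <- ds$m[, vi]
  if (length(parents)) {
    pc <- ds$card[pidx]
    q <- prod(pc)
    cfg <- integer(nrow(ds$m))
    mult <- 1L
    for (j in seq_along(pidx)) {
      cfg <- cfg + (ds$m[, pidx[j]] - 1L) * mult
      mult <- mult * pc[j]
    }
    counts <- matrix(tabulate(x + r * cfg, nbins = r * q), nrow = r)
  } else {
    q <- 1L
    counts <- matrix(tabulate(x, nbins = r), nrow = r)
  }
  list(counts = counts, n_parent = colSums(counts), r = r, q = as.integer(q))
}

canonical_parents <- function(ds, parents) {
  if (!length(parents)) return(character(0))
  pidx <- match(parents, ds$vars)
  if (anyNA(pidx)) {
    stop("unknown parent(s): ", paste(parents[is.na(pidx)], collapse = ", "))
  }
  parents[order(pidx)]
}

#' Local-score cache
#'
#' A memoised map from (variable, sorted parent set) to its local BIC
#' value, the backbone of delta scoring: the decomposable score lets a
#' single-edge move be priced by recomputing at most two local terms.  The
#' cache also counts hits, misses and delta evaluations, which is how
#' search drivers are given comparable move-evaluation budgets.
#'
#' @return An environment of class `score_cache`.
#' @seealso [cache_stats()]
#' @export
score_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(hash = TRUE, parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  e$delta_evals <- 0
  class(e) <- "score_cache"
  e
}

#' @rdname score_cache
#' @param cache a [score_cache()].
#' @export
cache_stats <- function(cache) {
  list(size = length(ls(cache$map)), hits = cache$hits,
       misses = cache$misses, delta_evals = cache$delta_evals)
}

#' @export
print.score_cache <- function(x, ...) {
  s <- cache_stats(x)
  cat(sprintf("score_cache: %d entries, %d hits, %d misses, %g delta evals\n",
              s$size, s$hits, s$misses, s$delta_evals))
  invisible(x)
}

#' Local BIC of one variable given a parent set
#'
#' The decomposable BIC contribution of one node: the maximised
#' multinomial log-likelihood `sum N(x,pi) ln(N(x,pi)/N(pi))` minus the
#' complexity penalty `(ln N)/2 * (r - 1) * q`, where `r` is the variable's
#' cardinality and `q` the product of the parent cardinalities (1 for the
#' empty parent set).  Natural logarithms; `0 ln 0 = 0`; parent
#' configurations never observed contribute nothing to the likelihood but
#' are counted in `q`.
#'
#' @inheritParams count_table
#' @param cache optional [score_cache()]; cached values are reused keyed on
#'   the sorted parent set.
#' @return The local score (a negative number for any non-degenerate data).
#' @export
local_bic <- function(ds, var, parents = character(), cache = NULL) {
  parents <- canonical_parents(ds, parents)
  if (!is.null(cache)) {
    key <- paste(var, paste(parents, collapse = "\x1f"), sep = "\x1e")
    hit <- get0(key, envir = cache$map, inherits = FALSE)
    if (!is.null(hit)) {
      cache$hits <- cache$hits + 1L
      return(hit)
    }
  }
  n <- nrow(ds$m)
  if (n < 1L) stop("empty dataset")
  ct <- count_table(ds, var, parents)
  nz <- ct$counts > 0L
  denom <- rep(ct$n_parent, each = ct$r)
  ll <- sum(ct$counts[nz] * log(ct$counts[nz] / denom[nz]))
  penalty <- log(n) / 2 * (ct$r - 1L) * ct$q
  val <- ll - penalty
  if (!is.null(cache)) {
    assign(key, val, envir = cache$map)
    cache$misses <- cache$misses + 1L
  }
  val
}

#' BIC score of a DAG against a dataset
#'
#' The decomposable network score: the sum of [local_bic()] over every
#' node with its parent set in `g`.
#'
#' @param g a [dag] whose nodes are all dataset variables.
#' @param ds a [discrete_dataset].
#' @param cache optional [score_cache()].
#' @return The network BIC (natural-log scale; higher is better).
#' @export
bic_score <- function(g, ds, cache = NULL) {
  unknown <- setdiff(g$nodes, ds$vars)
  if (length(unknown)) {
    stop("graph nodes missing from dataset: ", paste(unknown, collapse = ", "))
  }
  sum(vapply(g$nodes,
             function(x) local_bic(ds, x, parents(g, x), cache),
             numeric(1)))
}

#' Score difference of a single-edge move
#'
#' Prices a legal Add/Delete/Reverse move by touching only the local
#' scores it can change: Add and Delete re-score the child node, Reverse
#' re-scores both endpoints.  Equal to
#' `bic_score(after) - bic_score(before)` exactly (up to floating-point
#' roundoff).
#'
#' @param g a [dag].
#' @param move a list with elements `kind` (`"add"`, `"delete"` or
#'   `"reverse"`), `from`, `to`.
#' @param ds a [discrete_dataset].
#' @param cache optional [score_cache()]; its `delta_evals` counter is
#'   incremented per call.
#' @export
score_delta <- function(g, move, ds, cache = NULL) {
  f <- move$from
  t <- move$to
  if (f == t) stop("self-loop move")
  stop_unknown_node(g, f)
  stop_unknown_node(g, t)
  if (!is.null(cache)) cache$delta_evals <- cache$delta_evals + 1
  switch(
    match.arg(move$kind, c("add", "delete", "reverse")),
    add = {
      if (has_edge(g, f, t) || has_edge(g, t, f)) {
        stop("illegal add: ", f, " and ", t, " are already adjacent")
      }
      pa <- parents(g, t)
      local_bic(ds, t, c(pa, f), cache) - local_bic(ds, t, pa, cache)
    },
    delete = {
      if (!has_edge(g, f, t)) stop("no such edge: ", f, " -> ", t)
      pa <- parents(g, t)
      local_bic(ds, t, setdiff(pa, f), cache) - local_bic(ds, t, pa, cache)
    },
    reverse = {
      if (!has_edge(g, f, t)) stop("no such edge: ", f, " -> ", t)
      pa_t <- parents(g, t)
      pa_f <- parents(g, f)
      (local_bic(ds, t, setdiff(pa_t, f), cache) -
         local_bic(ds, t, pa_t, cache)) +
        (local_bic(ds, f, c(pa_f, t), cache) -
           local_bic(ds, f, pa_f, cache))
    }
  )
}
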