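#' Search configuration
#'
#' Collects the tunables of the iterated-local-search drivers.  Defaults
#' follow the method's standard tuning: stride array `{n/10, n/5, n/2, n}`
#' (rounded, at least 1, duplicates removed), Momentum object count
#' `mo = n`, `rs = 20` non-improving outer steps before Momentum, `rh = 5`
#' Momentum applications before a full restart.  `pf` is the basic
#' perturbation count used by plain ILSG, and `sr` its soft-restart
#' patience.  `max_iter` bounds the outer loop and `inner_iter` the ILSG
#' loop nested inside ILSM; `max_in_degree` optionally caps parent-set
#' sizes (unlimited by default); `tol` is the improvement tolerance.
#'
#' @param n_vars number of variables (used for the stride and Momentum
#'   defaults).
#' @param pf basic-perturbation count per ILSG iteration.
#' @param sr soft-restart patience for ILSG, in iterations (`Inf`
#'   disables).
#' @param stride nondecreasing vector of perturbation magnitudes.
#' @param mo Momentum object count.
#' @param rs non-improving outer iterations before Momentum fires.
#' @param rh Momentum applications (since the last best-score improvement)
#'   before a full restart.
#' @param max_iter outer iteration budget.
#' @param inner_iter ILSG iterations per outer ILSM step.
#' @param max_in_degree optional parent-count cap.
#' @param tol score-improvement tolerance.
#' @param seed optional integer seed; when set, [ilsg()]/[ilsm()] seed the
#'   session RNG on entry so runs are exactly reproducible.
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_vars,
                          pf = max(1L, as.integer(round(n_vars / 10))),
                          sr = 20L,
                          stride = unique(pmax(1L, as.integer(
                            round(n_vars * c(0.1, 0.2, 0.5, 1))))),
                          mo = n_vars,
                          rs = 20L,
                          rh = 5L,
                          max_iter = 100L,
                          inner_iter = 5L,
                          max_in_degree = Inf,
                          tol = 1e-9,
                          seed = NULL) {
  stopifnot(pf >= 0, sr > 0, mo >= 0, rs > 0, rh > 0,
            max_iter >= 0, inner_iter >= 0, tol >= 0)
  if (!length(stride) || any(diff(stride) < 0)) {
    stop("stride must be a nonempty nondecreasing vector")
  }
  structure(list(n_vars = n_vars, pf = pf, sr = sr, stride = stride,
                 mo = mo, rs = rs, rh = rh, max_iter = max_iter,
                 inner_iter = inner_iter, max_in_degree = max_in_degree,
                 tol = tol, seed = seed),
            class = "search_config")
}

# all legal Add/Delete/Reverse moves, ordered (kind, from, to) so that
# best-improvement tie-breaking is deterministic
enumerate_moves <- function(g, max_in_degree = Inf) {
  indeg <- tabulate(match(g$to, g$nodes), nbins = length(g$nodes))
  names(indeg) <- g$nodes
  adds <- nonadjacent_ordered_pairs(g)
  if (nrow(adds)) {
    ok <- vapply(seq_len(nrow(adds)), function(k) {
      indeg[[adds[k, 2L]]] < max_in_degree &&
        !would_create_cycle(g, adds[k, 1L], adds[k, 2L])
    }, logical(1))
    adds <- adds[ok, , drop = FALSE]
  }
  revs_ok <- logical(length(g$from))
  if (length(g$from)) {
    revs_ok <- vapply(seq_along(g$from), function(k) {
      indeg[[g$from[k]]] < max_in_degree &&
        !path_exists(drop_edge(g, g$from[k], g$to[k]), g$from[k], g$to[k])
    }, logical(1))
  }
  moves <- rbind(
    if (nrow(adds)) data.frame(kind = "add", from = adds[, 1L],
                               to = adds[, 2L], stringsAsFactors = FALSE),
    if (length(g$from)) data.frame(kind = "delete", from = g$from,
                                   to = g$to, stringsAsFactors = FALSE),
    if (any(revs_ok)) data.frame(kind = "reverse", from = g$from[revs_ok],
                                 to = g$to[revs_ok], stringsAsFactors = FALSE)
  )
  if (is.null(moves)) {
    return(data.frame(kind = character(0), from = character(0),
                      to = character(0)))
  }
  moves[order(moves$kind, moves$from, moves$to), , drop = FALSE]
}

apply_move <- function(g, move) {
  switch(move$kind,
         add = add_edge_unchecked(g, move$from, move$to),
         delete = drop_edge(g, move$from, move$to),
         reverse = add_edge_unchecked(drop_edge(g, move$from, move$to),
                                      move$to, move$from),
         stop("unknown move kind"))
}

#' Greedy hill climbing over the DAG space
#'
#' Best-improvement (steepest-ascent) local search over the
#' Add/Delete/Reverse neighbourhood, priced with [score_delta()]: at each
#' step every legal move is evaluated and the best one applied, until no
#' move improves the score by more than `tol`.  Ties are broken by the
#' lexicographic (kind, from, to) order of moves, making the trajectory
#' deterministic.  The returned graph is a local optimum: every single
#' basic move has delta `<= tol`.
#'
#' @param start a [dag] to start from.
#' @param ds a [discrete_dataset] covering the graph's nodes.
#' @param cache optional [score_cache()] (created if missing); shared
#'   caches make repeated climbs cheap and keep an evaluation count.
#' @param max_in_degree optional parent-count cap.
#' @param tol improvement tolerance.
#' @return The locally optimal [dag].
#' @export
hill_climb <- function(start, ds, cache = NULL, max_in_degree = Inf,
                       tol = 1e-9) {
  if (is.null(cache)) cache <- score_cache()
  g <- start
  repeat {
    moves <- enumerate_moves(g, max_in_degree)
    if (!nrow(moves)) break
    deltas <- vapply(seq_len(nrow(moves)), function(k) {
      score_delta(g, as.list(moves[k, ]), ds, cache)
    }, numeric(1))
    best <- which.max(deltas)
    if (deltas[best] <= tol) break
    g <- apply_move(g, as.list(moves[best, ]))
  }
  g
}

new_search_result <- function(best, score, trace, evals, algorithm) {
  structure(list(best = best, score = score, trace = trace, evals = evals,
                 algorithm = algorithm),
            class = "bn_search")
}

#' @export
print.bn_search <- function(x, ...) {
  cat(sprintf("%s search result: BIC %.4f, %d edges, %g move evaluations\n",
              x$algorithm, x$score, n_edges(x$best), x$evals))
  invisible(x)
}

trace_row <- function(iter, best_score, current_score, event) {
  data.frame(iter = iter, best_score = best_score,
             current_score = current_score, event = event,
             stringsAsFactors = FALSE)
}

#' Iterated local search over the DAG space (ILSG)
#'
#' The basic iterated-local-search driver: starting from a hill-climbed
#' random (or given) structure, each iteration perturbs the incumbent
#' with `pf` basic operations, re-optimises by [hill_climb()], and keeps
#' the better of the two; the best structure ever seen is tracked
#' separately and returned.  After `sr` consecutive iterations without
#' improving the best score, the incumbent is re-randomised (soft
#' restart) while the best-so-far is kept.
#'
#' @param ds a [discrete_dataset].
#' @param config a [search_config()].
#' @param start optional starting [dag]; a random DAG is drawn otherwise.
#' @param cache optional [score_cache()].
#' @return A `bn_search` result: `best` (the best DAG), `score` (its BIC,
#'   recomputed from scratch), `trace` (per-iteration best/current scores
#'   and events), `evals` (cumulative delta evaluations in the cache).
#' @export
ilsg <- function(ds, config, start = NULL, cache = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(cache)) cache <- score_cache()
  g <- if (is.null(start)) random_dag(ds$vars) else start
  g <- hill_climb(g, ds, cache, config$max_in_degree, config$tol)
  g_score <- bic_score(g, ds, cache)
  best <- g
  best_score <- g_score
  trace <- trace_row(0L, best_score, g_score, "init")
  nonimp <- 0L
  for (it in seq_len(config$max_iter)) {
    gp <- perturb_basic(g, config$pf)
    gp <- hill_climb(gp, ds, cache, config$max_in_degree, config$tol)
    s <- bic_score(gp, ds, cache)
    if (s > g_score + config$tol) {
      g <- gp
      g_score <- s
    }
    event <- "no-improve"
    if (s > best_score + config$tol) {
      best <- gp
      best_score <- s
      nonimp <- 0L
      event <- "improve"
    } else {
      nonimp <- nonimp + 1L
    }
    if (nonimp >= config$sr) {
      g <- random_dag(ds$vars)
      g_score <- bic_score(g, ds, cache)
      nonimp <- 0L
      event <- "soft-restart"
    }
    trace <- rbind(trace, trace_row(it, best_score, g_score, event))
  }
  new_search_result(best, bic_score(best, ds), trace,
                    cache$delta_evals, "ILSG")
}

#' Iterated local search with Momentum (ILSM)
#'
#' The full driver: the outer loop repeatedly runs a short [ilsg()] from
#' the incumbent, using the current stride entry as the perturbation
#' magnitude.  After `rs` consecutive outer iterations without improving
#' the best score, the incumbent is hit with a [momentum()] perturbation
#' of `mo` objects and the stride advances one position (capped at its
#' last entry) — perturbation strength grows as the search stagnates.
#' After `rh` Momentum applications without a new best, the search
#' restarts from a fresh random DAG and the stride resets.  The best
#' structure over the whole run is returned.
#'
#' @inheritParams ilsg
#' @return A `bn_search` result (see [ilsg()]).
#' @export
ilsm <- function(ds, config, cache = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(cache)) cache <- score_cache()
  inner_cfg <- config
  inner_cfg$seed <- NULL
  inner_cfg$max_iter <- config$inner_iter
  inner_cfg$sr <- Inf

  g <- random_dag(ds$vars)
  g <- hill_climb(g, ds, cache, config$max_in_degree, config$tol)
  g_score <- bic_score(g, ds, cache)
  best <- g
  best_score <- g_score
  trace <- trace_row(0L, best_score, g_score, "init")
  stride_idx <- 1L
  nonimp <- 0L
  mom_count <- 0L
  for (it in seq_len(config$max_iter)) {
    inner_cfg$pf <- config$stride[stride_idx]
    inner <- ilsg(ds, inner_cfg, start = g, cache = cache)
    gp <- inner$best
    s <- bic_score(gp, ds, cache)
    if (s > g_score + config$tol) {
      g <- gp
      g_score <- s
    }
    event <- "no-improve"
    if (s > best_score + config$tol) {
      best <- gp
      best_score <- s
      nonimp <- 0L
      mom_count <- 0L
      event <- "improve"
    } else {
      nonimp <- nonimp + 1L
    }
    if (nonimp >= config$rs) {
      g <- momentum(g, config$mo)
      attr(g, "momentum_skipped") <- NULL
      g_score <- bic_score(g, ds, cache)
      stride_idx <- min(stride_idx + 1L, length(config$stride))
      mom_count <- mom_count + 1L
      nonimp <- 0L
      event <- "momentum"
    }
    if (mom_count >= config$rh) {
      g <- random_dag(ds$vars)
      g_score <- bic_score(g, ds, cache)
      stride_idx <- 1L
      mom_count <- 0L
      nonimp <- 0L
      event <- "restart"
    }
    trace <- rbind(trace, trace_row(it, best_score, g_score, event))
  }
  new_search_result(best, bic_score(best, ds), trace,
                    cache$delta_evals, "ILSM")
}

#' Random-restart hill climbing under an evaluation budget
#'
#' The classical baseline: hill climbs from fresh random DAGs until the
#' cumulative number of move (delta) evaluations reaches `eval_budget`,
#' and returns the best local optimum found.  Sharing the evaluation
#' counter with the ILS drivers makes head-to-head comparisons
#' budget-fair.
#'
#' @param ds a [discrete_dataset].
#' @param eval_budget total delta-evaluation budget (at least one full
#'   climb always runs).
#' @param cache optional [score_cache()].
#' @param max_in_degree,tol as in [hill_climb()].
#' @return A `bn_search` result (see [ilsg()]).
#' @export
random_restart_hc <- function(ds, eval_budget, cache = NULL,
                              max_in_degree = Inf, tol = 1e-9) {
  if (is.null(cache)) cache <- score_cache()
  best <- NULL
  best_score <- -Inf
  trace <- NULL
  it <- 0L
  repeat {
    it <- it + 1L
    g <- hill_climb(random_dag(ds$vars), ds, cache, max_in_degree, tol)
    s <- bic_score(g, ds, cache)
    event <- "no-improve"
    if (s > best_score + tol) {
      best <- g
      best_score <- s
      event <- "improve"
    }
    trace <- rbind(trace, trace_row(it, best_score, s, event))
    if (cache$delta_evals >= eval_budget) break
  }
  new_search_result(best, bic_score(best, ds), trace,
                    cache$delta_evals, "restart-HC")
}
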