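#' Discrete Bayesian network with conditional probability tables
#'
#' Couples a [dag] with per-node state universes and conditional
#' probability tables.  Each CPT is a matrix with one row per state of the
#' node and one column per configuration of its parents; parents are taken
#' in canonical order (their order of appearance in the node universe) and
#' configurations are enumerated with the first parent varying fastest.
#' Every column must sum to 1.
#'
#' @param g a [dag].
#' @param levels named list: per node, the character vector of its state
#'   labels (cardinality = length).
#' @param cpts named list of CPT matrices as described above.
#' @return An object of class `bayesian_network` with fields `dag`,
#'   `levels`, `card`, `cpts`.
#' @export
bayesian_network <- function(g, levels, cpts) {
  if (!inherits(g, "dag")) stop("g must be a dag")
  missing_lv <- setdiff(g$nodes, names(levels))
  if (length(missing_lv)) {
    stop("missing levels for: ", paste(missing_lv, collapse = ", "))
  }
  missing_cpt <- setdiff(g$nodes, names(cpts))
  if (length(missing_cpt)) {
    stop("missing CPTs for: ", paste(missing_cpt, collapse = ", "))
  }
  card <- vapply(levels[g$nodes], length, 1L)
  for (x in g$nodes) {
    pa <- bn_parents(g, x)
    q <- if (length(pa)) prod(card[pa]) else 1L
    cpt <- cpts[[x]]
    if (!is.matrix(cpt) || nrow(cpt) != card[[x]] || ncol(cpt) != q) {
      stop("CPT for ", x, " must be ", card[[x]], " x ", q)
    }
    if (any(cpt < 0)) stop("CPT for ", x, " has negative entries")
    sums <- colSums(cpt)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("CPT column(s) for ", x, " do not sum to 1 (max deviation ",
           format(max(abs(sums - 1))), ")")
    }
  }
  structure(list(dag = g, levels = levels[g$nodes], card = card,
                 cpts = cpts[g$nodes]),
            class = "bayesian_network")
}

# parents in canonical (node-universe) order; fixes CPT column layout
bn_parents <- function(g, x) {
  pa <- parents(g, x)
  pa[order(match(pa, g$nodes))]
}

#' @export
print.bayesian_network <- function(x, ...) {
  cat(sprintf("bayesian_network: %d nodes, %d edges, %d parameters\n",
              length(x$dag$nodes), n_edges(x$dag),
              sum(vapply(x$dag$nodes, function(v) {
                (x$card[[v]] - 1L) * ncol(x$cpts[[v]])
              }, 1L))))
  invisible(x)
}

#' Ancestral sampling from a Bayesian network
#'
#' Generates `n` complete records by sampling the nodes in topological
#' order, each from its CPT column selected by the already-sampled parent
#' states — the direct operational reading of the factorisation
#' `P(X1..Xn) = prod_i P(Xi | Pa(Xi))`.  Randomness comes from the R
#' session RNG.
#'
#' @param bn a [bayesian_network()].
#' @param n number of records (>= 1).
#' @return A [discrete_dataset].
#' @export
sample_dataset <- function(bn, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  g <- bn$dag
  ord <- topo_sort(g)
  m <- matrix(0L, n, length(g$nodes), dimnames = list(NULL, g$nodes))
  for (x in ord) {
    cpt <- bn$cpts[[x]]
    pa <- bn_parents(g, x)
    r <- bn$card[[x]]
    if (!length(pa)) {
      m[, x] <- sample.int(r, n, replace = TRUE, prob = cpt[, 1L])
    } else {
      cfg <- rep(1L, n)
      mult <- 1L
      for (p in pa) {
        cfg <- cfg + (m[, p] - 1L) * mult
        mult <- mult * bn$card[[p]]
      }
      for (u in unique(cfg)) {
        rows <- which(cfg == u)
        m[rows, x] <- sample.int(r, length(rows), replace = TRUE,
                                 prob = cpt[, u])
      }
    }
  }
  new_discrete_dataset(m, g$nodes, bn$levels)
}

#' Random CPTs by symmetric Dirichlet draws
#'
#' Equips a structure with conditional distributions drawn independently
#' per parent configuration from a symmetric Dirichlet.  Small
#' `concentration` yields peaked distributions and large values approach
#' uniform rows.  Note that peaked rows do not guarantee detectable
#' parent-child dependence: rows are drawn independently, so two
#' configurations can peak on the same state and leave the parent
#' statistically invisible — use a fixed parameterisation (for example
#' [fixture_asia()]) when a dependence of known strength is needed.
#'
#' @param g a [dag].
#' @param cards integer scalar or named vector of cardinalities (default:
#'   all binary).
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param levels optional named list of state labels; defaults to
#'   `s1, s2, ...`.
#' @return A [bayesian_network()].
#' @export
random_cpts <- function(g, cards = 2L, concentration = 1, levels = NULL) {
  if (concentration <= 0) stop("concentration must be > 0")
  if (length(cards) == 1L) {
    cards <- setNames(rep(as.integer(cards), length(g$nodes)), g$nodes)
  }
  if (is.null(levels)) {
    levels <- lapply(g$nodes, function(x) paste0("s", seq_len(cards[[x]])))
    names(levels) <- g$nodes
  }
  cpts <- lapply(g$nodes, function(x) {
    r <- cards[[x]]
    pa <- bn_parents(g, x)
    q <- if (length(pa)) prod(cards[pa]) else 1L
    raw <- matrix(rgamma(r * q, shape = concentration, rate = 1), nrow = r)
    # guard against all-zero columns at tiny concentrations
    raw[, colSums(raw) == 0] <- 1
    sweep(raw, 2L, colSums(raw), "/")
  })
  names(cpts) <- g$nodes
  bayesian_network(g, levels, cpts)
}

#' The shipped Asia network fixture
#'
#' The [asia_dag()] structure (8 nodes, 8 edges, max in- and out-degree 2)
#' equipped with fixed, strongly dependent binary CPTs.  The parameter
#' values are this package's own synthetic choices — deliberately NOT the
#' published Asia parameterisation — so that no numeric claim rests on
#' values the package does not ship.  All variables are binary with
#' states `no`/`yes`.
#'
#' @return A [bayesian_network()].
#' @export
fixture_asia <- function() {
  g <- asia_dag()
  yn <- c("no", "yes")
  levels <- setNames(rep(list(yn), 8L), g$nodes)
  p <- function(yes) rbind(no = 1 - yes, yes = yes)
  cpts <- list(
    A = p(0.30),
    S = p(0.50),
    T = p(c(0.10, 0.80)),            # by A: no, yes
    L = p(c(0.10, 0.70)),            # by S
    B = p(c(0.20, 0.80)),            # by S
    E = p(c(0.05, 0.90, 0.90, 0.98)),  # by (T, L): nn, yn, ny, yy
    X = p(c(0.05, 0.95)),            # by E
    D = p(c(0.10, 0.60, 0.70, 0.90))   # by (B, E): nn, yn, ny, yy
  )
  bayesian_network(g, levels, cpts)
}
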