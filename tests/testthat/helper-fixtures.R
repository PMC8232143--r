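`%||%` <- function(a, b) if (is.null(a)) b else a

# test fixtures built in code: random datasets, random legal moves, and an
# independent monolithic BIC oracle (factor/table based, sharing no code
# with the package's tabulate/index-arithmetic scoring path)

rand_ds <- function(nvars, n, cards = sample(2:3, nvars, replace = TRUE)) {
  vars <- paste0("V", seq_len(nvars))
  m <- vapply(cards, function(r) sample.int(r, n, replace = TRUE),
              integer(n))
  colnames(m) <- vars
  levels <- lapply(cards, function(r) paste0("s", seq_len(r)))
  names(levels) <- vars
  discrete_dataset(m, levels = levels)
}

oracle_bic <- function(g, ds) {
  df <- as.data.frame(ds)
  for (v in ds$vars) df[[v]] <- factor(df[[v]], levels = ds$levels[[v]])
  n <- nrow(df)
  total <- 0
  for (x in g$nodes) {
    pa <- parents(g, x)
    if (length(pa)) {
      tab <- as.matrix(table(df[[x]], interaction(df[pa], drop = FALSE)))
    } else {
      tab <- matrix(table(df[[x]]), ncol = 1)
    }
    cs <- colSums(tab)
    pos <- tab > 0
    denom <- rep(cs, each = nrow(tab))
    ll <- sum(tab[pos] * log(tab[pos] / denom[pos]))
    q <- if (length(pa)) prod(vapply(ds$levels[pa], length, 1L)) else 1
    total <- total + ll - log(n) / 2 * (length(ds$levels[[x]]) - 1) * q
  }
  total
}

# every legal single-edge move on g (adds that close a cycle excluded,
# reverses that would close one excluded)
all_legal_moves <- function(g) {
  moves <- list()
  for (f in g$nodes) {
    for (t in g$nodes) {
      if (f == t) next
      if (!has_edge(g, f, t) && !has_edge(g, t, f) &&
          !would_create_cycle(g, f, t)) {
        moves[[length(moves) + 1L]] <- list(kind = "add", from = f, to = t)
      }
    }
  }
  for (k in seq_along(g$from)) {
    moves[[length(moves) + 1L]] <-
      list(kind = "delete", from = g$from[k], to = g$to[k])
  }
  for (k in seq_along(g$from)) {
    g2 <- apply_basic(g, "delete", g$from[k], g$to[k])
    if (!would_create_cycle(g2, g$to[k], g$from[k])) {
      moves[[length(moves) + 1L]] <-
        list(kind = "reverse", from = g$from[k], to = g$to[k])
    }
  }
  moves
}

apply_move_oracle <- function(g, move) {
  switch(move$kind,
         add = dag(g$nodes, c(g$from, move$from), c(g$to, move$to)),
         delete = {
           keep <- !(g$from == move$from & g$to == move$to)
           dag(g$nodes, g$from[keep], g$to[keep])
         },
         reverse = {
           keep <- !(g$from == move$from & g$to == move$to)
           dag(g$nodes, c(g$from[keep], move$to), c(g$to[keep], move$from))
         })
}

expect_valid_dag <- function(g) {
  # re-runs the full constructor validation (no self-loops, duplicates,
  # bidirectional pairs, cycles)
  expect_no_error(dag(g$nodes, g$from, g$to))
}
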