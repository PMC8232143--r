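test_that("count_table tallies exact joint counts", {
  ds <- discrete_dataset(data.frame(X = c("a", "a", "b", "b"),
                                    P = c("a", "a", "b", "b")))
  ct <- count_table(ds, "X")
  expect_equal(ct$counts, matrix(c(2L, 2L), nrow = 2))
  expect_identical(ct$q, 1L)
  expect_identical(sum(ct$counts), 4L)

  ct2 <- count_table(ds, "X", "P")
  expect_equal(ct2$counts, matrix(c(2L, 0L, 0L, 2L), nrow = 2))
  expect_identical(sum(ct2$counts), 4L)
  expect_equal(ct2$n_parent, c(2, 2))

  expect_error(count_table(ds, "X", "X"), "own parent")
  expect_error(count_table(ds, "Z"), "unknown variable")
})

test_that("count totals equal N on random datasets", {
  set.seed(5)
  for (i in 1:20) {
    ds <- rand_ds(4, sample(10:60, 1))
    v <- sample(ds$vars, 1)
    pa <- setdiff(ds$vars, v)[1:sample(0:2, 1)]
    ct <- count_table(ds, v, pa[!is.na(pa)])
    expect_identical(sum(ct$counts), nrow(ds$m))
  }
})

test_that("local BIC reproduces hand-evaluated values", {
  ds <- discrete_dataset(data.frame(X = c("a", "a", "b", "b")))
  # 4 ln(1/2) - (ln 4)/2 * 1 * 1 = -5 ln 2
  expect_equal(local_bic(ds, "X"), -5 * log(2), tolerance = 1e-12)

  ds2 <- discrete_dataset(data.frame(X = c("a", "a", "b", "b"),
                                     P = c("a", "a", "b", "b")))
  # perfect dependence: zero log-likelihood, penalty (ln 4)/2 * 1 * 2
  expect_equal(local_bic(ds2, "X", "P"), -2 * log(2), tolerance = 1e-12)
})

test_that("the complexity penalty grows with each added parent", {
  set.seed(8)
  ds <- rand_ds(4, 30, cards = c(2L, 3L, 2L, 3L))
  n <- nrow(ds$m)
  pen <- function(v, pa) {
    q <- if (length(pa)) prod(ds$card[pa]) else 1
    log(n) / 2 * (ds$card[[v]] - 1) * q
  }
  expect_gt(pen("V1", c("V2", "V3")), pen("V1", "V2"))
  expect_gt(pen("V1", "V2"), pen("V1", character(0)))
})

test_that("network BIC decomposes and matches the monolithic oracle", {
  set.seed(13)
  for (i in 1:500) {
    nv <- sample(3:5, 1)
    ds <- rand_ds(nv, 30)
    g <- random_dag(ds$vars, runif(1, 0.2, 0.8))
    direct <- bic_score(g, ds)
    local_sum <- sum(vapply(g$nodes,
                            function(x) local_bic(ds, x, parents(g, x)),
                            numeric(1)))
    expect_equal(direct, local_sum, tolerance = 1e-9)
    expect_equal(direct, oracle_bic(g, ds), tolerance = 1e-9)
  }
})

test_that("likelihood term is nonpositive and penalty positive", {
  set.seed(2)
  for (i in 1:20) {
    ds <- rand_ds(3, 25)
    v <- sample(ds$vars, 1)
    pa <- setdiff(ds$vars, v)[seq_len(sample(0:2, 1))]
    ct <- count_table(ds, v, pa)
    pos <- ct$counts > 0
    denom <- rep(ct$n_parent, each = ct$r)
    ll <- sum(ct$counts[pos] * log(ct$counts[pos] / denom[pos]))
    expect_lte(ll, 1e-12)
    expect_gt(log(nrow(ds$m)) / 2 * (ct$r - 1) * ct$q, 0)
  }
})

test_that("cached scores equal fresh recomputation, warm or cold", {
  set.seed(19)
  ds <- rand_ds(5, 100)
  g <- random_dag(ds$vars, 0.5)
  cache <- score_cache()
  cold <- bic_score(g, ds, cache)
  warm <- bic_score(g, ds, cache)
  fresh <- bic_score(g, ds)
  expect_equal(cold, warm, tolerance = 1e-9)
  expect_equal(cold, fresh, tolerance = 1e-9)
  s <- cache_stats(cache)
  expect_gt(s$hits, 0)
  expect_identical(s$size, s$misses)
  # every cached value equals recomputation
  for (key in ls(cache$map)) {
    parts <- strsplit(key, "\x1e")[[1]]
    pa <- if (length(parts) > 1 && nzchar(parts[2])) {
      strsplit(parts[2], "\x1f")[[1]]
    } else {
      character(0)
    }
    expect_equal(get(key, envir = cache$map), local_bic(ds, parts[1], pa),
                 tolerance = 1e-9)
  }
})

test_that("delta scoring equals full rescoring for every move kind", {
  set.seed(29)
  checked <- 0
  while (checked < 500) {
    ds <- rand_ds(4, 40)
    cache <- score_cache()  # caches are per-dataset
    g <- random_dag(ds$vars, runif(1, 0.2, 0.7))
    moves <- all_legal_moves(g)
    if (!length(moves)) next
    mv <- moves[[sample(length(moves), 1)]]
    delta <- score_delta(g, mv, ds, cache)
    full <- bic_score(apply_move_oracle(g, mv), ds) - bic_score(g, ds)
    expect_equal(delta, full, tolerance = 1e-9)
    checked <- checked + 1
  }
})

test_that("add/delete deltas cancel and reverse composes", {
  set.seed(31)
  ds <- rand_ds(4, 50)
  g <- dag(ds$vars, c("V1", "V2"), c("V2", "V3"))
  d_add <- score_delta(g, list(kind = "add", from = "V1", to = "V4"), ds)
  g2 <- apply_basic(g, "add", "V1", "V4")
  d_del <- score_delta(g2, list(kind = "delete", from = "V1", to = "V4"), ds)
  expect_equal(d_add + d_del, 0, tolerance = 1e-12)

  d_rev <- score_delta(g, list(kind = "reverse", from = "V1", to = "V2"), ds)
  g_del <- apply_basic(g, "delete", "V1", "V2")
  d_two <- score_delta(g, list(kind = "delete", from = "V1", to = "V2"), ds) +
    score_delta(g_del, list(kind = "add", from = "V2", to = "V1"), ds)
  expect_equal(d_rev, d_two, tolerance = 1e-12)

  expect_error(score_delta(g, list(kind = "delete", from = "V1", to = "V3"),
                           ds), "no such edge")
  expect_error(score_delta(g, list(kind = "add", from = "V1", to = "V2"),
                           ds), "illegal add")
})

test_that("BIC prefers the true edge under dependence, sparsity under independence", {
  chain <- dag(c("A", "B"), "A", "B")
  both <- empty_dag(c("A", "B"))
  yn <- c("no", "yes")
  # fixed, strongly dependent chain parameterisation
  bn_dep <- bayesian_network(
    chain, list(A = yn, B = yn),
    list(A = rbind(no = 0.5, yes = 0.5),
         B = rbind(no = c(0.9, 0.1), yes = c(0.1, 0.9))))
  dep_wins <- 0
  ind_wins <- 0
  for (seed in 1:100) {
    set.seed(seed)
    ds_dep <- sample_dataset(bn_dep, 5000)
    if (bic_score(chain, ds_dep) > bic_score(both, ds_dep)) {
      dep_wins <- dep_wins + 1
    }
    bn_ind <- random_cpts(both, concentration = 1)
    ds_ind <- sample_dataset(bn_ind, 5000)
    if (bic_score(both, ds_ind) >= bic_score(chain, ds_ind)) {
      ind_wins <- ind_wins + 1
    }
  }
  expect_equal(dep_wins, 100)
  expect_gte(ind_wins, 95)
})

test_that("BIC is score-equivalent across Markov-equivalent orientations", {
  set.seed(41)
  bn <- random_cpts(dag(c("A", "B"), "A", "B"), concentration = 0.3)
  ds <- sample_dataset(bn, 500)
  fwd <- bic_score(dag(c("A", "B"), "A", "B"), ds)
  bwd <- bic_score(dag(c("A", "B"), "B", "A"), ds)
  expect_equal(fwd, bwd, tolerance = 1e-9)
})
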