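#' Read and write BIF (Bayesian Interchange Format) networks
#'
#' Implements the JavaBayes-style `network` / `variable` / `probability`
#' grammar used by the common benchmark repositories.  Whitespace and tabs
#' are insignificant; `//` comments are stripped.  `write_bif()` followed
#' by `read_bif()` reproduces the network exactly (structure, state
#' labels, and CPT values).  Conditional tables may be given either as
#' per-configuration rows `( stateA, stateB ) p1, p2;` (configurations are
#' matched by their state labels, so row order is free) or as a flat
#' `table` listing (node states varying fastest, first parent next).
#' Probability rows that do not sum to 1 (tolerance 1e-6), variables used
#' before declaration, missing configurations and cyclic structures are
#' all reported as errors with the offending line number where available.
#'
#' @param bn a [bayesian_network()].
#' @param path file path.
#' @return `read_bif()` returns a [bayesian_network()]; `write_bif()`
#'   returns `path` invisibly.
#' @export
write_bif <- function(bn, path) {
  g <- bn$dag
  out <- c("network unknown {", "}")
  for (x in g$nodes) {
    out <- c(out,
             sprintf("variable %s {", x),
             sprintf("  type discrete [ %d ] { %s };",
                     bn$card[[x]], paste(bn$levels[[x]], collapse = ", ")),
             "}")
  }
  fmt <- function(v) paste(formatC(v, format = "g", digits = 15),
                           collapse = ", ")
  for (x in g$nodes) {
    pa <- bn_parents(g, x)
    cpt <- bn$cpts[[x]]
    if (!length(pa)) {
      out <- c(out,
               sprintf("probability ( %s ) {", x),
               sprintf("  table %s;", fmt(cpt[, 1L])),
               "}")
    } else {
      hdr <- sprintf("probability ( %s | %s ) {", x, paste(pa, collapse = ", "))
      cfgs <- expand.grid(lapply(pa, function(p) bn$levels[[p]]),
                          stringsAsFactors = FALSE)
      rows <- vapply(seq_len(nrow(cfgs)), function(u) {
        sprintf("  ( %s ) %s;",
                paste(unlist(cfgs[u, ]), collapse = ", "), fmt(cpt[, u]))
      }, "")
      out <- c(out, hdr, rows, "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}

# tokenizer keeping punctuation and line numbers
bif_tokenize <- function(lines) {
  lines <- sub("//.*$", "", lines)
  pat <- "[{}()\\[\\],;|]|[^[:space:]{}()\\[\\],;|]+"
  toks <- character(0)
  tok_line <- integer(0)
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], gregexpr(pat, lines[i], perl = TRUE))[[1L]]
    if (length(m)) {
      toks <- c(toks, m)
      tok_line <- c(tok_line, rep(i, length(m)))
    }
  }
  list(tok = toks, line = tok_line)
}

bif_error <- function(tk, pos, msg) {
  line <- if (pos >= 1L && pos <= length(tk$line)) tk$line[pos] else NA
  stop("BIF parse error", if (!is.na(line)) paste0(" (line ", line, ")"),
       ": ", msg, call. = FALSE)
}

# cursor helpers; cur is an environment holding the position
bif_peek <- function(tk, cur) {
  if (cur$i > length(tk$tok)) NA_character_ else tk$tok[cur$i]
}
bif_next <- function(tk, cur) {
  t <- bif_peek(tk, cur)
  cur$i <- cur$i + 1L
  t
}
bif_expect <- function(tk, cur, what) {
  t <- bif_next(tk, cur)
  if (is.na(t) || t != what) {
    bif_error(tk, cur$i - 1L, paste0("expected '", what, "'",
                                     if (!is.na(t)) paste0(" but saw '", t, "'")))
  }
  t
}
bif_skip_block <- function(tk, cur) {
  bif_expect(tk, cur, "{")
  depth <- 1L
  while (depth > 0L) {
    t <- bif_next(tk, cur)
    if (is.na(t)) bif_error(tk, cur$i - 1L, "unterminated block")
    if (t == "{") depth <- depth + 1L
    if (t == "}") depth <- depth - 1L
  }
}

bif_number <- function(tk, cur) {
  t <- bif_next(tk, cur)
  v <- suppressWarnings(as.numeric(t))
  if (is.na(v)) bif_error(tk, cur$i - 1L, paste0("expected a number, saw '", t, "'"))
  v
}

#' @rdname write_bif
#' @export
read_bif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tk <- bif_tokenize(lines)
  if (!length(tk$tok)) stop("BIF parse error: empty file: ", path)
  cur <- new.env()
  cur$i <- 1L

  levels <- list()
  prob <- list()   # per node: list(parents=, values= matrix)
  order_seen <- character(0)

  while (!is.na(bif_peek(tk, cur))) {
    kw <- bif_next(tk, cur)
    if (kw == "network") {
      bif_next(tk, cur)  # name
      bif_skip_block(tk, cur)
    } else if (kw == "variable") {
      name <- bif_next(tk, cur)
      bif_expect(tk, cur, "{")
      bif_expect(tk, cur, "type")
      bif_expect(tk, cur, "discrete")
      bif_expect(tk, cur, "[")
      nstates <- bif_number(tk, cur)
      bif_expect(tk, cur, "]")
      bif_expect(tk, cur, "{")
      states <- character(0)
      repeat {
        t <- bif_next(tk, cur)
        if (is.na(t)) bif_error(tk, cur$i - 1L, "unterminated state list")
        if (t == "}") break
        if (t != ",") states <- c(states, t)
      }
      if (length(states) != nstates) {
        bif_error(tk, cur$i - 1L,
                  paste0("variable ", name, " declares ", nstates,
                         " states but lists ", length(states)))
      }
      # consume optional ';' then any extra properties up to '}'
      repeat {
        t <- bif_next(tk, cur)
        if (is.na(t)) bif_error(tk, cur$i - 1L, "unterminated variable block")
        if (t == "}") break
      }
      levels[[name]] <- states
      order_seen <- c(order_seen, name)
    } else if (kw == "probability") {
      bif_expect(tk, cur, "(")
      child <- bif_next(tk, cur)
      pa <- character(0)
      t <- bif_next(tk, cur)
      if (!is.na(t) && t == "|") {
        repeat {
          t <- bif_next(tk, cur)
          if (is.na(t)) bif_error(tk, cur$i - 1L, "unterminated header")
          if (t == ")") break
          if (t != ",") pa <- c(pa, t)
        }
      } else if (is.na(t) || t != ")") {
        bif_error(tk, cur$i - 1L, "malformed probability header")
      }
      if (is.null(levels[[child]])) {
        bif_error(tk, cur$i - 1L, paste0("undeclared variable: ", child))
      }
      for (p in pa) {
        if (is.null(levels[[p]])) {
          bif_error(tk, cur$i - 1L, paste0("undeclared parent: ", p))
        }
      }
      r <- length(levels[[child]])
      pc <- vapply(levels[pa], length, 1L)
      q <- if (length(pa)) prod(pc) else 1L
      vals <- matrix(NA_real_, r, q)
      bif_expect(tk, cur, "{")
      repeat {
        t <- bif_peek(tk, cur)
        if (is.na(t)) bif_error(tk, cur$i, "unterminated probability block")
        if (t == "}") {
          bif_next(tk, cur)
          break
        }
        if (t == "table") {
          bif_next(tk, cur)
          flat <- numeric(0)
          repeat {
            t2 <- bif_peek(tk, cur)
            if (is.na(t2)) bif_error(tk, cur$i, "unterminated table row")
            if (t2 == ";") {
              bif_next(tk, cur)
              break
            }
            if (t2 == ",") {
              bif_next(tk, cur)
              next
            }
            flat <- c(flat, bif_number(tk, cur))
          }
          if (length(flat) != r * q) {
            bif_error(tk, cur$i - 1L,
                      paste0("table for ", child, " has ", length(flat),
                             " values, expected ", r * q))
          }
          vals[] <- flat
        } else if (t == "(") {
          bif_next(tk, cur)
          cfg <- character(0)
          repeat {
            t2 <- bif_next(tk, cur)
            if (is.na(t2)) bif_error(tk, cur$i - 1L, "unterminated configuration")
            if (t2 == ")") break
            if (t2 != ",") cfg <- c(cfg, t2)
          }
          if (length(cfg) != length(pa)) {
            bif_error(tk, cur$i - 1L,
                      paste0("configuration arity mismatch for ", child))
          }
          col <- 1L
          mult <- 1L
          for (j in seq_along(pa)) {
            s <- match(cfg[j], levels[[pa[j]]])
            if (is.na(s)) {
              bif_error(tk, cur$i - 1L,
                        paste0("unknown state '", cfg[j], "' of ", pa[j]))
            }
            col <- col + (s - 1L) * mult
            mult <- mult * pc[j]
          }
          row_vals <- numeric(0)
          repeat {
            t2 <- bif_peek(tk, cur)
            if (is.na(t2)) bif_error(tk, cur$i, "unterminated probability row")
            if (t2 == ";") {
              bif_next(tk, cur)
              break
            }
            if (t2 == ",") {
              bif_next(tk, cur)
              next
            }
            row_vals <- c(row_vals, bif_number(tk, cur))
          }
          if (length(row_vals) != r) {
            bif_error(tk, cur$i - 1L,
                      paste0("probability row for ", child, " has ",
                             length(row_vals), " values, expected ", r))
          }
          vals[, col] <- row_vals
        } else {
          bif_error(tk, cur$i, paste0("unexpected token '", t,
                                      "' in probability block"))
        }
      }
      if (anyNA(vals)) {
        bif_error(tk, cur$i - 1L,
                  paste0("missing configuration row(s) for ", child))
      }
      sums <- colSums(vals)
      if (any(abs(sums - 1) > 1e-6)) {
        bif_error(tk, cur$i - 1L,
                  paste0("probability row for ", child, " sums to ",
                         format(sums[which.max(abs(sums - 1))])))
      }
      prob[[child]] <- list(parents = pa, values = vals)
    } else {
      bif_error(tk, cur$i - 1L, paste0("unexpected keyword '", kw, "'"))
    }
  }

  if (!length(order_seen)) stop("BIF parse error: no variables declared")
  missing_p <- setdiff(order_seen, names(prob))
  if (length(missing_p)) {
    stop("BIF parse error: no probability block for: ",
         paste(missing_p, collapse = ", "))
  }
  from <- character(0)
  to <- character(0)
  for (x in order_seen) {
    for (p in prob[[x]]$parents) {
      from <- c(from, p)
      to <- c(to, x)
    }
  }
  g <- dag(order_seen, from, to)   # errors on cyclic structure

  # re-index CPT columns from declared parent order to canonical order
  cpts <- lapply(order_seen, function(x) {
    pa_decl <- prob[[x]]$parents
    vals <- prob[[x]]$values
    pa_can <- bn_parents(g, x)
    if (length(pa_decl) <= 1L || identical(pa_decl, pa_can)) return(vals)
    pc_decl <- vapply(levels[pa_decl], length, 1L)
    cfgs <- as.matrix(expand.grid(lapply(pc_decl, seq_len)))
    col_can <- rep(1L, nrow(cfgs))
    mult <- 1L
    for (p in pa_can) {
      j <- match(p, pa_decl)
      col_can <- col_can + (cfgs[, j] - 1L) * mult
      mult <- mult * pc_decl[j]
    }
    out <- vals
    out[, col_can] <- vals
    out
  })
  names(cpts) <- order_seen
  bayesian_network(g, levels, cpts)
}
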