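#' Read and write plain-text edge lists
#'
#' The format is line-oriented: a header line `NODES: A,B,C` declares the
#' node universe (so isolated nodes survive round-trips), followed by one
#' `FROM<TAB>TO` pair per line.  Lines starting with `#` and blank lines
#' are ignored.  `read_edgelist(write_edgelist(g, path))` reproduces `g`
#' exactly, including node and edge storage order.
#'
#' @param g a [dag].
#' @param path file path.
#' @return `read_edgelist()` returns a [dag]; `write_edgelist()` returns
#'   `path` invisibly.
#' @export
write_edgelist <- function(g, path) {
  lines <- c(
    paste0("NODES: ", paste(g$nodes, collapse = ",")),
    paste(g$from, g$to, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty edge-list file: ", path)
  hdr <- grepl("^NODES:", lines)
  if (sum(hdr) != 1L) stop("expected exactly one 'NODES:' header line")
  nodes <- trimws(strsplit(sub("^NODES:", "", lines[hdr]), ",")[[1L]])
  nodes <- nodes[nzchar(nodes)]
  body <- lines[!hdr]
  if (!length(body)) return(dag(nodes))
  parts <- strsplit(body, "\t|[[:space:]]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed edge line(s): ", paste(body[bad], collapse = "; "))
  }
  dag(nodes,
      from = vapply(parts, `[`, "", 1L),
      to = vapply(parts, `[`, "", 2L))
}
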