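#' Complete discrete dataset
#'
#' A dataset of `N` complete records over `n` categorical variables with
#' known cardinalities.  States are stored internally as 1-based integer
#' indices; the mapping from state labels to indices is lexicographic by
#' label, so CSV round-trips are stable.
#'
#' @param x a data.frame whose columns are factors or character vectors
#'   (state labels), or an integer matrix of 1-based state indices when
#'   `levels` is supplied.
#' @param levels optional named list giving, per variable, the full state
#'   label universe.  Needed when a state never occurs in the data (every
#'   variable must have at least two states).
#' @return An object of class `discrete_dataset` with fields `m` (integer
#'   matrix, N x n), `vars`, `card` (named integer vector) and `levels`.
#' @examples
#' d <- discrete_dataset(data.frame(A = c("no", "yes"), B = c("no", "no")),
#'                       levels = list(A = c("no", "yes"), B = c("no", "yes")))
#' d$card
#' @export
discrete_dataset <- function(x, levels = NULL) {
  if (is.matrix(x)) {
    if (is.null(levels)) stop("matrix input requires explicit 'levels'")
    vars <- colnames(x)
    if (is.null(vars)) stop("matrix input requires column names")
    return(new_discrete_dataset(x, vars, levels[vars]))
  }
  if (!is.data.frame(x)) stop("expected a data.frame or integer matrix")
  if (nrow(x) < 1L) stop("dataset needs at least one record")
  if (anyNA(x)) stop("missing values are not supported")
  vars <- names(x)
  levs <- vector("list", length(vars))
  names(levs) <- vars
  m <- matrix(0L, nrow(x), length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    obs <- as.character(x[[v]])
    lv <- if (!is.null(levels) && !is.null(levels[[v]])) {
      as.character(levels[[v]])
    } else {
      sort(unique(obs))
    }
    idx <- match(obs, lv)
    if (anyNA(idx)) {
      stop("variable ", v, " has states outside its declared levels")
    }
    levs[[v]] <- lv
    m[, v] <- idx
  }
  new_discrete_dataset(m, vars, levs)
}

new_discrete_dataset <- function(m, vars, levels) {
  storage.mode(m) <- "integer"
  card <- vapply(levels, length, 1L)
  if (any(card < 2L)) {
    stop("every variable needs cardinality >= 2 (declare full 'levels' ",
         "for constant columns): ",
         paste(vars[card < 2L], collapse = ", "))
  }
  if (nrow(m) < 1L) stop("dataset needs at least one record")
  for (j in seq_along(vars)) {
    if (any(m[, j] < 1L | m[, j] > card[j])) {
      stop("state index out of range for variable ", vars[j])
    }
  }
  structure(list(m = m, vars = vars, card = card, levels = levels),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("discrete_dataset: %d records, %d variables\n",
              nrow(x$m), length(x$vars)))
  cat("  cardinalities:",
      paste(x$vars, x$card, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.discrete_dataset <- function(x, ...) {
  out <- as.data.frame(
    lapply(seq_along(x$vars), function(j) x$levels[[j]][x$m[, j]]),
    stringsAsFactors = FALSE
  )
  names(out) <- x$vars
  out
}

#' Dataset CSV input/output
#'
#' The CSV carries a header row of variable names and state labels as
#' cells.  On reading, state universes are inferred from the observed
#' labels (lexicographic order) unless `levels` declares them.
#'
#' @param ds a [discrete_dataset].
#' @param path file path.
#' @param levels optional named list of state label universes.
#' @export
write_dataset_csv <- function(ds, path) {
  write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, levels = NULL) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  discrete_dataset(df, levels = levels)
}
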